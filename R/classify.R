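#' Flat analysis parameter list
#'
#' One place holding every numeric constant of the analysis so each can
#' be discovered and overridden: the scoring scheme, the upstream window
#' (100 nt), the SL trimming rule (step 2, floor 7 nt), the per-length
#' detection threshold, the confident-match rule (score > 9 or end
#' offset <= 2), the hairpin stem rule (13 clip + 2 aligned bases, 12 of
#' 15 matches, 30-nt search window), and the gene-level thresholds
#' (10 discriminable reads for SL2 ratios with 0.60/0.40 bands, 20 reads
#' and 0.5 SL majority for gene calls, 100 reads and <10% SL for the
#' low-SL flag).
#'
#' @param ... overrides of any default.
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(...) {
  p <- list(
    max_window = 100L,
    match = 1, mismatch = -1, gap_open = -2, gap_extend = -2,
    threshold_offset = -4,       # T(L) = L + threshold_offset ...
    threshold_short_offset = -2, # ... but L + short_offset below:
    threshold_short_below = 14L,
    min_sl_len = 7L, trim_step = 2L, exhaust = FALSE,
    confident_min_score = 9, confident_max_offset = 2L,
    stem_clip_bases = 13L, stem_aligned_bases = 2L,
    hairpin_window = 30L, hairpin_min_match = 12L,
    min_discriminable = 10L, sl2_hi = 0.60, sl2_lo = 0.40,
    gene_min_reads = 20L, sl_majority = 0.5,
    lowsl_min_reads = 100L, lowsl_max_frac = 0.10,
    collapse_window = 0L,
    operon_max_distance = 200L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  structure(p, class = "pipeline_params")
}

params_scheme <- function(params) {
  scoring_scheme(params$match, params$mismatch,
                 params$gap_open, params$gap_extend)
}

params_threshold <- function(params) {
  off <- params$threshold_offset
  soff <- params$threshold_short_offset
  below <- params$threshold_short_below
  function(L) if (L >= below) L + off else L + soff
}

#' Classify every read by its 5'-end status
#'
#' The per-read core of the analysis: extract the upstream window, scan
#' the SL repertoire with the trimming semi-global aligner, keep the
#' confident detections (score > 9 or ending <= 2 nt from the alignment
#' start), and resolve ambiguity among them. Long soft-clips of hairpin
#' molecules contain enough antisense transcript sequence that short SL
#' truncations produce weak chance matches; gating the read class on the
#' confident-match rule keeps those from masking downstream calls while
#' every detection remains recorded. Antisense reads without a confident
#' SL are probed for an endogenous 5' hairpin (-13..+2 stem, reverse
#' complemented and locally aligned against the read's own aligned
#' prefix); the hairpin-negative remainder is `unidentified`. Sense
#' reads without a confident SL cannot be hairpin-probed and are
#' `sense_untested`.
#'
#' The hairpin stem is matched against the reference transcript at the
#' alignment start by default (`hairpin_target = "reference"`), because
#' the probe and the aligned prefix are distant parts of a single
#' sequencing pass whose errors are independent: matching read-side
#' doubles the error exposure of the 12-of-15 rule. Set
#' `hairpin_target = "read"` (or omit `transcripts`) to match against
#' the read's own aligned bases instead.
#'
#' @param reads data.frame from [load_alignments()].
#' @param repertoire named character vector of SL sequences.
#' @param params a [pipeline_params()].
#' @param sl1_primed the library used an SL1 second-strand primer: only
#'   antisense reads (first-strand cDNAs) contribute SL detections, to
#'   avoid false SL1 counts from heterologous primer binding.
#' @param transcripts named character vector of reference transcript
#'   sequences (needed for `hairpin_target = "reference"`).
#' @param hairpin_target match the reverse-complemented stem probe
#'   against the reference transcript (default) or the read's own
#'   aligned bases.
#' @return data.frame with one row per read: `read_id`, `ref_id`,
#'   `is_antisense`, `start_pos`, `class`, `sl_name`, `sl_family`,
#'   `score`, `trunc`, `matched_len`, `end_offset`, `confident`,
#'   `hp_matched_nt`.
#' @export
classify_reads <- function(reads, repertoire, params = pipeline_params(),
                           sl1_primed = FALSE, transcripts = NULL,
                           hairpin_target = c("reference", "read")) {
  hairpin_target <- match.arg(hairpin_target)
  if (hairpin_target == "reference" && is.null(transcripts)) {
    hairpin_target <- "read"
  }
  n <- nrow(reads)
  scheme <- params_scheme(params)
  plan <- sl_scan_plan(repertoire, params_threshold(params),
                       params$min_sl_len, params$trim_step)
  win <- upstream_windows(reads, params$max_window)$window

  cls <- character(n); sl_name <- rep(NA_character_, n)
  fam <- rep(NA_character_, n); score <- rep(NA_real_, n)
  trunc <- rep(NA_integer_, n); mlen <- rep(NA_integer_, n)
  eoff <- rep(NA_integer_, n); conf <- rep(NA, n)
  hp_nt <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    anti <- reads$is_antisense[i]
    det <- NULL
    if (!(sl1_primed && !anti)) {
      det <- detect_sl_planned(win[i], plan, scheme, params$exhaust)
    }
    confident_det <- NULL
    if (!is.null(det) && nrow(det$detections) > 0L) {
      dd <- det$detections
      keep <- is_confident(dd$score, dd$end_offset,
                           params$confident_min_score,
                           params$confident_max_offset)
      if (any(keep)) confident_det <- dd[keep, , drop = FALSE]
      # record the best detection even when not confident
      score[i] <- det$best$score; trunc[i] <- det$best$trunc
      mlen[i] <- det$best$matched_len; eoff[i] <- det$best$end_offset
      conf[i] <- FALSE
    }
    if (!is.null(confident_det)) {
      amb <- classify_ambiguity(confident_det)
      m <- amb$match
      cls[i] <- amb$class
      sl_name[i] <- amb$sl_name
      fam[i] <- if (amb$class == "SL.X") NA_character_ else m$family
      score[i] <- m$score; trunc[i] <- m$trunc
      mlen[i] <- m$matched_len; eoff[i] <- m$end_offset
      conf[i] <- TRUE
    } else if (anti) {
      probe <- extract_stem_probe(reads$seq[i], reads$clip5_len[i],
                                  params$stem_clip_bases,
                                  params$stem_aligned_bases)
      if (!is.na(probe)) {
        aligned <- if (hairpin_target == "reference") {
          tx <- transcripts[[reads$ref_id[i]]]
          substr(tx, reads$ref_start[i],
                 reads$ref_start[i] + params$hairpin_window - 1L)
        } else {
          substr(reads$seq[i], reads$clip5_len[i] + 1L,
                 nchar(reads$seq[i]) - reads$clip3_len[i])
        }
        hp <- detect_hairpin(probe, aligned, params$hairpin_window,
                             scheme, params$hairpin_min_match)
        hp_nt[i] <- hp$matched_nt
        cls[i] <- if (hp$is_hairpin) "endogenous_hairpin" else "unidentified"
      } else {
        cls[i] <- "unidentified"
      }
    } else {
      cls[i] <- "sense_untested"
    }
  }

  data.frame(read_id = reads$read_id, ref_id = reads$ref_id,
             is_antisense = reads$is_antisense,
             start_pos = reads$ref_start,
             class = cls, sl_name = sl_name, sl_family = fam,
             score = score, trunc = trunc, matched_len = mlen,
             end_offset = eoff, confident = conf,
             hp_matched_nt = hp_nt, stringsAsFactors = FALSE)
}
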