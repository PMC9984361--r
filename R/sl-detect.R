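#' Alignment scoring scheme
#'
#' Defaults (+1 match, -1 mismatch, -2 per gapped base) make k
#' substitutions in a length-L match score L - 2k, so the confidence
#' score thresholds read directly as mismatch budgets on a 22-nt SL.
#'
#' @param match,mismatch,gap_open,gap_extend numeric scores; a gap run of
#'   length k costs `gap_open + (k - 1) * gap_extend`.
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1,
                           gap_open = -2, gap_extend = -2) {
  if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
  if (gap_open > mismatch || gap_extend > mismatch)
    stop("gap penalties must be <= mismatch")
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Semi-global alignment (query global, target ends free)
#'
#' Aligns the query end-to-end against any stretch of the target, with no
#' penalty for unaligned target flanks. Score ties are broken toward the
#' smallest `target_end`.
#'
#' @param query,target DNA strings.
#' @param scheme a [scoring_scheme()].
#' @return list with `score` and `target_end` (1-based target coordinate
#'   of the query's 3' end); both `NA` when the target is empty.
#' @export
semiglobal_align <- function(query, target, scheme = scoring_scheme()) {
  if (!nzchar(target)) return(list(score = NA_real_, target_end = NA_integer_))
  .semiglobal_align_cpp(query, target, scheme$match, scheme$mismatch,
                        scheme$gap_open, scheme$gap_extend)
}

#' Default per-length detection threshold
#'
#' A truncated SL of length L is detected when its semi-global score
#' reaches `L - 4` (a two-substitution budget) for L >= 14, or `L - 2`
#' (one substitution) below 14. Short truncations placed freely in a
#' 100-nt window are weak evidence, so they get the tighter budget:
#' with a constant budget the required fractional identity would drop
#' from 91% at 22 nt to 75% at 8 nt and chance matches inside long
#' antisense soft-clips would masquerade as spliced leaders.
#'
#' @param L matched SL length.
#' @return numeric threshold.
#' @export
default_threshold <- function(L) if (L >= 14) L - 4 else L - 2

# SL family from the repertoire name: anything starting "SL2" is SL2,
# the rest SL1 (the repertoire naming convention)
sl_family <- function(sl_names) {
  ifelse(startsWith(sl_names, "SL2"), "SL2", "SL1")
}

# precompute the truncation lengths and thresholds of a repertoire scan
sl_scan_plan <- function(repertoire, threshold = default_threshold,
                         min_len = 7L, trim_step = 2L) {
  lens_list <- lapply(nchar(repertoire), function(L) {
    lens <- seq.int(L, min_len, by = -trim_step)
    as.integer(lens[lens >= min_len])
  })
  thr_list <- lapply(lens_list, function(lens)
    vapply(lens, threshold, numeric(1)))
  list(sls = unname(repertoire), names = names(repertoire),
       family = sl_family(names(repertoire)),
       full_len = nchar(repertoire),
       lens_list = lens_list, thr_list = thr_list)
}

#' Detect spliced leaders in a 5' upstream window
#'
#' Each SL of the repertoire is aligned semi-globally to the window; if
#' the score reaches the per-length threshold the SL is detected,
#' otherwise 2 nt are trimmed from the SL's 5' end and the scan repeats
#' until the truncated SL would fall below 7 nt, at which point that SL
#' is undetected. The best-scoring detection overall is returned together
#' with the full detection set (used for ambiguity classing).
#'
#' @param window upstream window sequence (reference orientation; offset
#'   0 abuts the alignment start).
#' @param repertoire named character vector of SL sequences.
#' @param scheme a [scoring_scheme()].
#' @param threshold function of the matched length L giving the detection
#'   threshold.
#' @param min_len stop trimming below this SL length.
#' @param trim_step nucleotides trimmed from the SL 5' end per round.
#' @param exhaust evaluate all truncations and keep the best passing one,
#'   instead of stopping at the first pass.
#' @return list with `best` (one-row data.frame: sl_name, family, score,
#'   trunc, matched_len, end_offset; or NULL) and `detections` (the same
#'   columns, one row per detected SL).
#' @export
detect_sl <- function(window, repertoire, scheme = scoring_scheme(),
                      threshold = default_threshold, min_len = 7L,
                      trim_step = 2L, exhaust = FALSE) {
  plan <- sl_scan_plan(repertoire, threshold, min_len, trim_step)
  detect_sl_planned(window, plan, scheme, exhaust)
}

detect_sl_planned <- function(window, plan, scheme, exhaust = FALSE) {
  empty <- data.frame(sl_name = character(0), family = character(0),
                      score = numeric(0), trunc = integer(0),
                      matched_len = integer(0), end_offset = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(window) || !nzchar(window)) return(list(best = NULL, detections = empty))
  sc <- .scan_repertoire_cpp(window, plan$sls, plan$lens_list, plan$thr_list,
                             scheme$match, scheme$mismatch,
                             scheme$gap_open, scheme$gap_extend,
                             first_stop = !exhaust)
  det <- which(sc$detected)
  if (!length(det)) return(list(best = NULL, detections = empty))
  d <- data.frame(sl_name = plan$names[det], family = plan$family[det],
                  score = sc$score[det],
                  trunc = plan$full_len[det] - sc$matched_len[det],
                  matched_len = sc$matched_len[det],
                  end_offset = nchar(window) - sc$target_end[det],
                  stringsAsFactors = FALSE)
  o <- order(-d$score, -d$matched_len, d$end_offset, d$sl_name)
  list(best = d[o[1], , drop = FALSE], detections = d[o, , drop = FALSE])
}

#' Resolve the read class from a detection set
#'
#' A unique best score names the SL. A best-score tie (at equal matched
#' length) spanning SL1 and SL2 is classed `SL.X`; a tie among several
#' SL2 variants only is classed `SL2.X`. Ties are first broken by the
#' larger matched length, then declared ambiguous.
#'
#' @param detections data.frame from [detect_sl()] (`detections`
#'   element); must have at least one row.
#' @return list with `class` (an SL name, `"SL.X"` or `"SL2.X"`),
#'   `sl_name` (`NA` when ambiguous) and `match` (the representative
#'   best-score row).
#' @export
classify_ambiguity <- function(detections) {
  stopifnot(nrow(detections) >= 1L)
  top <- detections[detections$score == max(detections$score), , drop = FALSE]
  if (nrow(top) > 1L)
    top <- top[top$matched_len == max(top$matched_len), , drop = FALSE]
  top <- top[order(top$end_offset, top$sl_name), , drop = FALSE]
  if (nrow(top) == 1L)
    return(list(class = top$sl_name, sl_name = top$sl_name,
                match = top[1, , drop = FALSE]))
  cls <- if (all(top$family == "SL2")) "SL2.X" else "SL.X"
  list(class = cls, sl_name = NA_character_, match = top[1, , drop = FALSE])
}

#' Confident SL match rule
#'
#' A match is confident when its alignment score is superior to
#' `min_score` (default 9) *or* it ends in the direct vicinity of the
#' alignment start (`end_offset <= max_offset`, default 2 nt). The
#' proximity clause keeps matches of poorly sequenced SL motifs that sit
#' exactly where a spliced leader is expected.
#'
#' @param score alignment score(s).
#' @param end_offset distance(s) from the match 3' end to the alignment
#'   start.
#' @param min_score,max_offset rule parameters.
#' @return logical vector.
#' @export
is_confident <- function(score, end_offset, min_score = 9, max_offset = 2) {
  score > min_score | end_offset <= max_offset
}
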