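#' Generate a synthetic reference (transcriptome, annotation, SLs)
#'
#' Lays out intronless genes on a single contig. Operonic downstream
#' genes sit ~`sl2_distance_mode` nt behind a same-strand neighbour (and
#' receive SL2 in the simulation); the remaining genes are isolated
#' (SL1), and `endogenous_hairpin_fraction` of the genes - always chosen
#' among the isolated ones - carry a 5' terminal hairpin instead of being
#' trans-spliced. Transcript sequences are rejection-sampled so that no
#' full SL (or its reverse complement) occurs in them, keeping detection
#' tests unambiguous. The transcriptome FASTA holds the genome-encoded
#' mRNA (the spliced leader is *not* part of the reference), so the gene
#' start is the trans-splice acceptor site.
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; when given, writes
#'   `transcriptome.fa`, `genes.gff3` and `sl.fa`.
#' @return list with `transcripts` (named character), `genes`
#'   (data.frame: gene_id, tx_id, class, sl_family, strand, start, end,
#'   is_downstream), `sls`, `contig`, `contig_len`, and `files` (paths or
#'   NULL).
#' @export
generate_reference <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ref <- with_seed(config$seed, build_reference(config))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(outdir, "transcriptome.fa")
    gff <- file.path(outdir, "genes.gff3")
    slfa <- file.path(outdir, "sl.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$transcripts),
                                fa, width = 80L)
    write_gff3(ref, gff)
    write_sl_fasta(ref$sls, slfa)
    ref$files <- list(transcriptome = fa, gff = gff, sl = slfa)
  }
  ref
}

build_reference <- function(config) {
  n <- config$n_genes
  n_down <- min(round(config$operon_fraction * n), n - 1L)
  n_hp <- round(config$endogenous_hairpin_fraction * n)
  n_isolated_single <- n - (if (n_down > 0L) n_down + 1L else 0L)
  if (n_hp > n_isolated_single)
    stop("impossible layout: not enough isolated genes to host ",
         n_hp, " endogenous-hairpin genes (operon_fraction too high)")

  # genes 2..(n_down+1) chain onto gene 1 as one operon block; the rest
  # are isolated singles. Hairpin genes take the last n_hp (isolated).
  is_chained <- c(FALSE, rep(TRUE, n_down), rep(FALSE, n - n_down - 1L))[seq_len(n)]
  gene_class <- rep("SL", n)
  if (n_hp > 0L) gene_class[seq.int(n - n_hp + 1L, n)] <- "hairpin"

  # strand: one draw per block
  block <- cumsum(!is_chained)
  block_strand <- sample(c("+", "-"), max(block), replace = TRUE)
  strand <- block_strand[block]

  lens <- as.integer(round(runif(n, config$transcript_len_range[1],
                                 config$transcript_len_range[2])))

  start <- integer(n); end <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    gap <- if (i == 1L) {
      as.integer(round(runif(1, config$intergenic_range[1],
                             config$intergenic_range[2])))
    } else if (is_chained[i]) {
      max(20L, as.integer(round(rnorm(1, config$sl2_distance_mode,
                                      config$operon_jitter_sd))))
    } else {
      as.integer(round(runif(1, config$intergenic_range[1],
                             config$intergenic_range[2])))
    }
    start[i] <- pos + gap + 1L
    end[i] <- start[i] + lens[i] - 1L
    pos <- end[i]
  }
  contig_len <- pos + 200L
  if (!is.null(config$contig_len) && contig_len > config$contig_len)
    stop("impossible layout: ", n, " genes need ", contig_len,
         " bp but contig_len is ", config$contig_len)

  # truth operon status from the realised layout: same-strand upstream
  # neighbour within 200 bp of the gene's 5' start
  is_downstream <- logical(n)
  for (i in seq_len(n)) {
    if (strand[i] == "+") {
      j <- i - 1L
      is_downstream[i] <- j >= 1L && strand[j] == strand[i] &&
        (start[i] - end[j] - 1L) <= 200L
    } else {
      j <- i + 1L
      is_downstream[i] <- j <= n && strand[j] == strand[i] &&
        (start[j] - end[i] - 1L) <= 200L
    }
  }
  sl_family <- ifelse(gene_class == "hairpin", NA_character_,
                      ifelse(is_downstream, "SL2", "SL1"))

  sls <- config$sl_repertoire
  transcripts <- character(n)
  for (i in seq_len(n)) {
    transcripts[i] <- sample_transcript(lens[i], gene_class[i] == "hairpin",
                                        sl_family[i], sls, config)
  }

  gene_id <- sprintf("g%03d", seq_len(n))
  tx_id <- paste0(gene_id, ".t1")
  names(transcripts) <- tx_id

  list(transcripts = transcripts,
       genes = data.frame(gene_id = gene_id, tx_id = tx_id,
                          class = gene_class, sl_family = sl_family,
                          strand = strand, start = start, end = end,
                          length = lens, is_downstream = is_downstream,
                          stringsAsFactors = FALSE),
       sls = sls, contig = config$contig, contig_len = contig_len,
       files = NULL)
}

# rejection-sample one transcript; hairpin transcripts get the terminal
# stem t[1..2] = GG, t[12..13] = CC (revcomp of the start) so the -13..+2
# probe matches perfectly at zero noise. Rejection rules: (a) no full SL
# or its reverse complement occurs in the transcript; (b) the canonical
# zero-noise upstream window of the gene's artifact reads yields no
# spurious confident SL detection under the default detection
# parameters, so zero-noise classification is unambiguous.
sample_transcript <- function(len, hairpin, family, sls, config) {
  pats <- c(sls, revcomp(sls))
  scheme <- scoring_scheme()
  plan <- sl_scan_plan(sls)
  repeat {
    s <- random_dna(len)
    if (hairpin) {
      ch <- strsplit(s, "")[[1]]
      ch[1:2] <- c("G", "G")
      stem <- config$hairpin_stem_offset
      ch[(stem - 1L):stem] <- c("C", "C")
      s <- paste(ch, collapse = "")
    }
    hit <- any(vapply(pats, function(p) grepl(p, s, fixed = TRUE), logical(1)))
    if (hit) next
    if (clean_zero_noise_windows(s, hairpin, family, sls, config,
                                 plan, scheme)) return(s)
  }
}

# check the canonical err = 0 windows of a candidate transcript: every
# shorter-copy window is a suffix of the canonical one, so a clean
# canonical window implies clean windows for all copy lengths
clean_zero_noise_windows <- function(s, hairpin, family, sls, config,
                                     plan, scheme) {
  conf_class <- function(window) {
    det <- detect_sl_planned(window, plan, scheme)
    if (nrow(det$detections) == 0L) return(NA_character_)
    dd <- det$detections
    keep <- is_confident(dd$score, dd$end_offset)
    if (!any(keep)) return(NA_character_)
    classify_ambiguity(dd[keep, , drop = FALSE])$class
  }
  if (hairpin) {
    d <- config$hairpin_stem_offset
    win <- revcomp(substr(s, d + 1L, min(nchar(s), d + 100L)))
    return(is.na(conf_class(win)))
  }
  d <- config$sl_foldback_offset
  for (nm in names(sls)[sl_family(names(sls)) == family]) {
    sl <- sls[[nm]]
    asl <- revcomp(substr(sl, d + 1L, nchar(sl)))
    room <- 100L - nchar(sl) - nchar(asl)
    win <- paste0(revcomp(substr(s, 1L, max(0L, room))), asl, sl)
    win <- substr(win, max(1L, nchar(win) - 99L), nchar(win))
    if (!identical(conf_class(win), nm)) return(FALSE)
  }
  TRUE
}

write_gff3 <- function(ref, path) {
  g <- ref$genes
  lines <- c("##gff-version 3",
             paste("##sequence-region", ref$contig, 1L, ref$contig_len))
  for (i in seq_len(nrow(g))) {
    lines <- c(lines,
      paste(ref$contig, "clipsl_sim", "gene", g$start[i], g$end[i], ".",
            g$strand[i], ".",
            paste0("ID=", g$gene_id[i], ";Name=", g$gene_id[i],
                   ";biotype=protein_coding"),
            sep = "\t"),
      paste(ref$contig, "clipsl_sim", "mRNA", g$start[i], g$end[i], ".",
            g$strand[i], ".",
            paste0("ID=", g$tx_id[i], ";Parent=", g$gene_id[i]),
            sep = "\t"))
  }
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
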