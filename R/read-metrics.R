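#' Strand bias of a set of alignments
#'
#' Sense/antisense read counts and fractions. Against a transcriptome
#' reference an antisense read is one that was reverse-complemented
#' during mapping (a first-strand cDNA).
#'
#' @param reads data.frame from [load_alignments()] (needs
#'   `is_antisense`).
#' @return one-row data.frame: `n_sense`, `n_antisense`, `sense_frac`,
#'   `antisense_frac` (fractions are `NA` when there are no reads).
#' @export
strand_bias <- function(reads) {
  n_anti <- sum(reads$is_antisense)
  n_sense <- nrow(reads) - n_anti
  n <- n_sense + n_anti
  data.frame(n_sense = n_sense, n_antisense = n_anti,
             sense_frac = if (n > 0) n_sense / n else NA_real_,
             antisense_frac = if (n > 0) n_anti / n else NA_real_)
}

#' Soft-clip length summary
#'
#' Order statistics and a histogram of 5' (or 3') soft-clip lengths.
#'
#' @param reads data.frame from [load_alignments()].
#' @param which `"5p"` or `"3p"`.
#' @return list with `summary` (one-row data.frame: n, median, q1, q3,
#'   mean, max) and `histogram` (data.frame length/count).
#' @export
softclip_stats <- function(reads, which = c("5p", "3p")) {
  which <- match.arg(which)
  x <- if (which == "5p") reads$clip5_len else reads$clip3_len
  if (length(x) == 0L) {
    return(list(summary = data.frame(n = 0L, median = NA_real_,
                                     q1 = NA_real_, q3 = NA_real_,
                                     mean = NA_real_, max = NA_integer_),
                histogram = data.frame(length = integer(0), count = integer(0))))
  }
  tab <- table(x)
  list(summary = data.frame(n = length(x),
                            median = as.numeric(median(x)),
                            q1 = as.numeric(quantile(x, 0.25)),
                            q3 = as.numeric(quantile(x, 0.75)),
                            mean = mean(x), max = max(x)),
       histogram = data.frame(length = as.integer(names(tab)),
                              count = as.integer(tab)))
}

#' Positional mean base-quality profile around the alignment start
#'
#' For every read each base is assigned an offset relative to the
#' alignment start (first aligned base = offset 0; soft-clip bases get
#' negative offsets), and the mean PHRED score is computed per offset
#' over all (or a seeded random subsample of) reads. This reproduces the
#' base-quality step between the low-quality 5' soft-clip and the aligned
#' portion of hairpin-artifact reads.
#'
#' @param reads data.frame from [load_alignments()].
#' @param offset_range integer vector of length 2, offsets to report.
#' @param sample_n optional cap on the number of reads used (seeded
#'   uniform subsample when exceeded).
#' @param seed seed for the subsample.
#' @param antisense_only restrict to antisense reads.
#' @return data.frame with `offset`, `mean_q` (`NA` where no base was
#'   observed), `n`.
#' @export
quality_profile <- function(reads, offset_range = c(-600L, 600L),
                            sample_n = NULL, seed = 1L,
                            antisense_only = FALSE) {
  if (antisense_only) reads <- reads[reads$is_antisense, , drop = FALSE]
  nr <- nrow(reads)
  if (!is.null(sample_n) && nr > sample_n) {
    idx <- with_seed(seed, sample.int(nr, sample_n))
    reads <- reads[sort(idx), , drop = FALSE]
    nr <- nrow(reads)
  }
  lo <- offset_range[1]; hi <- offset_range[2]
  width <- hi - lo + 1L
  sums <- numeric(width)
  counts <- integer(width)
  for (i in seq_len(nr)) {
    q <- phred_to_int(reads$qual[i])
    if (!length(q)) next
    offs <- seq_along(q) - reads$clip5_len[i] - 1L
    sel <- offs >= lo & offs <= hi
    if (!any(sel)) next
    idx <- offs[sel] - lo + 1L
    sums[idx] <- sums[idx] + q[sel]
    counts[idx] <- counts[idx] + 1L
  }
  data.frame(offset = lo:hi,
             mean_q = ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_),
             n = counts)
}
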