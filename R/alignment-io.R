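#' Load transcriptomic alignments as reference-oriented records
#'
#' Parses a SAM or BAM file of long-read cDNA alignments against a
#' transcriptome. Only primary alignments are kept by default
#' (secondary/supplementary records are dropped but counted); unmapped
#' records and records without a quality string are skipped and counted;
#' hard-clipped primaries are rejected with a warning because soft-clip
#' mining needs the full read sequence. SAM stores the sequence of a
#' reverse-mapped read already reverse-complemented into reference
#' orientation, so `seq`/`qual` are reference-oriented as stored and the
#' leading/trailing soft-clip lengths are the 5'/3' clips in reference
#' orientation. A read is antisense when it was reverse-flagged during
#' mapping against the (5'->3') transcript reference.
#'
#' @param path SAM or BAM file.
#' @param primary_only drop secondary and supplementary records
#'   (default TRUE).
#' @param min_mapq minimum MAPQ to keep (default 0 = no filter; the
#'   analysis applies no MAPQ filter unless asked).
#' @return data.frame with one row per kept alignment: `read_id`,
#'   `ref_id`, `is_antisense`, `ref_start`, `ref_end` (1-based,
#'   inclusive), `seq`, `qual` (reference orientation), `clip5_len`,
#'   `clip3_len`, `aligned_len` (read bases in the aligned block),
#'   `mapq`. Filter tallies are attached as `attr(x, "filter_counts")`.
#' @export
load_alignments <- function(path, primary_only = TRUE, min_mapq = 0L) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]

  flag <- res$flag
  n_total <- length(flag)
  counts <- c(total = n_total, emitted = 0L, unmapped = 0L,
              secondary_supplementary = 0L, hard_clipped = 0L,
              missing_quality = 0L, low_mapq = 0L)
  if (n_total == 0L) {
    out <- empty_alignments()
    attr(out, "filter_counts") <- counts
    return(out)
  }

  seqs <- as.character(res$seq)
  quals <- as.character(res$qual)
  cigar <- res$cigar

  unmapped <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  keep <- !unmapped
  counts["unmapped"] <- sum(unmapped)
  if (primary_only) {
    counts["secondary_supplementary"] <- sum(secondary & keep)
    keep <- keep & !secondary
  }
  hard <- keep & grepl("H", cigar, fixed = TRUE)
  if (any(hard)) {
    warning(sum(hard), " hard-clipped primary record(s) rejected; ",
            "soft-clip mining requires the full read sequence")
    counts["hard_clipped"] <- sum(hard)
    keep <- keep & !hard
  }
  # Rsamtools renders a missing QUAL ("*") as an all-space string
  noq <- keep & (is.na(quals) | quals == "*" | !nzchar(quals) |
                   grepl("^ +$", quals))
  counts["missing_quality"] <- sum(noq)
  keep <- keep & !noq
  if (min_mapq > 0L) {
    lowq <- keep & res$mapq < min_mapq
    counts["low_mapq"] <- sum(lowq)
    keep <- keep & !lowq
  }
  counts["emitted"] <- sum(keep)

  cg <- cigar[keep]
  clip5 <- rep(0L, length(cg))
  has5 <- grepl("^[0-9]+S", cg)
  clip5[has5] <- as.integer(sub("^([0-9]+)S.*$", "\\1", cg[has5]))
  clip3 <- rep(0L, length(cg))
  has3 <- grepl("[0-9]+S$", cg)
  clip3[has3] <- as.integer(sub("^(.*[^0-9])?([0-9]+)S$", "\\2", cg[has3]))
  refw <- cigar_ref_width(cg)

  out <- data.frame(
    read_id = res$qname[keep],
    ref_id = as.character(res$rname[keep]),
    is_antisense = bitwAnd(flag[keep], 16L) > 0L,
    ref_start = res$pos[keep],
    ref_end = res$pos[keep] + refw - 1L,
    seq = seqs[keep],
    qual = quals[keep],
    clip5_len = clip5,
    clip3_len = clip3,
    aligned_len = nchar(seqs[keep]) - clip5 - clip3,
    mapq = res$mapq[keep],
    stringsAsFactors = FALSE)
  attr(out, "filter_counts") <- counts
  out
}

empty_alignments <- function() {
  data.frame(read_id = character(0), ref_id = character(0),
             is_antisense = logical(0), ref_start = integer(0),
             ref_end = integer(0), seq = character(0), qual = character(0),
             clip5_len = integer(0), clip3_len = integer(0),
             aligned_len = integer(0), mapq = integer(0),
             stringsAsFactors = FALSE)
}

# reference-space width of CIGAR strings (M/D/N/=/X consume reference)
cigar_ref_width <- function(cg) {
  vapply(cg, function(x) {
    ops <- regmatches(x, gregexpr("[0-9]+[MIDNSHP=X]", x))[[1]]
    if (!length(ops)) return(0L)
    len <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Extract the 5' upstream windows of alignments
#'
#' Returns, for each record, the last `min(clip5_len, max_len)` soft-clip
#' bases in reference orientation - the bases immediately upstream of the
#' alignment start, where a spliced leader is expected to end. Offset 0
#' is the position abutting the alignment start.
#'
#' @param reads data.frame from [load_alignments()] (needs `seq`, `qual`,
#'   `clip5_len`).
#' @param max_len maximum window length (default 100 nt).
#' @return data.frame with `window` and `wqual` (empty strings when
#'   `clip5_len == 0`).
#' @export
upstream_windows <- function(reads, max_len = 100L) {
  w <- pmin(reads$clip5_len, max_len)
  start <- reads$clip5_len - w + 1L
  data.frame(window = substr(reads$seq, start, reads$clip5_len),
             wqual = substr(reads$qual, start, reads$clip5_len),
             stringsAsFactors = FALSE)
}

#' @rdname upstream_windows
#' @param seq,qual,clip5_len fields of a single alignment record.
#' @export
extract_upstream_window <- function(seq, qual, clip5_len, max_len = 100L) {
  w <- min(clip5_len, max_len)
  start <- clip5_len - w + 1L
  list(window = substr(seq, start, clip5_len),
       wqual = substr(qual, start, clip5_len),
       offset0 = clip5_len)
}
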