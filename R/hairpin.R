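#' Extract the -13..+2 stem probe of a read
#'
#' The potential complementary stem of an endogenous 5' hairpin spans
#' positions -13 to +2 relative to the alignment start: the last 13
#' soft-clip bases plus the first 2 aligned bases (reference
#' orientation), 15 nt in total. `NA` when the 5' clip is shorter than
#' 13 nt or fewer than 2 aligned bases exist.
#'
#' @param seq reference-oriented read sequence.
#' @param clip5_len 5' soft-clip length.
#' @param clip_bases,aligned_bases probe composition (13 + 2 by default).
#' @return the probe string or `NA_character_`.
#' @export
extract_stem_probe <- function(seq, clip5_len, clip_bases = 13L,
                               aligned_bases = 2L) {
  if (clip5_len < clip_bases) return(NA_character_)
  if (nchar(seq) < clip5_len + aligned_bases) return(NA_character_)
  substr(seq, clip5_len - clip_bases + 1L, clip5_len + aligned_bases)
}

#' Call an endogenous 5' hairpin from a stem probe
#'
#' The probe is reverse complemented and aligned locally (gapped) against
#' the first `window_w` aligned bases of the read itself, so sequencing
#' errors affect both sides of the molecule consistently. The hairpin is
#' validated when at least `min_match` of the probe's 15 nt land on
#' identity columns of the best local alignment.
#'
#' @param probe 15-nt probe from [extract_stem_probe()].
#' @param aligned_seq the aligned read bases (reference orientation).
#' @param window_w how many 5'-terminal aligned bases to search
#'   (terminal hairpins are terminal; default 30).
#' @param scheme a [scoring_scheme()].
#' @param min_match identity columns required (default 12 of 15).
#' @return list of class `hairpin_call`: `is_hairpin`, `matched_nt`,
#'   `probe`, `stem_target_span` (1-based span within the aligned
#'   prefix, `c(0, 0)` for an empty alignment).
#' @export
detect_hairpin <- function(probe, aligned_seq, window_w = 30L,
                           scheme = scoring_scheme(), min_match = 12L) {
  stopifnot(!is.na(probe), nzchar(probe))
  target <- substr(aligned_seq, 1L, min(window_w, nchar(aligned_seq)))
  if (!nzchar(target)) {
    return(structure(list(is_hairpin = FALSE, matched_nt = 0L,
                          probe = probe, stem_target_span = c(0L, 0L)),
                     class = "hairpin_call"))
  }
  res <- .local_align_cpp(revcomp(probe), target, scheme$match,
                          scheme$mismatch, scheme$gap_open,
                          scheme$gap_extend)
  structure(list(is_hairpin = res$matches >= min_match,
                 matched_nt = as.integer(res$matches),
                 probe = probe,
                 stem_target_span = c(res$target_start, res$target_end)),
            class = "hairpin_call")
}
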