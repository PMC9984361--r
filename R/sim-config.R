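#' Default synthetic spliced-leader repertoire
#'
#' Twelve 22-nt sequences (one SL1, eleven SL2 variants) carrying the
#' SL1-like structural motif: a 5' GG dinucleotide and a CCC triplet at
#' positions 11-13, which is the self-complementarity that drives the
#' hairpin-cDNA library artifact. The sequences are synthetic (pairwise
#' Hamming distance >= 10) so that detection tests are unambiguous; any
#' real repertoire can be supplied as a FASTA instead.
#'
#' @return named character vector of SL sequences.
#' @export
sl_repertoire_default <- function() {
  c(SL1     = "GGAAAAAAGCCCCGGTTCGACT",
    SL2.1   = "GGAGAGGACCCCCAAAATCGCA",
    SL2.2   = "GGCTGAACCTCCCTCATGGTGC",
    SL2.3   = "GGTGTAAGTCCCCGACCTGAGT",
    SL2.4   = "GGTCACAAGACCCACGACGTAT",
    SL2.5   = "GGCGCAGGAGCCCAGTTTCAGC",
    SL2.6   = "GGCCAGCCCCCCCTCCGCGTCT",
    SL2.7   = "GGGGTCGGATCCCCCTCTATAC",
    SL2.8   = "GGTCTGGACGCCCTAACGCTAC",
    SL2.9   = "GGTTCATTTGCCCACAGAGGTT",
    SL2.10  = "GGACTGCATCCCCAGCCACACC",
    SL2.11  = "GGGTAGAATACCCGCCGGCAGG")
}

#' Default per-SL sampling weights
#'
#' SL1 carries 93% of the trans-spliced reads; the SL2 family carries the
#' remaining 7%, within which SL2.1 accounts for 21% and SL2.8 for 15%,
#' the other nine variants sharing the rest evenly.
#'
#' @param sl_names names of the repertoire (defaults to
#'   [sl_repertoire_default()]).
#' @return named numeric vector summing to 1.
#' @export
sl_weights_default <- function(sl_names = names(sl_repertoire_default())) {
  w <- numeric(length(sl_names))
  names(w) <- sl_names
  is2 <- startsWith(sl_names, "SL2")
  w[!is2] <- 0.93 / sum(!is2)
  w2 <- rep((1 - 0.21 - 0.15) / (sum(is2) - 2), sum(is2))
  names(w2) <- sl_names[is2]
  if ("SL2.1" %in% names(w2)) w2["SL2.1"] <- 0.21
  if ("SL2.8" %in% names(w2)) w2["SL2.8"] <- 0.15
  w[is2] <- 0.07 * w2 / sum(w2)
  w / sum(w)
}

#' Simulation configuration
#'
#' Parameters of the synthetic direct-cDNA experiment. The defaults are
#' the study conditions the simulator is meant to emulate: a strongly
#' antisense library (95% self-primed hairpin cDNAs), a base-quality step
#' between the aligned first strand (Q ~ 14, ~5% error) and the fold-back
#' second strand (Q ~ 7, ~15% error), second-strand copies of 200-600 nt
#' giving long 5' soft-clips, ~100 nt spacing for operonic (SL2) genes,
#' and an endogenous-hairpin gene fraction of 12.5%.
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical outputs.
#' @param n_genes number of genes to simulate.
#' @param operon_fraction fraction of genes placed as downstream operon
#'   members (<= 200 bp behind a same-strand neighbour).
#' @param sl2_distance_mode target spacing (nt) between an operonic gene
#'   and its upstream neighbour.
#' @param operon_jitter_sd SD (nt) of the operonic spacing.
#' @param endogenous_hairpin_fraction fraction of genes whose mRNAs carry
#'   a 5' self-complementary stem instead of a spliced leader.
#' @param hairpin_artifact_prob probability that a cDNA self-primes into a
#'   hairpin molecule and is read antisense.
#' @param err_first_strand,err_second_strand per-base total error rates
#'   (substitutions + indels) on the first-strand (aligned) and fold-back
#'   second-strand segments; `err_second_strand >= err_first_strand`.
#' @param err_composition proportions of substitution / insertion /
#'   deletion among errors (named numeric, sums to 1).
#' @param q_aligned,q_softclip mean emitted PHRED per segment
#'   (`q_aligned > q_softclip`).
#' @param q_sd SD of the per-base PHRED draw (clamped to `[2, 41]`).
#' @param reads_per_gene Poisson mean of the per-gene read count.
#' @param sl_weights named per-SL sampling weights; renormalised within
#'   the family dictated by each gene's layout (operonic downstream gene
#'   -> SL2, isolated gene -> SL1).
#' @param sl_repertoire named character vector of SL sequences.
#' @param transcript_len_range uniform range of transcript body lengths.
#' @param copy_len_range uniform range of second-strand copy lengths
#'   (controls the 5' soft-clip length distribution).
#' @param sl_foldback_offset position within the SL after which the
#'   second-strand copy starts (the 2-bp GG:CC fold-back pairs just after
#'   the central CCC; the copied antisense SL fragment has length
#'   `nchar(SL) - sl_foldback_offset`).
#' @param hairpin_stem_offset transcript position after which the
#'   second-strand copy of an endogenous-hairpin molecule starts; hairpin
#'   transcripts are built with `t[12..13] == revcomp(t[1..2])` so the
#'   stem probe matches 15/15 at zero noise.
#' @param polya_len length of the polyA tail.
#' @param intergenic_range uniform range of non-operonic intergenic gaps.
#' @param contig name of the simulated contig.
#' @param contig_len optional maximum contig length; the layout fails
#'   explicitly if the genes do not fit.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 60L,
                       operon_fraction = 0.15,
                       sl2_distance_mode = 100,
                       operon_jitter_sd = 10,
                       endogenous_hairpin_fraction = 0.125,
                       hairpin_artifact_prob = 0.95,
                       err_first_strand = 0.05,
                       err_second_strand = 0.15,
                       err_composition = c(sub = 0.4, ins = 0.3, del = 0.3),
                       q_aligned = 14,
                       q_softclip = 7,
                       q_sd = 3,
                       reads_per_gene = 50,
                       sl_weights = sl_weights_default(names(sl_repertoire)),
                       sl_repertoire = sl_repertoire_default(),
                       transcript_len_range = c(700L, 1200L),
                       copy_len_range = c(200L, 600L),
                       sl_foldback_offset = 13L,
                       hairpin_stem_offset = 13L,
                       polya_len = 30L,
                       intergenic_range = c(500L, 3000L),
                       contig = "simtig1",
                       contig_len = NULL) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              operon_fraction = operon_fraction,
              sl2_distance_mode = sl2_distance_mode,
              operon_jitter_sd = operon_jitter_sd,
              endogenous_hairpin_fraction = endogenous_hairpin_fraction,
              hairpin_artifact_prob = hairpin_artifact_prob,
              err_first_strand = err_first_strand,
              err_second_strand = err_second_strand,
              err_composition = err_composition,
              q_aligned = q_aligned, q_softclip = q_softclip, q_sd = q_sd,
              reads_per_gene = reads_per_gene,
              sl_weights = sl_weights, sl_repertoire = sl_repertoire,
              transcript_len_range = as.integer(transcript_len_range),
              copy_len_range = as.integer(copy_len_range),
              sl_foldback_offset = as.integer(sl_foldback_offset),
              hairpin_stem_offset = as.integer(hairpin_stem_offset),
              polya_len = as.integer(polya_len),
              intergenic_range = as.integer(intergenic_range),
              contig = contig, contig_len = contig_len)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$operon_fraction, cfg$endogenous_hairpin_fraction,
             cfg$hairpin_artifact_prob, cfg$err_first_strand,
             cfg$err_second_strand)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$err_second_strand < cfg$err_first_strand)
    stop("err_second_strand must be >= err_first_strand")
  if (!(cfg$q_aligned > cfg$q_softclip))
    stop("q_aligned must exceed q_softclip (base-quality step)")
  if (abs(sum(cfg$err_composition) - 1) > 1e-8 ||
      !all(c("sub", "ins", "del") %in% names(cfg$err_composition)))
    stop("err_composition must be named sub/ins/del and sum to 1")
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  reps <- cfg$sl_repertoire
  if (anyDuplicated(names(reps))) stop("SL names must be unique")
  if (any(nchar(reps) < 7L)) stop("each SL sequence must be >= 7 nt")
  if (!all(names(cfg$sl_weights) %in% names(reps)))
    stop("sl_weights names must match the SL repertoire")
  if (any(cfg$sl_weights < 0)) stop("sl_weights must be non-negative")
  if (cfg$sl_foldback_offset >= min(nchar(reps)))
    stop("sl_foldback_offset must be smaller than the shortest SL")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes, seed", x$seed, "\n")
  cat("  hairpin_artifact_prob", x$hairpin_artifact_prob,
      "| operon_fraction", x$operon_fraction,
      "| endogenous_hairpin_fraction", x$endogenous_hairpin_fraction, "\n")
  cat("  err first/second", x$err_first_strand, "/", x$err_second_strand,
      "| Q aligned/softclip", x$q_aligned, "/", x$q_softclip, "\n")
  invisible(x)
}

#' Read an SL repertoire FASTA
#'
#' @param path FASTA file of SL sequences.
#' @return named character vector.
#' @export
read_sl_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

write_sl_fasta <- function(sls, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sls), path, width = 80L)
  invisible(path)
}
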