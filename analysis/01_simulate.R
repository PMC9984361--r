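#!/usr/bin/env Rscript

# Step 1 - simulate the direct-cDNA experiment.
#
# Generates a synthetic transcriptome with operon structure, an SL
# repertoire, and ~10,000 long cDNA reads reproducing the self-primed
# hairpin library artifact (antisense dominance, long low-quality 5'
# soft-clips carrying SL + partial antisense SL + a sense-strand copy),
# together with per-read ground truth and oracle SAM alignments.
# Downstream steps consume only the emitted files, exactly as they would
# consume a real alignment of SRA reads against a transcriptome.

library(clipsl)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
outdir <- file.path("results", "sim")

cfg <- sim_config(seed = seed, n_genes = 50L, reads_per_gene = 200)
cat("Simulating with study-condition defaults:\n")
print(cfg)

run <- simulate_run(cfg, outdir)
tr <- run$reads$truth

cat(sprintf("\n%d reads over %d genes -> %s\n", nrow(tr), cfg$n_genes, outdir))
cat(sprintf("  antisense (hairpin-cDNA) reads: %.1f%%\n",
            100 * mean(tr$is_antisense)))
cat(sprintf("  endogenous-hairpin truth reads: %.1f%%\n",
            100 * mean(tr$true_class == "endogenous_hairpin")))
cat("  files:", paste(basename(unlist(run$files)), collapse = ", "), "\n")
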