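#!/usr/bin/env Rscript

# Step 3 - per-read 5'-end classification.
#
# For every read: search the 100-nt window upstream of the alignment
# start for each SL of the repertoire (semi-global alignment with
# progressive 5' trimming), keep confident matches (score > 9 or ending
# within 2 nt of the alignment start), resolve SL.X / SL2.X ambiguity,
# and probe SL-negative antisense reads for an endogenous 5' hairpin
# (the -13..+2 stem, reverse complemented, 12-of-15 rule). Reports the
# classification table, SL variant usage, and recovery against the
# simulation truth.

library(clipsl)

simdir <- file.path("results", "sim")
outdir <- file.path("results", "classification")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

reads <- load_alignments(file.path(simdir, "alignments.sam"))
sls <- read_sl_fasta(file.path(simdir, "sl.fa"))
tx <- Biostrings::readDNAStringSet(file.path(simdir, "transcriptome.fa"))
transcripts <- structure(as.character(tx), names = names(tx))

cl <- classify_reads(reads, sls, transcripts = transcripts)
write.table(cl, file.path(outdir, "classification.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Read classes:\n")
cls <- ifelse(cl$class %in% c("endogenous_hairpin", "unidentified",
                              "sense_untested", "SL.X", "SL2.X"),
              cl$class, "SL (specific)")
print(table(cls))

usage <- sl_variant_usage(cl)
write.table(usage, file.path(outdir, "variant_usage.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nSL1 carries %.1f%% of confident SL reads\n",
            100 * sum(usage$frac[usage$family == "SL1"])))
top2 <- usage[usage$family == "SL2" & usage$sl_name != "SL2.X", ]
top2 <- top2[order(-top2$n), ][1:2, ]
cat(sprintf("Top SL2 variants within the family: %s %.0f%%, %s %.0f%%\n",
            top2$sl_name[1], 100 * top2$frac_within_sl2[1],
            top2$sl_name[2], 100 * top2$frac_within_sl2[2]))

truth <- read.delim(file.path(simdir, "truth.tsv"))
tm <- truth[match(cl$read_id, truth$read_id), ]
anti <- tm$artifact == "hairpin_cDNA_antisense"
slr <- anti & tm$true_class != "endogenous_hairpin"
hpr <- anti & tm$true_class == "endogenous_hairpin"
fam <- ifelse(startsWith(tm$true_class, "SL2"), "SL2", "SL1")
cat(sprintf("\nRecovery vs truth: %.1f%% SL family, %.1f%% hairpin reads\n",
            100 * mean(!is.na(cl$sl_family[slr]) &
                       cl$sl_family[slr] == fam[slr]),
            100 * mean(cl$class[hpr] == "endogenous_hairpin")))
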