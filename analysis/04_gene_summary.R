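#!/usr/bin/env Rscript

# Step 4 - gene-level trans-splicing summary.
#
# Aggregates the read classification per (gene, start position),
# computes SL2/SL1 ratios at discriminable sites and relates them to the
# distance to the closest upstream coding gene (operonic genes ~100 nt
# downstream of their neighbour are SL2-favored), classifies genes as
# trans-spliced / hairpin / unidentified at their dominant start, flags
# well-expressed genes with <10% SL detection (the endogenous-hairpin
# candidates), and writes a per-gene start-site report.

library(clipsl)

simdir <- file.path("results", "sim")
clsdir <- file.path("results", "classification")
outdir <- file.path("results", "genes")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cl <- read.delim(file.path(clsdir, "classification.tsv"))
ann <- read_gene_annotation(file.path(simdir, "genes.gff3"))

sites <- aggregate_start_sites(cl, ann)
write.table(sites, file.path(outdir, "start_sites.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

st <- sl2_site_table(sites)
gc <- classify_gene(sites, ann)
write.table(st, file.path(outdir, "sl2_sites.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(gc, file.path(outdir, "gene_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

called <- gc[gc$status != "low_coverage", ]
cat(sprintf("%d/%d genes have >= 20 reads; %.1f%% are mostly trans-spliced\n",
            nrow(called), nrow(gc),
            100 * mean(called$status == "trans_spliced")))

sl2_fav <- st[st$sl2_category == "SL2", ]
ud <- gc$upstream_distance[match(sl2_fav$gene_id, gc$gene_id)]
cat(sprintf("%d SL2-favored sites; median upstream distance %.0f nt; %.0f%% within 200 nt\n",
            nrow(sl2_fav), median(ud, na.rm = TRUE),
            100 * mean(!is.na(ud) & ud <= 200)))

sw <- classify_gene_sweep(sites)
write.table(sw, file.path(outdir, "threshold_sweep.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

flagged <- flag_low_sl_genes(sites)
cat(sprintf("%d genes flagged as well-expressed with <10%% SL detection\n",
            length(flagged)))
writeLines(flagged, file.path(outdir, "low_sl_genes.txt"))

# per-gene start-site map for the first flagged (hairpin-like) gene
gene <- if (length(flagged)) flagged[1] else gc$gene_id[1]
rep <- start_site_report(sites, gene, ann)
write.table(rep, file.path(outdir, paste0("start_sites_", gene, ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_start_site_bed(rep, "simtig1",
                     file.path(outdir, paste0("start_sites_", gene, ".bed")))
cat("Example start-site report written for", gene, "\n")
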