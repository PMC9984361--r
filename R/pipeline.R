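#' Run the full soft-clip analysis on an alignment file
#'
#' Orchestrates the analysis stages: load alignments, read-level metrics
#' (strand bias, soft-clip stats, quality profile), per-read SL/hairpin
#' classification, and gene-level summaries (start-site table, SL2 site
#' table, gene calls, threshold sweep, variant usage). All tables are
#' written as TSV under `outdir` with a `manifest.tsv` listing them; a
#' rerun with `overwrite = FALSE` skips stages whose outputs exist.
#' Given identical inputs and parameters the outputs are byte-identical.
#'
#' @param alignments SAM/BAM path.
#' @param transcriptome transcriptome FASTA path (or NULL; without it
#'   the hairpin stem is matched against the read's own aligned bases).
#' @param gff GFF3 annotation path (or NULL).
#' @param sl_fasta SL repertoire FASTA (or NULL to use `repertoire`).
#' @param repertoire named character vector of SL sequences (used when
#'   `sl_fasta` is NULL; defaults to [sl_repertoire_default()]).
#' @param outdir output directory.
#' @param params a [pipeline_params()].
#' @param sl1_primed see [classify_reads()].
#' @param profile_sample_n,profile_seed subsampling of the quality
#'   profile.
#' @param overwrite recompute stages whose outputs already exist.
#' @return (invisibly) list with the in-memory results and `files`.
#' @export
run_pipeline <- function(alignments, transcriptome = NULL, gff = NULL,
                         sl_fasta = NULL, repertoire = NULL, outdir,
                         params = pipeline_params(), sl1_primed = FALSE,
                         profile_sample_n = 20000L, profile_seed = 1L,
                         overwrite = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(repertoire)) {
    repertoire <- if (!is.null(sl_fasta)) read_sl_fasta(sl_fasta)
                  else sl_repertoire_default()
  }
  transcripts <- if (!is.null(transcriptome)) {
    tx <- Biostrings::readDNAStringSet(transcriptome)
    structure(as.character(tx), names = sub("\\s.*$", "", names(tx)))
  } else NULL
  annotation <- if (!is.null(gff)) read_gene_annotation(gff) else NULL

  f <- function(name) file.path(outdir, name)
  files <- c(strand_bias = f("strand_bias.tsv"),
             softclip = f("softclip_stats.tsv"),
             quality_profile = f("quality_profile.tsv"),
             classification = f("classification.tsv"),
             sites = f("start_sites.tsv"),
             sl2_sites = f("sl2_sites.tsv"),
             gene_calls = f("gene_calls.tsv"),
             sweep = f("threshold_sweep.tsv"),
             variant_usage = f("variant_usage.tsv"),
             filter_counts = f("filter_counts.tsv"))

  reads <- load_alignments(alignments)
  res <- list(filter_counts = attr(reads, "filter_counts"))

  stage <- function(name, compute) {
    if (!overwrite && file.exists(files[[name]])) return(NULL)
    compute()
  }

  stage("strand_bias", function() {
    res$strand_bias <<- strand_bias(reads)
    write_tsv_plain(res$strand_bias, files[["strand_bias"]])
  })
  stage("softclip", function() {
    res$softclip <<- softclip_stats(reads, "5p")
    write_tsv_plain(res$softclip$summary, files[["softclip"]])
  })
  stage("quality_profile", function() {
    res$quality_profile <<- quality_profile(reads,
                                            sample_n = profile_sample_n,
                                            seed = profile_seed)
    write_tsv_plain(res$quality_profile, files[["quality_profile"]])
  })
  stage("classification", function() {
    res$classified <<- classify_reads(reads, repertoire, params,
                                      sl1_primed = sl1_primed,
                                      transcripts = transcripts)
    write_tsv_plain(res$classified, files[["classification"]])
  })
  if (is.null(res$classified) && file.exists(files[["classification"]]))
    res$classified <- read_tsv_plain(files[["classification"]])

  stage("sites", function() {
    res$sites <<- aggregate_start_sites(res$classified, annotation,
                                        params$collapse_window)
    write_tsv_plain(res$sites, files[["sites"]])
  })
  if (is.null(res$sites) && file.exists(files[["sites"]]))
    res$sites <- read_tsv_plain(files[["sites"]])

  stage("sl2_sites", function() {
    res$sl2_sites <<- sl2_site_table(res$sites, params$min_discriminable,
                                     params$sl2_hi, params$sl2_lo)
    write_tsv_plain(res$sl2_sites, files[["sl2_sites"]])
  })
  stage("gene_calls", function() {
    res$gene_calls <<- classify_gene(res$sites, annotation,
                                     params$gene_min_reads,
                                     params$sl_majority,
                                     params$min_discriminable,
                                     params$sl2_hi, params$sl2_lo)
    write_tsv_plain(res$gene_calls, files[["gene_calls"]])
  })
  stage("sweep", function() {
    res$sweep <<- classify_gene_sweep(res$sites,
                                      min_reads = params$gene_min_reads)
    write_tsv_plain(res$sweep, files[["sweep"]])
  })
  stage("variant_usage", function() {
    res$variant_usage <<- sl_variant_usage(res$classified)
    write_tsv_plain(res$variant_usage, files[["variant_usage"]])
  })
  stage("filter_counts", function() {
    fc <- res$filter_counts
    write_tsv_plain(data.frame(what = names(fc), n = as.integer(fc)),
                    files[["filter_counts"]])
  })

  manifest <- data.frame(output = names(files),
                         path = basename(unname(files)),
                         stringsAsFactors = FALSE)
  write_tsv_plain(manifest, f("manifest.tsv"))
  res$files <- c(files, manifest = f("manifest.tsv"))
  res$reads <- reads
  invisible(res)
}
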