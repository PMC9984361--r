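# Shared simulation fixtures, built once per test run and cached.

.sim_cache <- new.env(parent = emptyenv())

cached_run <- function(key, config) {
  if (!exists(key, envir = .sim_cache)) {
    dir <- file.path(tempdir(), paste0("clipsl_fix_", key))
    run <- simulate_run(config, dir)
    run$config <- config
    run$classified <- NULL
    assign(key, run, envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# zero-noise, all-antisense, mixed SL1/SL2/hairpin truth
fix_zero_noise <- function() {
  cached_run("zero", sim_config(
    seed = 101L, n_genes = 10L, reads_per_gene = 40,
    err_first_strand = 0, err_second_strand = 0,
    hairpin_artifact_prob = 1, operon_fraction = 0.3,
    endogenous_hairpin_fraction = 0.2))
}

# study-condition noise, moderate size
fix_noisy <- function() {
  cached_run("noisy", sim_config(
    seed = 202L, n_genes = 12L, reads_per_gene = 60,
    err_first_strand = 0.05, err_second_strand = 0.15,
    hairpin_artifact_prob = 0.95, operon_fraction = 0.25,
    endogenous_hairpin_fraction = 0.2))
}

classified_of <- function(run) {
  key <- paste0("cls_", run$config$seed)
  if (!exists(key, envir = .sim_cache)) {
    reads <- load_alignments(run$files$sam)
    cl <- classify_reads(reads, run$config$sl_repertoire,
                         transcripts = run$reference$transcripts)
    assign(key, list(reads = reads, classified = cl), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

truth_of <- function(run, classified) {
  tr <- run$reads$truth
  tr[match(classified$read_id, tr$read_id), , drop = FALSE]
}

# minimal hand-written SAM for CIGAR arithmetic tests
write_toy_sam <- function(records,
                          refs = c(tx1 = 2000L),
                          path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
  writeLines(c(hdr, records), path, sep = "\n")
  path
}

toy_record <- function(qname, flag, rname, pos, cigar, seq,
                       qual = strrep("I", nchar(seq)), mapq = 60L) {
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0L, 0L, seq, qual,
        sep = "\t")
}
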