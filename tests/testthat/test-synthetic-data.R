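test_that("sim_config validates its invariants", {
  expect_error(sim_config(err_first_strand = 0.2, err_second_strand = 0.1),
               "err_second_strand")
  expect_error(sim_config(q_aligned = 7, q_softclip = 7), "q_aligned")
  expect_error(sim_config(hairpin_artifact_prob = 1.2), "probabilities")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(sl_repertoire = c(SL1 = "ACGT")), ">= 7")
})

test_that("a single-gene reference is well formed", {
  cfg <- sim_config(seed = 5, n_genes = 1, operon_fraction = 0,
                    endogenous_hairpin_fraction = 0)
  out <- tempfile()
  ref <- generate_reference(cfg, out)
  expect_equal(length(ref$transcripts), 1L)
  expect_equal(nrow(ref$genes), 1L)
  ann <- read_gene_annotation(ref$files$gff)
  expect_equal(nrow(ann$genes), 1L)
  expect_true(is.na(upstream_distance(ann)$upstream_distance))
})

test_that("operon_fraction = 1 chains all genes at the target spacing", {
  cfg <- sim_config(seed = 6, n_genes = 8, operon_fraction = 1,
                    endogenous_hairpin_fraction = 0,
                    sl2_distance_mode = 100, operon_jitter_sd = 10)
  out <- tempfile()
  ref <- generate_reference(cfg, out)
  # recompute the gaps from the emitted GFF3, not from internals
  ann <- read_gene_annotation(ref$files$gff)
  g <- ann$genes[order(ann$genes$start), ]
  gaps <- g$start[-1] - g$end[-nrow(g)]
  expect_length(gaps, 7L)
  expect_true(all(abs(gaps - 100) <= 50))  # ~5 SD of the stated jitter
  expect_equal(sum(ref$genes$is_downstream), 7L)
})

test_that("impossible layouts fail explicitly", {
  expect_error(generate_reference(
    sim_config(seed = 1, n_genes = 5, operon_fraction = 1,
               endogenous_hairpin_fraction = 0.4)),
    "impossible layout")
  expect_error(generate_reference(
    sim_config(seed = 1, n_genes = 50, contig_len = 1000L,
               operon_fraction = 0, endogenous_hairpin_fraction = 0)),
    "impossible layout")
})

test_that("transcripts never contain a full SL in either orientation", {
  run <- fix_zero_noise()
  sls <- run$config$sl_repertoire
  for (tx in run$reference$transcripts) {
    for (p in c(sls, revcomp(sls))) {
      expect_false(grepl(p, tx, fixed = TRUE))
    }
  }
})

test_that("identical configs give byte-identical outputs", {
  cfg <- sim_config(seed = 33, n_genes = 4, reads_per_gene = 10)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_run(cfg, d1)
  simulate_run(cfg, d2)
  for (f in c("transcriptome.fa", "genes.gff3", "sl.fa", "reads.fastq",
              "truth.tsv", "alignments.sam")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("zero reads requested gives empty outputs without failure", {
  cfg <- sim_config(seed = 8, n_genes = 2, reads_per_gene = 0,
                    endogenous_hairpin_fraction = 0)
  ref <- generate_reference(cfg)
  out <- simulate_reads(ref, cfg, tempfile())
  expect_equal(nrow(out$fastq), 0L)
  expect_equal(nrow(out$truth), 0L)
})

test_that("zero-noise artifact reads end their soft-clip with the exact SL", {
  run <- fix_zero_noise()
  tr <- run$reads$truth
  sls <- run$config$sl_repertoire
  sl_reads <- tr[tr$true_class != "endogenous_hairpin" &
                 tr$artifact == "hairpin_cDNA_antisense", ]
  fq <- run$reads$fastq
  for (i in seq_len(nrow(sl_reads))) {
    r <- sl_reads[i, ]
    seq_ref <- revcomp(fq$seq[fq$read_id == r$read_id])  # antisense read
    clip <- substr(seq_ref, 1L, r$clip5_len)
    sl <- sls[[r$true_class]]
    expect_equal(substr(clip, nchar(clip) - nchar(sl) + 1L, nchar(clip)), sl)
  }
})

test_that("zero-noise hairpin reads carry the reverse-complemented stem copy", {
  run <- fix_zero_noise()
  tr <- run$reads$truth
  hp <- tr[tr$true_class == "endogenous_hairpin" &
           tr$artifact == "hairpin_cDNA_antisense", ]
  expect_gt(nrow(hp), 0L)
  fq <- run$reads$fastq
  d <- run$config$hairpin_stem_offset
  for (i in seq_len(min(nrow(hp), 50L))) {
    r <- hp[i, ]
    tx <- run$reference$transcripts[[r$transcript_id]]
    seq_ref <- revcomp(fq$seq[fq$read_id == r$read_id])
    clip <- substr(seq_ref, 1L, r$clip5_len)
    # clip suffix = revcomp of the transcript fragment just past the stem
    expect_equal(substr(clip, nchar(clip) - 12L, nchar(clip)),
                 revcomp(substr(tx, d + 1L, d + 13L)))
  }
})

test_that("segment spans tile each read exactly", {
  run <- fix_noisy()
  tr <- run$reads$truth
  fq <- run$reads$fastq
  lens <- nchar(fq$seq[match(tr$read_id, fq$read_id)])
  for (i in seq_len(nrow(tr))) {
    spans <- strsplit(strsplit(tr$segment_spans[i], ";")[[1]], "[:-]")
    starts <- as.integer(vapply(spans, `[`, "", 2))
    ends <- as.integer(vapply(spans, `[`, "", 3))
    widths <- ends - starts + 1L
    expect_equal(sum(pmax(widths, 0L)), lens[i])
    expect_equal(starts[1], 1L)
    expect_true(all(starts[-1] == head(ends, -1) + 1L))
  }
})

test_that("antisense fraction converges to hairpin_artifact_prob", {
  cfg <- sim_config(seed = 55, n_genes = 8, reads_per_gene = 150,
                    err_first_strand = 0, err_second_strand = 0,
                    hairpin_artifact_prob = 0.8,
                    endogenous_hairpin_fraction = 0)
  ref <- generate_reference(cfg)
  out <- simulate_reads(ref, cfg)
  n <- nrow(out$truth)
  p_hat <- mean(out$truth$is_antisense)
  expect_lt(abs(p_hat - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})

test_that("emitted qualities step between aligned and soft-clip segments", {
  run <- fix_noisy()
  fq <- run$reads$fastq
  tr <- run$reads$truth
  anti <- tr$artifact == "hairpin_cDNA_antisense"
  qs_clip <- numeric(0); qs_aln <- numeric(0)
  for (i in which(anti)[1:100]) {
    q <- rev(as.integer(charToRaw(fq$qual[fq$read_id == tr$read_id[i]])) - 33L)
    # reference orientation: second-strand copy occupies the clip start
    spans <- strsplit(strsplit(tr$segment_spans[i], ";")[[1]], "[:-]")
    nm <- vapply(spans, `[`, "", 1)
    ss <- spans[[which(nm == "second_strand_copy")]]
    body <- spans[[which(nm == "body")]]
    qs_clip <- c(qs_clip, q[as.integer(ss[2]):as.integer(ss[3])])
    qs_aln <- c(qs_aln, q[as.integer(body[2]):as.integer(body[3])])
  }
  expect_lt(mean(qs_clip), mean(qs_aln))
  expect_lt(abs(mean(qs_clip) - run$config$q_softclip), 1)
  expect_lt(abs(mean(qs_aln) - run$config$q_aligned), 1)
})

test_that("oracle SAM round-trips truth soft-clip lengths at any error rate", {
  for (run in list(fix_zero_noise(), fix_noisy())) {
    reads <- load_alignments(run$files$sam)
    tr <- truth_of(run, reads)
    expect_equal(reads$clip5_len, tr$clip5_len)
    expect_equal(reads$clip3_len, tr$clip3_len)
    expect_equal(reads$is_antisense, tr$is_antisense)
  }
})
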