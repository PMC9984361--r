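# build a classification table by hand: one row per read
mk_class <- function(gene, start, class, confident = TRUE,
                     family = NULL, n = 1L) {
  if (is.null(family)) {
    family <- ifelse(class %in% c("endogenous_hairpin", "unidentified",
                                  "sense_untested", "SL.X"), NA_character_,
                     ifelse(startsWith(class, "SL2"), "SL2", "SL1"))
  }
  out <- data.frame(read_id = NA_character_, ref_id = paste0(gene, ".t1"),
                    is_antisense = TRUE, start_pos = start, class = class,
                    sl_name = class, sl_family = family, score = 20,
                    trunc = 0L, matched_len = 22L, end_offset = 0L,
                    confident = confident, hp_matched_nt = NA_integer_,
                    stringsAsFactors = FALSE)
  out <- out[rep(1L, n), , drop = FALSE]
  out$read_id <- sprintf("%s_%s_%d", gene, class, seq_len(n))
  rownames(out) <- NULL
  out
}

mk_gene <- function(...) do.call(rbind, list(...))

test_that("start-site aggregation yields exact per-class counts", {
  cls <- mk_class("gA", 1L, "SL1", n = 10L)
  s <- aggregate_start_sites(cls)
  expect_equal(nrow(s), 1L)
  expect_equal(s$n_total, 10L)
  expect_equal(s$n_sl, 10L)
  expect_equal(s$n_confident_sl1, 10L)
  expect_equal(s$n_hairpin, 0L)
})

test_that("aggregation conserves the classified-read total", {
  cls <- mk_gene(mk_class("gA", 1L, "SL1", n = 7L),
                 mk_class("gA", 40L, "endogenous_hairpin", n = 3L),
                 mk_class("gB", 1L, "SL2.1", n = 5L),
                 mk_class("gB", 1L, "unidentified", confident = NA, n = 2L),
                 mk_class("gB", 1L, "sense_untested", confident = NA, n = 1L))
  s <- aggregate_start_sites(cls)
  expect_equal(sum(s$n_total), nrow(cls))
  counted <- s$n_sl + s$n_hairpin + s$n_unidentified + s$n_sense_untested
  expect_equal(counted, s$n_total)
})

test_that("dominant starts prefer support then the 5'-most coordinate", {
  cls <- mk_gene(mk_class("gA", 20L, "SL1", n = 60L),
                 mk_class("gA", 90L, "SL1", n = 40L))
  d <- dominant_starts(aggregate_start_sites(cls))
  expect_equal(d$start_pos, 20L)
  # tie: the 5'-most wins
  cls2 <- mk_gene(mk_class("gA", 50L, "SL1", n = 30L),
                  mk_class("gA", 10L, "SL1", n = 30L))
  d2 <- dominant_starts(aggregate_start_sites(cls2))
  expect_equal(d2$start_pos, 10L)
})

test_that("SL2 ratios and categories follow the printed bands", {
  cls <- mk_gene(mk_class("gA", 1L, "SL2.1", n = 7L),
                 mk_class("gA", 1L, "SL1", n = 3L),
                 mk_class("gB", 1L, "SL1", n = 10L),
                 mk_class("gC", 1L, "SL2.4", n = 6L),
                 mk_class("gC", 1L, "SL1", n = 4L),
                 mk_class("gD", 1L, "SL1", n = 9L))  # below threshold
  st <- sl2_site_table(aggregate_start_sites(cls))
  expect_equal(nrow(st), 3L)  # gD excluded at < 10 discriminable reads
  gA <- st[st$gene_id == "gA.t1", ]
  expect_equal(gA$sl2_ratio, 0.7)
  expect_equal(gA$sl2_category, "SL2")
  gB <- st[st$gene_id == "gB.t1", ]
  expect_equal(gB$sl2_ratio, 0)
  expect_equal(gB$sl2_category, "SL1")
  gC <- st[st$gene_id == "gC.t1", ]
  expect_equal(gC$sl2_ratio, 0.6)
  expect_equal(gC$sl2_category, "intermediate")  # strict inequality
})

test_that("ambiguous family reads are excluded from the SL2 ratio", {
  cls <- mk_gene(mk_class("gA", 1L, "SL2.1", n = 6L),
                 mk_class("gA", 1L, "SL2.X", family = "SL2", n = 4L),
                 mk_class("gA", 1L, "SL.X", n = 5L),
                 mk_class("gA", 1L, "SL1", n = 4L))
  s <- aggregate_start_sites(cls)
  # SL2.X counts toward the SL2 family, SL.X toward neither
  expect_equal(s$n_confident_sl2, 10L)
  expect_equal(s$n_confident_sl1, 4L)
  expect_equal(s$n_sl, 19L)
})

test_that("upstream distances are strand aware", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 20000",
    "chr1\tx\tgene\t200\t1000\t.\t+\t.\tID=up1;biotype=protein_coding",
    "chr1\tx\tgene\t1100\t2000\t.\t+\t.\tID=gPlus;biotype=protein_coding",
    "chr1\tx\tgene\t5000\t5900\t.\t-\t.\tID=gMinus;biotype=protein_coding",
    "chr1\tx\tgene\t6000\t6800\t.\t-\t.\tID=up2;biotype=protein_coding",
    "chr1\tx\tgene\t15000\t15800\t.\t+\t.\tID=lonely;biotype=protein_coding"),
    gff)
  ann <- read_gene_annotation(gff)
  ud <- upstream_distance(ann)
  expect_equal(ud$upstream_distance[ud$gene_id == "gPlus"], 100L)
  expect_equal(ud$upstream_distance[ud$gene_id == "gMinus"], 100L)
  # first gene on the contig in its orientation: undefined
  expect_true(is.na(ud$upstream_distance[ud$gene_id == "up1"]))
  expect_equal(ud$upstream_distance[ud$gene_id == "lonely"], 8200L)
})

test_that("overlapping upstream genes give distance zero", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t100\t1200\t.\t+\t.\tID=a;biotype=protein_coding",
    "chr1\tx\tgene\t1100\t2000\t.\t+\t.\tID=b;biotype=protein_coding"),
    gff)
  ud <- upstream_distance(read_gene_annotation(gff))
  expect_equal(ud$upstream_distance[ud$gene_id == "b"], 0L)
})

test_that("gene calls apply the majority and coverage rules", {
  cls <- mk_gene(mk_class("gA", 1L, "SL1", n = 15L),
                 mk_class("gA", 1L, "endogenous_hairpin", n = 5L))
  gc <- classify_gene(aggregate_start_sites(cls))
  expect_equal(gc$status, "trans_spliced")
  expect_equal(gc$sl_fraction, 0.75)
  # 19 reads -> low coverage
  cls19 <- mk_gene(mk_class("gB", 1L, "SL1", n = 14L),
                   mk_class("gB", 1L, "endogenous_hairpin", n = 5L))
  expect_equal(classify_gene(aggregate_start_sites(cls19))$status,
               "low_coverage")
  # hairpin-dominated gene
  clsH <- mk_gene(mk_class("gC", 1L, "endogenous_hairpin", n = 18L),
                  mk_class("gC", 1L, "SL1", n = 2L))
  expect_equal(classify_gene(aggregate_start_sites(clsH))$status, "hairpin")
  # only unidentified evidence
  clsU <- mk_class("gD", 1L, "unidentified", confident = NA, n = 25L)
  expect_equal(classify_gene(aggregate_start_sites(clsU))$status,
               "unidentified")
})

test_that("the threshold sweep is monotone non-increasing", {
  set.seed(12)
  cls <- do.call(rbind, lapply(1:30, function(i) {
    n_sl <- sample(0:30, 1); n_hp <- sample(0:20, 1)
    rbind(if (n_sl > 0) mk_class(paste0("g", i), 1L, "SL1", n = n_sl),
          if (n_hp > 0) mk_class(paste0("g", i), 1L, "endogenous_hairpin",
                                 n = n_hp))
  }))
  sw <- classify_gene_sweep(aggregate_start_sites(cls),
                            thresholds = seq(0.05, 0.95, by = 0.05),
                            min_reads = 10L)
  expect_true(all(diff(sw$frac_trans_spliced) <= 1e-12))
})

test_that("low-SL flagging applies both boundaries exactly", {
  mk <- function(g, n_sl, n_hp) {
    mk_gene(if (n_sl > 0) mk_class(g, 1L, "SL1", n = n_sl),
            mk_class(g, 1L, "endogenous_hairpin", n = n_hp))
  }
  cls <- mk_gene(mk("g9sl", 9L, 91L),     # 100 reads, 9% SL -> flagged
                 mk("g10sl", 10L, 90L),   # 10% is not < 10% -> not flagged
                 mk("g99", 0L, 99L))      # support too low -> not flagged
  flagged <- flag_low_sl_genes(aggregate_start_sites(cls))
  expect_equal(flagged, "g9sl.t1")
})

test_that("variant usage fractions are exact and SL2.X is tallied apart", {
  cls <- mk_gene(mk_class("gA", 1L, "SL1", n = 64L),
                 mk_class("gA", 1L, "SL2.1", n = 21L),
                 mk_class("gA", 1L, "SL2.8", n = 15L),
                 mk_class("gA", 1L, "SL2.X", family = "SL2", n = 10L),
                 mk_class("gA", 1L, "SL1", confident = FALSE, n = 5L))
  u <- sl_variant_usage(cls)
  expect_equal(sum(u$n), 110L)  # non-confident rows excluded
  expect_equal(u$frac_within_sl2[u$sl_name == "SL2.1"], 21 / 36)
  expect_equal(u$frac_within_sl2[u$sl_name == "SL2.8"], 15 / 36)
  expect_true(is.na(u$frac_within_sl2[u$sl_name == "SL2.X"]))
  expect_equal(u$frac[u$sl_name == "SL1"], 64 / 110)
})

test_that("per-site SL2 variant profiles have rows summing to one", {
  cls <- mk_gene(mk_class("gA", 1L, "SL2.1", n = 12L),
                 mk_class("gB", 1L, "SL2.1", n = 6L),
                 mk_class("gB", 1L, "SL2.4", n = 6L))
  st <- sl2_site_table(aggregate_start_sites(cls))
  m <- sl2_variant_profile(cls, st)
  expect_equal(nrow(m), 2L)
  expect_true(all(abs(rowSums(m) - 1) < 1e-12))
  expect_equal(unname(m["gA.t1:1", "SL2.1"]), 1)  # one-hot site
  # empty site set -> empty matrix
  m0 <- sl2_variant_profile(cls, st[0, , drop = FALSE])
  expect_equal(nrow(m0), 0L)
})

test_that("start-site reports label positions by majority class", {
  # two-promoter gene: distal hairpin start, proximal SL start
  cls <- mk_gene(mk_class("gA", 1L, "endogenous_hairpin", n = 50L),
                 mk_class("gA", 1L, "SL1", n = 5L),
                 mk_class("gA", 300L, "SL1", n = 30L))
  s <- aggregate_start_sites(cls)
  rep <- start_site_report(s, "gA.t1")
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$majority_class[rep$start_pos == 1L], "hairpin")
  expect_equal(rep$majority_class[rep$start_pos == 300L], "SL")
  # zero-read gene -> empty report
  expect_equal(nrow(start_site_report(s, "absent")), 0L)
})

test_that("genomic lift-over of start sites is strand aware", {
  run <- fix_zero_noise()
  ann <- read_gene_annotation(run$files$gff)
  cls <- classified_of(run)$classified
  s <- aggregate_start_sites(cls, ann)
  g <- ann$genes[1, ]
  rep <- start_site_report(s, g$gene_id, ann)
  expect_gt(nrow(rep), 0L)
  if (g$strand == "+") {
    expect_equal(rep$genomic_pos, g$start + rep$start_pos - 1L)
  } else {
    expect_equal(rep$genomic_pos, g$end - rep$start_pos + 1L)
  }
  bed <- tempfile(fileext = ".bed")
  write_start_site_bed(rep, "simtig1", bed)
  expect_equal(length(readLines(bed)), nrow(rep))
})

test_that("reads on unannotated transcripts fall back to their ref_id", {
  cls <- mk_class("gZ", 1L, "SL1", n = 3L)
  ann <- list(genes = data.frame(), tx2gene = c(other.t1 = "other"))
  expect_warning(s <- aggregate_start_sites(cls, ann), "absent")
  expect_equal(s$gene_id, "gZ.t1")
})
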