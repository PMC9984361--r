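sls <- sl_repertoire_default()

test_that("an exact SL at the window end is detected untrimmed and confident", {
  for (nm in c("SL1", "SL2.1", "SL2.8")) {
    win <- paste0(random_seq(60), sls[[nm]])
    det <- detect_sl(win, sls)
    expect_false(is.null(det$best))
    expect_equal(det$best$sl_name, nm)
    expect_equal(det$best$score, 22)
    expect_equal(det$best$trunc, 0L)
    expect_equal(det$best$end_offset, 0L)
    expect_true(is_confident(det$best$score, det$best$end_offset))
  }
})

test_that("a 5'-truncated SL is recovered by the trimming loop", {
  set.seed(77)
  sl <- sls[["SL1"]]
  # the SL's first 10 nt lost to quality dropout: only its 12-nt tail
  # remains in the window
  win <- paste0(random_seq(70), substr(sl, 11, 22))
  det <- detect_sl(win, sls)
  expect_equal(det$best$sl_name, "SL1")
  expect_equal(det$best$end_offset, 0L)
  expect_gte(det$best$trunc, 8L)   # at least the lost bases minus budget
  # brute force over all truncations: the loop must stop at the first
  # (longest) suffix whose semi-global score passes the threshold
  lens <- seq(22, 8, by = -2)
  passes <- vapply(lens, function(len) {
    sub <- substr(sl, 22 - len + 1, 22)
    oracle_semiglobal(sub, win)$score >= default_threshold(len)
  }, logical(1))
  expect_true(any(passes))
  first_len <- lens[which(passes)[1]]
  expect_equal(det$best$matched_len, first_len)
  expect_equal(det$best$trunc, 22L - first_len)
  expect_equal(det$best$score,
               oracle_semiglobal(substr(sl, 22 - first_len + 1, 22),
                                 win)$score)
})

test_that("detection thresholds behave as mismatch budgets", {
  sl <- sls[["SL2.3"]]
  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- c(A = "C", C = "G", G = "T", T = "A")[ch[pos]]
    paste(ch, collapse = "")
  }
  # two substitutions in the full-length SL still pass (score 18)
  win2 <- paste0(random_seq(50), mutate_at(mutate_at(sl, 5), 15))
  det <- detect_sl(win2, sls)
  expect_equal(det$best$sl_name, "SL2.3")
  expect_equal(det$best$score, 18)
  expect_equal(det$best$trunc, 0L)
})

test_that("trimming adds nothing when the full-length SL passes", {
  set.seed(99)
  for (i in 1:10) {
    win <- paste0(random_seq(40), sls[[sample(names(sls), 1)]])
    first <- detect_sl(win, sls)
    exhaust <- detect_sl(win, sls, exhaust = TRUE)
    expect_equal(first$best$sl_name, exhaust$best$sl_name)
    expect_equal(first$best$score, exhaust$best$score)
    expect_equal(first$best$trunc, exhaust$best$trunc)
  }
})

test_that("SL-free windows rarely yield confident detections", {
  set.seed(123)
  n <- 300
  n_det <- 0L; n_conf <- 0L
  for (i in 1:n) {
    repeat {
      win <- random_seq(100)
      if (!any(vapply(sls, grepl, logical(1), x = win, fixed = TRUE))) break
    }
    det <- detect_sl(win, sls)
    if (!is.null(det$best)) {
      n_det <- n_det + 1L
      conf <- is_confident(det$detections$score, det$detections$end_offset)
      if (any(conf)) n_conf <- n_conf + 1L
    }
  }
  # report the empirical false-positive rates
  message(sprintf("SL-free windows: %.1f%% any detection, %.1f%% confident",
                  100 * n_det / n, 100 * n_conf / n))
  expect_lt(n_conf / n, 0.05)
})

test_that("ambiguity classes follow the best-score tie rules", {
  d1 <- data.frame(sl_name = "SL1", family = "SL1", score = 20,
                   trunc = 0L, matched_len = 22L, end_offset = 0L)
  expect_equal(classify_ambiguity(d1)$class, "SL1")

  d2 <- data.frame(sl_name = c("SL2.1", "SL2.3"), family = "SL2",
                   score = 18, trunc = 0L, matched_len = 22L,
                   end_offset = c(0L, 3L))
  expect_equal(classify_ambiguity(d2)$class, "SL2.X")

  d3 <- data.frame(sl_name = c("SL1", "SL2.1"), family = c("SL1", "SL2"),
                   score = 15, trunc = 0L, matched_len = 22L,
                   end_offset = 0L)
  expect_equal(classify_ambiguity(d3)$class, "SL.X")

  # a longer matched length breaks the tie before declaring ambiguity
  d4 <- data.frame(sl_name = c("SL1", "SL2.1"), family = c("SL1", "SL2"),
                   score = 15, trunc = c(0L, 6L), matched_len = c(22L, 16L),
                   end_offset = 0L)
  expect_equal(classify_ambiguity(d4)$class, "SL1")
})

test_that("the confident-match rule applies both clauses exactly", {
  expect_true(is_confident(10, 50))    # score clause: superior to 9
  expect_false(is_confident(9, 50))
  expect_true(is_confident(9, 2))      # proximity clause: <= 2 nt
  expect_true(is_confident(4, 0))
  expect_false(is_confident(9, 3))
})

test_that("high-scoring matches concentrate just upstream of the alignment start", {
  run <- fix_noisy()
  cls <- classified_of(run)$classified
  hi <- cls[!is.na(cls$score) & cls$score > 15, ]
  expect_gt(nrow(hi), 50L)
  expect_gt(mean(hi$end_offset <= 2), 0.9)
})

test_that("SL1-primed inputs only count antisense reads for SL detection", {
  run <- fix_noisy()
  reads <- load_alignments(run$files$sam)
  cl <- classify_reads(reads, run$config$sl_repertoire,
                       transcripts = run$reference$transcripts,
                       sl1_primed = TRUE)
  sense <- !reads$is_antisense
  expect_true(all(cl$class[sense] == "sense_untested"))
  expect_true(all(is.na(cl$score[sense])))
})
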