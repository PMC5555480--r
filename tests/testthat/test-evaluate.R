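test_that("window matching hits the documented transition points", {
  # exact requires identical interval and family
  expect_true(match_prediction("c1", 800L, 805L, "c1", 800L, 805L,
                               "exact", "Ty1", "Ty1"))
  expect_false(match_prediction("c1", 804L, 806L, "c1", 800L, 805L,
                                "exact", "Ty1", "Ty1"))
  expect_true(match_prediction("c1", 804L, 806L, "c1", 800L, 805L,
                               100, "Ty1", "Ty1"))
  # window boundary: [700,701) touches [700, 905), [699,700) does not
  expect_true(match_prediction("c1", 700L, 701L, "c1", 800L, 805L,
                               100, family_required = FALSE))
  expect_false(match_prediction("c1", 699L, 700L, "c1", 800L, 805L,
                                100, family_required = FALSE))
  # family mismatch fails, but resolves through the hierarchy
  expect_false(match_prediction("c1", 800L, 805L, "c1", 800L, 805L,
                                "exact", "Ty2", "Ty1"))
  expect_true(match_prediction("c1", 800L, 805L, "c1", 800L, 805L,
                               "exact", "Ty1-3", "Ty1",
                               hierarchy = c("Ty1-3" = "Ty1")))
  # different chromosome never matches
  expect_false(match_prediction("c2", 800L, 805L, "c1", 800L, 805L,
                                500, family_required = FALSE))
})

test_that("window matching agrees with the brute-force per-base oracle", {
  # sweep all offsets through the transition region
  for (off in seq(-600L, 600L, by = 7L)) {
    for (w in list(0, 100, 300, 500)) {
      got <- match_prediction("c1", 800L + off, 805L + off, "c1",
                              800L, 805L, w, family_required = FALSE)
      expect_identical(got, oracle_match(800L + off, 805L + off,
                                         800L, 805L, w))
    }
  }
  # randomized intervals and windows
  set.seed(99)
  for (i in 1:400) {
    ts <- sample(0:2000, 1); te <- ts + sample(1:10, 1)
    ps <- sample(0:2000, 1); pe <- ps + sample(1:400, 1)
    w <- sample(list("exact", 0, 3, 100, 300, 500), 1)[[1]]
    expect_identical(
      match_prediction("c1", ps, pe, "c1", ts, te, w,
                       family_required = FALSE),
      oracle_match(ps, pe, ts, te, w),
      info = sprintf("p=[%d,%d) t=[%d,%d) w=%s", ps, pe, ts, te,
                     format(w))
    )
  }
})

test_that("a perfect caller scores 1.0 everywhere; empty scores 0", {
  fx <- toy()
  ss <- generate_sample_set(fx$genome, fx$trna, fx$te_library,
                            keep_genomes = FALSE)
  cl <- chrom_lengths(fx$genome)
  perfect <- make_mock_predictions(ss$truth, mock_caller_profile(), cl)
  sc <- score_sample_set(perfect, ss$truth)
  for (col in c("correct_exact", "correct_100", "correct_300",
                "correct_500", "mean_nonreference")) {
    expect_equal(sc$summary[[col]], rep(1, nrow(sc$summary)))
  }
  empty <- score_sample_set(standard_predictions(), ss$truth)
  expect_true(all(empty$summary$correct_exact == 0))
  expect_true(all(empty$summary$mean_nonreference == 0))
})

test_that("samples missing from the predictions count as zero", {
  fx <- toy()
  ss <- generate_sample_set(fx$genome, fx$trna, fx$te_library,
                            keep_genomes = FALSE)
  perfect <- make_mock_predictions(ss$truth, mock_caller_profile(),
                                   chrom_lengths(fx$genome))
  half <- perfect[perfect$sample_id %in% ss$truth$sample_id[
    seq(1, nrow(ss$truth), 2)], ]
  sc <- score_sample_set(half, ss$truth)
  expect_equal(sum(sc$summary$n_samples), nrow(ss$truth))
  expect_equal(weighted.mean(sc$summary$correct_exact,
                             sc$summary$n_samples), 0.5)
})

test_that("correctness means are non-decreasing across widening windows", {
  fx <- toy()
  ss <- generate_sample_set(fx$genome, fx$trna, fx$te_library,
                            keep_genomes = FALSE)
  cl <- chrom_lengths(fx$genome)
  profiles <- list(
    mock_caller_profile("exact"),
    mock_caller_profile("jitter", pos_error_sd = 50),
    mock_caller_profile("lossy", p_detect = 0.5, pos_error_sd = 120,
                        fp_rate = 1)
  )
  for (k in seq_along(profiles)) {
    pred <- make_mock_predictions(ss$truth, profiles[[k]], cl, seed = k)
    sc <- score_sample_set(pred, ss$truth)
    m <- as.matrix(sc$summary[, c("correct_exact", "correct_100",
                                  "correct_300", "correct_500")])
    expect_true(all(diff(t(m)) >= 0))
    expect_true(all(sc$summary$correct_500 <=
                      sc$summary$mean_nonreference + 1e-12))
  }
})

test_that("recurrent sites across samples are flagged and removed", {
  fx <- toy()
  # one strand batch, so every truth site is unique to one sample
  ss <- generate_sample_set(fx$genome, fx$trna, fx$te_library,
                            strands = "+", keep_genomes = FALSE)
  cl <- chrom_lengths(fx$genome)
  pred <- make_mock_predictions(ss$truth, mock_caller_profile(), cl)
  # plant one site recurring in many samples
  rec <- do.call(rbind, lapply(ss$truth$sample_id, function(s) {
    data.frame(chrom = "chrI", start = 50L, end = 55L, family = "Ty1",
               category = "nonreference", sample_id = s, method = "mock",
               evidence = "sr", strand = ".", stringsAsFactors = FALSE)
  }))
  mixed <- standard_predictions(rbind(pred, standard_predictions(rec)))
  res <- recurrent_site_filter(mixed)
  expect_equal(nrow(res$flagged_sites), 1L)
  expect_equal(res$flagged_sites$n_samples, nrow(ss$truth))
  expect_equal(nrow(res$kept) + nrow(ss$truth), nrow(mixed))
  # a site present in one sample only is kept
  single <- recurrent_site_filter(pred)
  expect_equal(nrow(single$flagged_sites), 0L)
  expect_equal(single$kept, pred)
})

test_that("concordance regions are exhaustive and total the sample count", {
  fx <- toy()
  ss <- generate_sample_set(fx$genome, fx$trna, fx$te_library,
                            keep_genomes = FALSE)
  cl <- chrom_lengths(fx$genome)
  n <- nrow(ss$truth)
  pa <- make_mock_predictions(ss$truth, mock_caller_profile("a"), cl)
  pb <- make_mock_predictions(ss$truth, mock_caller_profile("b"), cl)
  cfg <- concordance_config(c("a", "b"), c(0, 100))
  cc <- concordance_sets(rbind(pa, pb), ss$truth, cfg)
  expect_equal(sum(cc$regions$count), n)
  expect_equal(cc$regions$count[cc$regions$region == "a&b"], n)
  expect_true(all(cc$regions$count[cc$regions$region != "a&b"] == 0))

  # independent 50% callers: both-region near p^2 * n
  set.seed(8)
  big <- toy(n_trna = 8L)
  truths <- generate_sample_set(big$genome, big$trna, big$te_library,
                                keep_genomes = FALSE)$truth
  truths <- truths[rep(seq_len(nrow(truths)), 40), ]
  truths$sample_id <- sprintf("s%04d", seq_len(nrow(truths)))
  nb <- nrow(truths)
  qa <- make_mock_predictions(truths, mock_caller_profile("a", p_detect = 0.5),
                              chrom_lengths(big$genome), seed = 1)
  qb <- make_mock_predictions(truths, mock_caller_profile("b", p_detect = 0.5),
                              chrom_lengths(big$genome), seed = 2)
  cc2 <- concordance_sets(rbind(qa, qb), truths, cfg)
  both <- cc2$regions$count[cc2$regions$region == "a&b"]
  expect_lt(abs(both - nb / 4), 2.58 * sqrt(nb * 0.25 * 0.75) + 1)
  expect_equal(sum(cc2$regions$count), nb)
})
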