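test_that("a perfect caller yields a unit delta over the TSD bases", {
  fx <- toy()
  ss <- generate_sample_set(fx$genome, fx$trna, fx$te_library,
                            keep_genomes = FALSE)
  pred <- make_mock_predictions(ss$truth, mock_caller_profile(),
                                chrom_lengths(fx$genome))
  anchors <- ss$truth
  anchors$strand <- anchors$te_strand
  pr <- anchored_profile(pred, anchors, flank = 10)
  expect_equal(nrow(pr), 25L)
  expect_equal(pr$value[pr$offset %in% 0:4], rep(1, 5))
  expect_equal(sum(pr$value), 5)
  # no predictions: all-zero vector
  z <- anchored_profile(standard_predictions(), anchors, flank = 10)
  expect_equal(z$value, rep(0, 25L))
})

test_that("indicator profiles are bounded by 1; multiplicity can exceed it", {
  fx <- toy()
  ss <- generate_sample_set(fx$genome, fx$trna, fx$te_library,
                            keep_genomes = FALSE)
  pred <- make_mock_predictions(ss$truth, mock_caller_profile(),
                                chrom_lengths(fx$genome))
  # duplicate every prediction: indicator unchanged, multiplicity doubles
  dup <- standard_predictions(rbind(pred, pred))
  anchors <- ss$truth
  anchors$strand <- anchors$te_strand
  ind <- anchored_profile(dup, anchors, flank = 10)
  expect_true(all(ind$value <= 1 + 1e-12))
  mult <- anchored_profile(dup, anchors, flank = 10, mode = "multiplicity")
  expect_equal(max(mult$value), 2)
})

test_that("jittered predictions concentrate profile mass within 3 sigma", {
  fx <- toy(n_trna = 8L)
  ss <- generate_sample_set(fx$genome, fx$trna, fx$te_library,
                            keep_genomes = FALSE)
  truths <- ss$truth[rep(seq_len(nrow(ss$truth)), 25), ]
  truths$sample_id <- sprintf("s%04d", seq_len(nrow(truths)))
  pred <- make_mock_predictions(
    truths, mock_caller_profile(pos_error_sd = 50),
    chrom_lengths(fx$genome), seed = 6
  )
  anchors <- truths
  anchors$strand <- anchors$te_strand
  pr <- anchored_profile(pred, anchors, flank = 500)
  inner <- sum(pr$value[abs(pr$offset) <= 150])
  expect_gt(inner / sum(pr$value), 0.985)
})

test_that("profiles are equivariant under strand reversal with mirrored coordinates", {
  # one plus-strand anchor with an asymmetric prediction next to it
  L <- 1000L
  pred <- standard_predictions(data.frame(
    chrom = "c", start = 480L, end = 490L, family = "Ty1",
    category = "nonreference", sample_id = "s1", method = "m",
    evidence = "sr", strand = ".", stringsAsFactors = FALSE
  ))
  anch <- data.frame(chrom = "c", start = 500L, end = 505L, strand = "+",
                     sample_id = "s1", stringsAsFactors = FALSE)
  fwd <- anchored_profile(pred, anch, flank = 50)
  # mirror: x' = L - x, strands flipped
  predm <- pred
  predm$start <- L - pred$end
  predm$end <- L - pred$start
  anchm <- anch
  anchm$start <- L - anch$end
  anchm$end <- L - anch$start
  anchm$strand <- "-"
  rev <- anchored_profile(predm, anchm, flank = 50)
  expect_equal(rev$value, fwd$value)
})

test_that("TSD length histogram honours unique-site collapsing", {
  mk <- function(start, end, sample, fam = "Ty1") {
    data.frame(chrom = "c1", start = start, end = end, family = fam,
               category = "nonreference", sample_id = sample,
               method = "m", evidence = "sr", strand = ".",
               stringsAsFactors = FALSE)
  }
  pred <- standard_predictions(rbind(
    mk(800L, 805L, "s1"), mk(800L, 805L, "s2"), mk(800L, 805L, "s3"),
    mk(800L, 807L, "s4")
  ))
  h <- tsd_length_histogram(pred, unique_sites_only = TRUE)
  expect_equal(h$length, c(5L, 7L))
  expect_equal(h$count, c(1L, 1L))
  h2 <- tsd_length_histogram(pred, unique_sites_only = FALSE)
  expect_equal(h2$count[h2$length == 5], 3L)
})

test_that("tRNA region membership is orientation-aware with exact boundaries", {
  trna <- data.frame(
    chrom = "c1", start = c(5000L, 9000L), end = c(5072L, 9072L),
    strand = c("+", "-"), name = c("tP", "tM"), stringsAsFactors = FALSE
  )
  win <- trna_region_windows(trna)
  expect_equal(win$start, c(4000L, 8572L))
  expect_equal(win$end, c(5500L, 10072L))
  expect_equal(win$end - win$start, c(1500L, 1500L))

  mk <- function(start, end, fam = "Ty1") {
    standard_predictions(data.frame(
      chrom = "c1", start = start, end = end, family = fam,
      category = "nonreference", sample_id = "s1", method = "m",
      evidence = "sr", strand = ".", stringsAsFactors = FALSE
    ))
  }
  # tss + 600 downstream of the plus-strand tRNA: outside
  out <- trna_region_table(mk(5600L, 5605L), trna)
  expect_equal(out$in_region, 0L)
  # last base of the window: inside; first base past it: outside
  expect_equal(trna_region_table(mk(5499L, 5504L), trna)$in_region, 1L)
  expect_equal(trna_region_table(mk(5500L, 5505L), trna)$in_region, 0L)
  # a prediction overlapping two regions counts once
  trna2 <- rbind(trna, data.frame(chrom = "c1", start = 5100L, end = 5172L,
                                  strand = "+", name = "tQ"))
  expect_equal(trna_region_table(mk(4500L, 4505L), trna2)$in_region, 1L)
  # totals conserve raw per-family counts
  set.seed(2)
  pred <- random_predictions(200, c(c1 = 20000L), c("Ty1", "Ty2"))
  tab <- trna_region_table(pred, trna)
  expect_equal(sum(tab$total), nrow(pred))
})

test_that("uniform random placement converges to the analytic expectation", {
  # wide spacing so tRNA-region windows cannot overlap and the
  # non-overlap assumption of the formula holds
  fx <- toy(chrom_len = 200000L, n_trna = 10L, n_reference_copies = 0L,
            feature_gap = 3000L)
  cl <- chrom_lengths(fx$genome)
  glen <- sum(cl)
  p_exp <- expected_random_proportion(nrow(fx$trna), 1500, glen)
  set.seed(17)
  n <- 20000L
  pred <- random_predictions(n, cl, "Ty1")
  tab <- trna_region_table(pred, fx$trna)
  # prediction width 5 slightly inflates hit probability; allow for it
  p_wide <- expected_random_proportion(nrow(fx$trna), 1500 + 4, glen)
  se <- sqrt(p_wide * (1 - p_wide) / n)
  expect_lt(abs(tab$in_region / tab$total - p_wide), 3 * se)
  expect_gt(tab$in_region / tab$total, p_exp - 3 * se)
})

test_that("the analytic expectation formula behaves at its edges", {
  expect_equal(expected_random_proportion(1, 100, 1000), 0.1)
  expect_equal(expected_random_proportion(1, 500, 500), 1)
  expect_warning(p <- expected_random_proportion(10, 1000, 500), "clamped")
  expect_equal(p, 1)
})

test_that("bedGraph merges runs and round-trips vectors exactly", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "a.bedgraph")
  write_bedgraph(rep(2.5, 10), "c1", p)
  expect_equal(length(readLines(p)), 1L)

  delta <- c(rep(0, 5), 1, rep(0, 4))
  write_bedgraph(delta, "c1", p)
  expect_equal(length(readLines(p)), 3L)
  back <- read_bedgraph(p)
  expect_equal(back$values, delta)
  expect_equal(back$chrom, "c1")

  set.seed(4)
  v <- sample(c(0, 0.25, 1, 3), 200, replace = TRUE)
  write_bedgraph(v, "chrX", p, offset = 100L)
  back <- read_bedgraph(p)
  expect_equal(back$values, v)
  expect_equal(back$offset, 100L)
})
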