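test_that("median-of-ratios size factors match hand computation and oracle", {
  # doubled column: factors 1/sqrt(2), sqrt(2)
  m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(estimate_size_factors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # identical columns -> all 1
  m2 <- cbind(a = c(3, 7, 9), b = c(3, 7, 9))
  expect_equal(unname(estimate_size_factors(m2)), c(1, 1), tolerance = 1e-12)
  # random NB matrix vs independently coded oracle
  set.seed(11)
  m3 <- matrix(rnbinom(100 * 4, mu = 50, size = 5), 100, 4,
               dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  m3[m3 == 0] <- 1
  expect_equal(estimate_size_factors(m3), oracle_size_factors(m3),
               tolerance = 1e-12)
  # scale equivariance up to geometric-mean renormalization
  m4 <- m3; m4[, 2] <- m4[, 2] * 3
  sf3 <- estimate_size_factors(m3); sf4 <- estimate_size_factors(m4)
  expect_equal(unname(sf4[2] / sf4[1]), unname(3 * sf3[2] / sf3[1]),
               tolerance = 1e-9)
  # degenerate: no feature positive everywhere
  expect_error(estimate_size_factors(cbind(c(0, 1), c(1, 0))), "no feature")
})

test_that("bh_adjust equals the step-up oracle and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(1), 1)
  set.seed(4)
  p <- runif(1000)
  q <- bh_adjust(p)
  expect_equal(q, oracle_bh(p), tolerance = 1e-15)
  expect_true(all(q >= p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential test handles null, planted, and degenerate features", {
  set.seed(21)
  d <- make_two_stratum_counts(300, 3, mu0 = rlnorm(300, log(100), 1),
                               fc = 8, planted = 1L)
  d$counts[2, ] <- 0L  # all-zero feature
  sf <- estimate_size_factors(d$counts)
  de <- test_differential(d$counts, d$samples, sf, "dox", 3)
  expect_identical(nrow(de), 300L)
  expect_true(all(de$q >= de$p - 1e-15))
  expect_true(all(de$q >= 0 & de$q <= 1))
  expect_identical(de$significant, de$q < 0.05)
  # planted 8-fold gene strongly detected
  expect_true(de$q[1] < 0.05)
  expect_gt(de$log2fc[1], 1.5)
  # all-zero feature: NA fold change, p = 1
  expect_true(is.na(de$log2fc[2]))
  expect_equal(de$p[2], 1)
  # identical normalized means -> log2fc 0, p 1
  cts <- d$counts
  cts[3, ] <- 50L
  sf1 <- setNames(rep(1, 6), colnames(cts))
  de2 <- test_differential(cts, d$samples, sf1, "dox", 3)
  expect_equal(de2$log2fc[3], 0)
  expect_equal(de2$p[3], 1)
  # replicate guard
  expect_error(test_differential(d$counts[, c(1, 4:6)], d$samples[c(1, 4:6), ],
                                 sf[c(1, 4:6)], "dox", 3), ">=2 replicates")
})

test_that("planted 8-fold gene is recovered in nearly all simulation replicates", {
  # dispersion 0.05, n = 3 per stratum, 500 null genes
  set.seed(100)
  hits <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    d <- make_two_stratum_counts(501, 3, mu0 = rlnorm(501, log(100), 1),
                                 fc = 8, planted = 1L)
    sf <- estimate_size_factors(d$counts)
    de <- test_differential(d$counts, d$samples, sf, "dox", 3)
    hits <- hits + (de$q[1] < 0.05)
  }
  expect_gte(hits, 95L)
})

test_that("fold-change ratios follow the pseudocount arithmetic", {
  # counts: dox t 40, dox 0 10, ctrl t 10, ctrl 0 10; unit size factors
  counts <- matrix(c(10, 10, 40, 40, 10, 10, 10, 10), nrow = 1,
                   dimnames = list("g1", paste0("s", 1:8)))
  samples <- data.frame(
    sample_id = paste0("s", 1:8),
    condition = rep(c("dox", "dox", "control", "control"), each = 2),
    time_h = rep(c(0, 3), 4),
    replicate = rep(rep(1:2, each = 2), 2))
  # reorder so each (condition,time) has replicates 1,2
  samples <- data.frame(
    sample_id = paste0("s", 1:8),
    condition = rep(c("dox", "control"), each = 4),
    time_h = rep(c(0, 0, 3, 3), 2),
    replicate = rep(c(1, 2, 1, 2), 2))
  counts <- matrix(c(10, 10, 40, 40, 10, 10, 10, 10), nrow = 1,
                   dimnames = list("g1", samples$sample_id))
  sf <- setNames(rep(1, 8), samples$sample_id)
  fr <- fold_change_ratio(counts, samples, sf, 3)
  expect_equal(dim(fr$r), c(1L, 2L))
  expect_equal(unname(fr$r[1, ]), rep((40.5 / 10.5) / (10.5 / 10.5), 2),
               tolerance = 1e-12)
  # identical trajectories -> r = 1
  counts1 <- matrix(rep(c(10, 10, 40, 40), 2), nrow = 1,
                    dimnames = list("g1", samples$sample_id))
  fr1 <- fold_change_ratio(counts1, samples, sf, 3)
  expect_equal(unname(fr1$r[1, ]), c(1, 1))
  # all-pairs option returns one ratio per dox x control combination
  fr2 <- fold_change_ratio(counts, samples, sf, 3, pairing = "all_pairs")
  expect_identical(ncol(fr2$r), 4L)
})

test_that("ratio CI filter builds t intervals on log2 scale", {
  # zero variance -> point interval, flagged
  rc <- ratio_ci_filter(matrix(c(2, 2), 1), 0.95)
  expect_equal(rc$ci_low, 2)
  expect_equal(rc$ci_high, 2)
  expect_true(rc$osk_affected)
  # symmetric about 1 on log scale -> contains 1
  rc2 <- ratio_ci_filter(matrix(c(0.5, 2), 1), 0.95)
  expect_equal(rc2$r_geomean, 1)
  expect_false(rc2$osk_affected)
  # r = (2,4): mean log2 = 1.5, sd = sqrt(1/2), half-width = t(.975,1)*0.5
  rc3 <- ratio_ci_filter(matrix(c(2, 4), 1), 0.95)
  half <- qt(0.975, 1) * sqrt(0.5) / sqrt(2)
  expect_equal(rc3$ci_low, 2^(1.5 - half), tolerance = 1e-9)
  expect_equal(rc3$ci_high, 2^(1.5 + half), tolerance = 1e-9)
  expect_false(rc3$osk_affected)  # enormous df=1 interval contains 1
  expect_error(ratio_ci_filter(matrix(c(-1, 2), 1)), "positive")
  expect_error(ratio_ci_filter(matrix(2, 1, 1)), ">=2")
})

test_that("null CI-filter flag rate matches its nominal level", {
  # n = 2 log-normal ratios around 1: the t interval is exact, so the
  # flagged fraction at 95% confidence is 5% up to binomial error
  set.seed(31)
  n <- 20000
  r <- matrix(2^rnorm(2 * n, 0, 0.4), n, 2)
  frac <- mean(ratio_ci_filter(r, 0.95)$osk_affected)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac - 0.05), 4 * se)
})

test_that("OSKM-affected genes are the DE / CI-flag intersection", {
  de <- data.frame(feature_id = c("g1", "g2", "g3"), q = c(0.01, 0.01, 0.5))
  ratio <- data.frame(feature_id = c("g1", "g2", "g3"),
                      osk_affected = c(TRUE, FALSE, TRUE))
  expect_identical(osk_affected_genes(de, ratio, 0.05), "g1")
  expect_error(osk_affected_genes(de, ratio[1:2, ], 0.05), "universes")
})
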