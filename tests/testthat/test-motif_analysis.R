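test_that("PWM scanning reproduces the log2-odds arithmetic", {
  pw <- consensus_pwm("ACGT")
  hits <- scan_pwm("TTACGTTT", pw, 5)
  plus <- hits[hits$strand == "+", ]
  expect_identical(plus$offset, 2L)
  expect_equal(plus$score, 4 * log2(0.97 / 0.25), tolerance = 1e-12)
  # uniform PWM scores 0 everywhere
  upwm <- new_pwm("u", matrix(0.25, 4, 3))
  h <- scan_pwm("ACGTACG", upwm, -Inf)
  expect_true(all(abs(h$score) < 1e-12))
  expect_identical(nrow(h), 2L * 5L)
  # N windows skipped: only offsets 4..4 clear of the N at position 3 (0-based)
  hN <- scan_pwm("ACGNACGT", consensus_pwm("ACGT"), -Inf)
  expect_true(all(hN$offset == 4L))
  # motif longer than sequence: empty result, not an error
  expect_identical(nrow(scan_pwm("ACG", pw)), 0L)
  expect_error(scan_pwm("ACGX", pw), "invalid sequence")
})

test_that("scanning is strand-symmetric", {
  set.seed(5)
  pw <- random_pwm("r", 5)
  seq <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  rc <- revcomp(seq)
  h1 <- scan_pwm(seq, pw, -Inf)
  h2 <- scan_pwm(rc, pw, -Inf)
  # a + hit at offset o maps to a - hit at n - L - o on the reverse complement
  n <- nchar(seq); L <- 5
  m1 <- h1[order(h1$offset, h1$strand), ]
  h2$offset <- as.integer(n - L - h2$offset)
  h2$strand <- ifelse(h2$strand == "+", "-", "+")
  m2 <- h2[order(h2$offset, h2$strand), ]
  expect_equal(m1$score, m2$score, tolerance = 1e-12)
  expect_identical(m1$offset, m2$offset)
})

test_that("DP score p-values match enumeration for short motifs", {
  set.seed(9)
  for (L in c(3, 5, 6)) {
    pw <- random_pwm(paste0("r", L), L)
    scores <- quantile(replicate(5, sum(pw$lom[cbind(sample(1:4, L, TRUE),
                                                     seq_len(L))])),
                       c(0.1, 0.5, 0.9))
    for (s in scores)
      expect_lt(abs(score_pvalue(pw, s) - oracle_pwm_tail(pw, s)), 1e-3)
  }
  # uniform PWM: every achievable score ties, p = 1
  upwm <- new_pwm("u", matrix(0.25, 4, 4))
  expect_equal(score_pvalue(upwm, 0), 1)
  # above the maximum: bounded below by the top atom (1/4^L for uniform bg)
  pw <- consensus_pwm("ACGTA")
  expect_equal(score_pvalue(pw, 1e6), 0.25^5, tolerance = 1e-6)
  # monotone nonincreasing in score
  ss <- seq(-5, 10, length.out = 20)
  ps <- vapply(ss, function(s) score_pvalue(pw, s), numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("promoter presence calls recover planted sites at the designed rate", {
  set.seed(17)
  pw <- consensus_pwm("ATGCAAATTA", id = "Oct4")
  lib <- list(Oct4 = pw)
  # planted consensus site always found
  bg <- replicate(50, paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""))
  planted <- vapply(bg[1:25], function(s) {
    off <- sample(190, 1)
    substr(s, off, off + 9) <- "ATGCAAATTA"; s
  }, character(1))
  proms <- c(planted, bg[26:50])
  names(proms) <- sprintf("g%02d", 1:50)
  pres <- promoter_motif_presence(proms, lib, 1e-4)
  expect_true(all(pres[1:25, "Oct4"]))
  # empty promoter set rejected
  expect_error(promoter_motif_presence(character(), lib), "empty")
})

test_that("background presence probability matches the attained tail", {
  # null promoters: presence rate ~ 1 - (1 - p_tail)^(2 * n_windows) where
  # p_tail is the attained tail at the chosen threshold
  set.seed(23)
  pw <- consensus_pwm("ATGCAAAT", id = "m8")
  d <- oskmtc:::pwm_score_distribution(pw, 1e-3)
  thr <- pwm_score_threshold(pw, 1e-4)
  p_tail <- sum(d$probs[d$values >= thr])
  n_prom <- 4000; len <- 100
  proms <- vapply(seq_len(n_prom), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), character(1))
  names(proms) <- paste0("g", seq_len(n_prom))
  pres <- promoter_motif_presence(proms, list(m8 = pw), 1e-4)
  expected <- 1 - (1 - p_tail)^(2 * (len - 8 + 1))
  obs <- mean(pres)
  se <- sqrt(expected * (1 - expected) / n_prom)
  expect_lt(abs(obs - expected), 4 * se + 1e-4)
})

test_that("direct-effect genes are DE genes with an OSKM promoter motif", {
  pres <- matrix(FALSE, 3, 5,
                 dimnames = list(c("g1", "g2", "g3"),
                                 c("Oct4", "Sox2", "Klf4", "cMyc", "Oct4-Sox2")))
  pres["g1", "Sox2"] <- TRUE
  pres["g3", ] <- TRUE
  # g1: DE with Sox2 -> in; g2: DE without motifs -> out; g3: non-DE -> out
  expect_identical(direct_effect_genes(c("g1", "g2"), pres), "g1")
  expect_error(direct_effect_genes("g9", pres), "no promoter")
  expect_error(direct_effect_genes("g1", pres, motif_ids = "Nanog"),
               "unknown motif")
})

test_that("motif enrichment is an exact hypergeometric upper tail", {
  set.seed(41)
  pw <- consensus_pwm("ATGCAAAT", id = "m")
  site <- "ATGCAAAT"
  mk <- function(with_site) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    if (with_site) substr(s, 20, 27) <- site
    s
  }
  targets <- setNames(vapply(c(rep(TRUE, 8), rep(FALSE, 2)), mk, character(1)),
                      paste0("t", 1:10))
  background <- setNames(vapply(c(rep(TRUE, 10), rep(FALSE, 80)), mk, character(1)),
                         paste0("b", 1:90))
  p <- motif_enrichment(targets, background, pw, 1e-4)
  pres <- promoter_motif_presence(c(targets, background), list(m = pw), 1e-4)
  k <- sum(pres[1:10]); K <- sum(pres)
  expect_equal(p, oracle_hyper_tail(k, K, 10, 100), tolerance = 1e-12)
  # absent everywhere and present everywhere both give p = 1
  none <- setNames(vapply(rep(FALSE, 10), mk, character(1)), paste0("n", 1:10))
  expect_equal(motif_enrichment(none[1:5], none[6:10], pw), 1)
  all_in <- setNames(vapply(rep(TRUE, 10), mk, character(1)), paste0("a", 1:10))
  expect_equal(motif_enrichment(all_in[1:5], all_in[6:10], pw), 1)
})

test_that("hypergeometric tails match the enumeration oracle on small universes", {
  set.seed(3)
  for (i in 1:25) {
    N <- sample(20:200, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(oskmtc:::hypergeom_test(k, K, n, N),
                 oracle_hyper_tail(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("fluctuation ranking orders by SD of transformed p-values", {
  series <- rbind(
    data.frame(motif_id = "flat", time_h = c(0, 3, 6, 12, 24), p = 1e-3),
    data.frame(motif_id = "osc", time_h = c(0, 3, 6, 12, 24),
               p = c(1e-10, 1, 1e-10, 1, 1e-10)),
    data.frame(motif_id = "aaa", time_h = c(0, 3, 6, 12, 24), p = 1e-3))
  fr <- fluctuation_rank(series, k = 2)
  expect_identical(fr$motif_id[1], "osc")
  expect_equal(fr$score[fr$motif_id == "flat"], 0)
  # ties broken lexicographically: aaa before flat
  expect_lt(which(fr$motif_id == "aaa"), which(fr$motif_id == "flat"))
  expect_identical(sort(fr$rank), 1:3)
  expect_true(all(diff(fr$score) <= 1e-15))
  expect_identical(fr$top, c(TRUE, TRUE, FALSE))
  expect_error(fluctuation_rank(series[series$time_h == 0, ]), ">=2 time")
})

test_that("a planted oscillating motif outranks static decoys", {
  set.seed(55)
  n_genes <- 400
  pres <- matrix(runif(n_genes * 51) < 0.15, n_genes, 51,
                 dimnames = list(sprintf("g%03d", 1:n_genes),
                                 c("planted", sprintf("decoy%02d", 1:50))))
  carriers <- which(pres[, "planted"])
  times <- c(3, 6, 12, 24)
  targets <- lapply(seq_along(times), function(i) {
    if (i %% 2 == 1) {
      # carrier-rich target set
      rownames(pres)[c(sample(carriers, min(30, length(carriers))),
                       sample(seq_len(n_genes), 10))]
    } else rownames(pres)[sample(seq_len(n_genes), 40)]
  })
  names(targets) <- times
  series <- motif_enrichment_series(pres, targets)
  fr <- fluctuation_rank(series, k = 20)
  expect_identical(fr$motif_id[1], "planted")
})
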