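# Shared fixture builders: everything is generated in code, no stored data.

# minimal count table + sheet on disk; returns the two paths
write_tiny_counts <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  cp <- file.path(dir, "counts.tsv")
  sp <- file.path(dir, "samples.tsv")
  writeLines(c("feature_id\ts1\ts2",
               "g1\t10\t20",
               "g2\t5\t0"), cp)
  writeLines(c("sample_id\tcondition\ttime_h\treplicate",
               "s1\tdox\t0\t1",
               "s2\tdox\t3\t1"), sp)
  c(counts = cp, sheet = sp)
}

# near-consensus PWM: `consensus` string gets prob `p_hit`, others share the rest
consensus_pwm <- function(consensus, id = "m", p_hit = 0.97,
                          background = rep(0.25, 4)) {
  bases <- strsplit(consensus, "")[[1]]
  L <- length(bases)
  mat <- matrix((1 - p_hit) / 3, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  mat[cbind(match(bases, c("A", "C", "G", "T")), seq_len(L))] <- p_hit
  new_pwm(id, mat, background)
}

random_pwm <- function(id, L) {
  m <- matrix(stats::runif(4 * L, 0.05, 1), 4, L)
  new_pwm(id, sweep(m, 2, colSums(m), "/"))
}

# NB time-course matrix with two strata for DE unit tests
make_two_stratum_counts <- function(n_genes, n_rep, mu0, fc = 1, dispersion = 0.05,
                                    planted = integer(0)) {
  mu <- matrix(rep(mu0, 2 * n_rep), n_genes, 2 * n_rep)
  if (length(planted)) mu[planted, (n_rep + 1):(2 * n_rep)] <-
    mu[planted, (n_rep + 1):(2 * n_rep)] * fc
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   n_genes, 2 * n_rep,
                   dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                   sprintf("s%d", seq_len(2 * n_rep))))
  samples <- data.frame(sample_id = colnames(counts), condition = "dox",
                        time_h = rep(c(0, 3), each = n_rep),
                        replicate = rep(seq_len(n_rep), 2))
  list(counts = counts, samples = samples)
}

# independent brute-force oracles -------------------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  # q_(i) = min_{j >= i} m * p_(j) / j
  ps <- p[o]
  qs <- rev(cummin(rev(m * ps / seq_len(m))))
  q[o] <- pmin(qs, 1)
  q
}

oracle_size_factors <- function(counts) {
  keep <- apply(counts > 0, 1, all)
  ref <- apply(counts[keep, , drop = FALSE], 1, function(x) prod(x)^(1 / length(x)))
  sf <- vapply(seq_len(ncol(counts)), function(j)
    stats::median(counts[keep, j] / ref), numeric(1))
  sf <- sf / prod(sf)^(1 / length(sf))
  stats::setNames(sf, colnames(counts))
}

oracle_hyper_tail <- function(k, K, n, N) {
  # sum of choose() terms, upper tail P(X >= k)
  kk <- k:min(n, K)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# enumerate all 4^L words: exact score tail for small PWMs
oracle_pwm_tail <- function(pwm, score) {
  L <- ncol(pwm$prob)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- apply(words, 1, function(w) sum(pwm$lom[cbind(w, seq_len(L))]))
  pr <- apply(words, 1, function(w) prod(pwm$background[w]))
  sum(pr[sc >= score - 1e-9])
}

oracle_lda_grid <- function(groups, n_grid = 10000) {
  lf <- seq(log(1e-9), 0, length.out = n_grid)
  ll <- vapply(lf, function(x) {
    f <- exp(x)
    sum(groups$n_responded * log(-expm1(-f * groups$dose)) -
          (groups$n_tested - groups$n_responded) * f * groups$dose)
  }, numeric(1))
  exp(lf[which.max(ll)])
}
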