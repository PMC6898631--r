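#' Median-of-ratios size factors
#'
#' Computes per-sample library-size multipliers by the median-of-ratios
#' estimator: a per-feature geometric-mean reference over samples (restricted
#' to features positive in every sample), a per-sample median of
#' count/reference, rescaled so the size factors have geometric mean 1.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @return Named numeric vector of positive size factors, geometric mean 1.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0)) stop_data("counts must be non-negative")
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos))
    stop_data("no feature positive in all samples; size factors undefined")
  sub <- counts[allpos, , drop = FALSE]
  logref <- rowMeans(log(sub))
  sf <- apply(sub, 2L, function(col) stats::median(exp(log(col) - logref)))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Normalize counts by size factors
#' @param counts count matrix.
#' @param size_factors per-sample size factors (same order as columns).
#' @return Matrix of normalized counts (count / size factor).
#' @export
normalize_counts <- function(counts, size_factors) {
  sweep(as.matrix(counts), 2L, size_factors, "/")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; order preserving, output in [0, 1].
#'
#' @param p vector of p-values in [0, 1].
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop_data("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Method-of-moments NB dispersions with 50/50 shrinkage toward an
# a0 + a1/mu mean-dispersion trend. `group` is a factor over columns of the
# normalized count matrix; moments are pooled within groups.
estimate_dispersions <- function(norm, group, floor = 1e-8) {
  group <- as.factor(group)
  lv <- levels(group)
  num <- 0
  den <- 0
  for (g in lv) {
    cols <- which(group == g)
    if (length(cols) < 2L) next
    m <- rowMeans(norm[, cols, drop = FALSE])
    v <- apply(norm[, cols, drop = FALSE], 1L, stats::var)
    df <- length(cols) - 1L
    # (v - m) = alpha * m^2 under NB; pool numerator/denominator over groups
    num <- num + df * (v - m)
    den <- den + df * m^2
  }
  dftot <- sum(vapply(lv, function(g) max(sum(group == g) - 1L, 0L), integer(1)))
  mm <- ifelse(den > 0, num / den, NA_real_)
  mm <- pmax(mm, floor)
  mm[is.na(mm)] <- floor
  basemean <- rowMeans(norm)
  use <- basemean > 0 & mm > floor
  if (sum(use) >= 10L) {
    fit <- stats::lm(mm[use] ~ I(1 / basemean[use]))
    a0 <- max(unname(stats::coef(fit)[1]), floor)
    a1 <- max(unname(stats::coef(fit)[2]), 0)
  } else {
    a0 <- max(mean(mm[mm > floor], na.rm = TRUE), floor)
    if (!is.finite(a0)) a0 <- floor
    a1 <- 0
  }
  trend <- ifelse(basemean > 0, a0 + a1 / basemean, a0)
  structure(pmax(0.5 * mm + 0.5 * trend, floor), df = dftot)
}

#' Per-time-point negative-binomial differential test against 0 h
#'
#' For one condition, compares the time-`time` stratum with the same
#' condition's 0 h stratum feature by feature: normalized-count NB model with
#' per-feature method-of-moments dispersion (floored at 1e-8 and shrunk 50/50
#' toward a fitted mean-dispersion trend), Wald test on the log2 fold change,
#' two-sided p, and Benjamini-Hochberg q across features.
#'
#' @param counts feature x sample count matrix.
#' @param samples sample sheet (see [read_counts()]).
#' @param size_factors per-sample size factors aligned with `counts` columns.
#' @param condition `"dox"` or `"control"`.
#' @param time time point in hours (must be nonzero and present).
#' @param alpha FDR threshold for the `significant` flag.
#' @return Data frame with `feature_id`, `condition`, `time_h`, `base_mean`,
#'   `log2fc`, `p`, `q`, `significant`. Features with zero counts in both
#'   strata get `log2fc = NA` and `p = 1`.
#' @export
test_differential <- function(counts, samples, size_factors, condition, time,
                              alpha = 0.05) {
  if (time == 0) stop_data("time must be nonzero (contrast is vs 0 h)")
  idx_t <- which(samples$condition == condition & samples$time_h == time)
  idx_0 <- which(samples$condition == condition & samples$time_h == 0)
  if (length(idx_t) < 2L || length(idx_0) < 2L)
    stop_data("need >=2 replicates in both the time-", time,
              " and time-0 strata of condition '", condition, "'")
  # dispersions pooled within-stratum over ALL time points of the condition:
  # replicate-level moments from every stratum inform the per-feature
  # dispersion, which stabilizes the Wald statistic for the n = 2 design
  idx_all <- which(samples$condition == condition)
  norm_all <- normalize_counts(counts[, idx_all, drop = FALSE], size_factors[idx_all])
  disp <- estimate_dispersions(norm_all, factor(samples$time_h[idx_all]))
  cols <- c(idx_0, idx_t)
  norm <- normalize_counts(counts[, cols, drop = FALSE], size_factors[cols])
  group <- factor(rep(c("t0", "t1"), c(length(idx_0), length(idx_t))),
                  levels = c("t0", "t1"))
  s0 <- size_factors[idx_0]
  s1 <- size_factors[idx_t]
  q0 <- rowMeans(norm[, group == "t0", drop = FALSE])
  q1 <- rowMeans(norm[, group == "t1", drop = FALSE])
  # Var of the mean-of-normalized-counts estimator; for groups with mean 0 a
  # half-count floor keeps the Wald statistic finite and monotone.
  var_of_mean <- function(qhat, s, alpha_i) {
    qv <- pmax(qhat, 0.5)
    (1 / length(s)^2) * (qv * sum(1 / s) + alpha_i * qv^2 * length(s))
  }
  v0 <- var_of_mean(q0, s0, disp)
  v1 <- var_of_mean(q1, s1, disp)
  # delta method on log2 scale
  se <- sqrt(v1 / pmax(q1, 0.5)^2 + v0 / pmax(q0, 0.5)^2) / log(2)
  log2fc <- ifelse(q0 == 0 & q1 == 0, NA_real_,
            ifelse(q0 == 0, Inf, ifelse(q1 == 0, -Inf, log2(q1 / q0))))
  # Wald z uses floored means when one side is zero so p stays finite
  lfc_for_z <- log2(pmax(q1, 0.5) / pmax(q0, 0.5))
  z <- lfc_for_z / se
  # Small-sample reference: t with effective df = 2x the pooled
  # within-stratum replication df behind the dispersion estimate (the factor
  # 2 credits the variance reduction of the 50/50 trend shrinkage). A normal
  # reference is anticonservative at this replication depth.
  nu <- max(2 * attr(disp, "df"), 1L)
  p <- 2 * stats::pt(-abs(z), df = nu)
  p[q0 == 0 & q1 == 0] <- 1
  p[!is.na(log2fc) & log2fc == 0] <- 1
  p <- pmin(p, 1)
  q <- bh_adjust(p)
  data.frame(feature_id = rownames(counts),
             condition = condition, time_h = time,
             base_mean = rowMeans(norm),
             log2fc = log2fc, p = p, q = q,
             significant = q < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Replicate-pair fold-change ratios between dox and control arms
#'
#' For each feature at time `time`, and each replicate pair i (dox replicate
#' i matched with control replicate i by default), computes the fold change
#' vs the same arm's 0 h sample with pseudocount `pseudocount` on normalized
#' counts, and the ratio r_i = FC_dox,i / FC_ctrl,i. Ratios near 1 indicate
#' changes shared with the untreated culture (culture-intrinsic drift) rather
#' than effects of OSKM induction.
#'
#' @param counts,samples,size_factors as in [test_differential()].
#' @param time nonzero time point.
#' @param pairing `"index"` pairs dox and control replicates by replicate
#'   number; `"all_pairs"` uses every dox x control combination.
#' @param pseudocount added to normalized counts before forming fold changes.
#' @return List with `feature_id`, `time_h` and matrix `r` (features x pairs).
#' @export
fold_change_ratio <- function(counts, samples, size_factors, time,
                              pairing = c("index", "all_pairs"),
                              pseudocount = 0.5) {
  pairing <- match.arg(pairing)
  norm <- normalize_counts(counts, size_factors)
  pick <- function(cond, tt) {
    i <- which(samples$condition == cond & samples$time_h == tt)
    i[order(samples$replicate[i])]
  }
  d_t <- pick("dox", time); d_0 <- pick("dox", 0)
  c_t <- pick("control", time); c_0 <- pick("control", 0)
  if (length(d_t) < 2L || length(d_0) < 2L || length(c_t) < 2L || length(c_0) < 2L)
    stop_data("dox and control strata at time ", time, " and 0 each need >=2 replicates")
  fc <- function(it, i0) (norm[, it] + pseudocount) / (norm[, i0] + pseudocount)
  if (pairing == "index") {
    rd <- samples$replicate[d_t]
    if (!identical(rd, samples$replicate[d_0]) ||
        !identical(rd, samples$replicate[c_t]) ||
        !identical(rd, samples$replicate[c_0]))
      stop_data("replicate indices do not match across strata under 'index' pairing")
    r <- vapply(seq_along(d_t),
                function(i) fc(d_t[i], d_0[i]) / fc(c_t[i], c_0[i]),
                numeric(nrow(norm)))
  } else {
    combos <- expand.grid(di = seq_along(d_t), ci = seq_along(c_t))
    r <- vapply(seq_len(nrow(combos)), function(k) {
      i <- combos$di[k]; j <- combos$ci[k]
      fc(d_t[i], d_0[i]) / fc(c_t[j], c_0[j])
    }, numeric(nrow(norm)))
  }
  r <- matrix(r, nrow = nrow(norm))
  rownames(r) <- rownames(counts)
  list(feature_id = rownames(counts), time_h = time, r = r)
}

#' Confidence-interval filter on replicate fold-change ratios
#'
#' Builds a t confidence interval on the mean of log2(r) across replicate
#' pairs (df = n - 1), exponentiates back to the ratio scale, and flags a
#' feature as OSKM-affected when the interval excludes 1. With zero variance
#' the interval degenerates to the point {r}.
#'
#' @param ratios result of [fold_change_ratio()], or a bare matrix of
#'   positive ratios (features x replicate pairs).
#' @param confidence confidence level in (0, 1).
#' @return Data frame with `feature_id`, `time_h` (NA for bare matrices),
#'   `r_geomean`, `ci_low`, `ci_high`, `osk_affected`.
#' @export
ratio_ci_filter <- function(ratios, confidence = 0.95) {
  if (confidence <= 0 || confidence >= 1) stop_config("confidence must be in (0,1)")
  if (is.list(ratios) && !is.data.frame(ratios)) {
    r <- ratios$r; time_h <- ratios$time_h; ids <- ratios$feature_id
  } else {
    r <- as.matrix(ratios); time_h <- NA_real_
    ids <- rownames(r)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(r)))
  }
  if (ncol(r) < 2L) stop_data("need >=2 replicate ratios")
  if (any(r <= 0)) stop_data("ratios must be positive")
  lr <- log2(r)
  m <- rowMeans(lr)
  s <- sqrt(rowSums((lr - m)^2) / (ncol(r) - 1L))
  half <- stats::qt((1 + confidence) / 2, df = ncol(r) - 1L) * s / sqrt(ncol(r))
  ci_low <- 2^(m - half)
  ci_high <- 2^(m + half)
  data.frame(feature_id = ids, time_h = time_h,
             r_geomean = 2^m, ci_low = ci_low, ci_high = ci_high,
             osk_affected = ci_low > 1 | ci_high < 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' OSKM-affected differentially expressed genes
#'
#' Intersects, per time point, the dox-vs-0h differential calls (q < alpha)
#' with the fold-change-ratio CI flag: a gene is OSKM-affected when it is
#' both differentially expressed and its dox/control ratio interval excludes
#' 1 (so shared culture drift is filtered out).
#'
#' @param de data frame from [test_differential()] (dox arm).
#' @param ratio data frame from [ratio_ci_filter()] for the same time point.
#' @param alpha FDR threshold.
#' @return Character vector of gene ids (sorted).
#' @export
osk_affected_genes <- function(de, ratio, alpha = 0.05) {
  if (!setequal(de$feature_id, ratio$feature_id))
    stop_data("DE and ratio results cover different feature universes")
  flag <- ratio$osk_affected[match(de$feature_id, ratio$feature_id)]
  sort(de$feature_id[de$q < alpha & flag])
}
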