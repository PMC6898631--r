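encode_seq <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% c("A", "C", "G", "T", "N"))
  if (any(bad)) stop_data("invalid sequence character: ", chars[which(bad)[1]])
  match(chars, c("A", "C", "G", "T"))  # N -> NA
}

# PWM for the reverse-complement strand: complement bases, reverse columns
revcomp_pwm_matrix <- function(lom) lom[4:1, rev(seq_len(ncol(lom))), drop = FALSE]

#' Scan a sequence with a PWM
#'
#' Scores every offset on both strands with the log2-odds score
#' sum(log2(p_base / q_base)); the minus strand is scored via the
#' reverse-complement matrix on the same coordinates. Windows containing N
#' are skipped.
#'
#' @param seq DNA string over ACGTN.
#' @param pwm a `pwm` object ([new_pwm()]).
#' @param score_threshold minimum score (bits) to report.
#' @return Data frame of hits (`offset` 0-based, `strand`, `score`) sorted by
#'   offset; empty when the motif is longer than the sequence.
#' @export
scan_pwm <- function(seq, pwm, score_threshold = -Inf) {
  code <- encode_seq(seq)
  L <- ncol(pwm$lom)
  n <- length(code)
  if (L > n)
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  n_off <- n - L + 1L
  score_with <- function(lom) {
    sc <- numeric(n_off)
    for (j in seq_len(L)) {
      b <- code[seq.int(j, j + n_off - 1L)]
      sc <- sc + lom[b + (j - 1L) * 4L]   # lom[b, j]; NA propagates for N
    }
    sc
  }
  sp <- score_with(pwm$lom)
  sm <- score_with(revcomp_pwm_matrix(pwm$lom))
  keep_p <- which(!is.na(sp) & sp >= score_threshold)
  keep_m <- which(!is.na(sm) & sm >= score_threshold)
  hits <- rbind(
    data.frame(offset = keep_p - 1L, strand = rep("+", length(keep_p)),
               score = sp[keep_p]),
    data.frame(offset = keep_m - 1L, strand = rep("-", length(keep_m)),
               score = sm[keep_m]))
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Exact distribution of the log2-odds score of a random background word,
# by dynamic programming over a lattice of bin-width `bin` bits.
# Returns list(values = score at each lattice point, probs).
pwm_score_distribution <- function(pwm, bin = 1e-3) {
  lom_int <- round(pwm$lom / bin)
  L <- ncol(lom_int)
  lo <- sum(apply(lom_int, 2L, min))
  hi <- sum(apply(lom_int, 2L, max))
  probs <- numeric(hi - lo + 1L)
  # start: distribution concentrated at 0 before adding columns
  cur_lo <- 0L
  cur <- 1
  for (j in seq_len(L)) {
    cmin <- min(lom_int[, j]); cmax <- max(lom_int[, j])
    new_lo <- cur_lo + cmin
    new <- numeric(length(cur) + (cmax - cmin))
    for (b in 1:4) {
      off <- lom_int[b, j] - cmin
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + pwm$background[b] * cur
    }
    cur <- new
    cur_lo <- new_lo
  }
  list(values = (cur_lo + seq_along(cur) - 1L) * bin, probs = cur, bin = bin)
}

#' Exact p-value of a PWM score
#'
#' P(random background word of length L scores >= `score`), computed by exact
#' dynamic programming over a discretized score lattice (bin width 1e-3
#' bits). For a score above the maximum achievable the top atom of the
#' distribution is returned, so p never drops below the probability of the
#' best word (>= 1/4^L under a uniform background).
#'
#' @param pwm a `pwm` object.
#' @param score score in bits.
#' @param bin lattice bin width in bits.
#' @return p-value in (0, 1].
#' @export
score_pvalue <- function(pwm, score, bin = 1e-3) {
  d <- pwm_score_distribution(pwm, bin)
  # half-bin slack keeps exact tie scores counted; per-column rounding is
  # unbiased so total lattice error stays well under the bin width
  p <- sum(d$probs[d$values >= score - bin / 2 - 1e-12])
  if (p <= 0) p <- d$probs[length(d$probs)]
  min(p, 1)
}

#' Score threshold attaining a target p-value
#'
#' Smallest score whose exact tail probability is at most `presence_p`; used
#' to calibrate motif-presence calls comparably across motifs of different
#' lengths and information content.
#'
#' @param pwm a `pwm` object.
#' @param presence_p target tail probability in (0, 1).
#' @param bin lattice bin width in bits.
#' @return Score in bits, or `Inf` when no achievable score is rare enough
#'   (then the motif can never be called present at this stringency).
#' @export
pwm_score_threshold <- function(pwm, presence_p, bin = 1e-3) {
  d <- pwm_score_distribution(pwm, bin)
  occ <- which(d$probs > 0)
  tail <- rev(cumsum(rev(d$probs)))
  i <- occ[tail[occ] <= presence_p]
  if (!length(i)) return(Inf)
  i <- i[1]
  below <- occ[occ < i]
  # midpoint between the included and excluded score tiers: robust to the
  # per-window lattice rounding error, which is far smaller than tier gaps
  if (length(below)) (d$values[i] + d$values[max(below)]) / 2
  else d$values[i] - bin
}

#' Promoter motif presence matrix
#'
#' A gene's promoter contains a motif when at least one window on either
#' strand scores with exact p-value <= `presence_p`.
#'
#' @param promoters named character vector of promoter sequences (names are
#'   gene ids).
#' @param motifs motif library from [read_motifs()].
#' @param presence_p per-window score p-value threshold.
#' @return Logical matrix, genes x motifs.
#' @export
promoter_motif_presence <- function(promoters, motifs, presence_p = 1e-4) {
  if (!length(promoters)) stop_data("empty promoter set")
  if (is.null(names(promoters))) stop_data("promoters must be named by gene id")
  out <- matrix(FALSE, length(promoters), length(motifs),
                dimnames = list(names(promoters), names(motifs)))
  for (mid in names(motifs)) {
    thr <- pwm_score_threshold(motifs[[mid]], presence_p)
    if (!is.finite(thr)) next
    out[, mid] <- vapply(promoters, function(s) {
      nrow(scan_pwm(s, motifs[[mid]], thr)) > 0L
    }, logical(1))
  }
  out
}

#' OSKM direct-effect genes
#'
#' Differentially expressed genes whose promoter contains at least one of
#' the named reprogramming-factor motifs (by default Oct4, Sox2, Klf4, cMyc
#' or the composite Oct4-Sox2 element).
#'
#' @param de_genes character vector of DE gene ids for one time point, or a
#'   named list of such vectors (one per time point).
#' @param presence logical gene x motif matrix from
#'   [promoter_motif_presence()].
#' @param motif_ids motifs whose presence defines a direct effect.
#' @return Sorted gene vector, or a named list of them when `de_genes` is a
#'   list.
#' @export
direct_effect_genes <- function(de_genes, presence,
                                motif_ids = c("Oct4", "Sox2", "Klf4", "cMyc",
                                              "Oct4-Sox2")) {
  unknown <- setdiff(motif_ids, colnames(presence))
  if (length(unknown)) stop_data("unknown motif id: ", paste(unknown, collapse = ", "))
  one <- function(genes) {
    missing <- setdiff(genes, rownames(presence))
    if (length(missing)) stop_data("no promoter for gene: ",
                                   paste(missing, collapse = ", "))
    hit <- rowSums(presence[genes, motif_ids, drop = FALSE]) > 0L
    sort(genes[hit])
  }
  if (is.list(de_genes)) lapply(de_genes, one) else one(de_genes)
}

#' Motif enrichment of a target sequence set over a background
#'
#' Calls sequence-level presence at `presence_p` in both sets and tests
#' over-representation of the motif among targets with a one-sided
#' hypergeometric upper tail on the union universe.
#'
#' @param targets,background named character vectors of sequences; overlap
#'   (by name) is allowed and deduplicated into the universe.
#' @param pwm a `pwm` object.
#' @param presence_p presence threshold (exact score p-value).
#' @return Enrichment p-value in (0, 1].
#' @export
motif_enrichment <- function(targets, background, pwm, presence_p = 1e-4) {
  if (!length(targets) || !length(background))
    stop_data("target and background sets must be non-empty")
  if (is.null(names(targets)))
    names(targets) <- paste0("t", seq_along(targets))
  if (is.null(names(background)))
    names(background) <- paste0("b", seq_along(background))
  universe <- c(targets, background[setdiff(names(background), names(targets))])
  lib <- list(m = pwm); names(lib) <- pwm$id
  pres <- promoter_motif_presence(universe, structure(list(pwm), names = pwm$id),
                                  presence_p)[, 1L]
  hypergeom_test(k = sum(pres[names(targets)]),
                 K = sum(pres),
                 n = length(targets),
                 N = length(universe))
}

# one-sided upper-tail hypergeometric: P(X >= k), X ~ Hypergeom(N, K, n)
hypergeom_test <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Per-time enrichment series from a presence matrix
#'
#' Computes, for every motif and time point, the hypergeometric enrichment
#' p-value of the motif among the target genes for that time against the
#' rest of the universe (or a supplied background).
#'
#' @param presence logical gene x motif matrix.
#' @param targets_by_time named list (names are time points) of gene-id
#'   vectors; each must be a subset of the presence rows.
#' @param background_ids optional background gene ids; defaults to all
#'   presence rows not in the target set at that time.
#' @return Long data frame `motif_id`, `time_h`, `p`.
#' @export
motif_enrichment_series <- function(presence, targets_by_time,
                                    background_ids = NULL) {
  if (is.null(names(targets_by_time)))
    stop_data("targets_by_time must be named by time point")
  rows <- list()
  for (tt in names(targets_by_time)) {
    tg <- targets_by_time[[tt]]
    missing <- setdiff(tg, rownames(presence))
    if (length(missing)) stop_data("target gene not in presence matrix: ",
                                   paste(missing, collapse = ", "))
    bg <- if (is.null(background_ids))
      setdiff(rownames(presence), tg) else setdiff(background_ids, tg)
    if (!length(tg) || !length(bg))
      stop_data("empty target or background at time ", tt)
    uni <- c(tg, bg)
    sub <- presence[uni, , drop = FALSE]
    k <- colSums(presence[tg, , drop = FALSE])
    K <- colSums(sub)
    p <- hypergeom_test(k, K, length(tg), length(uni))
    rows[[tt]] <- data.frame(motif_id = colnames(presence),
                             time_h = as.numeric(tt), p = pmin(pmax(p, 0), 1),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank motifs by fluctuation of enrichment p-values across time
#'
#' The score is the sample standard deviation of the (transformed)
#' enrichment p-value across time points: a motif whose enrichment swings
#' between time points scores high, a statically enriched or never-enriched
#' motif scores near zero. By default p-values are -log10 transformed
#' (floored at 1e-300) so the score does not saturate when p pins near 0; a
#' raw-p option preserves the alternative reading.
#'
#' @param series long data frame `motif_id`, `time_h`, `p` (all motifs on
#'   the same time grid, >= 2 time points).
#' @param transform `"neglog10"` or `"raw"`.
#' @param k number of top motifs to flag.
#' @return Data frame `motif_id`, `score`, `rank`, `top`, sorted by rank;
#'   ties in score are broken lexicographically by motif id.
#' @export
fluctuation_rank <- function(series, transform = c("neglog10", "raw"), k = 20) {
  transform <- match.arg(transform)
  times <- sort(unique(series$time_h))
  if (length(times) < 2L) stop_data("need >=2 time points")
  tab <- table(series$motif_id)
  if (any(tab != length(times)))
    stop_data("every motif needs exactly one p-value per time point")
  f <- if (transform == "neglog10") function(p) -log10(pmax(p, 1e-300)) else identity
  sp <- split(f(series$p), series$motif_id)
  score <- vapply(sp, stats::sd, numeric(1))
  ids <- names(score)
  ord <- order(-score, ids)
  out <- data.frame(motif_id = ids[ord], score = unname(score[ord]),
                    rank = seq_along(ord),
                    top = seq_along(ord) <= min(k, length(ord)),
                    stringsAsFactors = FALSE)
  if (k > length(ord)) warning("k exceeds number of motifs; returning all")
  out
}
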