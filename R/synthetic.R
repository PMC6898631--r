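# deterministic per-stage seed derivation: polynomial hash of the stage name
# mixed with the global seed, kept inside 32-bit integer range
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Build a simulation configuration
#'
#' Defaults encode the study conditions the pipeline is designed for: a
#' doxycycline time course at 0/3/6/12/24 h with 2 biological replicates,
#' negative-binomial counts (dispersion 0.05), 4-fold planted OSKM effects
#' on 5% of genes, a culture-drift term shared between the dox and control
#' arms, and two response profiles: `AML`-like cells respond from 3 h with
#' CO-dominated chromatin dynamics, `HSPC`-like cells show no change until
#' 12 h with mostly OC dynamics and ~37x fewer changed regions.
#'
#' @param seed integer master seed; every generator derives its own stream
#'   from it.
#' @param n_genes,n_peaks problem sizes.
#' @param times time grid in hours (must include 0).
#' @param replicates biological replicates per (condition, time) stratum.
#' @param lib_size_range uniform range of per-sample library scale factors.
#' @param dispersion NB dispersion (1/size).
#' @param base_mean_meanlog,base_mean_sdlog log-normal base-mean parameters.
#' @param affected_fraction fraction of genes with a planted OSKM effect.
#' @param effect_size multiplicative effect of induction on affected genes.
#' @param drift_fraction,drift_sd fraction of genes with shared culture
#'   drift and the sd (log2) of the per-time drift factor.
#' @param onset named onset hours per profile (effects apply from t >= onset).
#' @param peak_effect multiplicative accessibility change of planted peaks.
#' @param peak_plan named list per profile; each entry is a data frame with
#'   `class` ("CO"/"OC"), `onset`, `n`.
#' @param genome_length,n_tss toy genome size and TSS count.
#' @param peak_width_range peak widths (bp).
#' @param promoter_window c(upstream, downstream) of TSS, strand-aware.
#' @param gc background GC content of simulated promoters.
#' @param n_death_genes designated "death-pathway" genes that receive
#'   CO peaks within 1 kb of their TSS in the AML profile.
#' @param presence_p motif presence threshold carried into downstream calls.
#' @param lda list: true frequencies `f_a`, `f_b`, `doses`, `n_per_dose`.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1000L, n_peaks = 1000L,
                       times = c(0, 3, 6, 12, 24),
                       replicates = 2L,
                       lib_size_range = c(0.7, 1.4),
                       dispersion = 0.05,
                       base_mean_meanlog = log(100), base_mean_sdlog = 1,
                       affected_fraction = 0.05, effect_size = 4,
                       drift_fraction = 0.10, drift_sd = 0.75,
                       onset = c(AML = 3, HSPC = 12),
                       peak_effect = 6,
                       peak_plan = list(
                         AML = data.frame(class = c("CO", "CO", "OC"),
                                          onset = c(3, 12, 12),
                                          n = c(180L, 80L, 40L)),
                         HSPC = data.frame(class = c("CO", "OC"),
                                           onset = c(12, 12),
                                           n = c(3L, 5L))),
                       genome_length = 1e6, n_tss = 500L,
                       peak_width_range = c(200L, 400L),
                       promoter_window = c(-500L, 100L),
                       gc = 0.5,
                       n_death_genes = 30L,
                       presence_p = 1e-4,
                       lda = list(f_a = 1 / 620, f_b = 1 / 28000,
                                  doses = c(3e2, 3e3, 3e4, 3e5),
                                  n_per_dose = 6L)) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_peaks = as.integer(n_peaks), times = times,
              replicates = as.integer(replicates),
              lib_size_range = lib_size_range, dispersion = dispersion,
              base_mean_meanlog = base_mean_meanlog,
              base_mean_sdlog = base_mean_sdlog,
              affected_fraction = affected_fraction,
              effect_size = effect_size,
              drift_fraction = drift_fraction, drift_sd = drift_sd,
              onset = onset, peak_effect = peak_effect, peak_plan = peak_plan,
              genome_length = genome_length, n_tss = as.integer(n_tss),
              peak_width_range = peak_width_range,
              promoter_window = promoter_window, gc = gc,
              n_death_genes = as.integer(n_death_genes),
              presence_p = presence_p, lda = lda)
  if (!0 %in% cfg$times) stop_config("time grid must include 0")
  if (cfg$replicates < 2L) stop_config("need >=2 replicates")
  fr <- c(cfg$affected_fraction, cfg$drift_fraction, cfg$gc)
  if (any(fr < 0 | fr > 1)) stop_config("fractions must lie in [0, 1]")
  if (any(c(cfg$n_genes, cfg$n_peaks, cfg$n_tss) < 1L))
    stop_config("counts must be positive")
  if (cfg$dispersion <= 0 || cfg$effect_size <= 0 || cfg$peak_effect <= 0)
    stop_config("dispersion and effect sizes must be positive")
  for (pf in names(cfg$peak_plan)) {
    pl <- cfg$peak_plan[[pf]]
    if (sum(pl$n) > cfg$n_peaks)
      stop_config("peak plan for ", pf, " exceeds n_peaks")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a dox/control expression time course with planted truth
#'
#' Generates NB counts for a dox arm and a parallel control arm over the
#' configured time grid. Affected genes get a multiplicative dox-only effect
#' (up or down, balanced) from the profile's onset time. Drift genes get a
#' per-time log-normal factor applied to BOTH arms: these are the
#' culture-intrinsic changes the ratio CI filter is designed to remove.
#'
#' @param config a [sim_config()].
#' @param profile `"AML"` or `"HSPC"`.
#' @return List `counts`, `samples`, `truth` (per-gene `osk_affected`,
#'   `direction`, `drift`).
#' @export
generate_timecourse_counts <- function(config, profile = c("AML", "HSPC")) {
  profile <- match.arg(profile)
  onset <- config$onset[[profile]]
  with_seed(derive_seed(config$seed, paste0("counts_", profile)), {
    ng <- config$n_genes
    genes <- sprintf("gene%04d", seq_len(ng))
    base <- stats::rlnorm(ng, config$base_mean_meanlog, config$base_mean_sdlog)
    n_aff <- round(ng * config$affected_fraction)
    affected <- sort(sample.int(ng, n_aff))
    direction <- rep(0L, ng)
    direction[affected] <- rep_len(c(1L, -1L), n_aff)
    n_drift <- round(ng * config$drift_fraction)
    drift_genes <- sort(sample.int(ng, n_drift))
    tt <- config$times
    drift <- matrix(1, ng, length(tt), dimnames = list(genes, tt))
    for (j in which(tt > 0))
      drift[drift_genes, j] <- 2^stats::rnorm(n_drift, 0, config$drift_sd)
    samples <- expand.grid(replicate = seq_len(config$replicates),
                           time_h = tt, condition = c("dox", "control"),
                           stringsAsFactors = FALSE)
    samples <- samples[, c("condition", "time_h", "replicate")]
    samples$sample_id <- sprintf("%s_t%g_r%d", samples$condition,
                                 samples$time_h, samples$replicate)
    samples <- samples[, c("sample_id", "condition", "time_h", "replicate")]
    lib <- stats::runif(nrow(samples), config$lib_size_range[1],
                        config$lib_size_range[2])
    counts <- matrix(0L, ng, nrow(samples), dimnames = list(genes, samples$sample_id))
    eff <- config$effect_size^direction
    for (s in seq_len(nrow(samples))) {
      j <- match(samples$time_h[s], tt)
      mu <- base * drift[, j]
      if (samples$condition[s] == "dox" && samples$time_h[s] >= onset)
        mu <- mu * eff
      counts[, s] <- stats::rnbinom(ng, mu = mu * lib[s],
                                    size = 1 / config$dispersion)
    }
    storage.mode(counts) <- "integer"
    truth <- data.frame(gene_id = genes,
                        osk_affected = seq_len(ng) %in% affected,
                        direction = direction,
                        drift = seq_len(ng) %in% drift_genes,
                        stringsAsFactors = FALSE)
    list(counts = counts, samples = samples, truth = truth)
  })
}

#' Simulate an accessibility peak experiment with planted CO/OC dynamics
#'
#' Builds a toy genome (one chromosome) with TSSs, draws peak intervals, and
#' plants CO/OC accessibility changes per the profile's peak plan: each
#' planted peak's mean is multiplied (CO) or divided (OC) by `peak_effect`
#' from its onset time onward. A subset of CO peaks is placed within 1 kb of
#' designated "death-pathway" gene TSSs (AML profile). Counts carry only a
#' dox arm (accessibility is compared to the 0 h baseline within the induced
#' cells).
#'
#' @param config a [sim_config()].
#' @param profile `"AML"` or `"HSPC"`.
#' @return List `counts`, `samples`, `peaks`, `tss`, `truth` (per-peak
#'   planted class/onset and, per time, the planted class), plus
#'   `death_genes`.
#' @export
generate_peak_experiment <- function(config, profile = c("AML", "HSPC")) {
  profile <- match.arg(profile)
  plan <- config$peak_plan[[profile]]
  with_seed(derive_seed(config$seed, paste0("peaks_", profile)), {
    np <- config$n_peaks
    glen <- config$genome_length
    tsspos <- sort(sample.int(glen - 20000L, config$n_tss) + 10000L)
    tss <- data.frame(gene_id = sprintf("gene%04d", seq_len(config$n_tss)),
                      chrom = "chr1", tss_position = tsspos,
                      strand = sample(c("+", "-"), config$n_tss, replace = TRUE),
                      stringsAsFactors = FALSE)
    death_genes <- sort(sample(tss$gene_id, config$n_death_genes))
    width <- sample(seq(config$peak_width_range[1], config$peak_width_range[2]),
                    np, replace = TRUE)
    center <- sample.int(glen - 2000L, np) + 1000L
    # planted classes: assign plan rows to distinct peaks
    planted_class <- rep("NC", np)
    planted_onset <- rep(NA_real_, np)
    pool <- sample.int(np)   # random distinct peaks for planting
    taken <- 0L
    for (r in seq_len(nrow(plan))) {
      idx <- pool[taken + seq_len(plan$n[r])]
      taken <- taken + plan$n[r]
      planted_class[idx] <- plan$class[r]
      planted_onset[idx] <- plan$onset[r]
    }
    # place some planted CO peaks within 1 kb of death-gene TSSs
    co_idx <- which(planted_class == "CO")
    n_place <- min(length(co_idx), length(death_genes))
    if (n_place > 0) {
      place <- co_idx[seq_len(n_place)]
      dg_pos <- tss$tss_position[match(death_genes[seq_len(n_place)], tss$gene_id)]
      center[place] <- dg_pos + sample(-800:800, n_place, replace = TRUE)
    }
    start <- pmax(center - width %/% 2L, 0L)
    end <- start + width
    peaks <- data.frame(peak_id = sprintf("peak%04d", seq_len(np)),
                        chrom = "chr1", start = start, end = end,
                        stringsAsFactors = FALSE)
    tt <- config$times
    samples <- expand.grid(replicate = seq_len(config$replicates), time_h = tt,
                           stringsAsFactors = FALSE)
    samples$condition <- "dox"
    samples$sample_id <- sprintf("atac_t%g_r%d", samples$time_h, samples$replicate)
    samples <- samples[, c("sample_id", "condition", "time_h", "replicate")]
    lib <- stats::runif(nrow(samples), config$lib_size_range[1],
                        config$lib_size_range[2])
    base <- stats::rlnorm(np, config$base_mean_meanlog, config$base_mean_sdlog)
    counts <- matrix(0L, np, nrow(samples),
                     dimnames = list(peaks$peak_id, samples$sample_id))
    for (s in seq_len(nrow(samples))) {
      mu <- base
      active <- !is.na(planted_onset) & samples$time_h[s] >= planted_onset
      mu[active & planted_class == "CO"] <-
        mu[active & planted_class == "CO"] * config$peak_effect
      mu[active & planted_class == "OC"] <-
        mu[active & planted_class == "OC"] / config$peak_effect
      counts[, s] <- stats::rnbinom(np, mu = mu * lib[s],
                                    size = 1 / config$dispersion)
    }
    storage.mode(counts) <- "integer"
    class_at <- sapply(tt, function(t0) {
      ifelse(!is.na(planted_onset) & t0 >= planted_onset, planted_class, "NC")
    })
    colnames(class_at) <- tt
    truth <- data.frame(peak_id = peaks$peak_id,
                        planted_class = planted_class,
                        planted_onset = planted_onset,
                        stringsAsFactors = FALSE)
    truth <- cbind(truth, stats::setNames(as.data.frame(class_at),
                                          paste0("class_t", tt)))
    list(counts = counts, samples = samples, peaks = peaks, tss = tss,
         truth = truth, death_genes = death_genes)
  })
}

#' Consensus word of a PWM (argmax base per column)
#' @param pwm a `pwm` object.
#' @return Consensus DNA string.
#' @export
pwm_consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$prob, 2L, which.max)], collapse = "")
}

#' Simulate promoter sequences with planted motif sites
#'
#' Generates i.i.d. background promoters at the configured GC content for
#' every gene, then plants one consensus site (random offset, random strand)
#' per (gene, motif) pair in `plant`, so planted sites are recoverable at
#' any presence threshold the motif can attain.
#'
#' @param config a [sim_config()].
#' @param gene_ids promoter names.
#' @param motifs motif library.
#' @param plant data frame `gene_id`, `motif_id` of sites to plant (may be
#'   empty).
#' @return List `promoters` (named character vector) and `plant` (with the
#'   chosen `offset` and `strand` recorded).
#' @export
generate_promoters <- function(config, gene_ids, motifs, plant = NULL) {
  if (is.null(plant))
    plant <- data.frame(gene_id = character(), motif_id = character())
  width <- config$promoter_window[2] - config$promoter_window[1]
  with_seed(derive_seed(config$seed, "promoters"), {
    pr <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2, (1 - config$gc) / 2)
    proms <- vapply(gene_ids, function(g)
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE, prob = pr),
            collapse = ""), character(1))
    names(proms) <- gene_ids
    offs <- integer(nrow(plant)); strs <- character(nrow(plant))
    for (i in seq_len(nrow(plant))) {
      g <- plant$gene_id[i]
      pwm <- motifs[[plant$motif_id[i]]]
      if (is.null(pwm)) stop_data("unknown motif id: ", plant$motif_id[i])
      L <- ncol(pwm$prob)
      if (L > width) stop_data("promoter shorter than motif ", pwm$id)
      site <- pwm_consensus(pwm)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") site <- revcomp(site)
      off <- sample.int(width - L + 1L, 1L) - 1L
      s <- proms[[g]]
      substr(s, off + 1L, off + L) <- site
      proms[[g]] <- s
      offs[i] <- off; strs[i] <- strand
    }
    plant$offset <- offs
    plant$strand <- strs
    list(promoters = proms, plant = plant)
  })
}

#' Reverse complement of a DNA string
#' @param seq DNA string over ACGTN.
#' @return Reverse complement.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' Draws random sets from the universe plus one set (`CELL_DEATH_UP`) whose
#' membership is enriched for the planted OSKM-affected genes at the given
#' odds ratio.
#'
#' @param config a [sim_config()].
#' @param universe gene ids.
#' @param affected_genes planted OSKM-affected gene ids.
#' @param n_sets number of random decoy sets.
#' @param size_range decoy set size range.
#' @param odds_ratio membership odds ratio affected : unaffected in the
#'   planted set.
#' @param target_size expected size of the planted set.
#' @return Named list in [read_gmt()] form; the planted set is first.
#' @export
generate_gene_sets <- function(config, universe, affected_genes,
                               n_sets = 30L, size_range = c(10L, 60L),
                               odds_ratio = 10, target_size = 50L) {
  with_seed(derive_seed(config$seed, "gene_sets"), {
    sets <- list()
    n_aff <- length(intersect(affected_genes, universe))
    n_other <- length(universe) - n_aff
    # pick base rate q0 so expected size hits target at the configured OR
    fsize <- function(q0) {
      odds1 <- odds_ratio * q0 / (1 - q0)
      q1 <- odds1 / (1 + odds1)
      n_aff * q1 + n_other * q0 - target_size
    }
    q0 <- stats::uniroot(fsize, c(1e-6, 0.999))$root
    odds1 <- odds_ratio * q0 / (1 - q0)
    q1 <- odds1 / (1 + odds1)
    prob <- ifelse(universe %in% affected_genes, q1, q0)
    members <- universe[stats::runif(length(universe)) < prob]
    if (length(members) < 2L) members <- sample(universe, max(2L, target_size %/% 2L))
    sets[["CELL_DEATH_UP"]] <- list(
      description = "planted set enriched for OSKM-affected genes",
      genes = members)
    for (i in seq_len(n_sets)) {
      sz <- sample(seq(size_range[1], size_range[2]), 1L)
      sets[[sprintf("RANDOM_SET_%02d", i)]] <-
        list(description = "random decoy set", genes = sample(universe, sz))
    }
    sets
  })
}
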