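#' Default pipeline configuration
#'
#' A pipeline configuration bundles the synthetic-data settings
#' ([sim_config()]) with the analysis knobs: the FDR threshold, the
#' ratio-filter confidence level, the per-window motif presence thresholds
#' (a permissive one for enrichment counting and a strict one for
#' direct-effect assignment), the fluctuation transform, the TSS window and
#' the number of top pathways/motifs reported.
#'
#' @param seed master seed; fans out to per-stage derived seeds.
#' @param ... overrides for [sim_config()] fields.
#' @return List of class `pipeline_config` with `sim` and `analysis` parts.
#' @export
default_config <- function(seed = 1L, ...) {
  structure(list(
    sim = sim_config(seed = seed, ...),
    analysis = list(alpha = 0.05, confidence = 0.95,
                    presence_p = 1e-4, direct_presence_p = 1e-6,
                    tss_window = 2000, transform = "neglog10",
                    top_pathways = 15L, top_motifs = 20L)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `seed`, any [sim_config()] argument, and the analysis
#' keys of [default_config()]. Unknown keys raise a config error listing
#' them.
#'
#' @param path YAML file.
#' @return `pipeline_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  sim_keys <- names(formals(sim_config))
  ana_keys <- c("alpha", "confidence", "presence_p", "direct_presence_p",
                "tss_window", "transform", "top_pathways", "top_motifs")
  unknown <- setdiff(names(raw), c(sim_keys, ana_keys))
  if (length(unknown))
    stop_config("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- do.call(default_config, raw[intersect(names(raw), sim_keys)])
  for (k in intersect(names(raw), ana_keys)) cfg$analysis[[k]] <- raw[[k]]
  cfg
}

manifest_path <- function(outdir) file.path(outdir, "MANIFEST.tsv")

log_line <- function(outdir, stage, seed, msg, t0 = NULL) {
  el <- if (is.null(t0)) NA_real_ else round(as.numeric(Sys.time()) - t0, 2)
  line <- sprintf("[%s] stage=%s seed=%s elapsed_s=%s %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, seed, el, msg)
  cat(line, "\n", file = file.path(outdir, "run.log"), append = TRUE, sep = "")
  message(line)
}

# register stage outputs in the manifest with md5 checksums
update_manifest <- function(outdir, stage, files) {
  files <- files[file.exists(file.path(outdir, files))]
  sums <- unname(tools::md5sum(file.path(outdir, files)))
  new <- data.frame(file = files, md5 = sums, stage = stage,
                    stringsAsFactors = FALSE)
  mp <- manifest_path(outdir)
  if (file.exists(mp)) {
    old <- utils::read.delim(mp, stringsAsFactors = FALSE)
    old <- old[!old$file %in% files, , drop = FALSE]
    new <- rbind(old, new)
  }
  write_table(new[order(new$file), ], mp)
  invisible(new)
}

stage_guard <- function(outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
}

#' Simulate the full synthetic dataset directory
#'
#' Emits, for each profile (AML-like and HSPC-like): expression counts +
#' sample sheet + truth, accessibility counts + sample sheet + peak BED +
#' TSS table + truth; plus promoters with planted OSKM motif sites for the
#' AML direct-effect genes, a gene-set GMT with one planted enriched set,
#' the bundled synthetic OSKM motif library, and two simulated
#' limiting-dilution dose tables at the configured frequencies. Every file
#' is checksummed into `MANIFEST.tsv`.
#'
#' @param config a `pipeline_config` ([default_config()]).
#' @param outdir output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
run_simulate <- function(config, outdir) {
  stage_guard(outdir)
  sim <- config$sim
  t0 <- as.numeric(Sys.time())
  # config snapshot: the run directory records exactly what produced it
  snap <- file.path(outdir, "config.yaml")
  yaml::write_yaml(list(sim = unclass(sim), analysis = config$analysis), snap)
  log_line(outdir, "simulate", sim$seed,
           sprintf("config_md5=%s oskmtc_version=%s",
                   unname(tools::md5sum(snap)),
                   as.character(utils::packageVersion("oskmtc"))))
  files <- c("config.yaml")
  for (pf in c("AML", "HSPC")) {
    tc <- generate_timecourse_counts(sim, pf)
    write_counts(tc$counts, tc$samples,
                 file.path(outdir, sprintf("counts_%s.tsv", pf)),
                 file.path(outdir, sprintf("samples_%s.tsv", pf)))
    write_table(tc$truth, file.path(outdir, sprintf("truth_genes_%s.tsv", pf)))
    pe <- generate_peak_experiment(sim, pf)
    write_counts(pe$counts, pe$samples,
                 file.path(outdir, sprintf("atac_counts_%s.tsv", pf)),
                 file.path(outdir, sprintf("atac_samples_%s.tsv", pf)))
    write_bed(pe$peaks, file.path(outdir, sprintf("peaks_%s.bed", pf)))
    write_table(pe$tss, file.path(outdir, sprintf("tss_%s.tsv", pf)))
    write_table(pe$truth, file.path(outdir, sprintf("truth_peaks_%s.tsv", pf)))
    files <- c(files, sprintf(c("counts_%s.tsv", "samples_%s.tsv",
                                "truth_genes_%s.tsv", "atac_counts_%s.tsv",
                                "atac_samples_%s.tsv", "peaks_%s.bed",
                                "tss_%s.tsv", "truth_peaks_%s.tsv"), pf))
    if (pf == "AML") aml_truth <- tc$truth
  }
  motif_src <- system.file("extdata", "synthetic_oskm_motifs.meme",
                           package = "oskmtc")
  file.copy(motif_src, file.path(outdir, "motifs.meme"), overwrite = TRUE)
  files <- c(files, "motifs.meme")
  motifs <- read_motifs(file.path(outdir, "motifs.meme"))
  # direct-effect plan: half of the planted OSKM-affected genes get one
  # OSKM motif site in their promoter
  affected <- aml_truth$gene_id[aml_truth$osk_affected]
  plant <- with_seed(derive_seed(sim$seed, "plant_plan"), {
    chosen <- sort(sample(affected, max(1L, length(affected) %/% 2L)))
    data.frame(gene_id = chosen,
               motif_id = sample(names(motifs), length(chosen), replace = TRUE),
               stringsAsFactors = FALSE)
  })
  pr <- generate_promoters(sim, aml_truth$gene_id, motifs, plant)
  write_fasta(pr$promoters, file.path(outdir, "promoters.fasta"))
  write_table(pr$plant, file.path(outdir, "truth_motif_plants.tsv"))
  gs <- generate_gene_sets(sim, aml_truth$gene_id, affected)
  write_gmt(gs, file.path(outdir, "gene_sets.gmt"))
  lda <- sim$lda
  ga <- simulate_lda(lda$f_a, lda$doses, lda$n_per_dose,
                     seed = derive_seed(sim$seed, "lda_a"))
  gb <- simulate_lda(lda$f_b, lda$doses, lda$n_per_dose,
                     seed = derive_seed(sim$seed, "lda_b"))
  write_table(ga, file.path(outdir, "lda_group_a.tsv"))
  write_table(gb, file.path(outdir, "lda_group_b.tsv"))
  files <- c(files, "promoters.fasta", "truth_motif_plants.tsv",
             "gene_sets.gmt", "lda_group_a.tsv", "lda_group_b.tsv")
  m <- update_manifest(outdir, "simulate", files)
  log_line(outdir, "simulate", sim$seed, "dataset written", t0)
  invisible(m)
}

load_profile_counts <- function(outdir, pf, prefix = "") {
  read_counts(file.path(outdir, sprintf("%scounts_%s.tsv", prefix, pf)),
              file.path(outdir, sprintf("%ssamples_%s.tsv", prefix, pf)))
}

#' Differential-expression stage
#'
#' For each profile and nonzero time point: NB Wald test of the dox arm vs
#' its 0 h baseline, replicate fold-change ratios vs the control arm, the
#' ratio CI filter, and the intersected OSKM-affected gene lists.
#'
#' @param config `pipeline_config`.
#' @param outdir dataset directory produced by [run_simulate()].
#' @return Invisibly, the manifest.
#' @export
run_de <- function(config, outdir) {
  t0 <- as.numeric(Sys.time())
  ana <- config$analysis
  files <- character()
  for (pf in c("AML", "HSPC")) {
    d <- load_profile_counts(outdir, pf)
    sf <- estimate_size_factors(d$counts)
    times <- setdiff(sort(unique(d$samples$time_h)), 0)
    de_all <- list(); ratio_all <- list(); aff_all <- list()
    for (tt in times) {
      de <- test_differential(d$counts, d$samples, sf, "dox", tt, ana$alpha)
      fc <- fold_change_ratio(d$counts, d$samples, sf, tt)
      rc <- ratio_ci_filter(fc, ana$confidence)
      aff <- osk_affected_genes(de, rc, ana$alpha)
      de_all[[as.character(tt)]] <- de
      ratio_all[[as.character(tt)]] <- rc
      aff_all[[as.character(tt)]] <-
        if (length(aff)) data.frame(time_h = tt, gene_id = aff) else NULL
    }
    write_table(do.call(rbind, de_all), file.path(outdir, sprintf("de_%s.tsv", pf)))
    write_table(do.call(rbind, ratio_all),
                file.path(outdir, sprintf("ratio_%s.tsv", pf)))
    aff_df <- do.call(rbind, aff_all)
    if (is.null(aff_df)) aff_df <- data.frame(time_h = numeric(), gene_id = character())
    write_table(aff_df, file.path(outdir, sprintf("osk_affected_%s.tsv", pf)))
    files <- c(files, sprintf(c("de_%s.tsv", "ratio_%s.tsv", "osk_affected_%s.tsv"), pf))
  }
  m <- update_manifest(outdir, "de", files)
  log_line(outdir, "de", config$sim$seed, "differential tables written", t0)
  invisible(m)
}

#' Chromatin-dynamics stage
#'
#' Per profile and time point: differential accessibility vs 0 h, CO/OC/NC
#' classification, the dynamics count table, TSS assignment within the
#' configured window, and per-(time, class) gene lists.
#'
#' @inheritParams run_de
#' @return Invisibly, the manifest.
#' @export
run_atac <- function(config, outdir) {
  t0 <- as.numeric(Sys.time())
  ana <- config$analysis
  files <- character()
  for (pf in c("AML", "HSPC")) {
    d <- load_profile_counts(outdir, pf, prefix = "atac_")
    peaks <- read_bed(file.path(outdir, sprintf("peaks_%s.bed", pf)))
    tss <- read_tss(file.path(outdir, sprintf("tss_%s.tsv", pf)))
    sf <- estimate_size_factors(d$counts)
    times <- setdiff(sort(unique(d$samples$time_h)), 0)
    cls <- do.call(rbind, lapply(times, function(tt)
      classify_peaks(test_peak_differential(d$counts, d$samples, sf, "dox", tt,
                                            ana$alpha), ana$alpha)))
    dyn <- count_dynamics(cls)
    asn <- assign_peaks_to_tss(peaks, tss, ana$tss_window)
    genes <- dynamic_region_genes(cls, asn)
    gl <- do.call(rbind, lapply(names(genes), function(k) {
      if (!length(genes[[k]])) return(NULL)
      parts <- strsplit(k, "_", fixed = TRUE)[[1]]
      data.frame(time_h = as.numeric(parts[1]), class = parts[2],
                 gene_id = genes[[k]], stringsAsFactors = FALSE)
    }))
    if (is.null(gl))
      gl <- data.frame(time_h = numeric(), class = character(), gene_id = character())
    write_table(cls, file.path(outdir, sprintf("peaks_classified_%s.tsv", pf)))
    write_table(dyn, file.path(outdir, sprintf("dynamics_%s.tsv", pf)))
    write_table(asn, file.path(outdir, sprintf("assignments_%s.tsv", pf)))
    write_table(gl, file.path(outdir, sprintf("region_genes_%s.tsv", pf)))
    files <- c(files, sprintf(c("peaks_classified_%s.tsv", "dynamics_%s.tsv",
                                "assignments_%s.tsv", "region_genes_%s.tsv"), pf))
  }
  m <- update_manifest(outdir, "atac", files)
  log_line(outdir, "atac", config$sim$seed, "chromatin dynamics written", t0)
  invisible(m)
}

#' Motif stage: presence, direct-effect genes, enrichment, fluctuation
#'
#' Scans the simulated promoters with the OSKM motif library: a permissive
#' presence matrix (at `presence_p`) drives per-time enrichment of the
#' OSKM-affected gene lists and the fluctuation ranking; a strict presence
#' matrix (at `direct_presence_p`) assigns direct-effect genes.
#'
#' @inheritParams run_de
#' @return Invisibly, the manifest.
#' @export
run_motifs <- function(config, outdir) {
  t0 <- as.numeric(Sys.time())
  ana <- config$analysis
  motifs <- read_motifs(file.path(outdir, "motifs.meme"))
  proms <- read_fasta(file.path(outdir, "promoters.fasta"))
  aff <- utils::read.delim(file.path(outdir, "osk_affected_AML.tsv"),
                           stringsAsFactors = FALSE)
  pres <- promoter_motif_presence(proms, motifs, ana$presence_p)
  pres_strict <- promoter_motif_presence(proms, motifs, ana$direct_presence_p)
  targets <- split(as.character(aff$gene_id), aff$time_h)
  direct <- direct_effect_genes(targets, pres_strict)
  dd <- do.call(rbind, lapply(names(direct), function(tt) {
    if (!length(direct[[tt]])) return(NULL)
    data.frame(time_h = as.numeric(tt), gene_id = direct[[tt]])
  }))
  if (is.null(dd)) dd <- data.frame(time_h = numeric(), gene_id = character())
  targets_ok <- targets[lengths(targets) > 0]
  series <- if (length(targets_ok) >= 2)
    motif_enrichment_series(pres, targets_ok) else
    data.frame(motif_id = character(), time_h = numeric(), p = numeric())
  fluct <- if (nrow(series))
    fluctuation_rank(series, ana$transform,
                     min(ana$top_motifs, length(unique(series$motif_id)))) else
    data.frame(motif_id = character(), score = numeric(),
               rank = integer(), top = logical())
  pres_df <- data.frame(gene_id = rownames(pres), pres, check.names = FALSE)
  write_table(pres_df, file.path(outdir, "motif_presence.tsv"))
  write_table(dd, file.path(outdir, "direct_effect_genes.tsv"))
  write_table(series, file.path(outdir, "motif_enrichment.tsv"))
  write_table(fluct, file.path(outdir, "motif_fluctuation.tsv"))
  m <- update_manifest(outdir, "motifs",
                       c("motif_presence.tsv", "direct_effect_genes.tsv",
                         "motif_enrichment.tsv", "motif_fluctuation.tsv"))
  log_line(outdir, "motifs", config$sim$seed, "motif tables written", t0)
  invisible(m)
}

#' Over-representation stage
#'
#' Tests the union of OSKM-affected genes (AML profile) against the
#' simulated gene-set collection over the full gene universe.
#'
#' @inheritParams run_de
#' @return Invisibly, the manifest.
#' @export
run_ora <- function(config, outdir) {
  t0 <- as.numeric(Sys.time())
  ana <- config$analysis
  d <- load_profile_counts(outdir, "AML")
  aff <- utils::read.delim(file.path(outdir, "osk_affected_AML.tsv"),
                           stringsAsFactors = FALSE)
  sets <- read_gmt(file.path(outdir, "gene_sets.gmt"))
  query <- unique(as.character(aff$gene_id))
  if (!length(query)) stop_data("no OSKM-affected genes to test")
  res <- ora(query, rownames(d$counts), sets, ana$alpha)
  write_table(res, file.path(outdir, "ora.tsv"))
  write_table(top_pathways(res, min(ana$top_pathways, nrow(res))),
              file.path(outdir, "ora_top.tsv"))
  m <- update_manifest(outdir, "ora", c("ora.tsv", "ora_top.tsv"))
  log_line(outdir, "ora", config$sim$seed, "ORA tables written", t0)
  invisible(m)
}

#' Limiting-dilution stage
#'
#' Fits the single-hit model to both simulated dose tables and compares the
#' two frequencies with the 1-df likelihood-ratio test.
#'
#' @inheritParams run_de
#' @return Invisibly, the manifest.
#' @export
run_lda <- function(config, outdir) {
  t0 <- as.numeric(Sys.time())
  ga <- read_dose_table(file.path(outdir, "lda_group_a.tsv"))
  gb <- read_dose_table(file.path(outdir, "lda_group_b.tsv"))
  cmp <- compare_frequencies(ga, gb)
  est <- do.call(rbind, lapply(list(a = cmp$fit_a, b = cmp$fit_b),
                               function(f) data.frame(
    f_hat = f$f_hat, inverse = f$inverse, ci_low = f$ci_low,
    ci_high = f$ci_high, loglik = f$loglik, flag = f$flag)))
  est <- cbind(group = c("a", "b"), est)
  write_table(est, file.path(outdir, "lda_estimates.tsv"))
  write_table(data.frame(lr_statistic = cmp$lr_statistic, df = cmp$df, p = cmp$p),
              file.path(outdir, "lda_comparison.tsv"))
  m <- update_manifest(outdir, "lda", c("lda_estimates.tsv", "lda_comparison.tsv"))
  log_line(outdir, "lda", config$sim$seed, "frequency estimates written", t0)
  invisible(m)
}

#' Run the complete pipeline
#'
#' simulate -> de -> atac -> motifs -> ora -> lda, followed by a plain-text
#' report aggregating the headline tables (OSKM-affected gene counts per
#' time, the CO/OC dynamics tables for both profiles, the top fluctuating
#' motifs, and the limiting-dilution estimates).
#'
#' @inheritParams run_de
#' @return Invisibly, the final manifest.
#' @export
run_all <- function(config, outdir) {
  stage_guard(outdir)
  run_simulate(config, outdir)
  run_de(config, outdir)
  run_atac(config, outdir)
  run_motifs(config, outdir)
  run_ora(config, outdir)
  run_lda(config, outdir)
  rpt <- file.path(outdir, "report.txt")
  con <- file(rpt, "w")
  closed <- FALSE
  on.exit(if (!closed) close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("OSKM time-course pipeline report (seed ", config$sim$seed, ")")
  for (pf in c("AML", "HSPC")) {
    aff <- utils::read.delim(file.path(outdir, sprintf("osk_affected_%s.tsv", pf)))
    w("\n== ", pf, "-like profile ==")
    w("OSKM-affected genes per time point:")
    if (nrow(aff)) for (tt in sort(unique(aff$time_h)))
      w("  t=", tt, " h: ", sum(aff$time_h == tt), " genes") else w("  none")
    dyn <- utils::read.delim(file.path(outdir, sprintf("dynamics_%s.tsv", pf)))
    w("CO/OC dynamics (time_h n_CO n_OC):")
    for (i in seq_len(nrow(dyn)))
      w("  ", dyn$time_h[i], " ", dyn$n_CO[i], " ", dyn$n_OC[i])
  }
  fl <- utils::read.delim(file.path(outdir, "motif_fluctuation.tsv"))
  w("\nTop fluctuating motifs:")
  for (i in seq_len(min(5L, nrow(fl))))
    w("  ", fl$motif_id[i], " score=", signif(fl$score[i], 4))
  est <- utils::read.delim(file.path(outdir, "lda_estimates.tsv"))
  cmp <- utils::read.delim(file.path(outdir, "lda_comparison.tsv"))
  w("\nLimiting-dilution frequencies:")
  for (i in seq_len(nrow(est)))
    w("  group ", est$group[i], ": 1/", round(est$inverse[i]),
      " (CI 1/", round(1 / est$ci_low[i]), " - 1/", round(1 / est$ci_high[i]), ")")
  w("  LR test: LR=", signif(cmp$lr_statistic, 4), " p=", signif(cmp$p, 4))
  close(con); closed <- TRUE   # flush before checksumming
  m <- update_manifest(outdir, "report", "report.txt")
  log_line(outdir, "report", config$sim$seed, "report written")
  invisible(m)
}
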