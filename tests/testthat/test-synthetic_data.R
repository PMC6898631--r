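test_that("generators are deterministic under the same seed", {
  cfg <- sim_config(seed = 8, n_genes = 100, n_peaks = 120,
                    peak_plan = list(
                      AML = data.frame(class = "CO", onset = 3, n = 20L),
                      HSPC = data.frame(class = "OC", onset = 12, n = 2L)))
  a <- generate_timecourse_counts(cfg, "AML")
  b <- generate_timecourse_counts(cfg, "AML")
  expect_identical(a, b)
  pa <- generate_peak_experiment(cfg, "AML")
  pb <- generate_peak_experiment(cfg, "AML")
  expect_identical(pa, pb)
  motifs <- read_motifs(system.file("extdata", "synthetic_oskm_motifs.meme",
                                    package = "oskmtc"))
  plant <- data.frame(gene_id = a$truth$gene_id[1:5], motif_id = "Oct4")
  g1 <- generate_promoters(cfg, a$truth$gene_id[1:20], motifs, plant)
  g2 <- generate_promoters(cfg, a$truth$gene_id[1:20], motifs, plant)
  expect_identical(g1, g2)
  # different profiles use different streams
  h <- generate_timecourse_counts(cfg, "HSPC")
  expect_false(identical(a$counts, h$counts))
})

test_that("time-course structure matches the configured design", {
  cfg <- sim_config(seed = 9, n_genes = 200)
  tc <- generate_timecourse_counts(cfg, "AML")
  expect_identical(dim(tc$counts), c(200L, 20L))  # 2 conditions x 5 times x 2 reps
  expect_setequal(unique(tc$samples$condition), c("dox", "control"))
  expect_setequal(unique(tc$samples$time_h), c(0, 3, 6, 12, 24))
  expect_identical(sum(tc$truth$osk_affected), 10L)  # 5% of 200
  expect_true(all(tc$counts >= 0))
  # emitted files parse back through core_io
  dir <- withr::local_tempdir()
  write_counts(tc$counts, tc$samples, file.path(dir, "c.tsv"), file.path(dir, "s.tsv"))
  rt <- read_counts(file.path(dir, "c.tsv"), file.path(dir, "s.tsv"))
  expect_identical(rt$counts, tc$counts)
})

test_that("planted dox effects respect each profile's onset time", {
  cfg <- sim_config(seed = 10, n_genes = 600, dispersion = 0.01,
                    effect_size = 6, drift_fraction = 0)
  for (pf in c("AML", "HSPC")) {
    tc <- generate_timecourse_counts(cfg, pf)
    onset <- cfg$onset[[pf]]
    aff <- tc$truth$osk_affected & tc$truth$direction == 1L
    mean_at <- function(tt, cond) {
      cols <- tc$samples$time_h == tt & tc$samples$condition == cond
      rowMeans(tc$counts[aff, cols, drop = FALSE])
    }
    pre <- setdiff(cfg$times, 0)[setdiff(cfg$times, 0) < onset]
    for (tt in pre)  # before onset: dox ~ control for affected genes
      expect_lt(median(mean_at(tt, "dox") / pmax(mean_at(tt, "control"), 1)), 2)
    expect_gt(median(mean_at(24, "dox") / pmax(mean_at(24, "control"), 1)), 3)
  }
})

test_that("a null configuration drives DE calls to the null rate", {
  cfg <- sim_config(seed = 12, n_genes = 800, affected_fraction = 0,
                    drift_fraction = 0)
  tc <- generate_timecourse_counts(cfg, "AML")
  sf <- estimate_size_factors(tc$counts)
  de <- test_differential(tc$counts, tc$samples, sf, "dox", 24)
  expect_lt(sum(de$q < 0.05), 0.02 * nrow(de) + 3)
  # dox and control arms exchangeable: similar p-value spread
  de_c <- test_differential(tc$counts, tc$samples, sf, "control", 24)
  expect_lt(abs(mean(de$p) - mean(de_c$p)), 0.1)
})

test_that("peak experiment plants the configured classes and genome layout", {
  cfg <- sim_config(seed = 13)
  pe <- generate_peak_experiment(cfg, "AML")
  plan <- cfg$peak_plan$AML
  expect_identical(sum(pe$truth$planted_class == "CO"), sum(plan$n[plan$class == "CO"]))
  expect_identical(sum(pe$truth$planted_class == "OC"), sum(plan$n[plan$class == "OC"]))
  # class-at-time columns respect onsets
  expect_identical(sum(pe$truth$class_t3 != "NC"), sum(plan$n[plan$onset <= 3]))
  expect_identical(sum(pe$truth$class_t24 != "NC"), sum(plan$n))
  # HSPC: silent before 12 h
  ph <- generate_peak_experiment(cfg, "HSPC")
  expect_identical(sum(ph$truth$class_t3 != "NC"), 0L)
  expect_identical(sum(ph$truth$class_t6 != "NC"), 0L)
  # intervals valid BED, ids unique
  expect_true(all(pe$peaks$start < pe$peaks$end))
  expect_false(anyDuplicated(pe$peaks$peak_id) > 0)
  # some planted CO peaks sit within 1 kb of death-gene TSSs
  asn <- assign_peaks_to_tss(pe$peaks, pe$tss, 2000)
  co_genes <- asn$gene_id[match(pe$truth$peak_id[pe$truth$planted_class == "CO"],
                                asn$peak_id)]
  expect_gt(length(intersect(co_genes, pe$death_genes)), 0.5 * length(pe$death_genes))
})

test_that("promoter generator plants recoverable consensus sites", {
  cfg <- sim_config(seed = 14)
  motifs <- read_motifs(system.file("extdata", "synthetic_oskm_motifs.meme",
                                    package = "oskmtc"))
  genes <- sprintf("gene%04d", 1:300)
  plant <- data.frame(gene_id = genes[1:100],
                      motif_id = rep(names(motifs), 20))
  gp <- generate_promoters(cfg, genes, motifs, plant)
  expect_identical(length(gp$promoters), 300L)
  expect_identical(unique(nchar(gp$promoters)), 600L)
  pres <- promoter_motif_presence(gp$promoters, motifs, 1e-4)
  hit <- vapply(seq_len(nrow(plant)), function(i)
    pres[plant$gene_id[i], plant$motif_id[i]], logical(1))
  expect_identical(mean(hit), 1)  # every planted site recovered
  # null planting: presence at the designed false-positive rate only
  gp0 <- generate_promoters(cfg, genes, motifs)
  pres0 <- promoter_motif_presence(gp0$promoters, motifs, 1e-4)
  # expected false-positive rate from the attained per-window tails
  exp_rate <- mean(vapply(motifs, function(pw) {
    d <- oskmtc:::pwm_score_distribution(pw, 1e-3)
    thr <- pwm_score_threshold(pw, 1e-4)
    p_tail <- sum(d$probs[d$values >= thr])
    n_win <- 600 - ncol(pw$prob) + 1
    1 - (1 - p_tail)^(2 * n_win)
  }, numeric(1)))
  expect_lt(abs(mean(pres0) - exp_rate), 0.015)
  expect_error(generate_promoters(sim_config(seed = 1, promoter_window = c(-4L, 4L)),
                                  genes[1], motifs,
                                  data.frame(gene_id = genes[1], motif_id = "Oct4")),
               "shorter than motif")
})

test_that("gene-set generator respects sizes and plants enrichment", {
  cfg <- sim_config(seed = 15)
  universe <- sprintf("gene%04d", 1:1000)
  set.seed(15); affected <- sample(universe, 50)
  sets <- generate_gene_sets(cfg, universe, affected,
                             n_sets = 20, size_range = c(10L, 40L))
  sizes <- lengths(lapply(sets[-1], `[[`, "genes"))
  expect_true(all(sizes >= 10 & sizes <= 40))
  overlap <- length(intersect(sets$CELL_DEATH_UP$genes, affected))
  expect_gt(overlap, 5)  # enriched well beyond the ~2.5 expected by chance
})
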