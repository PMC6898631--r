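#' Per-time-point differential chromatin openness vs 0 h
#'
#' Applies the shared negative-binomial Wald core ([test_differential()]) to
#' a peak x sample accessibility count matrix, contrasting the time-`time`
#' stratum with the 0 h stratum of the same condition.
#'
#' @inheritParams test_differential
#' @return Data frame as from [test_differential()] with `peak_id` instead
#'   of `feature_id` (class assignment pending; see [classify_peaks()]).
#' @export
test_peak_differential <- function(counts, samples, size_factors, condition,
                                   time, alpha = 0.05) {
  de <- test_differential(counts, samples, size_factors, condition, time, alpha)
  names(de)[names(de) == "feature_id"] <- "peak_id"
  de
}

#' Classify differential peaks as CO / OC / NC
#'
#' Closed-to-open (CO): accessibility significantly greater than at 0 h
#' (q < alpha and log2fc > 0). Open-to-closed (OC): significantly smaller
#' (q < alpha and log2fc < 0). Everything else, including peaks with
#' undefined fold change, is no-change (NC).
#'
#' @param peaks data frame from [test_peak_differential()].
#' @param alpha FDR threshold.
#' @return The input with a `class` column added.
#' @export
classify_peaks <- function(peaks, alpha = 0.05) {
  sig <- !is.na(peaks$q) & peaks$q < alpha & !is.na(peaks$log2fc)
  cls <- rep("NC", nrow(peaks))
  cls[sig & peaks$log2fc > 0] <- "CO"
  cls[sig & peaks$log2fc < 0] <- "OC"
  peaks$class <- cls
  peaks
}

#' Count CO/OC dynamics per time point
#'
#' @param classified data frame (possibly row-bound over time points) with
#'   `time_h` and `class` columns.
#' @return Data frame `time_h`, `n_CO`, `n_OC`, `co_oc_ratio` (NA when no OC).
#' @export
count_dynamics <- function(classified) {
  times <- sort(unique(classified$time_h))
  n_co <- vapply(times, function(tt)
    sum(classified$time_h == tt & classified$class == "CO"), integer(1))
  n_oc <- vapply(times, function(tt)
    sum(classified$time_h == tt & classified$class == "OC"), integer(1))
  data.frame(time_h = times, n_CO = n_co, n_OC = n_oc,
             co_oc_ratio = ifelse(n_oc > 0, n_co / n_oc, NA_real_))
}

#' Assign peaks to the closest TSS within a 2 kb window
#'
#' The peak center is floor((start + end) / 2); a peak is assigned to the
#' closest TSS iff |center - tss| <= window / 2 (i.e. the peak center falls
#' in the 2 kb window centered on the TSS). Distance ties are broken toward
#' the lexicographically smaller gene id. The reported distance is signed
#' and strand-oriented: positive when the peak center lies downstream of the
#' TSS in the gene's orientation.
#'
#' @param peaks PeakSet data frame ([read_bed()]).
#' @param tss TSS table ([read_tss()]).
#' @param window full window width in bp (default 2000).
#' @return Data frame `peak_id`, `gene_id` (NA when unassigned), `distance`.
#' @export
assign_peaks_to_tss <- function(peaks, tss, window = 2000) {
  center <- floor((peaks$start + peaks$end) / 2)
  gene <- rep(NA_character_, nrow(peaks))
  dist_signed <- rep(NA_real_, nrow(peaks))
  half <- window / 2
  for (chr in unique(peaks$chrom)) {
    ti <- which(tss$chrom == chr)
    pi <- which(peaks$chrom == chr)
    if (!length(ti) || !length(pi)) next
    # collapse duplicate TSS positions to the smallest gene id at each
    idx_split <- split(ti, tss$tss_position[ti])
    pick <- vapply(idx_split, function(ii) ii[order(tss$gene_id[ii])][1], integer(1))
    upos <- as.integer(names(idx_split))
    o <- order(upos)
    upos <- upos[o]; pick <- pick[o]
    ugene <- tss$gene_id[pick]
    ustrand <- tss$strand[pick]
    for (p in pi) {
      ctr <- center[p]
      j <- findInterval(ctr, upos)
      cand <- unique(pmin(pmax(c(j, j + 1L), 1L), length(upos)))
      dd <- abs(ctr - upos[cand])
      dmin <- min(dd)
      if (dmin > half) next
      best <- cand[dd == dmin]
      pickgene <- ugene[best]
      b <- best[order(pickgene)][1]
      gene[p] <- ugene[b]
      raw <- ctr - upos[b]
      dist_signed[p] <- if (ustrand[b] == "-") -raw else raw
    }
  }
  data.frame(peak_id = peaks$peak_id, gene_id = gene, distance = dist_signed,
             stringsAsFactors = FALSE)
}

#' Genes regulated by dynamic chromatin regions
#'
#' For each (time point, CO/OC class), the unique TSS-assigned genes whose
#' peaks carry that class at that time.
#'
#' @param classified classified peak table (with `peak_id`, `time_h`, `class`).
#' @param assignments output of [assign_peaks_to_tss()].
#' @return Named list (`"<time>_<class>"`) of sorted gene-id vectors.
#' @export
dynamic_region_genes <- function(classified, assignments) {
  if (!all(classified$peak_id %in% assignments$peak_id))
    stop_data("classified peaks and assignments cover different peak universes")
  g <- assignments$gene_id[match(classified$peak_id, assignments$peak_id)]
  out <- list()
  for (tt in sort(unique(classified$time_h))) {
    for (cl in c("CO", "OC")) {
      sel <- classified$time_h == tt & classified$class == cl & !is.na(g)
      out[[paste0(tt, "_", cl)]] <- sort(unique(g[sel]))
    }
  }
  out
}
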