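#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in the query list with a
#' one-sided hypergeometric upper tail, after intersecting set members with
#' the universe. Sets smaller than `min_size` after intersection are skipped.
#' q-values are Benjamini-Hochberg across the tested sets.
#'
#' @param query gene ids (must be a subset of `universe`).
#' @param universe background gene ids.
#' @param gene_sets collection from [read_gmt()] (named list with `genes`).
#' @param alpha FDR threshold for the `significant` flag.
#' @param min_size minimum set size after universe intersection.
#' @return Data frame `set_id`, `k` (overlap), `n` (query size), `K` (set
#'   size in universe), `N` (universe size), `gene_ratio` = k/n, `p`, `q`,
#'   `significant`, sorted by q then p then set id.
#' @export
ora <- function(query, universe, gene_sets, alpha = 0.05, min_size = 5) {
  query <- unique(query)
  universe <- unique(universe)
  if (!length(query)) stop_data("empty query")
  if (!length(universe)) stop_data("empty universe")
  if (!all(query %in% universe))
    stop_data("query genes outside universe: ",
              paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  rows <- list()
  skipped <- character()
  for (sid in names(gene_sets)) {
    members <- intersect(gene_sets[[sid]]$genes, universe)
    if (length(members) < min_size) { skipped <- c(skipped, sid); next }
    k <- length(intersect(query, members))
    rows[[sid]] <- data.frame(set_id = sid, k = k, n = length(query),
                              K = length(members), N = length(universe),
                              gene_ratio = k / length(query),
                              p = hypergeom_test(k, length(members),
                                                 length(query), length(universe)),
                              stringsAsFactors = FALSE)
  }
  if (length(skipped))
    message("ora: skipped ", length(skipped),
            " set(s) below min_size after universe intersection")
  if (!length(rows)) stop_data("no testable gene sets")
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha
  out <- out[order(out$q, out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top enriched pathways for plotting
#'
#' @param results [ora()] output.
#' @param top_n number of rows to keep (truncated with a warning when larger
#'   than the number of tested sets).
#' @return The first `top_n` rows (ties in q broken by p then set id, as in
#'   [ora()]'s ordering) with `set_id`, `gene_ratio`, `q`.
#' @export
top_pathways <- function(results, top_n = 15) {
  if (top_n > nrow(results)) {
    warning("top_n exceeds number of tested sets; truncating")
    top_n <- nrow(results)
  }
  out <- results[seq_len(top_n), c("set_id", "gene_ratio", "q"), drop = FALSE]
  rownames(out) <- NULL
  out
}
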