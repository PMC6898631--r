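#' @keywords internal
"_PACKAGE"

# condition constructors: config errors vs data errors get distinct classes so
# callers (and the pipeline wrapper) can map them to distinct exit codes.
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("oskmtc_data_error", "error")))
}
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("oskmtc_config_error", "error")))
}

#' Read a feature-by-sample count table with its sample sheet
#'
#' The count table is tab-delimited with a header row of sample ids and the
#' feature ids in the first column. The sample sheet is tab-delimited with
#' columns `sample_id`, `condition` (one of `dox`, `control`), `time_h`
#' (hours since induction) and `replicate` (positive integer).
#'
#' @param counts_path path to the tab-delimited count table.
#' @param sheet_path path to the tab-delimited sample sheet.
#' @return A list with elements `counts` (integer matrix, features x samples)
#'   and `samples` (data frame), validated jointly: every table column must
#'   appear in the sheet and vice versa, counts must be non-negative integers,
#'   and each condition present must include a time-0 stratum.
#' @export
read_counts <- function(counts_path, sheet_path) {
  tab <- utils::read.delim(counts_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_data("count table needs a feature column and >=1 sample")
  feature_ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- feature_ids
  samples <- utils::read.delim(sheet_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  validate_count_matrix(m)
  mode(m) <- "integer"
  samples <- validate_sample_sheet(samples, colnames(m))
  list(counts = m, samples = samples)
}

validate_count_matrix <- function(m) {
  if (anyDuplicated(rownames(m))) stop_data("duplicate feature ids")
  if (anyDuplicated(colnames(m))) stop_data("duplicate sample ids")
  if (anyNA(m)) stop_data("missing values in count table")
  if (any(m < 0)) stop_data("negative count in table")
  if (any(m != round(m))) stop_data("non-integer count in table")
  invisible(m)
}

validate_sample_sheet <- function(samples, sample_ids) {
  need <- c("sample_id", "condition", "time_h", "replicate")
  if (!all(need %in% names(samples)))
    stop_data("sample sheet must have columns: ", paste(need, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$condition <- as.character(samples$condition)
  samples$time_h <- as.numeric(samples$time_h)
  samples$replicate <- as.integer(samples$replicate)
  if (!all(samples$condition %in% c("dox", "control")))
    stop_data("condition must be 'dox' or 'control'")
  if (anyNA(samples$time_h) || any(samples$time_h < 0))
    stop_data("time_h must be non-negative")
  if (anyNA(samples$replicate) || any(samples$replicate < 1L))
    stop_data("replicate must be a positive integer")
  unknown <- setdiff(sample_ids, samples$sample_id)
  if (length(unknown))
    stop_data("unknown sample in count table: ", paste(unknown, collapse = ", "))
  missing <- setdiff(samples$sample_id, sample_ids)
  if (length(missing))
    stop_data("sample sheet rows absent from count table: ",
              paste(missing, collapse = ", "))
  key <- paste(samples$condition, samples$time_h, samples$replicate)
  if (anyDuplicated(key))
    stop_data("(condition, time, replicate) combinations must be unique")
  for (cond in unique(samples$condition)) {
    if (!any(samples$time_h[samples$condition == cond] == 0))
      stop_data("condition '", cond, "' has no time-0 stratum")
  }
  samples[match(sample_ids, samples$sample_id), , drop = FALSE]
}

#' Read peak intervals from a BED file
#'
#' @param path BED file with at least 3 columns; an optional 4th column is
#'   used as the peak id, otherwise ids are generated as `chrom:start-end`.
#' @return Data frame with columns `peak_id`, `chrom`, `start`, `end`;
#'   coordinates kept 0-based half-open exactly as in the file.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  if (any(start0 >= end0)) stop_data("BED interval with start >= end")
  nm <- gr$name
  auto <- sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)), start0, end0)
  ids <- if (is.null(nm)) auto else ifelse(is.na(nm) | nm == "", auto, nm)
  if (anyDuplicated(ids)) stop_data("duplicate peak ids in BED")
  data.frame(peak_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = start0, end = end0, stringsAsFactors = FALSE)
}

#' Write a PeakSet to BED (0-based half-open, 4 columns)
#' @param peaks data frame with `peak_id`, `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_bed <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a MEME-minimal motif file into a motif library
#'
#' Parses the minimal MEME text dialect (`MEME version`, `ALPHABET= ACGT`,
#' optional `Background letter frequencies` line, and one
#' `letter-probability matrix` block per `MOTIF`). Each probability column
#' must sum to 1 within 1e-3 before pseudocounting; columns are then
#' regularized with pseudocount 1e-3 and renormalized, so all entries are
#' strictly positive.
#'
#' @param path motif file path.
#' @param pseudocount probability added to every cell before renormalization.
#' @return A list of `pwm` objects (see [new_pwm()]), named by motif id.
#' @export
read_motifs <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  i <- 1L
  n <- length(lines)
  while (i <= n && !grepl("^Background letter frequencies", lines[i]) &&
         !grepl("^MOTIF", lines[i])) i <- i + 1L
  if (i <= n && grepl("^Background letter frequencies", lines[i])) {
    toks <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(toks) < 8L) stop_data("malformed background line")
    vals <- as.numeric(toks[c(FALSE, TRUE)])
    names(vals) <- toks[c(TRUE, FALSE)]
    bg <- vals[c("A", "C", "G", "T")]
    if (anyNA(bg) || abs(sum(bg) - 1) > 1e-3)
      stop_data("background frequencies must cover ACGT and sum to 1")
    bg <- bg / sum(bg)
  }
  motifs <- list()
  while (i <= n) {
    if (grepl("^MOTIF\\b", lines[i])) {
      id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1L
      while (j <= n && !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
      if (j > n) stop_data("motif ", id, " lacks a letter-probability matrix")
      w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[j])
      w <- suppressWarnings(as.integer(w))
      rows <- list()
      j <- j + 1L
      while (j <= n && grepl("^\\s*[0-9.eE+-]", lines[j])) {
        rows[[length(rows) + 1L]] <-
          as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]])
        j <- j + 1L
      }
      if (!is.na(w) && length(rows) != w)
        stop_data("motif ", id, ": expected ", w, " matrix rows, got ", length(rows))
      if (!length(rows)) stop_data("motif ", id, ": empty matrix")
      if (any(lengths(rows) != 4L))
        stop_data("motif ", id, ": each matrix row needs 4 probabilities")
      prob <- t(do.call(rbind, rows))  # 4 x L, rows A C G T
      rownames(prob) <- c("A", "C", "G", "T")
      sums <- colSums(prob)
      if (any(abs(sums - 1) > 1e-3))
        stop_data("motif ", id, ": probability column does not sum to 1")
      prob <- sweep(prob + pseudocount, 2L, sums + 4 * pseudocount, "/")
      motifs[[id]] <- new_pwm(id, prob, bg)
      i <- j
    } else i <- i + 1L
  }
  if (!length(motifs)) stop_data("no motifs found in ", path)
  motifs
}

#' Construct a position weight matrix object
#'
#' @param id motif identifier.
#' @param prob 4 x L base-probability matrix with rows A, C, G, T; every
#'   column must sum to 1 within 1e-6 and all entries must be positive.
#' @param background length-4 background probabilities (A, C, G, T).
#' @return An object of class `pwm` with elements `id`, `prob`, `background`
#'   and the log2-odds matrix `lom`.
#' @export
new_pwm <- function(id, prob, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  prob <- as.matrix(prob)
  if (nrow(prob) != 4L) stop_data("PWM must have 4 rows (A,C,G,T)")
  rownames(prob) <- c("A", "C", "G", "T")
  if (any(prob <= 0)) stop_data("PWM entries must be positive after pseudocount")
  if (any(abs(colSums(prob) - 1) > 1e-6)) stop_data("PWM columns must sum to 1")
  background <- as.numeric(background)
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6)
    stop_data("background must be 4 probabilities summing to 1")
  names(background) <- c("A", "C", "G", "T")
  structure(list(id = id, prob = prob, background = background,
                 lom = log2(prob / background)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (length %d, max score %.2f bits)\n",
              x$id, ncol(x$prob), sum(apply(x$lom, 2L, max))))
  invisible(x)
}

#' Read DNA sequences from FASTA
#'
#' Sequences are uppercased; characters outside ACGTN are rejected.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop_data("sequence contains characters outside ACGTN: ",
              paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a TSS table
#'
#' Tab-delimited with header columns `gene_id`, `chrom`, `tss_position`
#' (non-negative integer) and `strand` (`+` or `-`).
#'
#' @param path file path.
#' @return Validated data frame.
#' @export
read_tss <- function(path) {
  tss <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss_position", "strand")
  if (!all(need %in% names(tss)))
    stop_data("TSS table must have columns: ", paste(need, collapse = ", "))
  tss$gene_id <- as.character(tss$gene_id)
  tss$tss_position <- as.integer(tss$tss_position)
  if (anyDuplicated(tss$gene_id)) stop_data("duplicate gene ids in TSS table")
  if (any(tss$tss_position < 0)) stop_data("negative TSS position")
  if (!all(tss$strand %in% c("+", "-"))) stop_data("strand must be '+' or '-'")
  tss[, need]
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file: one set per line, `set_id<TAB>description<TAB>genes...`.
#' @param universe optional character vector; when supplied every member must
#'   belong to it.
#' @return Named list; each element has `description` and `genes`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop_data("malformed GMT line (need id, description, >=1 gene)")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop_data("empty gene set: ", f[1])
    if (!is.null(universe) && !all(genes %in% universe))
      stop_data("set ", f[1], " has members outside the declared universe")
    if (f[1] %in% names(sets)) stop_data("duplicate set id: ", f[1])
    sets[[f[1]]] <- list(description = f[2], genes = genes)
  }
  sets
}

#' Write a gene-set collection to GMT
#' @param sets named list as returned by [read_gmt()].
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, sets[[id]]$description, sets[[id]]$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a limiting-dilution dose-response table
#'
#' Tab-delimited with header `dose`, `n_tested`, `n_responded`: cells
#' transplanted per recipient, recipients tested, and recipients that
#' developed leukemia / engrafted.
#'
#' @param path file path.
#' @return Validated data frame of dose groups.
#' @export
read_dose_table <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("dose", "n_tested", "n_responded")
  if (!all(need %in% names(d)))
    stop_data("dose table must have columns: ", paste(need, collapse = ", "))
  d <- d[, need]
  d$dose <- as.numeric(d$dose)
  d$n_tested <- as.integer(d$n_tested)
  d$n_responded <- as.integer(d$n_responded)
  validate_dose_groups(d)
}

validate_dose_groups <- function(d) {
  if (any(d$dose <= 0)) stop_data("doses must be positive")
  if (any(d$n_tested < 1L)) stop_data("n_tested must be positive")
  if (any(d$n_responded < 0L | d$n_responded > d$n_tested))
    stop_data("n_responded must lie in [0, n_tested]")
  d
}

#' Write a data frame as a tab-delimited table
#'
#' All pipeline writers emit UTF-8 tab-delimited text with a header line and
#' a trailing newline.
#'
#' @param records data frame.
#' @param path output path.
#' @export
write_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a count matrix with its sample sheet
#' @param counts integer matrix with feature row names and sample column names.
#' @param samples sample sheet data frame.
#' @param counts_path,sheet_path output paths.
#' @export
write_counts <- function(counts, samples, counts_path, sheet_path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table(df, counts_path)
  write_table(samples, sheet_path)
  invisible(c(counts_path, sheet_path))
}
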