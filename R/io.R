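# File input, expression preprocessing, and result writers.

dc_guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         csv = "csv",
         mtx = "mtx",
         tsv = ,
         txt = "tsv",
         dc_abort_format(sprintf("cannot infer format from extension '.%s'",
                                 ext)))
}

#' Read a point matrix from delimited text or MatrixMarket
#'
#' TSV/CSV files must have a header line; a non-numeric first column is
#' treated as row identifiers and kept as an `id` column (which
#' [density_cut()] ignores). Any other non-numeric cell is a format error
#' reported with its line number. `format = "mtx"` reads MatrixMarket
#' coordinate files via [Matrix::readMM()], with optional sidecar name files
#' `<stem>.rows.txt` / `<stem>.cols.txt` (one name per line).
#'
#' @param path Input file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; inferred from the extension if
#'   omitted.
#' @param transpose Transpose after reading (for feature-major files).
#' @return A tibble of numeric columns (plus optional leading `id`).
#' @export
read_points <- function(path, format = NULL, transpose = FALSE) {
  if (!file.exists(path)) dc_abort_format(sprintf("file not found: %s", path))
  format <- format %||% dc_guess_format(path)
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rn <- paste0(stem, ".rows.txt")
    cn <- paste0(stem, ".cols.txt")
    if (file.exists(cn)) colnames(m) <- readLines(cn)
    if (transpose) m <- t(m)
    out <- as_tibble(m, .name_repair = "unique_quiet")
    if (file.exists(rn) && !transpose) {
      out <- dplyr::bind_cols(tibble(id = readLines(rn)), out)
    }
    return(out)
  }
  delim <- if (format == "csv") "," else "\t"
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    dc_abort_format(sprintf("malformed row at line %d of %s (%s)",
                            prob$row[1] + 1L, path, prob$expected[1]))
  }
  if (ncol(raw) == 0L || nrow(raw) == 0L) {
    dc_abort_format(sprintf("no data in %s", path))
  }
  parsed <- lapply(raw, function(col) suppressWarnings(as.numeric(col)))
  bad <- vapply(seq_along(parsed),
                function(j) anyNA(parsed[[j]]) && !anyNA(raw[[j]]),
                logical(1))
  id <- NULL
  if (bad[1]) {
    id <- raw[[1]]
    parsed <- parsed[-1]
    bad <- bad[-1]
    raw <- raw[-1]
  }
  if (any(bad)) {
    j <- which(bad)[1]
    i <- which(is.na(parsed[[j]]))[1]
    dc_abort_format(sprintf(
      "non-numeric value '%s' in column '%s' at line %d of %s",
      raw[[j]][i], names(raw)[j], i + 1L, path))
  }
  out <- as_tibble(parsed)
  if (transpose) {
    out <- as_tibble(t(as.matrix(out)), .name_repair = "unique_quiet")
    id <- NULL
  }
  if (!is.null(id)) out <- dplyr::bind_cols(tibble(id = id), out)
  out
}

#' Filter and transform an expression matrix
#'
#' Keeps the genes (columns) expressed -- value at or above
#' `expressed_threshold` -- in strictly more than `min_cells` cells (rows),
#' then optionally applies `log2(x + 1)`. Rows are cells, columns genes; use
#' `transpose = TRUE` in [read_points()] for gene-major files.
#'
#' @param data Data frame or matrix, cells x genes; non-numeric columns
#'   (ids) are passed through untouched.
#' @param min_cells Keep a gene only if expressed in more than this many
#'   cells. Default 5.
#' @param log2_transform Apply `log2(x + 1)` (default `TRUE`).
#' @param expressed_threshold Expression call threshold. Default 1.
#' @return A tibble with the retained (and transformed) gene columns.
#' @export
preprocess_expression <- function(data, min_cells = 5L, log2_transform = TRUE,
                                  expressed_threshold = 1) {
  df <- as_tibble(data, .name_repair = "unique_quiet")
  num <- vapply(df, is.numeric, logical(1))
  x <- as.matrix(df[num])
  n_expr <- colSums(x >= expressed_threshold)
  keep <- n_expr > min_cells
  x <- x[, keep, drop = FALSE]
  if (log2_transform) x <- log2(x + 1)
  dplyr::bind_cols(df[!num], as_tibble(x, .name_repair = "unique_quiet"))
}

# Result writers ---------------------------------------------------------

#' Write per-node cluster labels as TSV
#'
#' Columns `node_id` (0-based) and `label` (1-based clusters, 0 = outlier).
#'
#' @param labels Integer label vector (or a `densitycut` fit).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "densitycut")) labels <- labels$labels
  readr::write_tsv(tibble(node_id = seq_along(labels) - 1L,
                          label = as.integer(labels)), path)
  invisible(path)
}

#' Read a label TSV written by [write_labels()]
#'
#' @param path Input path.
#' @return Integer label vector ordered by `node_id`.
#' @export
read_labels <- function(path) {
  tab <- readr::read_tsv(path, col_types = "ii", progress = FALSE)
  if (!all(c("node_id", "label") %in% names(tab))) {
    dc_abort_format(sprintf("%s must have columns node_id, label", path))
  }
  tab$label[order(tab$node_id)]
}

#' Write the merge tree as JSON
#'
#' Serialises thresholds, per-level counts, merge events, the frequency table
#' and the selected cluster count.
#'
#' @param tree A `dc_merge_tree` (or a `densitycut` fit).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_merge_tree <- function(tree, path) {
  if (inherits(tree, "densitycut")) tree <- tree$tree
  stopifnot(inherits(tree, "dc_merge_tree"))
  jsonlite::write_json(
    list(
      levels = tree$levels,
      adjust = tree$adjust,
      thresholds = tree$thresholds,
      counts_per_level = tree$counts_per_level,
      merges = tree$merges,
      frequency = tree$frequency,
      selected_count = tree$selected_count
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Write the cluster-number frequency table as TSV
#'
#' @inheritParams write_merge_tree
#' @return `path`, invisibly.
#' @export
write_frequency <- function(tree, path) {
  if (inherits(tree, "densitycut")) tree <- tree$tree
  readr::write_tsv(tree$frequency, path)
  invisible(path)
}
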