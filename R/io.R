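# Readers/writers for the plain-text interchange formats used throughout:
# Matrix Market counts with TSV sidecars, GMT gene-set collections,
# gene-position tables and the JSON run report.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop_io("file not found: '", path, "'")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "")
}

#' Read a counts directory (Matrix Market + TSV sidecars)
#'
#' Expects `counts.mtx` (cells x genes), `genes.tsv` (first column
#' gene_id) and `cells.tsv` (cell_id, tumor_id) as written by
#' [write_dataset()]. Truth tables are attached when present.
#'
#' @param dir_path Directory containing the files.
#' @return A `count_matrix` object: list(values, cell_ids, gene_ids,
#'   tumor_labels) plus any truth tables.
#' @export
read_dataset <- function(dir_path) {
  mtx <- file.path(dir_path, "counts.mtx")
  if (!file.exists(mtx)) stop_io("missing counts file: '", mtx, "'")
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- read_tsv(file.path(dir_path, "genes.tsv"))
  cells <- read_tsv(file.path(dir_path, "cells.tsv"))
  if (nrow(genes) != ncol(m))
    stop_validation("genes.tsv rows (", nrow(genes),
                    ") do not match matrix columns (", ncol(m), ")")
  if (nrow(cells) != nrow(m))
    stop_validation("cells.tsv rows (", nrow(cells),
                    ") do not match matrix rows (", nrow(m), ")")
  storage.mode(m) <- "integer"
  rownames(m) <- cells[[1]]
  colnames(m) <- genes[[1]]
  out <- count_matrix(m, tumor_labels = cells$tumor_id)
  for (tt in c("cell_truth", "gene_truth")) {
    p <- file.path(dir_path, paste0(tt, ".tsv"))
    if (file.exists(p)) out[[tt]] <- read_tsv(p)
  }
  out$gene_positions <- genes
  out
}

#' Construct a validated count matrix
#'
#' @param values Non-negative integer cells x genes matrix with unique
#'   row (cell) and column (gene) names.
#' @param tumor_labels Optional per-cell tumor-of-origin labels.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(values, tumor_labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("'values' must be a numeric matrix")
  if (any(values < 0) || any(values != round(values)))
    stop_validation("counts must be non-negative integers")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_validation("count matrix needs cell (row) and gene (column) names")
  if (anyDuplicated(rownames(values)))
    stop_validation("duplicate cell_ids in count matrix")
  if (anyDuplicated(colnames(values)))
    stop_validation("duplicate gene_ids in count matrix")
  if (!is.null(tumor_labels) && length(tumor_labels) != nrow(values))
    stop_validation("'tumor_labels' length must equal the number of cells")
  structure(list(values = values,
                 cell_ids = rownames(values),
                 gene_ids = colnames(values),
                 tumor_labels = tumor_labels),
            class = "count_matrix")
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_io("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop_io("malformed GMT line ", i, ": expected name, description ",
              "and at least one gene")
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_validation("'sets' must be a fully named list")
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write the machine-readable run report
#'
#' @param report Named list of run parameters and statistics.
#' @param path Output JSON path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
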