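#' Library-size normalize counts to log2(CPM + 1)
#'
#' Each cell's counts are scaled to counts-per-million and
#' log2(x + 1)-transformed. When the input is already length-normalized
#' (TPM, SMART-seq style) use `mode = "tpm"`: values are taken as given
#' and only log2(x + 1) is applied. The normalization mode is recorded
#' and re-normalizing an already-normalized matrix is refused.
#'
#' @param counts A `count_matrix` (or plain named matrix; for
#'   `mode = "tpm"` the matrix may be non-integer).
#' @param mode `"cpm"` (default) or `"tpm"`.
#' @return An `expr_matrix`: list(values, normalization_mode,
#'   tumor_labels).
#' @export
normalize_log2_cpm <- function(counts, mode = c("cpm", "tpm")) {
  mode <- match.arg(mode)
  if (inherits(counts, "expr_matrix"))
    stop_validation("input is already normalized (mode '",
                    counts$normalization_mode, "'); refusing to re-normalize")
  tumor <- NULL
  if (inherits(counts, "count_matrix")) {
    tumor <- counts$tumor_labels
    values <- counts$values
  } else if (is.matrix(counts) && is.numeric(counts)) {
    values <- counts
  } else stop_validation("'counts' must be a count_matrix or numeric matrix")
  if (mode == "cpm") {
    totals <- rowSums(values)
    bad <- which(totals == 0)
    if (length(bad))
      stop_validation("cells with zero total count: ",
                      paste(rownames(values)[bad], collapse = ", "))
    values <- log2(1 + 1e6 * values / totals)
  } else {
    if (any(values < 0)) stop_validation("TPM values must be non-negative")
    values <- log2(1 + values)
  }
  expr_matrix(values, mode = paste0("log2_", mode, "1"), tumor_labels = tumor)
}

#' Construct an expression matrix container
#'
#' @param values Finite, non-negative real cells x genes matrix.
#' @param mode Normalization mode tag.
#' @param tumor_labels Optional per-cell tumor labels.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, mode = "log2_cpm1", tumor_labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("'values' must be a numeric matrix")
  if (any(!is.finite(values)) || any(values < 0))
    stop_validation("expression values must be finite and >= 0")
  if (!is.null(tumor_labels) && length(tumor_labels) != nrow(values))
    stop_validation("'tumor_labels' length must equal the number of cells")
  structure(list(values = values, normalization_mode = mode,
                 tumor_labels = tumor_labels),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d cells x %d genes (%s)\n",
              nrow(x$values), ncol(x$values), x$normalization_mode))
  invisible(x)
}

# Accept either an expr_matrix or a bare numeric matrix in downstream code.
expr_values <- function(x) {
  if (inherits(x, "expr_matrix")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else stop_validation("expected an expr_matrix or numeric matrix")
}

#' Filter scarcely detected genes
#'
#' Removes genes detected (value > 0) in less than `min_frac` of cells;
#' the boundary is strict, so a gene detected in exactly `min_frac` of
#' cells is kept.
#'
#' @param X An `expr_matrix`.
#' @param min_frac Minimum detection fraction (default 0.01, i.e. 1%).
#' @return The filtered `expr_matrix`.
#' @export
filter_rare_genes <- function(X, min_frac = 0.01) {
  assert_prob(min_frac, "min_frac")
  v <- expr_values(X)
  det <- colMeans(v > 0)
  keep <- det >= min_frac
  if (!any(keep))
    stop_validation("filter removed every gene (min_frac = ", min_frac, ")")
  ms_log(sprintf("filter_rare_genes: kept %d/%d genes (min_frac=%g)",
                 sum(keep), length(keep), min_frac))
  out <- if (inherits(X, "expr_matrix")) X else expr_matrix(v)
  out$values <- v[, keep, drop = FALSE]
  out
}

#' Windowed copy-number scores from expression
#'
#' A simplified expression-based CNV profile: genes are ordered by
#' genomic position, per-gene expression is centered on the mean of a
#' reference (presumed non-malignant) cell set and clipped, then
#' averaged in moving windows within each chromosome. Each cell's
#' overall CNV signal is the sum of squared window scores.
#'
#' @param X An `expr_matrix` (log scale).
#' @param gene_positions data.frame with columns gene_id, chrom, start
#'   (0-based) covering every gene of `X`.
#' @param reference_cell_ids Cell ids of the reference set (>= 20).
#' @param window_genes Moving-average window length in genes.
#' @param cap Clipping bound for centered expression (+/- cap).
#' @return A `cnv_profile`: list(window_scores, cnv_signal, windows,
#'   reference_cell_ids).
#' @export
cnv_score_cells <- function(X, gene_positions, reference_cell_ids,
                            window_genes = 100, cap = 3.0) {
  v <- expr_values(X)
  if (is.null(rownames(v)) || is.null(colnames(v)))
    stop_validation("expression matrix needs cell and gene names")
  missing <- setdiff(colnames(v), gene_positions$gene_id)
  if (length(missing))
    stop_validation("genes without positions: ",
                    paste(utils::head(missing, 5), collapse = ", "),
                    if (length(missing) > 5) sprintf(" (+%d more)",
                                                     length(missing) - 5))
  if (length(reference_cell_ids) < 20)
    stop_validation("need >= 20 reference cells, got ",
                    length(reference_cell_ids))
  if (!all(reference_cell_ids %in% rownames(v)))
    stop_validation("reference_cell_ids absent from the matrix")
  pos <- gene_positions[match(colnames(v), gene_positions$gene_id), ]
  ord <- order(pos$chrom, pos$start)
  v <- v[, ord, drop = FALSE]
  pos <- pos[ord, ]
  centered <- sweep(v, 2, colMeans(v[reference_cell_ids, , drop = FALSE]))
  centered <- pmin(pmax(centered, -cap), cap)
  # moving average over window_genes within each chromosome
  scores <- list()
  win_meta <- list()
  for (ch in unique(pos$chrom)) {
    idx <- which(pos$chrom == ch)
    w <- min(window_genes, length(idx))
    cs <- cbind(0, t(apply(centered[, idx, drop = FALSE], 1, cumsum)))
    starts <- seq_len(length(idx) - w + 1)
    sc <- (cs[, starts + w, drop = FALSE] - cs[, starts, drop = FALSE]) / w
    colnames(sc) <- sprintf("%s_w%04d", ch, starts)
    scores[[ch]] <- sc
    win_meta[[ch]] <- data.frame(window = colnames(sc), chrom = ch,
                                 first_gene = pos$gene_id[idx[starts]],
                                 stringsAsFactors = FALSE)
  }
  window_scores <- do.call(cbind, scores)
  # re-center each cell on its median window (inferCNV-style): a large
  # amplification shifts a cell's CPM composition everywhere, and the
  # median restores the diploid baseline to zero
  window_scores <- window_scores -
    apply(window_scores, 1, stats::median)
  structure(list(window_scores = window_scores,
                 cnv_signal = rowSums(window_scores^2),
                 windows = do.call(rbind, win_meta),
                 window_genes = window_genes, cap = cap,
                 reference_cell_ids = reference_cell_ids),
            class = "cnv_profile")
}

#' Call malignant cells from CNV signal
#'
#' Flags a cell as malignant when its CNV signal exceeds the reference
#' cells' mean by more than `k_sd` reference standard deviations.
#'
#' @param profile A `cnv_profile` from [cnv_score_cells()].
#' @param k_sd Threshold in reference s.d. units (default 2).
#' @return Named logical vector (TRUE = malignant).
#' @export
call_malignant <- function(profile, k_sd = 2.0) {
  if (!inherits(profile, "cnv_profile"))
    stop_validation("'profile' must come from cnv_score_cells()")
  ref <- profile$cnv_signal[profile$reference_cell_ids]
  if (stats::sd(ref) == 0)
    stop_validation("reference CNV signal variance is zero; cannot threshold")
  thr <- mean(ref) + k_sd * stats::sd(ref)
  calls <- profile$cnv_signal > thr
  ms_log(sprintf("call_malignant: %d/%d cells above mean+%g*sd (thr=%.3g)",
                 sum(calls), length(calls), k_sd, thr))
  calls
}
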