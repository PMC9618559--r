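# Mann-Whitney differential expression with Benjamini-Hochberg control,
# fold-change filtering, hypergeometric / Fisher gene-set enrichment and
# cross-dataset overlap of marker lists.

# Shared two-sided Mann-Whitney U test. Exact null distribution
# (stats::pwilcox) when both groups are small and tie-free, otherwise a
# tie-corrected, continuity-corrected normal approximation with an
# Edgeworth kurtosis term (the U null is platykurtic at small n; the
# correction keeps the approximate p within ~2e-3 of the exact one at
# 6+6 and vanishes as n grows).
mann_whitney <- function(a, b, exact_max = 12) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- rle(sort(r))$lengths
  if (na + nb <= exact_max && !any(ties > 1)) {
    p <- min(1, 2 * min(stats::pwilcox(U, na, nb),
                        stats::pwilcox(U - 1, na, nb, lower.tail = FALSE)))
  } else {
    mu <- na * nb / 2
    n <- na + nb
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1))
    sigma <- sqrt(sigma2)
    # exact excess kurtosis of U for untied ranks
    g2 <- -1.2 * (na^2 + nb^2 + na * nb + na + nb) / (na * nb * (n + 1))
    Fe <- function(x) {
      z <- (x + 0.5 - mu) / sigma
      min(1, max(0, stats::pnorm(z) -
                   stats::dnorm(z) * g2 / 24 * (z^3 - 3 * z)))
    }
    p <- min(1, 2 * min(Fe(U), 1 - Fe(U - 1)))
  }
  list(U = U, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; q >= p, q <= 1, monotone in
#' the p-value ranks.
#'
#' @param pvals Numeric p-values in [0, 1].
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop_validation("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Mann-Whitney differential expression between two cell groups
#'
#' Per-gene two-sided Mann-Whitney U test of group A versus group B
#' with BH adjustment across all tested genes. The log2 fold change is
#' mean_A - mean_B on the log2-normalized values (so fold change =
#' 2^log2FC); a gene is flagged overexpressed in A when q <
#' `q_threshold` and log2FC > 0.
#'
#' @param X An `expr_matrix` (log2 scale) or numeric matrix.
#' @param cells_a,cells_b Disjoint cell id/index sets, >= 3 cells each.
#' @param q_threshold Significance threshold on q (default 0.01).
#' @return A `data.frame` (class `de_table`): gene_id, U, p, q, log2_fc,
#'   fold_change, overexpressed_in_a; sorted by (q, gene_id).
#' @export
mann_whitney_de <- function(X, cells_a, cells_b, q_threshold = 0.01) {
  v <- expr_values(X)
  if (length(intersect(cells_a, cells_b)))
    stop_validation("cell groups overlap")
  va <- v[cells_a, , drop = FALSE]
  vb <- v[cells_b, , drop = FALSE]
  if (nrow(va) < 3 || nrow(vb) < 3)
    stop_validation("each group needs >= 3 cells")
  res <- vapply(seq_len(ncol(v)), function(g) {
    mw <- mann_whitney(va[, g], vb[, g])
    c(mw$U, mw$p)
  }, numeric(2))
  log2_fc <- colMeans(va) - colMeans(vb)
  out <- data.frame(gene_id = colnames(v),
                    U = res[1, ], p = res[2, ],
                    q = bh_adjust(res[2, ]),
                    log2_fc = log2_fc,
                    fold_change = 2^log2_fc,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$overexpressed_in_a <- out$q < q_threshold & out$log2_fc > 0
  out <- out[order(out$q, out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' Select overexpressed genes for ontology/enrichment input
#'
#' Genes overexpressed in group A with fold change >= `fc_min`
#' (inclusive) and q < `q_max`.
#'
#' @param de A `de_table` from [mann_whitney_de()].
#' @param fc_min Minimum fold change (default 2).
#' @param q_max Maximum BH-adjusted p (default 0.05).
#' @return Character vector of gene ids (possibly empty).
#' @export
filter_for_ontology <- function(de, fc_min = 2.0, q_max = 0.05) {
  keep <- de$fold_change >= fc_min & de$q < q_max & de$log2_fc > 0
  genes <- de$gene_id[keep]
  if (!length(genes)) ms_log("filter_for_ontology: empty gene list")
  genes
}

#' Hypergeometric module enrichment
#'
#' Upper-tail hypergeometric probability P(X >= k) of observing `k`
#' module genes in a list of size `n` drawn from a universe of size `N`
#' containing `K` module genes. The module is first restricted to the
#' universe.
#'
#' @param list_genes Gene list (must lie within `universe`).
#' @param module Module gene set.
#' @param universe Universe gene set.
#' @param name Module name for the record.
#' @return list(gene_set, N, K, n, k, p, overlap).
#' @export
hypergeometric_enrichment <- function(list_genes, module, universe,
                                      name = "module") {
  list_genes <- unique(list_genes)
  universe <- unique(universe)
  if (!all(list_genes %in% universe))
    stop_validation("gene list is not a subset of the universe")
  K_set <- intersect(module, universe)
  ov <- intersect(list_genes, K_set)
  N <- length(universe); K <- length(K_set)
  n <- length(list_genes); k <- length(ov)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(gene_set = name, N = N, K = K, n = n, k = k, p = p, overlap = ov)
}

#' Fisher-exact enrichment over a GMT collection
#'
#' One-sided Fisher exact test of list membership versus set membership
#' for every set of a GMT collection, BH-adjusted across the sets of
#' the collection. Sets with no gene in the universe are skipped with a
#' warning.
#'
#' @param list_genes Gene list (within `universe`).
#' @param gene_sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Universe gene set (typically all tested genes).
#' @param q_max Reporting threshold recorded per set (default 0.05).
#' @return data.frame: gene_set, N, K, n, k, p, q, significant,
#'   overlap_genes; sorted by q.
#' @export
gmt_enrichment <- function(list_genes, gene_sets, universe, q_max = 0.05) {
  if (!length(gene_sets)) stop_validation("empty gene-set collection")
  recs <- lapply(names(gene_sets), function(nm) {
    K_set <- intersect(gene_sets[[nm]], universe)
    if (!length(K_set)) {
      warning("gene set '", nm, "' has no gene in the universe; skipped")
      return(NULL)
    }
    hypergeometric_enrichment(list_genes, gene_sets[[nm]], universe, nm)
  })
  recs <- Filter(Negate(is.null), recs)
  if (!length(recs)) stop_validation("no gene set overlaps the universe")
  out <- data.frame(
    gene_set = vapply(recs, `[[`, character(1), "gene_set"),
    N = vapply(recs, `[[`, numeric(1), "N"),
    K = vapply(recs, `[[`, numeric(1), "K"),
    n = vapply(recs, `[[`, numeric(1), "n"),
    k = vapply(recs, `[[`, numeric(1), "k"),
    p = vapply(recs, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < q_max
  out$overlap_genes <- vapply(recs, function(r)
    paste(r$overlap, collapse = ","), character(1))
  out <- out[order(out$q, out$gene_set), ]
  rownames(out) <- NULL
  out
}

#' Cross-dataset overlap of marker lists
#'
#' Restricts each list to the genes detected in every dataset, then
#' reports the global intersection and, per list, the fraction of its
#' (restricted) genes shared by all lists.
#'
#' @param de_lists Named list of >= 2 gene lists.
#' @param detected_sets Named list of per-dataset detected-gene
#'   universes.
#' @return list(universe_size, restricted_sizes, global_intersection,
#'   shared_fraction, pairwise (matrix of pairwise intersection sizes)).
#' @export
cross_dataset_overlap <- function(de_lists, detected_sets) {
  if (length(de_lists) < 2) stop_validation("need >= 2 gene lists")
  universe <- Reduce(intersect, detected_sets)
  if (!length(universe)) stop_validation("empty common universe")
  lists <- lapply(de_lists, intersect, universe)
  global <- Reduce(intersect, lists)
  frac <- vapply(lists, function(l)
    if (length(l)) length(intersect(l, global)) / length(l) else NA_real_,
    numeric(1))
  nm <- names(lists)
  pairwise <- outer(seq_along(lists), seq_along(lists),
                    Vectorize(function(i, j)
                      length(intersect(lists[[i]], lists[[j]]))))
  dimnames(pairwise) <- list(nm, nm)
  list(universe_size = length(universe),
       restricted_sizes = lengths(lists),
       global_intersection = global,
       shared_fraction = frac,
       pairwise = pairwise)
}
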