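#' Hierarchical clustering on components (HCPC-style)
#'
#' Ward-linkage agglomeration on Euclidean distances in the embedding
#' space. The number of clusters is chosen within `k_range` by the
#' largest relative within-inertia gain when cutting the dendrogram
#' (the inertia-gain criterion of hierarchical-clustering-on-components
#' workflows), optionally followed by a k-means consolidation step
#' initialized at the cut's cluster centroids.
#'
#' @param emb An `embedding` (typically `"combined"`).
#' @param k_range Candidate cluster counts, default 3:10. Supply a
#'   single value (or `c(k, k)`) to force k.
#' @param consolidate Run the k-means consolidation step (default TRUE).
#' @param tumor_labels Optional per-cell tumor labels; when given, the
#'   tumor-mixing diagnostic NMI(clusters, tumors) is computed.
#' @return A `cluster_assignment`: list(labels, k, silhouette,
#'   mean_silhouette, nmi_vs_tumor, linkage, consolidated).
#' @export
hcpc_cluster <- function(emb, k_range = 3:10, consolidate = TRUE,
                         tumor_labels = NULL) {
  coords <- if (inherits(emb, "embedding")) emb$coords else emb
  n <- nrow(coords)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) stop_validation("'k_range' must be >= 2")
  if (n <= max(k_range))
    stop_validation("need more cells than max(k_range)")
  hc <- stats::hclust(stats::dist(coords), method = "ward.D2")
  k <- if (length(k_range) == 1) k_range else
    select_k_inertia(coords, hc, k_range)
  labels <- stats::cutree(hc, k = k)
  if (consolidate) {
    centers <- apply(coords, 2, function(col) tapply(col, labels, mean))
    centers <- matrix(centers, nrow = k)
    km <- suppressWarnings(
      stats::kmeans(coords, centers = centers, iter.max = 20))
    if (length(unique(km$cluster)) == k) labels <- km$cluster
  }
  sil <- silhouette_width(coords, labels)
  nmi_t <- if (!is.null(tumor_labels)) nmi(labels, tumor_labels) else NA_real_
  structure(list(labels = labels, k = k,
                 silhouette = sil$widths,
                 mean_silhouette = sil$mean,
                 nmi_vs_tumor = nmi_t,
                 linkage = "ward.D2",
                 consolidated = consolidate),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "cluster_assignment: k=%d, mean silhouette=%.3f, NMI vs tumor=%s\n",
    x$k, x$mean_silhouette,
    if (is.na(x$nmi_vs_tumor)) "NA" else sprintf("%.3f", x$nmi_vs_tumor)))
  print(table(cluster = x$labels))
  invisible(x)
}

# Within-cluster inertia for each candidate cut; pick k maximizing the
# relative gain ratio gain(k)/gain(k+1).
select_k_inertia <- function(coords, hc, k_range) {
  ks <- seq(min(k_range) - 1, max(k_range) + 1)
  ks <- ks[ks >= 1 & ks < nrow(coords)]
  W <- vapply(ks, function(k) {
    lab <- stats::cutree(hc, k = k)
    sum(vapply(split(seq_len(nrow(coords)), lab), function(idx) {
      cc <- coords[idx, , drop = FALSE]
      sum(sweep(cc, 2, colMeans(cc))^2)
    }, numeric(1)))
  }, numeric(1))
  names(W) <- ks
  gain <- function(k) W[as.character(k - 1)] - W[as.character(k)]
  cand <- k_range[k_range + 1 <= max(ks) & k_range - 1 >= min(ks)]
  ratios <- vapply(cand, function(k) {
    g1 <- gain(k); g2 <- gain(k + 1)
    if (!is.finite(g1) || !is.finite(g2)) return(-Inf)
    (g1 + 1e-12) / (g2 + 1e-12)
  }, numeric(1))
  cand[which.max(ratios)]
}

#' Per-cell silhouette widths
#'
#' Euclidean silhouette s(i) = (b(i) - a(i)) / max(a(i), b(i)).
#' Singleton clusters and fully degenerate distances get s = 0 by
#' convention.
#'
#' @param coords Cells x components coordinate matrix (or `embedding`).
#' @param labels Per-cell cluster labels (>= 2 clusters).
#' @return list(widths, mean).
#' @export
silhouette_width <- function(coords, labels) {
  if (inherits(coords, "embedding")) coords <- coords$coords
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2)
    stop_validation("silhouette needs at least 2 clusters")
  s <- cluster::silhouette(labels, stats::dist(coords))
  w <- s[, "sil_width"]
  w[!is.finite(w)] <- 0
  list(widths = as.numeric(w), mean = mean(w))
}

#' Normalized mutual information between two labelings
#'
#' NMI = I(A;B) / mean(H(A), H(B)) (arithmetic-mean normalization),
#' with the convention NMI = 0 when either partition has zero entropy.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return NMI in [0, 1].
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || !length(labels_a))
    stop_validation("labelings must be non-empty and of equal length")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  ha <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  hb <- -sum(pk[pk > 0] * log(pk[pk > 0]))
  if (ha == 0 || hb == 0) return(0)
  p <- tab / n
  e <- outer(pj, pk)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / e[nz]))
  max(0, min(1, mi / ((ha + hb) / 2)))
}
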