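# Low-dimensional representations of the signature submatrix: PCA and
# UMAP blocks (combined for clustering) and the graph-Laplacian spectral
# embedding used by the trajectory stage.

embedding <- function(coords, method, params = list(),
                      variance_explained = NULL) {
  if (any(!is.finite(coords))) stop_validation("non-finite coordinates")
  structure(list(coords = coords, method = method,
                 component_count = ncol(coords),
                 variance_explained = variance_explained,
                 params = params),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding (%s): %d cells x %d components\n",
              x$method, nrow(x$coords), x$component_count))
  invisible(x)
}

#' Restrict an expression matrix to a gene signature
#'
#' @param X An `expr_matrix`.
#' @param genes Character vector of gene ids; all must be present.
#' @return The cells x signature-genes submatrix.
#' @export
signature_submatrix <- function(X, genes) {
  v <- expr_values(X)
  if (!length(genes) || anyDuplicated(genes))
    stop_validation("signature must be a non-empty set of unique gene ids")
  missing <- setdiff(genes, colnames(v))
  if (length(missing))
    stop_validation("signature genes absent from matrix: ",
                    paste(missing, collapse = ", "))
  v[, genes, drop = FALSE]
}

#' Principal components of the signature submatrix
#'
#' Column-centered PCA (no scaling); components ordered by decreasing
#' variance, with the variance explained recorded.
#'
#' @param X_sig Cells x signature-genes matrix (or `expr_matrix`).
#' @param n_components Number of components (default: all).
#' @return An `embedding` with method `"pca"`.
#' @export
pca_components <- function(X_sig, n_components = NULL) {
  v <- expr_values(X_sig)
  n_components <- n_components %||% min(nrow(v) - 1, ncol(v))
  if (n_components > min(nrow(v) - 1, ncol(v)))
    stop_validation("'n_components' exceeds min(#cells-1, #genes)")
  if (all(apply(v, 2, stats::var) == 0))
    stop_validation("zero-variance input matrix")
  p <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  coords <- p$x[, seq_len(n_components), drop = FALSE]
  embedding(coords, "pca",
            variance_explained = p$sdev[seq_len(n_components)]^2)
}

#' UMAP components of the signature submatrix
#'
#' Deterministic given `seed` (single-threaded stochastic gradient
#' descent).
#'
#' @param X_sig Cells x signature-genes matrix (or `expr_matrix`).
#' @param n_components Output dimensionality (default 2).
#' @param n_neighbors Neighborhood size (default 30).
#' @param min_dist Minimum embedding distance (default 0.3).
#' @param seed RNG seed.
#' @return An `embedding` with method `"umap"`.
#' @export
umap_components <- function(X_sig, n_components = 2, n_neighbors = 30,
                            min_dist = 0.3, seed = 1L) {
  v <- expr_values(X_sig)
  if (n_neighbors >= nrow(v))
    stop_validation("'n_neighbors' must be < the number of cells")
  set.seed(seed)
  coords <- uwot::umap(v, n_components = n_components,
                       n_neighbors = n_neighbors, min_dist = min_dist,
                       n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  rownames(coords) <- rownames(v)
  embedding(coords, "umap",
            params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                          seed = seed))
}

#' Concatenate PCA and UMAP blocks with variance matching
#'
#' The UMAP block is rescaled so that its total variance equals the PCA
#' block's total variance, preventing either block from dominating the
#' Ward distances of the downstream clustering.
#'
#' @param pca,umap `embedding` objects over the same cells, same order.
#' @return An `embedding` with method `"combined"`.
#' @export
combine_components <- function(pca, umap) {
  if (nrow(pca$coords) != nrow(umap$coords))
    stop_validation("PCA and UMAP blocks have different cell counts")
  rp <- rownames(pca$coords); ru <- rownames(umap$coords)
  if (!is.null(rp) && !is.null(ru) && !identical(rp, ru))
    stop_validation("PCA and UMAP blocks have mismatched cell order")
  var_pca <- sum(apply(pca$coords, 2, stats::var))
  var_umap <- sum(apply(umap$coords, 2, stats::var))
  if (var_umap == 0) stop_validation("zero-variance UMAP block")
  u <- scale(umap$coords, center = TRUE, scale = FALSE) *
    sqrt(var_pca / var_umap)
  embedding(cbind(pca$coords, u), "combined",
            params = list(pca_components = ncol(pca$coords),
                          umap_components = ncol(umap$coords)))
}

#' Spectral embedding of the signature submatrix
#'
#' Builds a symmetrized k-nearest-neighbor graph (ties at the k-th
#' distance included, so duplicated cells share a neighborhood), bridges
#' disconnected components with minimum-distance edges, and returns the
#' eigenvectors of the normalized graph Laplacian for the smallest
#' nontrivial eigenvalues, scaled by inverse square-root degree
#' (Laplacian eigenmaps). Sign convention: the first nonzero entry of
#' each component is positive.
#'
#' @param X_sig Cells x signature-genes matrix (or `expr_matrix`).
#' @param n_components Number of components (default 4).
#' @param knn Neighborhood size (default 30).
#' @return An `embedding` with method `"spectral"`.
#' @export
spectral_embed <- function(X_sig, n_components = 4, knn = 30) {
  v <- expr_values(X_sig)
  n <- nrow(v)
  if (knn >= n) stop_validation("'knn' must be < the number of cells")
  d <- as.matrix(stats::dist(v))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    kth <- sort(di[-i], partial = knn)[knn]
    A[i, di <= kth] <- 1
  }
  diag(A) <- 0
  A <- pmax(A, t(A))  # symmetrize: neighbor if either direction
  # bridge disconnected components by their closest cell pairs
  comp <- graph_components(A)
  while (max(comp) > 1) {
    i1 <- which(comp == 1)
    i2 <- which(comp != 1)
    dd <- d[i1, i2, drop = FALSE]
    hit <- arrayInd(which.min(dd), dim(dd))
    a <- i1[hit[1]]; b <- i2[hit[2]]
    A[a, b] <- A[b, a] <- 1
    ms_log(sprintf("spectral_embed: bridged components via cells %d-%d", a, b))
    comp <- graph_components(A)
  }
  deg <- rowSums(A)
  dis <- 1 / sqrt(deg)
  L <- diag(n) - dis * t(dis * t(A))  # I - D^-1/2 A D^-1/2
  e <- eigen(L, symmetric = TRUE)
  # smallest eigenvalues are last; drop the trivial one
  idx <- seq(n - 1, by = -1, length.out = n_components)
  coords <- e$vectors[, idx, drop = FALSE] * dis
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(v)
  colnames(coords) <- sprintf("SE%d", seq_len(n_components))
  embedding(coords, "spectral", params = list(knn = knn))
}

# Connected components of an adjacency matrix via BFS.
graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  nbr <- apply(A > 0, 1, which, simplify = FALSE)
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      for (w in nbr[[u]]) if (comp[w] == 0L) {
        comp[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  comp
}
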