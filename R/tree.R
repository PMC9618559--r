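# Elastic principal tree: a tree of nodes fitted to embedded cells by
# minimizing mean squared reconstruction error plus a stretching penalty
# (mu, on squared edge lengths) and a bending penalty (lambda, on the
# deviation of each internal node from the mean of its neighbors). The
# tree is grown greedily from a two-node segment; at each step the
# candidate operations (bisect an edge / attach a leaf to a node) are
# locally optimized and the lowest-energy candidate is kept.

tree_energy <- function(coords, nodes, edges, assign, mu, lambda) {
  mse <- mean(rowSums((coords - nodes[assign, , drop = FALSE])^2))
  stretch <- sum((nodes[edges[, 1], , drop = FALSE] -
                  nodes[edges[, 2], , drop = FALSE])^2)
  bend <- 0
  deg <- tabulate(edges, nbins = nrow(nodes))
  for (j in which(deg >= 2)) {
    nb <- tree_neighbors(edges, j)
    bend <- bend + sum((nodes[j, ] - colMeans(nodes[nb, , drop = FALSE]))^2)
  }
  mse + mu * stretch + lambda * bend
}

tree_neighbors <- function(edges, j) {
  c(edges[edges[, 1] == j, 2], edges[edges[, 2] == j, 1])
}

# Alternate nearest-node assignment with the closed-form penalized
# least-squares node update (quadratic energy => linear system).
tree_optimize <- function(coords, nodes, edges, mu, lambda,
                          max_iter = 20, tol = 1e-6) {
  n <- nrow(coords)
  m <- nrow(nodes)
  energy <- Inf
  assign <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(coords^2), rowSums(nodes^2), "+") -
      2 * coords %*% t(nodes)
    assign <- max.col(-d2, ties.method = "first")
    counts <- tabulate(assign, nbins = m)
    # data term
    A <- diag(counts / n, m)
    T_ <- matrix(0, m, ncol(coords))
    sums <- rowsum(coords, assign)
    T_[as.integer(rownames(sums)), ] <- sums / n
    # stretching: mu * sum ||n_u - n_v||^2  => gradient 2*mu*L
    L <- diag(tabulate(edges, nbins = m), m)
    for (e in seq_len(nrow(edges))) {
      L[edges[e, 1], edges[e, 2]] <- L[edges[e, 1], edges[e, 2]] - 1
      L[edges[e, 2], edges[e, 1]] <- L[edges[e, 2], edges[e, 1]] - 1
    }
    # bending: lambda * sum_j ||n_j - mean(neighbors)||^2 = ||B n||^2
    deg <- tabulate(edges, nbins = m)
    B <- matrix(0, m, m)
    for (j in which(deg >= 2)) {
      B[j, j] <- 1
      nb <- tree_neighbors(edges, j)
      B[j, nb] <- -1 / deg[j]
    }
    M <- A + mu * L + lambda * crossprod(B)
    nodes <- solve(M + 1e-10 * diag(m), T_)
    e_now <- tree_energy(coords, nodes, edges, assign, mu, lambda)
    if (is.finite(energy) && energy - e_now < tol) {
      energy <- min(energy, e_now)
      break
    }
    energy <- e_now
  }
  list(nodes = nodes, assign = assign, energy = energy)
}

#' Fit an elastic principal tree
#'
#' Grows a tree through the embedded cells, starting from a two-node
#' segment on the first principal axis and greedily applying the
#' lowest-energy candidate operation (edge bisection or leaf
#' attachment) until `n_nodes` nodes are placed. Each candidate is
#' scored after local optimization alternating nearest-node assignment
#' and the closed-form penalized least-squares node update. The elastic
#' energy is non-increasing across accepted growth steps.
#'
#' @param emb An `embedding` (or coordinate matrix).
#' @param n_nodes Number of tree nodes (default 10).
#' @param mu Stretching penalty on squared edge lengths (default 0.1).
#' @param lambda Bending penalty on node-neighborhood deviations
#'   (default 0.01).
#' @param max_iter Local-optimization iterations per candidate.
#' @param tol Convergence / monotonicity tolerance.
#' @param seed Unused reserved seed (the fit is deterministic); kept for
#'   interface stability.
#' @return A `principal_tree`: list(node_coords, edges, energy,
#'   energy_trace, branches, mu, lambda).
#' @export
fit_elastic_tree <- function(emb, n_nodes = 10, mu = 0.1, lambda = 0.01,
                             max_iter = 20, tol = 1e-6, seed = NULL) {
  coords <- if (inherits(emb, "embedding")) emb$coords else emb
  if (any(!is.finite(coords))) stop_validation("non-finite coordinates")
  if (n_nodes < 2) stop_validation("'n_nodes' must be >= 2")
  if (nrow(unique(coords)) < n_nodes)
    stop_validation("'n_nodes' exceeds the number of distinct points")
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  pc1 <- svd(cc, nu = 0, nv = 1)$v[, 1]
  proj <- cc %*% pc1
  nodes <- rbind(ctr + min(proj) * pc1, ctr + max(proj) * pc1)
  edges <- matrix(c(1L, 2L), 1)
  fit <- tree_optimize(coords, nodes, edges, mu, lambda, max_iter, tol)
  trace <- fit$energy
  while (nrow(fit$nodes) < n_nodes) {
    best <- NULL
    m <- nrow(fit$nodes)
    # candidate: bisect each edge at its midpoint
    for (e in seq_len(nrow(edges))) {
      mid <- (fit$nodes[edges[e, 1], ] + fit$nodes[edges[e, 2], ]) / 2
      cand_nodes <- rbind(fit$nodes, mid)
      cand_edges <- rbind(edges[-e, , drop = FALSE],
                          c(edges[e, 1], m + 1L), c(m + 1L, edges[e, 2]))
      cf <- tree_optimize(coords, cand_nodes, cand_edges, mu, lambda,
                          max_iter, tol)
      if (is.null(best) || cf$energy < best$energy)
        best <- c(cf, list(edges = cand_edges))
    }
    # candidate: attach a leaf at the farthest cell assigned to a node
    for (j in seq_len(m)) {
      cells_j <- which(fit$assign == j)
      if (!length(cells_j)) next
      d2 <- rowSums(sweep(coords[cells_j, , drop = FALSE], 2,
                          fit$nodes[j, ])^2)
      leaf <- coords[cells_j[which.max(d2)], ]
      cand_nodes <- rbind(fit$nodes, leaf)
      cand_edges <- rbind(edges, c(j, m + 1L))
      cf <- tree_optimize(coords, cand_nodes, cand_edges, mu, lambda,
                          max_iter, tol)
      if (cf$energy < best$energy)
        best <- c(cf, list(edges = cand_edges))
    }
    if (best$energy > trace[length(trace)] + tol)
      ms_log(sprintf("tree growth step increased energy by %.3g",
                     best$energy - trace[length(trace)]), level = "warning")
    edges <- best$edges
    fit <- best
    trace <- c(trace, fit$energy)
  }
  structure(list(node_coords = fit$nodes, edges = edges,
                 energy = fit$energy, energy_trace = trace,
                 branches = tree_branches(edges),
                 mu = mu, lambda = lambda),
            class = "principal_tree")
}

# Branches: maximal paths whose internal nodes have degree 2; endpoints
# are leaves or junctions. Ids S0, S1, ... in discovery order.
tree_branches <- function(edges) {
  m <- max(edges)
  deg <- tabulate(edges, nbins = m)
  term <- which(deg != 2)
  if (!length(term)) stop_validation("tree has no terminal/junction node")
  visited <- matrix(FALSE, nrow(edges), 1)
  edge_key <- function(a, b) which((edges[, 1] == a & edges[, 2] == b) |
                                   (edges[, 1] == b & edges[, 2] == a))
  branches <- list()
  for (s in term) {
    for (nb in tree_neighbors(edges, s)) {
      ek <- edge_key(s, nb)
      if (visited[ek]) next
      path <- c(s, nb)
      visited[ek] <- TRUE
      while (deg[path[length(path)]] == 2) {
        cur <- path[length(path)]
        nxt <- setdiff(tree_neighbors(edges, cur), path[length(path) - 1])
        visited[edge_key(cur, nxt)] <- TRUE
        path <- c(path, nxt)
      }
      branches[[length(branches) + 1]] <- path
    }
  }
  names(branches) <- sprintf("S%d", seq_along(branches) - 1)
  branches
}

#' @export
print.principal_tree <- function(x, ...) {
  deg <- tabulate(x$edges, nbins = nrow(x$node_coords))
  cat(sprintf(
    "principal_tree: %d nodes, %d edges, %d leaves, %d junction(s), %d branch(es)\n",
    nrow(x$node_coords), nrow(x$edges), sum(deg == 1), sum(deg >= 3),
    length(x$branches)))
  cat(sprintf("  energy %.5g (mu=%g, lambda=%g)\n", x$energy, x$mu, x$lambda))
  invisible(x)
}

#' Subway-style plot of a fitted tree
#'
#' Draws cells in the first two embedding components, colored by an
#' optional per-cell score, with tree edges overlaid.
#'
#' @param x A `principal_tree`.
#' @param emb The embedding the tree was fitted on.
#' @param score Optional per-cell score used for coloring.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.principal_tree <- function(x, emb, score = NULL, ...) {
  coords <- if (inherits(emb, "embedding")) emb$coords else emb
  col <- if (is.null(score)) "grey60" else
    grDevices::hcl.colors(100, "viridis")[
      cut(score, 100, labels = FALSE, include.lowest = TRUE)]
  graphics::plot(coords[, 1], coords[, 2], col = col, pch = 16, cex = 0.5,
                 xlab = "component 1", ylab = "component 2", ...)
  for (e in seq_len(nrow(x$edges)))
    graphics::segments(x$node_coords[x$edges[e, 1], 1],
                       x$node_coords[x$edges[e, 1], 2],
                       x$node_coords[x$edges[e, 2], 1],
                       x$node_coords[x$edges[e, 2], 2],
                       lwd = 2, col = "black")
  graphics::points(x$node_coords[, 1], x$node_coords[, 2], pch = 21,
                   bg = "white", cex = 1.2)
  invisible(x)
}

#' Project cells onto a fitted tree
#'
#' Each cell is projected to the nearest point of the nearest edge
#' (Euclidean); the containing branch, the arc-length position along
#' that branch in [0, 1] and the projection distance are recorded.
#'
#' @param tree A `principal_tree`.
#' @param emb The embedding (same component space as the tree).
#' @return A `branch_assignment` data.frame: cell, branch, edge,
#'   position, distance.
#' @export
project_cells <- function(tree, emb) {
  coords <- if (inherits(emb, "embedding")) emb$coords else emb
  if (ncol(coords) != ncol(tree$node_coords))
    stop_validation("embedding and tree dimensionality differ")
  nodes <- tree$node_coords
  edges <- tree$edges
  n <- nrow(coords)
  best_d2 <- rep(Inf, n)
  best_edge <- integer(n)
  best_t <- numeric(n)
  for (e in seq_len(nrow(edges))) {
    p <- nodes[edges[e, 1], ]
    q <- nodes[edges[e, 2], ]
    v <- q - p
    len2 <- sum(v^2)
    t_ <- if (len2 == 0) rep(0, n) else
      pmin(1, pmax(0, (sweep(coords, 2, p) %*% v) / len2))
    proj <- outer(as.numeric(t_), v) + matrix(p, n, length(p), byrow = TRUE)
    d2 <- rowSums((coords - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_edge[upd] <- e
    best_t[upd] <- t_[upd]
  }
  # map edge + within-edge t to branch + arc-length position
  edge_branch <- rep(NA_integer_, nrow(edges))
  edge_offset <- rep(NA_real_, nrow(edges))
  edge_flip <- rep(FALSE, nrow(edges))
  branch_len <- numeric(length(tree$branches))
  for (b in seq_along(tree$branches)) {
    path <- tree$branches[[b]]
    seg_len <- sqrt(rowSums((nodes[path[-length(path)], , drop = FALSE] -
                             nodes[path[-1], , drop = FALSE])^2))
    branch_len[b] <- sum(seg_len)
    off <- 0
    for (s in seq_len(length(path) - 1)) {
      ek <- which((edges[, 1] == path[s] & edges[, 2] == path[s + 1]) |
                  (edges[, 1] == path[s + 1] & edges[, 2] == path[s]))
      edge_branch[ek] <- b
      edge_offset[ek] <- off
      edge_flip[ek] <- edges[ek, 1] != path[s]
      off <- off + seg_len[s]
    }
  }
  elen <- sqrt(rowSums((nodes[edges[, 1], , drop = FALSE] -
                        nodes[edges[, 2], , drop = FALSE])^2))
  t_branch <- ifelse(edge_flip[best_edge], 1 - best_t, best_t)
  pos <- (edge_offset[best_edge] + t_branch * elen[best_edge]) /
    pmax(branch_len[edge_branch[best_edge]], 1e-12)
  out <- data.frame(
    cell = rownames(coords) %||% seq_len(n),
    branch = names(tree$branches)[edge_branch[best_edge]],
    edge = best_edge,
    position = pmin(1, pmax(0, pos)),
    distance = sqrt(best_d2),
    stringsAsFactors = FALSE)
  class(out) <- c("branch_assignment", "data.frame")
  out
}

#' Order branches along the motility axis
#'
#' Finds the leaf branches with the lowest and highest mean motility
#' score, computes the tree geodesic between their leaf ends, and
#' returns the intermediate branch set: branches lying on the geodesic
#' other than the two terminal ones, together with branches hanging off
#' a geodesic junction whose mean score lies strictly between the low
#' and high leaf means (the side-arm carrying cells in transition). On a
#' path tree with monotone scores the intermediate set is empty.
#'
#' @param tree A `principal_tree`.
#' @param assignment A `branch_assignment` from [project_cells()].
#' @param motility Per-cell motility score (same cells/order).
#' @param min_cells Branches with fewer assigned cells are excluded
#'   from consideration (default 20).
#' @return list(low_branch, high_branch, geodesic_branches,
#'   intermediate_branches, branch_means).
#' @export
order_branches_by_score <- function(tree, assignment, motility,
                                    min_cells = 20) {
  if (nrow(assignment) != length(motility))
    stop_validation("assignment and motility score differ in length")
  means <- tapply(motility, assignment$branch, mean)
  counts <- table(assignment$branch)
  ok <- names(counts)[counts >= min_cells]
  dropped <- setdiff(names(tree$branches), ok)
  if (length(dropped))
    ms_log("branches excluded (too few cells): ",
           paste(dropped, collapse = ", "), level = "warning")
  if (!length(ok)) stop_validation("all branches are underpopulated")
  deg <- tabulate(tree$edges, nbins = nrow(tree$node_coords))
  is_leaf_branch <- vapply(tree$branches, function(p)
    any(deg[c(p[1], p[length(p)])] == 1), logical(1))
  leaf_ok <- intersect(ok, names(tree$branches)[is_leaf_branch])
  if (length(leaf_ok) == 1 && length(tree$branches) == 1) {
    # a pure path: the single branch carries both extremes
    ms_log("path tree: single branch holds both extremes; no intermediate")
    return(list(low_branch = leaf_ok, high_branch = leaf_ok,
                geodesic_branches = leaf_ok,
                intermediate_branches = character(0),
                branch_means = means))
  }
  if (length(leaf_ok) < 2)
    stop_validation("fewer than two populated leaf branches")
  lm <- means[leaf_ok]
  low_b <- leaf_ok[which.min(lm)]
  high_b <- leaf_ok[which.max(lm)]
  # geodesic between the leaf ends of the two extreme branches
  leaf_end <- function(b) {
    p <- tree$branches[[b]]
    if (deg[p[1]] == 1) p[1] else p[length(p)]
  }
  path <- tree_path(tree$edges, leaf_end(low_b), leaf_end(high_b))
  # a branch lies on the geodesic iff all its nodes do (tree paths are unique)
  on_geo <- vapply(tree$branches, function(p) all(p %in% path), logical(1))
  geo_branches <- names(tree$branches)[on_geo]
  inter <- setdiff(geo_branches, c(low_b, high_b))
  # side arms at geodesic junctions with strictly intermediate scores
  junctions <- intersect(path, which(deg >= 3))
  side <- names(tree$branches)[vapply(tree$branches, function(p)
    any(c(p[1], p[length(p)]) %in% junctions) && !all(p %in% path),
    logical(1))]
  side <- intersect(side, ok)
  side <- side[means[side] > means[low_b] & means[side] < means[high_b]]
  inter <- intersect(union(inter, side), ok)
  if (!length(inter))
    ms_log("no intermediate branch on the low-to-high geodesic")
  list(low_branch = low_b, high_branch = high_b,
       geodesic_branches = geo_branches,
       intermediate_branches = inter,
       branch_means = means)
}

# Unique path between two nodes of a tree (BFS parents).
tree_path <- function(edges, from, to) {
  m <- max(edges)
  adj <- lapply(seq_len(m), function(j) tree_neighbors(edges, j))
  parent <- rep(NA_integer_, m)
  parent[from] <- from
  queue <- from
  while (length(queue)) {
    u <- queue[[1]]
    queue <- queue[-1]
    if (u == to) break
    for (w in adj[[u]]) if (is.na(parent[w])) {
      parent[w] <- u
      queue <- c(queue, w)
    }
  }
  if (is.na(parent[to])) stop_validation("tree is disconnected")
  path <- to
  while (path[1] != from) path <- c(parent[path[1]], path)
  path
}

#' Branch-wise differential expression
#'
#' For a target branch, runs the shared Mann-Whitney test of its cells
#' against each other (sufficiently populated) branch with BH
#' adjustment per comparison. A gene is a target-branch marker when it
#' has q < `q_max` and a higher mean in the target branch in every
#' comparison.
#'
#' @param X An `expr_matrix` or matrix (cells in assignment order).
#' @param assignment A `branch_assignment`.
#' @param target Target branch id.
#' @param q_max Per-comparison significance threshold (default 0.05).
#' @param min_cells Minimum cells per compared branch (default 3).
#' @return list(markers, per_comparison (named list of `de_table`s)).
#' @export
branch_de <- function(X, assignment, target, q_max = 0.05, min_cells = 3) {
  v <- expr_values(X)
  if (nrow(v) != nrow(assignment))
    stop_validation("matrix and assignment differ in cell count")
  idx_t <- which(assignment$branch == target)
  if (length(idx_t) < min_cells)
    stop_validation("target branch has fewer than ", min_cells, " cells")
  others <- setdiff(unique(assignment$branch), target)
  others <- others[vapply(others, function(b)
    sum(assignment$branch == b) >= min_cells, logical(1))]
  if (!length(others))
    stop_validation("no comparison branch with >= ", min_cells, " cells")
  per <- lapply(others, function(b) {
    mann_whitney_de(v, idx_t, which(assignment$branch == b),
                    q_threshold = q_max)
  })
  names(per) <- others
  marker_sets <- lapply(per, function(de)
    de$gene_id[de$q < q_max & de$log2_fc > 0])
  list(markers = Reduce(intersect, marker_sets), per_comparison = per)
}

#' Intersect branch markers with high-motility marker lists
#'
#' Final switch-gene candidates are the intermediate-branch markers
#' also present in every provided high-motility (M-HIGH) overexpressed
#' list.
#'
#' @param branch_markers Marker genes of the intermediate branch.
#' @param mhigh_lists Named list of >= 1 high-motility gene lists.
#' @return list(candidates, provenance (data.frame of per-list
#'   membership)).
#' @export
intersect_switch_candidates <- function(branch_markers, mhigh_lists) {
  if (!length(mhigh_lists))
    stop_validation("need at least one M-HIGH gene list")
  if (is.null(names(mhigh_lists)))
    names(mhigh_lists) <- sprintf("list%d", seq_along(mhigh_lists))
  candidates <- Reduce(intersect, mhigh_lists, accumulate = FALSE,
                       right = FALSE)
  candidates <- intersect(branch_markers, candidates)
  prov <- data.frame(gene_id = branch_markers, stringsAsFactors = FALSE)
  for (nm in names(mhigh_lists))
    prov[[nm]] <- branch_markers %in% mhigh_lists[[nm]]
  prov$final_candidate <- branch_markers %in% candidates
  if (!length(candidates)) ms_log("no final switch candidates")
  list(candidates = candidates, provenance = prov)
}
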