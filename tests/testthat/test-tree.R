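test_that("collinear points yield a path and n_nodes=2 a single edge", {
  set.seed(1)
  line <- cbind(seq(0, 10, length.out = 120), rnorm(120, 0, 0.05))
  rownames(line) <- sprintf("c%03d", 1:120)
  tr <- fit_elastic_tree(line, n_nodes = 8)
  deg <- tabulate(tr$edges, nbins = 8)
  expect_identical(sum(deg == 1), 2L)
  expect_identical(sum(deg >= 3), 0L)
  expect_identical(length(tr$branches), 1L)
  tr2 <- fit_elastic_tree(line, n_nodes = 2)
  expect_identical(nrow(tr2$edges), 1L)
  expect_error_validation(fit_elastic_tree(line * NA_real_))
  expect_error_validation(fit_elastic_tree(line[1:3, ], n_nodes = 5))
})

test_that("elastic energy never increases across accepted growth steps", {
  y <- make_y(seed = 2)
  tr <- fit_elastic_tree(y$pts, n_nodes = 12)
  expect_true(all(diff(tr$energy_trace) <= 1e-6))
  expect_true(is.finite(tr$energy))
  # tree validity: connected and acyclic
  expect_identical(nrow(tr$edges), nrow(tr$node_coords) - 1L)
  comp <- motistate:::graph_components(
    (function(e, m) {
      A <- matrix(0, m, m); A[e] <- 1; pmax(A, t(A))
    })(tr$edges, nrow(tr$node_coords)))
  expect_identical(max(comp), 1L)
})

test_that("a planted Y is recovered with accurate branch assignment", {
  y <- make_y(seed = 3)
  tr <- fit_elastic_tree(y$pts)
  deg <- tabulate(tr$edges, nbins = nrow(tr$node_coords))
  expect_identical(sum(deg == 1), 3L)
  expect_identical(sum(deg >= 3), 1L)
  asn <- project_cells(tr, y$pts)
  expect_identical(nrow(asn), nrow(y$pts))
  expect_true(all(table(asn$branch) > 0))
  expect_true(all(asn$position >= 0 & asn$position <= 1))
  # away from the junction, fitted branches align with the true arms
  far <- y$t > 1
  tab <- table(asn$branch[far], y$arm[far])
  expect_gte(sum(apply(tab, 1, max)) / sum(tab), 0.9)
})

test_that("rigid motions preserve topology and node geometry", {
  y <- make_y(seed = 4, n_per_arm = 100)
  tr1 <- fit_elastic_tree(y$pts, n_nodes = 8)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  moved <- y$pts %*% R + matrix(c(3, -2), nrow(y$pts), 2, byrow = TRUE)
  tr2 <- fit_elastic_tree(moved, n_nodes = 8)
  d1 <- sort(tabulate(tr1$edges, nbins = 8))
  d2 <- sort(tabulate(tr2$edges, nbins = 8))
  expect_identical(d1, d2)
  # node numbering may differ (growth order flips with the principal
  # axis sign); compare node positions as a set
  back <- sweep(tr2$node_coords, 2, c(3, -2)) %*% t(R)
  d <- as.matrix(dist(rbind(tr1$node_coords, back)))[1:8, 9:16]
  expect_lt(max(apply(d, 1, min)), 1e-3)
  expect_equal(tr1$energy, tr2$energy, tolerance = 1e-6)
})

test_that("cells project to the nearest edge with sane positions", {
  y <- make_y(seed = 5)
  tr <- fit_elastic_tree(y$pts)
  # a point exactly at a node projects at distance zero
  probe <- tr$node_coords[1, , drop = FALSE]
  rownames(probe) <- "probe"
  asn <- project_cells(tr, probe)
  expect_equal(asn$distance, 0, tolerance = 1e-12)
  bad <- matrix(0, 2, 3, dimnames = list(c("a", "b"), NULL))
  expect_error_validation(project_cells(tr, bad))
})

test_that("branch ordering finds low, high and intermediate branches", {
  y <- make_y(seed = 6)
  tr <- fit_elastic_tree(y$pts)
  asn <- project_cells(tr, y$pts)
  # motility grows along arm 1 -> junction -> arm 2; arm 3 is intermediate
  mot <- ifelse(y$arm == 1, 5 - y$t, ifelse(y$arm == 2, 5 + y$t, 5 + 0.2))
  ord <- order_branches_by_score(tr, asn, mot)
  expect_false(ord$low_branch == ord$high_branch)
  expect_true(length(ord$intermediate_branches) >= 1)
  expect_false(ord$low_branch %in% ord$intermediate_branches)
  expect_false(ord$high_branch %in% ord$intermediate_branches)
  # flipping the score swaps extremes but keeps the intermediate set
  ord2 <- order_branches_by_score(tr, asn, -mot)
  expect_identical(ord2$low_branch, ord$high_branch)
  expect_identical(ord2$high_branch, ord$low_branch)
  expect_identical(sort(ord2$intermediate_branches),
                   sort(ord$intermediate_branches))
})

test_that("a monotone path tree has an empty intermediate set", {
  set.seed(7)
  line <- cbind(seq(0, 10, length.out = 150), rnorm(150, 0, 0.1))
  rownames(line) <- sprintf("c%03d", 1:150)
  tr <- fit_elastic_tree(line, n_nodes = 6)
  asn <- project_cells(tr, line)
  ord <- order_branches_by_score(tr, asn, line[, 1])
  expect_identical(length(ord$intermediate_branches), 0L)
})

test_that("branch DE recovers a planted branch marker and rejects nulls", {
  y <- make_y(seed = 8, n_per_arm = 100)
  tr <- fit_elastic_tree(y$pts)
  asn <- project_cells(tr, y$pts)
  far <- y$t > 1
  tab <- table(asn$branch[far], y$arm[far])
  arm3_branch <- rownames(tab)[which.max(tab[, 3])]
  set.seed(8)
  expr <- rand_matrix(nrow(y$pts), 40, seed = 8)
  rownames(expr) <- rownames(y$pts)
  expr[y$arm == 3, 1] <- expr[y$arm == 3, 1] + 2   # marker of arm 3
  de <- branch_de(expr, asn, arm3_branch)
  expect_true("g001" %in% de$markers)
  # permuted branch labels give (almost) no markers
  set.seed(9)
  counts <- vapply(1:5, function(i) {
    asn_p <- asn
    asn_p$branch <- sample(asn_p$branch)
    length(branch_de(expr, asn_p, arm3_branch)$markers)
  }, numeric(1))
  expect_identical(median(counts), 0)
  # constant genes are never markers
  expr[, 2] <- 1
  expect_false("g002" %in% branch_de(expr, asn, arm3_branch)$markers)
})

test_that("switch candidates are the intersection with every M-HIGH list", {
  r <- intersect_switch_candidates(
    c("g1", "g2"), list(a = c("g1", "g2", "g3"), b = c("g1", "g4")))
  expect_identical(r$candidates, "g1")
  expect_identical(r$provenance$final_candidate, c(TRUE, FALSE))
  expect_identical(
    intersect_switch_candidates(character(0), list(a = "g1"))$candidates,
    character(0))
  expect_error_validation(intersect_switch_candidates("g1", list()))
})
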