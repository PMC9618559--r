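test_that("Mann-Whitney exact p matches the enumeration oracle at small n", {
  set.seed(1)
  for (rep in 1:25) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- rnorm(na); b <- rnorm(nb)
    got <- motistate:::mann_whitney(a, b)
    expect_equal(got$p, oracle_mw_exact(a, b), tolerance = 1e-12)
  }
  # the printed separated-groups example
  expect_equal(motistate:::mann_whitney(1:3, 4:6)$p, 0.1)
  expect_equal(motistate:::mann_whitney(1:3, 4:6)$U, 0)
})

test_that("exact and normal-approximation paths agree closely at 6+6", {
  set.seed(2)
  diffs <- replicate(100, {
    a <- rnorm(6); b <- rnorm(6)
    pe <- motistate:::mann_whitney(a, b, exact_max = 12)$p
    pn <- motistate:::mann_whitney(a, b, exact_max = 0)$p
    abs(pe - pn)
  })
  expect_lte(max(diffs), 0.01)
})

test_that("BH adjustment matches the hand step-up and is order invariant", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  set.seed(3)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  q <- bh_adjust(p)
  expect_true(all(q >= p & q <= 1))
  expect_error_validation(bh_adjust(c(0.1, 1.2)))
})

test_that("differential expression flags planted genes and handles constants", {
  m <- rand_matrix(40, 30, seed = 4)
  m[1:20, 1:5] <- m[1:20, 1:5] + 3   # planted overexpression in group A
  m[, 30] <- 2                       # constant gene
  de <- mann_whitney_de(m, 1:20, 21:40)
  top <- de$gene_id[de$overexpressed_in_a]
  expect_true(all(sprintf("g%03d", 1:5) %in% top))
  cg <- de[de$gene_id == "g030", ]
  expect_equal(cg$p, 1)
  expect_equal(cg$log2_fc, 0)
  expect_false(cg$overexpressed_in_a)
  expect_true(all(diff(order(de$q)) != 0 | TRUE))  # sorted by q
  expect_true(!is.unsorted(de$q))
  expect_error_validation(mann_whitney_de(m, 1:20, 20:40))
  expect_error_validation(mann_whitney_de(m, 1:2, 3:40))
})

test_that("ontology filter applies an inclusive fold-change boundary", {
  de <- data.frame(gene_id = c("a", "b", "c"),
                   q = c(0.01, 0.2, 0.01),
                   log2_fc = c(1, 2, 0.9),
                   fold_change = c(2, 4, 1.866))
  class(de) <- c("de_table", "data.frame")
  expect_identical(filter_for_ontology(de), "a")   # FC exactly 2 kept
  expect_identical(filter_for_ontology(de, fc_min = 1.5), c("a", "c"))
})

test_that("hypergeometric enrichment matches combinatorics and enumeration", {
  uni <- sprintf("u%02d", 1:10)
  rec <- hypergeometric_enrichment(uni[1:4], uni[1:5], uni)
  expect_equal(rec$p, 5 / 210, tolerance = 1e-12)
  rec0 <- hypergeometric_enrichment(uni[6:9], uni[1:5], uni)
  expect_equal(rec0$k, 0)
  expect_equal(hypergeometric_enrichment(uni[6:9], uni, uni)$p, 1)
  # against the brute-force draw enumeration for several configurations
  for (cfg in list(c(10, 5, 4, 4), c(12, 6, 5, 3), c(8, 3, 4, 1))) {
    N <- cfg[1]; K <- cfg[2]; n <- cfg[3]; k <- cfg[4]
    u <- sprintf("x%02d", seq_len(N))
    lst <- c(u[seq_len(k)], if (n > k) u[(K + 1):(K + n - k)])
    rec <- hypergeometric_enrichment(lst, u[seq_len(K)], u)
    expect_equal(rec$p, oracle_hyper(N, K, n, k), tolerance = 1e-12)
  }
  # p is monotone decreasing in the overlap k
  ps <- vapply(0:4, function(k) {
    lst <- c(uni[seq_len(k)], uni[6:10])[1:4]
    hypergeometric_enrichment(lst, uni[1:5], uni)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error_validation(
    hypergeometric_enrichment(c("zz"), uni[1:5], uni))
})

test_that("GMT enrichment equals the one-sided Fisher test on the same table", {
  uni <- sprintf("u%02d", 1:10)
  # table [[3,1],[1,5]]: list of 4, set of 4, overlap 3
  lst <- c(uni[1:3], uni[5])
  set <- uni[c(1:3, 4)]
  rec <- gmt_enrichment(lst, list(s = set), uni, q_max = 0.05)
  expect_equal(rec$p, 25 / 210, tolerance = 1e-12)
  expect_equal(round(rec$p, 5), 0.11905)
  ft <- stats::fisher.test(matrix(c(3, 1, 1, 5), 2), alternative = "greater")
  expect_equal(rec$p, unname(ft$p.value), tolerance = 1e-10)
  # sets with no universe overlap are skipped with a warning
  expect_warning(
    gmt_enrichment(lst, list(s = set, none = c("q1", "q2")), uni),
    "skipped")
})

test_that("GMT files round-trip and malformed lines are reported", {
  td <- withr::local_tempdir()
  sets <- list(one = c("a", "b", "c"), two = c("d", "e"))
  p <- file.path(td, "sets.gmt")
  write_gmt(sets, p)
  expect_identical(read_gmt(p), sets)
  writeLines(c("ok\tdesc\tg1", "bad_line_without_tabs"), p)
  expect_error(read_gmt(p), "line 2")
})

test_that("cross-dataset overlap restricts lists to the common universe", {
  res <- cross_dataset_overlap(
    list(L1 = c("a", "b", "c"), L2 = c("b", "c", "d")),
    list(d1 = letters[1:10], d2 = letters[1:10]))
  expect_identical(sort(res$global_intersection), c("b", "c"))
  expect_equal(unname(res$shared_fraction["L1"]), 2 / 3)
  # identical lists share everything
  res2 <- cross_dataset_overlap(
    list(A = c("a", "b"), B = c("a", "b")),
    list(d1 = letters[1:5], d2 = letters[1:5]))
  expect_true(all(res2$shared_fraction == 1))
  # a gene absent from one dataset's universe is dropped before intersecting
  res3 <- cross_dataset_overlap(
    list(L1 = c("a", "z"), L2 = c("a", "z")),
    list(d1 = c("a", "z"), d2 = c("a", "b")))
  expect_identical(res3$global_intersection, "a")
  expect_equal(unname(res3$shared_fraction["L1"]), 1)
  expect_error_validation(cross_dataset_overlap(
    list(L1 = "a"), list(d1 = "a")))
  expect_error_validation(cross_dataset_overlap(
    list(L1 = "a", L2 = "a"), list(d1 = "a", d2 = "b")))
})
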