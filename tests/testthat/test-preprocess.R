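test_that("log2 CPM matches the closed form", {
  m <- matrix(c(1, 1, 2), 1, 3,
              dimnames = list("c1", c("g1", "g2", "g3")))
  X <- normalize_log2_cpm(count_matrix(m))
  expect_equal(unname(X$values[1, ]),
               c(log2(2.5e5 + 1), log2(2.5e5 + 1), log2(5e5 + 1)),
               tolerance = 1e-12)
  expect_equal(unname(round(X$values[1, ], 4)),
               c(17.9316, 17.9316, 18.9316))
  # linear-scale CPM values sum to 1e6
  expect_equal(sum(2^X$values[1, ] - 1), 1e6, tolerance = 1e-6)
})

test_that("normalization maps zero counts to exactly zero and is scale invariant", {
  m <- rand_matrix(5, 10, seed = 2, fun = function(k) rpois(k, 3))
  m[1, 1] <- 0
  m[, 10] <- m[, 10] + 1  # keep totals positive
  X1 <- normalize_log2_cpm(count_matrix(m))
  expect_identical(X1$values[1, 1], 0)
  m2 <- m
  m2[3, ] <- m2[3, ] * 2   # doubling a cell's counts leaves its row unchanged
  X2 <- normalize_log2_cpm(count_matrix(m2))
  expect_equal(X1$values[3, ], X2$values[3, ], tolerance = 1e-12)
})

test_that("zero-total cells and double normalization are refused", {
  m <- rand_matrix(3, 4, seed = 3, fun = function(k) rpois(k, 2))
  m[2, ] <- 0
  expect_error_validation(normalize_log2_cpm(count_matrix(m)))
  m[2, ] <- 1
  X <- normalize_log2_cpm(count_matrix(m))
  expect_error_validation(normalize_log2_cpm(X))
})

test_that("TPM mode applies log2(x+1) without rescaling", {
  m <- matrix(c(10, 30), 1, 2, dimnames = list("c1", c("g1", "g2")))
  X <- normalize_log2_cpm(count_matrix(m), mode = "tpm")
  expect_equal(unname(X$values[1, ]), log2(c(11, 31)))
  expect_identical(X$normalization_mode, "log2_tpm1")
})

test_that("rare-gene filter uses a strict 'less than' boundary", {
  m <- rand_matrix(100, 3, seed = 4, fun = function(k) rpois(k, 5) + 1)
  m[, 2] <- 0
  m[1, 2] <- 3          # detected in exactly 1% of cells -> kept
  m[, 3] <- 0           # detected nowhere -> removed
  X <- normalize_log2_cpm(count_matrix(m))
  f <- filter_rare_genes(X, 0.01)
  expect_identical(colnames(f$values), c("g001", "g002"))
  expect_identical(nrow(f$values), 100L)
  f0 <- filter_rare_genes(X, 0)
  expect_identical(ncol(f0$values), 3L)
})

test_that("raising min_frac never increases the surviving gene count", {
  m <- rand_matrix(50, 30, seed = 5, fun = function(k) rpois(k, 0.5))
  m[, 1] <- m[, 1] + 1
  X <- normalize_log2_cpm(count_matrix(m))
  kept <- vapply(c(0, 0.02, 0.05, 0.1, 0.3), function(f)
    ncol(filter_rare_genes(X, f)$values), numeric(1))
  expect_true(all(diff(kept) <= 0))
  # every gene undetected somewhere -> min_frac = 1 removes them all
  m1 <- rand_matrix(10, 3, seed = 6, fun = function(k) rpois(k, 1))
  m1[1, ] <- 0
  m1[2, ] <- 5
  expect_error_validation(
    filter_rare_genes(normalize_log2_cpm(count_matrix(m1)), 1))
})

test_that("CNV scores recover a planted amplification and stay flat elsewhere", {
  ds <- generate_dataset(cnv_config(
    seed = 5, cells_per_tumor = 100,
    cnv_spec = list(n_normal_cells = 60, block_genes = 80, log2_gain = 1)))
  X <- normalize_log2_cpm(count_matrix(ds$counts))
  pos <- ds$gene_truth[, c("gene_id", "chrom", "start")]
  ref <- ds$cell_truth$cell_id[!ds$cell_truth$malignant]
  prof <- cnv_score_cells(X, pos, ref, window_genes = 40)
  # windows fully inside the planted block average near +1 for carriers
  blk_genes <- ds$gene_truth$gene_id[ds$gene_truth$in_cnv_block]
  blk_win <- prof$windows$window[prof$windows$first_gene %in%
                                   utils::head(blk_genes, 40)]
  mal <- ds$cell_truth$malignant
  expect_equal(mean(prof$window_scores[mal, blk_win]), 1, tolerance = 0.3)
  # windows on the other chromosome stay centered at zero
  far_win <- prof$windows$window[prof$windows$chrom == "chr2"]
  expect_lt(abs(mean(prof$window_scores[mal, far_win])), 0.1)
  # reference cells carry low signal relative to carriers
  expect_lt(mean(prof$cnv_signal[ref]), mean(prof$cnv_signal[mal]) / 2)
  # cap = 0 kills every score
  p0 <- cnv_score_cells(X, pos, ref, window_genes = 40, cap = 0)
  expect_true(all(p0$window_scores == 0))
  expect_true(all(p0$cnv_signal == 0))
  # >= 90% of planted malignant cells are flagged at defaults
  calls <- call_malignant(prof)
  expect_gte(mean(calls[mal]), 0.9)
  # k_sd -> infinity flags nothing
  expect_identical(sum(call_malignant(prof, k_sd = 1e9)), 0L)
})

test_that("malignant calling controls false positives under the null", {
  fps <- vapply(1:10, function(s) {
    ds <- generate_dataset(cnv_config(seed = 100 + s, cells_per_tumor = 30))
    X <- normalize_log2_cpm(count_matrix(ds$counts))
    pos <- ds$gene_truth[, c("gene_id", "chrom", "start")]
    ref <- rownames(ds$counts)  # everyone is reference: no CNV anywhere
    prof <- cnv_score_cells(X, pos, ref, window_genes = 40)
    mean(call_malignant(prof))
  }, numeric(1))
  expect_lte(mean(fps), 0.05)
})

test_that("CNV scoring validates inputs", {
  ds <- generate_dataset(small_config(seed = 6))
  X <- normalize_log2_cpm(count_matrix(ds$counts))
  pos <- ds$gene_truth[, c("gene_id", "chrom", "start")]
  expect_error_validation(
    cnv_score_cells(X, pos[-1, ], rownames(ds$counts)[1:30]))
  expect_error_validation(cnv_score_cells(X, pos, rownames(ds$counts)[1:5]))
})
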