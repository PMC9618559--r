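test_that("generated dataset honors the configured shapes and annotations", {
  ds <- generate_dataset(small_config(seed = 7))
  expect_identical(dim(ds$counts), c(200L, 300L))
  expect_identical(nrow(ds$cell_truth), 200L)
  expect_identical(nrow(ds$gene_truth), 300L)
  expect_true(all(ds$counts >= 0))
  expect_identical(storage.mode(ds$counts), "integer")
  roles <- table(ds$gene_truth$role)
  expect_identical(unname(roles["signature"]), 10L)
  expect_identical(unname(roles["module:EMT"]), 10L)
  expect_identical(unname(roles["switch"]), 1L)
  # signature, module and switch gene sets are disjoint by construction
  expect_false(anyDuplicated(ds$gene_truth$gene_id) > 0)
  # every tumor contains every state
  tab <- table(ds$cell_truth$tumor_id, ds$cell_truth$state_id)
  expect_true(all(tab > 0))
})

test_that("generation is deterministic given the seed", {
  d1 <- generate_dataset(small_config(seed = 42))
  d2 <- generate_dataset(small_config(seed = 42))
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$cell_truth, d2$cell_truth)
  d3 <- generate_dataset(small_config(seed = 43))
  expect_false(identical(d1$counts, d3$counts))
})

test_that("invalid configurations are rejected with named fields", {
  expect_error(sim_config(n_tumors = 0), "n_tumors")
  expect_error(sim_config(dropout_rate = 1.5), "dropout_rate")
  expect_error(sim_config(n_states = 1), "n_states")
  expect_error(sim_config(n_genes = 50), "n_genes")
  expect_error(sim_config(state_motility_means = c(3, 1)),
               "state_motility_means")
})

test_that("signature genes correlate with each other and with latent motility", {
  ds <- generate_dataset(sim_config(n_tumors = 4, cells_per_tumor = 500,
                                    seed = 11))
  X <- normalize_log2_cpm(count_matrix(ds$counts))
  sig <- signature_submatrix(X, motility_signature())
  cs <- cor(sig, method = "spearman")
  expect_gt(median(cs[upper.tri(cs)]), 0)
  sp <- apply(sig, 2, function(g)
    cor(g, ds$cell_truth$motility, method = "spearman"))
  expect_true(all(sp > 0))
})

test_that("state assignment is independent of tumor of origin", {
  vals <- vapply(1:10, function(s) {
    ds <- generate_dataset(sim_config(n_tumors = 4, cells_per_tumor = 100,
                                      n_genes = 200, n_metabolic_genes = 10,
                                      module_specs = c(EMT = 10),
                                      seed = s))
    nmi(ds$cell_truth$state_id, ds$cell_truth$tumor_id)
  }, numeric(1))
  expect_lt(mean(vals), 0.05)
})

test_that("switch genes peak on the intermediate branch at truth level", {
  ds <- generate_dataset(small_config(seed = 3, cells_per_tumor = 200))
  X <- normalize_log2_cpm(count_matrix(ds$counts))
  br <- ds$cell_truth$branch_id
  sw <- X$values[, "SWITCH1"]
  m_int <- mean(sw[br == "intermediate"])
  expect_gt(m_int, mean(sw[br == "low"]))
  expect_gt(m_int, mean(sw[br == "high"]))
})

test_that("datasets round-trip through the Matrix Market + TSV writer", {
  ds <- generate_dataset(small_config(seed = 9))
  td <- withr::local_tempdir()
  paths <- write_dataset(ds, td)
  expect_true(all(file.exists(paths)))
  genes <- read.table(file.path(td, "genes.tsv"), sep = "\t", header = TRUE)
  expect_identical(nrow(genes), 300L)
  back <- read_dataset(td)
  expect_identical(unname(back$values), unname(ds$counts))
  expect_identical(back$cell_ids, rownames(ds$counts))
  expect_identical(back$tumor_labels, ds$cell_truth$tumor_id)
})

test_that("degenerate datasets are refused by the writer", {
  ds <- generate_dataset(small_config(seed = 1))
  ds$counts <- ds$counts[integer(0), , drop = FALSE]
  expect_error_validation(write_dataset(ds, withr::local_tempdir()))
})

test_that("CNV mode plants an amplified block and normal cells", {
  ds <- generate_dataset(cnv_config(
    seed = 5, cnv_spec = list(n_normal_cells = 60, block_genes = 80,
                              log2_gain = 1)))
  expect_identical(sum(!ds$cell_truth$malignant), 60L)
  expect_identical(sum(ds$gene_truth$in_cnv_block), 80L)
  blk <- ds$gene_truth$in_cnv_block
  mal <- ds$cell_truth$malignant
  lcpm <- normalize_log2_cpm(count_matrix(ds$counts))$values
  gain <- mean(lcpm[mal, blk]) - mean(lcpm[!mal, blk])
  expect_gt(gain, 0.5)
})
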