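#' Default motility signature
#'
#' The ten-gene glioblastoma motility signature used throughout the
#' package: autocrine pro-motile signaling (TGFB1, SMAD3, THBS1),
#' cytoskeleton/adhesion remodeling (ACTN4, PTK2, PXN, TLN1, VCL) and
#' matricellular remodeling (TNC, SPARCL1). The synthetic generator
#' reuses these symbols for its planted signature genes so that the
#' default signature applies unchanged to simulated data.
#'
#' @return Character vector of ten gene symbols.
#' @export
motility_signature <- function() {
  c("TGFB1", "SMAD3", "THBS1", "ACTN4", "PTK2",
    "PXN", "TLN1", "VCL", "TNC", "SPARCL1")
}

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic multi-tumor
#' single-cell dataset. The generated data carry a continuous latent
#' motility value per cell, discrete signature-combination states shared
#' across tumors, gene modules and metabolic programs loading on the
#' motility axis, a branched low/intermediate/high trajectory with one or
#' more planted intermediate-branch "switch" genes, negative-binomial
#' counts with dropout, and (optionally) an amplified copy-number block
#' separating malignant from normal cells.
#'
#' @param n_tumors Number of tumors (cell batches). Each tumor contains a
#'   balanced draw of every state, so state and tumor are independent.
#' @param cells_per_tumor Cells per tumor.
#' @param n_genes Total genes, including signature, module, metabolic,
#'   switch and background genes.
#' @param n_signature_genes Size of the motility signature (default 10).
#' @param module_specs Named integer vector of module sizes. Defaults to
#'   the three motility-associated modules EMT (14), oRG (36), TEAD (32).
#' @param n_metabolic_genes Genes forming the planted "metabolic_up"
#'   program that co-varies with motility.
#' @param n_states Number of discrete signature-combination states
#'   (>= 2); states have increasing latent-motility means, and the two
#'   extreme states play the planted low/high-motility roles.
#' @param n_branches Trajectory branches; only the default 3-branch
#'   low / intermediate (side arm) / high geometry is implemented.
#' @param n_switch_genes Number of planted switch genes (expression
#'   maximal on the intermediate branch, mildly increasing with motility).
#' @param state_motility_means Latent motility mean per state (length
#'   `n_states`, increasing). Default: evenly spaced on [0.5, 3].
#' @param state_motility_sd Within-state latent motility s.d.
#' @param signature_loading_range Range of per-gene positive loadings of
#'   signature genes on latent motility (log2 units per motility unit).
#' @param state_pattern_delta Log2 offset of the per-state on/off
#'   signature combination patterns.
#' @param branch_deflection_sd S.d. of the per-signature-gene deflection
#'   that pushes intermediate-motility cells off the low-high axis,
#'   creating the side arm of the "Y" in expression space.
#' @param module_loading_range Range of module/metabolic gene loadings on
#'   latent motility.
#' @param switch_slope,switch_bump Switch-gene log2 slope on motility and
#'   log2 bump on the intermediate branch.
#' @param tumor_effect_sd S.d. of per-tumor, per-gene log2 batch offsets.
#' @param nb_dispersion Negative-binomial size parameter (smaller =
#'   noisier).
#' @param dropout_rate Maximum dropout probability. Dropout is an
#'   independent Bernoulli zeroing applied after count sampling, with
#'   expression-dependent probability
#'   `dropout_rate * exp(-mu / dropout_decay)`: lowly expressed genes
#'   are zero-inflated, highly expressed ones essentially never drop
#'   out, as in real data.
#' @param dropout_decay Expected-count scale of the dropout decay.
#' @param library_size Expected total counts per cell.
#' @param cnv_spec Optional list(n_normal_cells, block_genes, log2_gain)
#'   planting one contiguous amplified block in malignant cells only.
#' @param seed Integer seed; one root seed drives all draws through
#'   deterministic sub-streams.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_tumors = 4,
                       cells_per_tumor = 250,
                       n_genes = 10000,
                       n_signature_genes = 10,
                       module_specs = c(EMT = 14, oRG = 36, TEAD = 32),
                       n_metabolic_genes = 40,
                       n_states = 6,
                       n_branches = 3,
                       n_switch_genes = 1,
                       state_motility_means = NULL,
                       state_motility_sd = 0.25,
                       signature_loading_range = c(0.5, 1.0),
                       state_pattern_delta = 6.0,
                       branch_deflection_sd = 0.7,
                       module_loading_range = c(0.3, 0.7),
                       switch_slope = 0.5,
                       switch_bump = 2.0,
                       tumor_effect_sd = 0.1,
                       nb_dispersion = 10,
                       dropout_rate = 0.3,
                       dropout_decay = 5,
                       library_size = 30000,
                       cnv_spec = NULL,
                       seed = 1L) {
  assert_count(n_tumors, "n_tumors")
  assert_count(cells_per_tumor, "cells_per_tumor")
  assert_count(n_genes, "n_genes")
  assert_count(n_signature_genes, "n_signature_genes")
  assert_count(n_states, "n_states")
  assert_count(n_switch_genes, "n_switch_genes")
  assert_count(library_size, "library_size")
  assert_prob(dropout_rate, "dropout_rate")
  if (n_states < 2) stop_validation("'n_states' must be >= 2")
  if (n_branches != 3)
    stop_validation("'n_branches': only the 3-branch Y geometry is supported")
  if (is.null(state_motility_means))
    state_motility_means <- seq(0.5, 3, length.out = n_states)
  if (length(state_motility_means) != n_states ||
      is.unsorted(state_motility_means, strictly = TRUE))
    stop_validation("'state_motility_means' must be increasing, one per state")
  if (length(module_specs) && is.null(names(module_specs)))
    stop_validation("'module_specs' must be a named vector of module sizes")
  n_special <- n_signature_genes + sum(module_specs) + n_metabolic_genes +
    n_switch_genes
  if (n_genes <= n_special)
    stop_validation("'n_genes' (", n_genes, ") must exceed the ",
                    n_special, " signature/module/metabolic/switch genes")
  if (!is.null(cnv_spec)) {
    if (!is.list(cnv_spec)) stop_validation("'cnv_spec' must be a list")
    cnv_spec$n_normal_cells <- cnv_spec$n_normal_cells %||% 100
    cnv_spec$block_genes <- cnv_spec$block_genes %||% 200
    cnv_spec$log2_gain <- cnv_spec$log2_gain %||% 1
    assert_count(cnv_spec$n_normal_cells, "cnv_spec$n_normal_cells")
    assert_count(cnv_spec$block_genes, "cnv_spec$block_genes")
    if (cnv_spec$block_genes > n_genes - n_special)
      stop_validation("'cnv_spec$block_genes' exceeds available background genes")
  }
  if (!is_count(abs(seed) + 1)) stop_validation("'seed' must be an integer")
  cfg <- list(
    n_tumors = as.integer(n_tumors),
    cells_per_tumor = as.integer(cells_per_tumor),
    n_genes = as.integer(n_genes),
    n_signature_genes = as.integer(n_signature_genes),
    module_specs = module_specs,
    n_metabolic_genes = as.integer(n_metabolic_genes),
    n_states = as.integer(n_states),
    n_branches = 3L,
    n_switch_genes = as.integer(n_switch_genes),
    state_motility_means = as.numeric(state_motility_means),
    state_motility_sd = state_motility_sd,
    signature_loading_range = signature_loading_range,
    state_pattern_delta = state_pattern_delta,
    branch_deflection_sd = branch_deflection_sd,
    module_loading_range = module_loading_range,
    switch_slope = switch_slope,
    switch_bump = switch_bump,
    tumor_effect_sd = tumor_effect_sd,
    nb_dispersion = nb_dispersion,
    dropout_rate = dropout_rate,
    dropout_decay = dropout_decay,
    library_size = as.integer(library_size),
    cnv_spec = cnv_spec,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

sim_gene_table <- function(cfg) {
  sig_ids <- if (cfg$n_signature_genes == 10) motility_signature() else
    sprintf("SIG%02d", seq_len(cfg$n_signature_genes))
  mod_ids <- character(0)
  mod_role <- character(0)
  for (m in names(cfg$module_specs)) {
    k <- cfg$module_specs[[m]]
    mod_ids <- c(mod_ids, sprintf("%s_%02d", m, seq_len(k)))
    mod_role <- c(mod_role, rep(paste0("module:", m), k))
  }
  met_ids <- sprintf("MET_%03d", seq_len(cfg$n_metabolic_genes))
  sw_ids <- sprintf("SWITCH%d", seq_len(cfg$n_switch_genes))
  n_bg <- cfg$n_genes - length(sig_ids) - length(mod_ids) -
    length(met_ids) - length(sw_ids)
  bg_ids <- sprintf("BG_%04d", seq_len(n_bg))
  data.frame(
    gene_id = c(sig_ids, mod_ids, met_ids, sw_ids, bg_ids),
    role = c(rep("signature", length(sig_ids)), mod_role,
             rep("metabolic_up", length(met_ids)),
             rep("switch", length(sw_ids)),
             rep("background", n_bg)),
    stringsAsFactors = FALSE)
}

# Distinct on/off signature-combination pattern per state. Patterns are
# nested: genes turn on progressively with the state's motility rank
# (roughly n_sig/(n_states-1) genes per step), so every state carries a
# distinct combination, adjacent states differ by several genes, and
# each gene stays monotone in motility.
sim_state_patterns <- function(n_states, n_sig) {
  # per-gene activation threshold, evenly spread over states 2..n_states
  thr <- rep(seq(2, n_states, length.out = min(n_states - 1, n_sig)),
             length.out = n_sig)
  thr <- round(sort(thr))
  pat <- outer(seq_len(n_states), thr, ">=") + 0L
  pat
}

#' Generate a synthetic multi-tumor single-cell dataset
#'
#' Draws a cells-by-genes count matrix with complete ground-truth
#' annotations. Expression follows a log-linear model on a latent
#' motility axis: signature genes load positively on motility with
#' per-state combination offsets and an intermediate-branch deflection
#' (which bends the manifold into a "Y"); module and metabolic genes
#' load positively on motility; switch genes peak on the intermediate
#' branch; background genes carry only baseline and tumor batch effects.
#' Counts are gamma-Poisson (negative binomial) with the cell's library
#' size, followed by independent dropout.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `synthetic_dataset`: list with `counts`
#'   (integer cells x genes matrix), `cell_truth` (data.frame: cell_id,
#'   tumor_id, state_id, motility, branch_id, branch_position,
#'   malignant), `gene_truth` (data.frame: gene_id, role, chrom, start,
#'   log2_effect) and `config`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_validation("'config' must be built with sim_config()")
  cfg <- config
  set.seed(sub_seed(cfg$seed, 1))

  genes <- sim_gene_table(cfg)
  G <- cfg$n_genes
  sig_idx <- which(genes$role == "signature")
  mod_idx <- grep("^module:", genes$role)
  met_idx <- which(genes$role == "metabolic_up")
  sw_idx <- which(genes$role == "switch")

  # gene-level parameters. Baseline abundances are heavy-tailed
  # log-normal (a few housekeeping-like genes dominate the library, as
  # in real transcriptomes, keeping any planted class's library share
  # small); signature genes sit on a raised, tighter baseline so both
  # their off and on levels are measurable; switch genes moderately
  # expressed so the branch contrast is well measured
  base <- rnorm(G, mean = 1, sd = 2.2)
  special <- c(sig_idx, mod_idx, met_idx, sw_idx)
  base[special] <- rnorm(length(special), mean = 1, sd = 1)
  base[sig_idx] <- base[sig_idx] + 2.5
  base[sw_idx] <- base[sw_idx] + 2
  beta <- numeric(G)                       # loading on latent motility
  beta[sig_idx] <- runif(length(sig_idx), cfg$signature_loading_range[1],
                         cfg$signature_loading_range[2])
  beta[c(mod_idx, met_idx)] <- runif(length(mod_idx) + length(met_idx),
                                     cfg$module_loading_range[1],
                                     cfg$module_loading_range[2])
  beta[sw_idx] <- cfg$switch_slope
  deflect <- numeric(G)                    # side-arm deflection (signature)
  deflect[sig_idx] <- rnorm(length(sig_idx), 0, cfg$branch_deflection_sd)
  patterns <- sim_state_patterns(cfg$n_states, length(sig_idx))

  # cells: balanced states within each tumor => state independent of tumor
  n_mal <- cfg$n_tumors * cfg$cells_per_tumor
  tumor <- rep(sprintf("T%02d", seq_len(cfg$n_tumors)),
               each = cfg$cells_per_tumor)
  state <- unlist(lapply(seq_len(cfg$n_tumors), function(t)
    sample(rep_len(seq_len(cfg$n_states), cfg$cells_per_tumor))))
  m <- rnorm(n_mal, cfg$state_motility_means[state], cfg$state_motility_sd)

  # branch geometry: thirds of the latent motility range
  lo <- min(cfg$state_motility_means) - 2 * cfg$state_motility_sd
  hi <- max(cfg$state_motility_means) + 2 * cfg$state_motility_sd
  cut1 <- lo + (hi - lo) / 3
  cut2 <- lo + 2 * (hi - lo) / 3
  branch <- ifelse(m < cut1, "low", ifelse(m < cut2, "intermediate", "high"))
  pos <- numeric(n_mal)
  pos[branch == "low"] <- (cut1 - m[branch == "low"]) / (cut1 - lo)
  pos[branch == "intermediate"] <-
    1 - 2 * abs(m[branch == "intermediate"] - (cut1 + cut2) / 2) / (cut2 - cut1)
  pos[branch == "high"] <- (m[branch == "high"] - cut2) / (hi - cut2)
  pos <- pmin(1, pmax(0, pos))
  # tent function: 1 at mid-motility, 0 outside the intermediate interval
  tent <- pmax(0, 1 - 2 * abs(m - (cut1 + cut2) / 2) / (cut2 - cut1))

  tum_eff <- matrix(rnorm(cfg$n_tumors * G, 0, cfg$tumor_effect_sd),
                    cfg$n_tumors, G)

  # the motility and deflection effects are centered across cells so
  # they model relative contrasts rather than inflating any gene
  # class's mean library share; the on/off state patterns are left
  # uncentered (an "off" gene sits at its baseline, an "on" gene at
  # baseline + delta), which is what combinatorial marker panels look
  # like. At the default transcriptome size the signature's library
  # share stays modest in every state, keeping CPM composition honest.
  m_c <- m - mean(m)
  tent_c <- tent - mean(tent)
  eta <- matrix(base, n_mal, G, byrow = TRUE) +
    outer(m_c, beta) +
    outer(tent_c, deflect) +
    tum_eff[as.integer(factor(tumor)), , drop = FALSE]
  eta[, sig_idx] <- eta[, sig_idx] +
    cfg$state_pattern_delta * patterns[state, , drop = FALSE]
  is_int <- branch == "intermediate"
  if (length(sw_idx))
    eta[is_int, sw_idx] <- eta[is_int, sw_idx] + cfg$switch_bump

  # optional normal cells + CNV block on malignant cells
  chrom <- rep(c("chr1", "chr2"), c(ceiling(G / 2), floor(G / 2)))
  start <- (ave(seq_len(G), chrom, FUN = seq_along) - 1L) * 1000L
  block <- integer(0)
  n_norm <- 0L
  if (!is.null(cfg$cnv_spec)) {
    n_norm <- cfg$cnv_spec$n_normal_cells
    bg_idx <- which(genes$role == "background" & chrom == "chr1")
    if (length(bg_idx) < cfg$cnv_spec$block_genes)
      bg_idx <- which(genes$role == "background")
    block <- sort(bg_idx)[seq_len(cfg$cnv_spec$block_genes)]
    eta[, block] <- eta[, block] + cfg$cnv_spec$log2_gain
    eta_norm <- matrix(base, n_norm, G, byrow = TRUE) +
      matrix(rnorm(n_norm * G, 0, cfg$tumor_effect_sd), n_norm, G)
    eta <- rbind(eta, eta_norm)
  }
  n_cells <- n_mal + n_norm

  rate <- 2^eta
  rate <- rate / rowSums(rate)
  mu <- rate * cfg$library_size
  counts <- matrix(rnbinom(n_cells * G, mu = as.vector(mu),
                           size = cfg$nb_dispersion), n_cells, G)
  if (cfg$dropout_rate > 0) {
    p_drop <- cfg$dropout_rate * exp(-mu / cfg$dropout_decay)
    counts <- counts *
      matrix(rbinom(n_cells * G, 1, 1 - as.vector(p_drop)), n_cells, G)
  }
  storage.mode(counts) <- "integer"
  # guard against fully-zero cells (dropout at tiny library sizes)
  empty <- rowSums(counts) == 0
  if (any(empty)) counts[empty, which.max(colMeans(counts))] <- 1L

  cell_ids <- sprintf("cell_%04d", seq_len(n_cells))
  rownames(counts) <- cell_ids
  colnames(counts) <- genes$gene_id

  cell_truth <- data.frame(
    cell_id = cell_ids,
    tumor_id = c(tumor, rep("normal", n_norm)),
    state_id = c(state, rep(NA_integer_, n_norm)),
    motility = c(m, rep(NA_real_, n_norm)),
    branch_id = c(branch, rep(NA_character_, n_norm)),
    branch_position = c(pos, rep(NA_real_, n_norm)),
    malignant = rep(c(TRUE, FALSE), c(n_mal, n_norm)),
    stringsAsFactors = FALSE)
  gene_truth <- data.frame(
    gene_id = genes$gene_id,
    role = genes$role,
    chrom = chrom,
    start = start,
    log2_effect = beta,
    in_cnv_block = seq_len(G) %in% block,
    stringsAsFactors = FALSE)

  structure(list(counts = counts, cell_truth = cell_truth,
                 gene_truth = gene_truth, config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d cells x %d genes, %d tumors, %d states\n",
              nrow(x$counts), ncol(x$counts), x$config$n_tumors,
              x$config$n_states))
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s=%d", names(table(x$gene_truth$role)),
                            table(x$gene_truth$role)), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits Matrix Market counts (`counts.mtx`, cells x genes) with TSV
#' sidecars `genes.tsv` (gene_id, chrom, start, role), `cells.tsv`
#' (cell_id, tumor_id) and full truth tables `cell_truth.tsv`,
#' `gene_truth.tsv`, readable by [read_dataset()].
#'
#' @param ds A `synthetic_dataset`.
#' @param dir_path Output directory (created if absent).
#' @return Invisibly, the vector of written file paths.
#' @export
write_dataset <- function(ds, dir_path) {
  if (!inherits(ds, "synthetic_dataset"))
    stop_validation("'ds' must be a synthetic_dataset")
  if (nrow(ds$counts) == 0 || ncol(ds$counts) == 0)
    stop_validation("refusing to write an empty dataset (0 cells or 0 genes)")
  ok <- dir.exists(dir_path) || dir.create(dir_path, recursive = TRUE,
                                           showWarnings = FALSE)
  if (!ok) stop_io("cannot create directory '", dir_path, "'")
  paths <- file.path(dir_path, c("counts.mtx", "genes.tsv", "cells.tsv",
                                 "cell_truth.tsv", "gene_truth.tsv"))
  Matrix::writeMM(methods::as(Matrix::Matrix(ds$counts, sparse = TRUE),
                              "generalMatrix"), paths[1])
  write_tsv(ds$gene_truth[, c("gene_id", "chrom", "start", "role")], paths[2])
  write_tsv(ds$cell_truth[, c("cell_id", "tumor_id")], paths[3])
  write_tsv(ds$cell_truth, paths[4])
  write_tsv(ds$gene_truth, paths[5])
  invisible(paths)
}
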