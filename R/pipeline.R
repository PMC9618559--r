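#' Pipeline configuration
#'
#' Collects every stage parameter and input path of the end-to-end
#' analysis. Either `input_dir` (a directory readable by
#' [read_dataset()]) or an in-memory `dataset` (a `synthetic_dataset`
#' or `count_matrix`) must be supplied.
#'
#' @param input_dir Directory with counts.mtx + genes.tsv + cells.tsv.
#' @param dataset In-memory dataset, alternative to `input_dir`.
#' @param out_dir Output directory for artifacts and the run report
#'   (`NULL` = no files written).
#' @param normalization `"cpm"` or `"tpm"`.
#' @param min_frac Rare-gene detection threshold (default 0.01).
#' @param signature Signature gene ids (default [motility_signature()]).
#' @param k_range Cluster-count search range (default 3:10).
#' @param umap_neighbors,umap_min_dist,umap_seed UMAP parameters.
#' @param de_q M-HIGH/M-LOW DE significance threshold (default 0.01).
#' @param ontology_q,ontology_fc Enrichment-input thresholds (default
#'   0.05 and fold change 2).
#' @param enrich_alpha Module-enrichment report threshold on the
#'   hypergeometric p (default 0.001).
#' @param gmt_files Named character vector of GMT paths for Fisher
#'   enrichment (optional).
#' @param trajectory_components Spectral components (default 4).
#' @param trajectory_knn Spectral-graph neighborhood size (default 30).
#' @param n_nodes,mu,lambda Elastic-tree parameters.
#' @param branch_q Branch-DE significance threshold (default 0.05).
#' @param branch_min_cells Minimum cells per considered branch.
#' @param cnv_reference Optional reference cell ids enabling the
#'   CNV-based malignant-cell call (skipped when annotations exist).
#' @param seed Root seed for all stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, dataset = NULL,
                            out_dir = NULL,
                            normalization = c("cpm", "tpm"),
                            min_frac = 0.01,
                            signature = motility_signature(),
                            k_range = 3:10,
                            umap_neighbors = 30, umap_min_dist = 0.3,
                            umap_seed = NULL,
                            de_q = 0.01,
                            ontology_q = 0.05, ontology_fc = 2.0,
                            enrich_alpha = 0.001,
                            gmt_files = NULL,
                            trajectory_components = 4,
                            trajectory_knn = 30,
                            n_nodes = 10, mu = 0.1, lambda = 0.01,
                            branch_q = 0.05, branch_min_cells = 20,
                            cnv_reference = NULL,
                            seed = 1L) {
  if (is.null(input_dir) && is.null(dataset))
    stop_validation("supply 'input_dir' or 'dataset'")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop_io("input directory not found: '", input_dir, "'")
  for (thr in c(min_frac = min_frac, de_q = de_q, ontology_q = ontology_q,
                enrich_alpha = enrich_alpha, branch_q = branch_q)) {
    if (thr < 0 || thr > 1) stop_validation("thresholds must lie in [0, 1]")
  }
  if (!is.null(gmt_files)) {
    missing <- gmt_files[!file.exists(gmt_files)]
    if (length(missing))
      stop_io("GMT file(s) not found: ", paste(missing, collapse = ", "))
  }
  cfg <- as.list(environment())
  cfg$normalization <- match.arg(normalization)
  cfg$umap_seed <- cfg$umap_seed %||% sub_seed(seed, 2)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full motility-state pipeline
#'
#' Stages: load -> (optional CNV malignant-cell call) -> normalize ->
#' rare-gene filter -> signature clustering (PCA + UMAP, Ward) ->
#' geometric-mean motility scoring -> extreme-cluster selection
#' (ANOVA/Tukey) -> M-HIGH vs M-LOW differential expression ->
#' module/GMT enrichment -> trajectory (spectral embedding + elastic
#' tree) -> intermediate-branch markers -> switch-gene candidates.
#' Deterministic given the config seeds.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list with per-stage parameters, counts and
#'   key statistics; artifacts and `run_report.json` are written to
#'   `out_dir` when set.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_validation("'config' must be built with pipeline_config()")
  cfg <- config
  report <- list(package_version = as.character(
    utils::packageVersion("motistate")), seed = cfg$seed, stages = list())

  # -- load ------------------------------------------------------------
  if (!is.null(cfg$input_dir)) {
    data <- read_dataset(cfg$input_dir)
    counts <- data$values
    tumor <- data$tumor_labels
    positions <- data$gene_positions
  } else if (inherits(cfg$dataset, "synthetic_dataset")) {
    counts <- cfg$dataset$counts
    tumor <- cfg$dataset$cell_truth$tumor_id
    positions <- cfg$dataset$gene_truth[, c("gene_id", "chrom", "start")]
  } else if (inherits(cfg$dataset, "count_matrix")) {
    counts <- cfg$dataset$values
    tumor <- cfg$dataset$tumor_labels
    positions <- NULL
  } else stop_validation("unsupported 'dataset' object")
  report$stages$load <- list(cells = nrow(counts), genes = ncol(counts))

  # -- optional malignant-cell call ------------------------------------
  if (!is.null(cfg$cnv_reference)) {
    Xall <- normalize_log2_cpm(count_matrix(counts, tumor))
    prof <- cnv_score_cells(Xall, positions, cfg$cnv_reference)
    mal <- call_malignant(prof)
    keep <- mal & !(rownames(counts) %in% cfg$cnv_reference)
    report$stages$malignant_call <-
      list(malignant = sum(mal), reference = length(cfg$cnv_reference))
    counts <- counts[keep, , drop = FALSE]
    tumor <- tumor[keep]
  }

  # -- normalize + filter ----------------------------------------------
  X <- normalize_log2_cpm(count_matrix(counts, tumor),
                          mode = cfg$normalization)
  X <- filter_rare_genes(X, cfg$min_frac)
  report$stages$preprocess <- list(
    normalization = X$normalization_mode,
    genes_kept = ncol(X$values), cells = nrow(X$values))

  # -- signature clustering --------------------------------------------
  sig <- signature_submatrix(X, cfg$signature)
  pca <- pca_components(sig)
  um <- umap_components(sig, n_neighbors = cfg$umap_neighbors,
                        min_dist = cfg$umap_min_dist, seed = cfg$umap_seed)
  emb <- combine_components(pca, um)
  clus <- hcpc_cluster(emb, k_range = cfg$k_range,
                       tumor_labels = X$tumor_labels)
  report$stages$clustering <- list(
    k = clus$k, mean_silhouette = clus$mean_silhouette,
    nmi_vs_tumor = clus$nmi_vs_tumor)

  # -- scoring + extreme clusters --------------------------------------
  motility <- geometric_mean_score(X, cfg$signature, name = "motility")
  sel <- select_extreme_clusters(motility, clus)
  report$stages$selection <- list(
    m_high = sel$m_high, m_low = sel$m_low,
    m_high_distinct = sel$m_high_distinct,
    m_low_distinct = sel$m_low_distinct,
    anova_p = sel$anova$p)

  # -- differential expression -----------------------------------------
  idx_high <- which(clus$labels == sel$m_high)
  idx_low <- which(clus$labels == sel$m_low)
  de <- mann_whitney_de(X, idx_high, idx_low, q_threshold = cfg$de_q)
  mhigh_genes <- de$gene_id[de$overexpressed_in_a]
  ontology_genes <- filter_for_ontology(de, cfg$ontology_fc, cfg$ontology_q)
  report$stages$de <- list(
    n_mhigh_overexpressed = length(mhigh_genes),
    n_ontology_input = length(ontology_genes))

  # -- enrichment -------------------------------------------------------
  enrich <- NULL
  if (!is.null(cfg$gmt_files)) {
    universe <- colnames(X$values)
    enrich <- lapply(cfg$gmt_files, function(p)
      gmt_enrichment(intersect(ontology_genes, universe), read_gmt(p),
                     universe, q_max = cfg$ontology_q))
    report$stages$enrichment <- lapply(enrich, function(e)
      list(n_sets = nrow(e), n_significant = sum(e$significant)))
  }

  # -- trajectory -------------------------------------------------------
  se <- spectral_embed(sig, n_components = cfg$trajectory_components,
                       knn = cfg$trajectory_knn)
  tree <- fit_elastic_tree(se, n_nodes = cfg$n_nodes, mu = cfg$mu,
                           lambda = cfg$lambda)
  assignment <- project_cells(tree, se)
  ord <- order_branches_by_score(tree, assignment, motility,
                                 min_cells = cfg$branch_min_cells)
  report$stages$trajectory <- list(
    n_branches = length(tree$branches),
    energy = tree$energy,
    low_branch = ord$low_branch, high_branch = ord$high_branch,
    intermediate_branches = ord$intermediate_branches)

  # -- switch candidates ------------------------------------------------
  markers <- character(0)
  switch_res <- NULL
  if (length(ord$intermediate_branches)) {
    # the intermediate segment may span several fitted branches; merge it
    # into one meta-branch so its markers are tested against the low/high
    # arms rather than against other parts of the same segment
    merged <- assignment
    merged$branch[merged$branch %in% ord$intermediate_branches] <-
      ".intermediate"
    markers <- branch_de(X, merged, ".intermediate",
                         q_max = cfg$branch_q)$markers
    switch_res <- intersect_switch_candidates(
      markers, list(run = mhigh_genes))
  }
  report$stages$switch <- list(
    n_branch_markers = length(markers),
    candidates = switch_res$candidates %||% character(0))

  result <- list(report = report, expression = X, clusters = clus,
                 motility = motility, selection = sel, de = de,
                 mhigh_genes = mhigh_genes,
                 ontology_genes = ontology_genes,
                 enrichment = enrich, embedding = se, tree = tree,
                 assignment = assignment, branch_order = ord,
                 switch = switch_res)
  class(result) <- "motistate_run"

  if (!is.null(cfg$out_dir)) write_run_artifacts(result, cfg$out_dir)
  result
}

#' @export
print.motistate_run <- function(x, ...) {
  r <- x$report$stages
  cat("motistate run\n")
  cat(sprintf("  %d cells x %d genes after preprocessing\n",
              r$preprocess$cells, r$preprocess$genes_kept))
  cat(sprintf("  k=%d clusters, mean silhouette %.3f, NMI vs tumor %.3f\n",
              r$clustering$k, r$clustering$mean_silhouette,
              r$clustering$nmi_vs_tumor))
  cat(sprintf("  M-HIGH=%s M-LOW=%s; %d genes overexpressed in M-HIGH\n",
              r$selection$m_high, r$selection$m_low,
              r$de$n_mhigh_overexpressed))
  cat(sprintf("  trajectory: %d branches (low=%s, high=%s, intermediate=%s)\n",
              r$trajectory$n_branches, r$trajectory$low_branch,
              r$trajectory$high_branch,
              paste(r$trajectory$intermediate_branches, collapse = ",")))
  cat(sprintf("  switch candidates: %s\n",
              if (length(r$switch$candidates))
                paste(r$switch$candidates, collapse = ", ") else "(none)"))
  invisible(x)
}

write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  X <- result$expression
  write_tsv(data.frame(cell_id = rownames(X$values),
                       cluster = result$clusters$labels,
                       silhouette = result$clusters$silhouette,
                       motility_score = as.numeric(result$motility)),
            file.path(out_dir, "clusters.tsv"))
  write_tsv(as.data.frame(result$de), file.path(out_dir, "de_table.tsv"))
  write_tsv(cbind(cell_id = result$assignment$cell,
                  result$assignment[, c("branch", "position", "distance")],
                  motility_score = as.numeric(result$motility)),
            file.path(out_dir, "subway_map.tsv"))
  if (!is.null(result$enrichment))
    for (nm in names(result$enrichment))
      write_tsv(result$enrichment[[nm]],
                file.path(out_dir, paste0("enrichment_", nm, ".tsv")))
  tree <- result$tree
  jsonlite::write_json(
    list(nodes = tree$node_coords, edges = tree$edges,
         branches = tree$branches, energy = tree$energy,
         energy_trace = tree$energy_trace),
    file.path(out_dir, "tree.json"), digits = NA)
  write_run_report(result$report, file.path(out_dir, "run_report.json"))
  invisible(out_dir)
}
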