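#' Geometric-mean signature score
#'
#' Per-cell geometric mean of the expression of a gene set. Null (zero)
#' expression values are imputed with 1 before the log transform, so the
#' score is always positive and equals 1 for a cell in which no
#' signature gene is detected.
#'
#' @param X An `expr_matrix` (or numeric matrix) of non-negative values.
#' @param genes Character vector of gene ids, all present in `X`.
#' @param name Gene-set name recorded on the result.
#' @return Named numeric vector of per-cell scores (attribute
#'   `gene_set` holds the name).
#' @export
geometric_mean_score <- function(X, genes, name = "signature") {
  v <- signature_submatrix(X, genes)
  if (any(v < 0)) stop_validation("negative expression values")
  v[v == 0] <- 1
  score <- exp(rowMeans(log(v)))
  names(score) <- rownames(v)
  attr(score, "gene_set") <- name
  score
}

#' Select the extreme motility clusters
#'
#' Identifies the clusters with the highest and lowest mean score, runs
#' a one-way ANOVA across clusters followed by Tukey's HSD multiple
#' comparisons (Tukey-Kramer for unequal sizes), and flags each extreme
#' cluster as "distinct" when all of its pairwise adjusted p-values are
#' below `alpha`. Mean ties are broken by larger cluster size, then
#' lexicographic cluster id.
#'
#' @param score Per-cell score vector.
#' @param clusters A `cluster_assignment` or per-cell label vector.
#' @param alpha Distinctness threshold on Tukey adjusted p (default
#'   0.01).
#' @return list(m_high, m_low, cluster_means, anova = list(F, df1, df2,
#'   p), tukey (data.frame), m_high_distinct, m_low_distinct).
#' @export
select_extreme_clusters <- function(score, clusters, alpha = 0.01) {
  labels <- if (inherits(clusters, "cluster_assignment")) clusters$labels
            else clusters
  if (length(labels) != length(score))
    stop_validation("score and cluster labels differ in length")
  f <- factor(labels)
  sizes <- table(f)
  if (any(sizes < 2))
    stop_validation("clusters with fewer than 2 cells: ",
                    paste(names(sizes)[sizes < 2], collapse = ", "))
  if (nlevels(f) < 3)
    warning("fewer than 3 clusters; extreme-cluster selection is weak")
  fit <- stats::aov(score ~ f)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$f
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  means <- tapply(score, f, mean)
  pick <- function(target) {
    cand <- names(means)[means == target]
    if (length(cand) > 1) {
      ms_log("tied extreme cluster means; breaking by size then id")
      cand <- cand[order(-as.numeric(sizes[cand]), cand)]
    }
    cand[1]
  }
  m_low <- pick(min(means))
  m_high <- pick(max(means))
  distinct <- function(cl) {
    hit <- grepl(paste0("(^|-)", cl, "(-|$)"), tukey$comparison)
    all(tukey$p_adj[hit] < alpha)
  }
  list(m_high = m_high, m_low = m_low,
       cluster_means = means,
       anova = list(F = an[1, "F value"], df1 = as.integer(an[1, "Df"]),
                    df2 = as.integer(an[2, "Df"]), p = an[1, "Pr(>F)"]),
       tukey = tukey,
       m_high_distinct = distinct(m_high),
       m_low_distinct = distinct(m_low))
}

#' Ordinary least-squares fit between two scores
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return list(slope, intercept, r_squared, f_pvalue, n).
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop_validation("'x' and 'y' lengths differ")
  if (length(x) < 3) stop_validation("need n >= 3 observations")
  if (stats::var(x) == 0) stop_validation("zero variance in 'x'")
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = y[1], r_squared = 0, f_pvalue = 1,
                n = length(x)))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fp <- if (is.null(sm$fstatistic)) 1 else
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       f_pvalue = fp,
       n = length(x))
}

#' Compare a score between two cell groups (Mann-Whitney)
#'
#' Two-sided Mann-Whitney U test between disjoint cell groups, using
#' the same test implementation as the differential-expression stage.
#'
#' @param score Named per-cell score vector.
#' @param cells_a,cells_b Disjoint, non-empty cell id (or index) sets.
#' @return list(U, p).
#' @export
compare_scores_between_groups <- function(score, cells_a, cells_b) {
  if (!length(cells_a) || !length(cells_b))
    stop_validation("both groups must be non-empty")
  if (length(intersect(cells_a, cells_b)))
    stop_validation("cell groups overlap")
  mw <- mann_whitney(score[cells_a], score[cells_b])
  list(U = mw$U, p = mw$p)
}
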