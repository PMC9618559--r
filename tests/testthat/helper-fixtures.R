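# Shared fixtures and independent oracles. Oracles are deliberately
# naive (brute force / enumeration) and never share code with the
# implementations they check.

# small, fast simulation configuration for contract-level tests
small_config <- function(seed = 7, cells_per_tumor = 50, ...) {
  sim_config(n_tumors = 4, cells_per_tumor = cells_per_tumor, n_genes = 300,
             n_metabolic_genes = 20,
             module_specs = c(EMT = 10, oRG = 12, TEAD = 10),
             seed = seed, ...)
}

# config for the CNV stage: planted state/motility effects toned down so
# that, at the small test gene count, the signature's library share stays
# negligible (as it is at realistic transcriptome sizes) and copy-number
# composition is the dominant signal
cnv_config <- function(seed = 7, cells_per_tumor = 50, ...) {
  sim_config(n_tumors = 4, cells_per_tumor = cells_per_tumor,
             n_genes = 1000, n_metabolic_genes = 20,
             module_specs = c(EMT = 10, oRG = 12, TEAD = 10),
             state_pattern_delta = 0.5, branch_deflection_sd = 0.2,
             switch_bump = 0.5, seed = seed, ...)
}

# named random matrix helper
rand_matrix <- function(n, g, seed = 1, fun = function(k) rnorm(k, 5, 1)) {
  set.seed(seed)
  m <- matrix(pmax(fun(n * g), 0), n, g,
              dimnames = list(sprintf("c%03d", seq_len(n)),
                              sprintf("g%03d", seq_len(g))))
  m
}

# three well-separated Gaussian blobs in 2-D
make_blobs <- function(n_per = 50, sd = 0.1, sep = 10, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  lab <- rep(1:3, each = n_per)
  pts <- centers[lab, ] + matrix(rnorm(2 * 3 * n_per, 0, sd), ncol = 2)
  rownames(pts) <- sprintf("b%03d", seq_len(nrow(pts)))
  list(pts = pts, labels = lab)
}

# noisy three-arm "Y" in 2-D with arm memberships and arc positions
make_y <- function(n_per_arm = 150, noise = 0.15, arm_len = 5, seed = 1) {
  set.seed(seed)
  dirs <- rbind(c(1, 0), c(-0.5, 0.866), c(-0.5, -0.866))
  t <- runif(3 * n_per_arm, 0, arm_len)
  arm <- rep(1:3, each = n_per_arm)
  pts <- dirs[arm, ] * t + matrix(rnorm(6 * n_per_arm, 0, noise), ncol = 2)
  rownames(pts) <- sprintf("y%04d", seq_len(nrow(pts)))
  list(pts = pts, arm = arm, t = t)
}

# ORACLE: silhouette by direct pairwise-distance computation
oracle_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  n <- nrow(coords)
  vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(d[i, labels == cl]), numeric(1)))
    if (max(a, b) == 0) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
}

# ORACLE: NMI by direct entropy computation over the contingency table,
# written with explicit loops
oracle_nmi <- function(a, b) {
  ua <- unique(a); ub <- unique(b); n <- length(a)
  h <- function(labs, u) {
    s <- 0
    for (v in u) {
      p <- sum(labs == v) / n
      if (p > 0) s <- s - p * log(p)
    }
    s
  }
  ha <- h(a, ua); hb <- h(b, ub)
  if (ha == 0 || hb == 0) return(0)
  mi <- 0
  for (va in ua) for (vb in ub) {
    pab <- sum(a == va & b == vb) / n
    if (pab > 0)
      mi <- mi + pab * log(pab / ((sum(a == va) / n) * (sum(b == vb) / n)))
  }
  mi / ((ha + hb) / 2)
}

# ORACLE: exact two-sided Mann-Whitney p by full enumeration of all
# C(na+nb, na) group assignments of the pooled sample
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# ORACLE: hypergeometric upper tail P(X >= k) by enumeration of all
# C(N, n) draws from a labeled universe
oracle_hyper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  inset <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% inset)) >= k)
}

expect_error_validation <- function(expr) {
  expect_error(expr, class = "motistate_validation_error")
}
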