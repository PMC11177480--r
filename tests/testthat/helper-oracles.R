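# Independent oracles used to cross-check the implementation paths, plus
# small fixture builders. Each oracle is a deliberately naive computation.

# Two-sided Fisher p-value by exhaustive hypergeometric enumeration over
# all tables with the same margins: sum the probabilities of every table
# at most as probable as the observed one.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC by counting concordant case/control pairs (ties count 1/2).
oracle_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (if (p > q) 1 else if (p == q) 0.5 else 0)
  total / (length(pos) * length(neg))
}

# Simplex grid search for constrained least squares, refined iteratively
# around the incumbent down to `step`; independent of the active-set path.
oracle_simplex_ls <- function(R, y, step = 1e-4) {
  p <- ncol(R)
  obj <- function(w) sum((R %*% w - y)^2)
  grid_around <- function(center, radius, by) {
    axes <- lapply(seq_len(p - 1), function(i)
      seq(max(0, center[i] - radius), min(1, center[i] + radius), by = by))
    g <- as.matrix(expand.grid(axes))
    last <- 1 - rowSums(g)
    g <- cbind(g, last)[last >= -1e-12, , drop = FALSE]
    g[g[, p] < 0, p] <- 0
    g
  }
  best <- rep(1 / p, p); radius <- 1; by <- 0.05
  repeat {
    g <- grid_around(best, radius, by)
    vals <- apply(g, 1, obj)
    best <- g[which.min(vals), ]
    if (by <= step) break
    radius <- by * 2
    by <- max(step, by / 10)
  }
  unname(best)
}

# Brute-force per-region scan: loop sites for every region independently.
oracle_summarize <- function(calls, regions) {
  t(vapply(seq_len(nrow(regions)), function(i) {
    inside <- calls$context == "CpG" &
      calls$chrom == regions$chrom[i] &
      calls$pos0 >= regions$start0[i] & calls$pos0 < regions$end0[i]
    m <- sum(calls$n_meth[inside]); u <- sum(calls$n_unmeth[inside])
    c(pooled_meth = m, pooled_unmeth = u, n_sites = sum(inside),
      level = if (m + u > 0) m / (m + u) else NA_real_)
  }, numeric(4)))
}

# Small well-separated atlas for mixture tests.
toy_atlas <- function(n_types = 6, n_sites = 60, margin = 0.6, seed = 42) {
  build_reference_atlas(n_types, n_sites, marker_fraction = 1,
                        margin = margin, seed = seed)
}

# Dirichlet draw for test mixtures.
.cfmeth_rdirichlet_test <- function(alpha) {
  g <- stats::rgamma(length(alpha), alpha, 1)
  g / sum(g)
}

# Region-level cohort: per-sample summaries with binomial counts at the
# given per-region methylation probabilities (one row per region).
region_cohort <- function(p_by_sample, reads_per_region) {
  n_regions <- nrow(p_by_sample)
  regions <- region_set(chrom = "chr1",
                        start0 = (seq_len(n_regions) - 1) * 3000,
                        end0 = seq_len(n_regions) * 3000)
  lapply(seq_len(ncol(p_by_sample)), function(s) {
    m <- stats::rbinom(n_regions, reads_per_region, p_by_sample[, s])
    regions$pooled_meth <- m
    regions$pooled_unmeth <- reads_per_region - m
    regions$n_sites <- 3L
    regions$level <- regions$pooled_meth / reads_per_region
    regions
  })
}
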