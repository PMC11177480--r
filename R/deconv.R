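# Tissue-of-origin and immune-cell deconvolution: pooled marker-region
# levels, mega-site construction by hierarchical clustering, k-NN
# imputation of missing features, and simplex-constrained least-squares
# estimation of cell-type proportions.

#' Pooled methylation level per marker region
#'
#' For each curated marker region, the level is the proportion of
#' methylated reads among all reads covering CpG sites inside the region
#' (calls should be loaded at \code{min_coverage = 1}: deconvolution keeps
#' every covered site). Uncovered markers are missing.
#'
#' @param calls a call table.
#' @param markers a region set; optional columns \code{target},
#'   \code{direction} annotate the discriminated cell type.
#' @return named numeric vector of marker levels (NA where uncovered).
#' @export
marker_region_levels <- function(calls, markers) {
  s <- summarize_regions(calls, markers)
  stats::setNames(s$level, s$name)
}

#' Aggregate reference marker sites into mega sites
#'
#' Individual reference CpGs are often uncovered in a low-pass cfDNA
#' sample. Sites are therefore clustered by their cell-type methylation
#' profiles (hierarchical clustering, Euclidean distance, complete linkage
#' by default), the dendrogram is cut into \code{k} groups, singleton
#' groups are dropped, and each retained group becomes one mega site whose
#' reference value per cell type is the unweighted mean over member sites.
#'
#' @param reference_matrix sites x cell types methylation matrix with
#'   rownames identifying sites ("chrom:pos0"); no missing values.
#' @param k number of dendrogram groups (default 32).
#' @param distance distance measure for \code{\link[stats]{dist}}.
#' @param linkage agglomeration method for \code{\link[stats]{hclust}}.
#' @return object of class \code{cfmeth_megasites}: list with
#'   \code{groups} (named list of member site ids), \code{sizes},
#'   \code{reference} (mega site x cell type matrix).
#' @export
build_mega_sites <- function(reference_matrix, k = 32,
                             distance = "euclidean", linkage = "complete") {
  if (k > nrow(reference_matrix))
    .stopf("k (%d) exceeds the number of sites (%d)", k, nrow(reference_matrix))
  if (anyNA(reference_matrix)) .stopf("reference matrix must be complete")
  if (is.null(rownames(reference_matrix)))
    rownames(reference_matrix) <- sprintf("site%d", seq_len(nrow(reference_matrix)))
  hc <- stats::hclust(stats::dist(reference_matrix, method = distance),
                      method = linkage)
  grp <- stats::cutree(hc, k = k)
  sizes <- table(grp)
  keep <- as.integer(names(sizes)[sizes >= 2])
  if (length(keep) == 0L) {
    warning("all clusters are singletons; empty mega-site set")
    return(structure(list(groups = list(), sizes = integer(0),
                          reference = matrix(numeric(0), 0,
                                             ncol(reference_matrix),
                                             dimnames = list(NULL, colnames(reference_matrix)))),
                     class = "cfmeth_megasites"))
  }
  groups <- lapply(keep, function(g) rownames(reference_matrix)[grp == g])
  names(groups) <- sprintf("mega%02d", seq_along(keep))
  ref <- t(vapply(groups, function(ids)
    colMeans(reference_matrix[ids, , drop = FALSE]),
    numeric(ncol(reference_matrix))))
  structure(list(groups = groups, sizes = lengths(groups), reference = ref),
            class = "cfmeth_megasites")
}

#' @export
print.cfmeth_megasites <- function(x, ...) {
  cat(sprintf("Mega sites: %d groups of %s CpGs (%d cell types)\n",
              length(x$groups),
              if (length(x$groups)) paste(range(x$sizes), collapse = "-") else "0",
              ncol(x$reference)))
  invisible(x)
}

#' Pool a sample's reads over each mega site
#'
#' Per mega site, the proportion of methylated reads over all covered
#' member sites; missing when no member is covered. Aggregating sites then
#' pooling reads equals pooling reads over the union of member sites.
#'
#' @param calls a call table (load at \code{min_coverage = 1}).
#' @param mega_sites a \code{cfmeth_megasites} whose member ids are
#'   "chrom:pos0" keys of the reference sites.
#' @return named numeric vector, one level per mega site (NA = uncovered).
#' @export
aggregate_sample_to_mega_sites <- function(calls, mega_sites) {
  key <- .site_key(calls$chrom, calls$pos0)
  m <- stats::setNames(as.numeric(calls$n_meth), key)
  u <- stats::setNames(as.numeric(calls$n_unmeth), key)
  vapply(mega_sites$groups, function(ids) {
    hit <- ids[ids %in% key]
    tot <- sum(m[hit]) + sum(u[hit])
    if (length(hit) == 0L || tot == 0) NA_real_ else sum(m[hit]) / tot
  }, numeric(1))
}

#' k-nearest-neighbour imputation of missing feature values
#'
#' For a features x samples matrix, each missing entry is replaced by the
#' mean of that sample's values at the k nearest features, where feature
#' distance is the Euclidean distance over jointly observed samples
#' (root-mean-square over the shared samples, so partial overlap is
#' comparable). A feature observed nowhere (or with no usable neighbour)
#' falls back to the sample mean, then the global mean.
#'
#' @param x numeric matrix, features in rows, samples in columns.
#' @param k number of neighbours (default 10).
#' @return the matrix with missing entries imputed.
#' @export
knn_impute <- function(x, k = 10) {
  if (all(is.na(x))) .stopf("matrix is entirely missing")
  if (!anyNA(x)) return(x)
  global_mean <- mean(x, na.rm = TRUE)
  out <- x
  obs <- !is.na(x)
  for (f in which(rowSums(!obs) > 0)) {
    miss_s <- which(!obs[f, ])
    for (s in miss_s) {
      cand <- which(obs[, s] & seq_len(nrow(x)) != f)
      if (length(cand) == 0L || all(!obs[f, ])) {
        smean <- mean(x[, s], na.rm = TRUE)
        out[f, s] <- if (is.nan(smean)) global_mean else smean
        next
      }
      d <- vapply(cand, function(g) {
        shared <- obs[f, ] & obs[g, ]
        if (!any(shared)) return(Inf)
        sqrt(mean((x[f, shared] - x[g, shared])^2))
      }, numeric(1))
      usable <- cand[is.finite(d)]
      if (length(usable) == 0L) {
        smean <- mean(x[, s], na.rm = TRUE)
        out[f, s] <- if (is.nan(smean)) global_mean else smean
      } else {
        nn <- usable[order(d[is.finite(d)])][seq_len(min(k, length(usable)))]
        out[f, s] <- mean(x[nn, s])
      }
    }
  }
  out
}

# Equality-constrained least squares on a given support via the KKT
# system, solved with an SVD pseudoinverse so collinear references do not
# abort. Returns the weight vector or NULL if infeasible.
.ls_on_support <- function(R, y, support, tol = 1e-9) {
  Rs <- R[, support, drop = FALSE]
  p <- ncol(Rs)
  A <- rbind(cbind(2 * crossprod(Rs), rep(1, p)), c(rep(1, p), 0))
  b <- c(2 * crossprod(Rs, y), 1)
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-12
  w <- (sv$v[, pos, drop = FALSE] %*%
          ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos]))[seq_len(p)]
  if (any(w < -tol)) return(NULL)
  pmax(w, 0)
}

#' Simplex-constrained least-squares deconvolution
#'
#' Estimates cell-type proportions w solving
#' min_w ||R w - y||^2 subject to w >= 0, sum(w) = 1,
#' by exhaustive search over active sets (every support receives an
#' equality-constrained least-squares fit; the feasible solution with the
#' smallest residual is the global optimum). Features missing in \code{y}
#' (or in \code{R}) are dropped before solving. This deterministic
#' constrained fit coincides with support-vector-regression-style
#' deconvolution in the noise-free limit.
#'
#' @param sample_vector named numeric vector of observed feature levels
#'   (marker regions or mega sites); NA allowed.
#' @param reference_matrix features x cell types reference levels.
#' @param drop_missing drop features missing in the sample (default TRUE;
#'   if FALSE, missing features raise an error).
#' @return object of class \code{cfmeth_mixture}: list(proportions,
#'   residual_norm, n_features_used).
#' @export
deconvolve <- function(sample_vector, reference_matrix, drop_missing = TRUE) {
  y <- sample_vector
  R <- as.matrix(reference_matrix)
  if (ncol(R) > 14) .stopf("active-set enumeration supports at most 14 cell types")
  if (!is.null(names(y)) && !is.null(rownames(R))) {
    common <- intersect(names(y), rownames(R))
    y <- y[common]; R <- R[common, , drop = FALSE]
  }
  usable <- !is.na(y) & rowSums(is.na(R)) == 0
  if (!drop_missing && any(!usable)) .stopf("missing features in sample vector")
  y <- y[usable]; R <- R[usable, , drop = FALSE]
  if (length(y) < 2) .stopf("fewer than 2 usable features")
  if (qr(R)$rank < ncol(R))
    warning("reference matrix is rank-deficient; proportions may be non-unique")
  p <- ncol(R)
  best <- NULL; best_obj <- Inf
  for (mask in seq_len(2^p - 1L)) {
    support <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
    w <- .ls_on_support(R, y, support)
    if (is.null(w)) next
    full <- numeric(p); full[support] <- w
    obj <- sum((R %*% full - y)^2)
    if (obj < best_obj - 1e-12) { best_obj <- obj; best <- full }
  }
  w <- best / sum(best)
  names(w) <- colnames(R)
  structure(list(proportions = w, residual_norm = sqrt(best_obj),
                 n_features_used = length(y)),
            class = "cfmeth_mixture")
}

#' @export
print.cfmeth_mixture <- function(x, digits = 3, ...) {
  cat(sprintf("Mixture estimate over %d features (residual %.4g):\n",
              x$n_features_used, x$residual_norm))
  print(round(x$proportions, digits))
  invisible(x)
}

#' Compare a cell type's estimated proportions between groups
#'
#' Two-sided Wilcoxon rank-sum (exact when both groups have <= 25 samples
#' and no ties; normal approximation with tie correction otherwise) or
#' Welch t-test on the per-sample proportion of one cell type.
#'
#' @param estimates_by_group list of two groups; each group is either a
#'   numeric vector of proportions, a list of \code{cfmeth_mixture}
#'   objects, or a samples x cell-types matrix.
#' @param cell_type cell-type name (ignored for plain numeric vectors).
#' @param test "wilcoxon" (default) or "t".
#' @return two-sided p-value.
#' @export
group_compare <- function(estimates_by_group, cell_type = NULL,
                          test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  extract <- function(g) {
    if (is.numeric(g) && is.null(dim(g))) return(g)
    if (is.matrix(g) || is.data.frame(g)) return(as.numeric(g[, cell_type]))
    vapply(g, function(e) e$proportions[[cell_type]], numeric(1))
  }
  if (length(estimates_by_group) != 2L) .stopf("exactly two groups required")
  x <- extract(estimates_by_group[[1]])
  y <- extract(estimates_by_group[[2]])
  if (length(x) < 2 || length(y) < 2) .stopf("need >= 2 samples per group")
  if (length(unique(c(x, y))) == 1L) return(1)
  if (test == "wilcoxon") {
    exact <- length(x) <= 25 && length(y) <= 25
    suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                        correct = TRUE)$p.value)
  } else {
    stats::t.test(x, y)$p.value
  }
}
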