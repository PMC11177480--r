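# Marker levels, mega-site clustering, k-NN imputation and
# simplex-constrained deconvolution.

test_that("marker levels pool reads over the sites inside each region", {
  calls <- cpg_calls("chr1", c(10L, 20L, 500L), n_meth = c(2L, 1L, 9L),
                     n_unmeth = c(2L, 3L, 1L))
  markers <- region_set("chr1", c(0, 400, 1000), c(100, 600, 1100),
                        name = c("m1", "m2", "m3"))
  lv <- marker_region_levels(calls, markers)
  expect_equal(lv[["m1"]], 3 / 8)
  expect_equal(lv[["m2"]], 0.9)
  expect_true(is.na(lv[["m3"]]))
})

test_that("mega sites drop singletons and average member profiles", {
  # two tight clusters of 3 plus one outlier; k = 3 leaves the outlier alone
  ref <- rbind(matrix(0.05, 3, 2), matrix(0.95, 3, 2), c(0.5, 0.5))
  ref <- ref + matrix(seq(0, 0.012, length.out = 14), 7, 2)
  rownames(ref) <- sprintf("s%d", 1:7)
  colnames(ref) <- c("t1", "t2")
  ms <- build_mega_sites(ref, k = 3)
  expect_length(ms$groups, 2L)
  expect_setequal(unlist(ms$groups), sprintf("s%d", 1:6))
  expect_equal(unname(ms$sizes), c(3L, 3L))
  expect_equal(as.numeric(ms$reference[1, ]),
               as.numeric(colMeans(ref[ms$groups[[1]], ])))
  # k = n sites: all singletons, empty set with a warning
  expect_warning(empty <- build_mega_sites(ref, k = 7), "singleton")
  expect_length(empty$groups, 0L)
  expect_error(build_mega_sites(ref, k = 10), "exceeds")
})

test_that("sample aggregation commutes with pooling over member sites", {
  a <- toy_atlas(3, 30, margin = 0.7)
  calls <- simulate_sample_calls(a, c(0.5, 0.3, 0.2), coverage_mean = 10,
                                 seed = 31)
  ms <- build_mega_sites(a$meth_prob, k = 8)
  v <- aggregate_sample_to_mega_sites(calls, ms)
  key <- paste(calls$chrom, calls$pos0, sep = ":")
  for (g in seq_along(ms$groups)) {
    idx <- match(ms$groups[[g]], key)
    idx <- idx[!is.na(idx)]
    m <- sum(calls$n_meth[idx]); u <- sum(calls$n_unmeth[idx])
    expect_equal(v[[g]], if (m + u > 0) m / (m + u) else NA_real_)
  }
  # hand example: counts (1,1) and (3,1) pool to 4/6
  small <- cpg_calls("chr1", c(0L, 5L), n_meth = c(1L, 3L),
                     n_unmeth = c(1L, 1L))
  ms2 <- list(groups = list(g1 = c("chr1:0", "chr1:5")))
  class(ms2) <- "cfmeth_megasites"
  expect_equal(unname(aggregate_sample_to_mega_sites(small, ms2)), 4 / 6)
})

test_that("k-NN imputation fills gaps from nearest features and stays within donor range", {
  x <- matrix(runif(40), 8, 5)
  expect_identical(knn_impute(x), x)
  # k = 1: the missing entry copies the nearest feature's value
  y <- rbind(c(0.50, 0.52, NA, 0.49),
             c(0.51, 0.53, 0.48, 0.50),
             c(0.90, 0.10, 0.90, 0.10))
  imp <- knn_impute(y, k = 1)
  expect_equal(imp[1, 3], y[2, 3])
  # convexity: imputed values lie inside the donor range
  set.seed(12)
  z <- matrix(runif(200), 20, 10)
  z[sample(200, 40)] <- NA
  zi <- knn_impute(z, k = 5)
  expect_false(anyNA(zi))
  expect_true(all(zi >= min(z, na.rm = TRUE) & zi <= max(z, na.rm = TRUE)))
  expect_error(knn_impute(matrix(NA_real_, 2, 2)), "entirely missing")
})

test_that("deconvolution solves the simplex-constrained least-squares problem", {
  # identity reference returns the observation itself
  R <- diag(2); rownames(R) <- c("f1", "f2"); colnames(R) <- c("t1", "t2")
  est <- deconvolve(c(f1 = 0.3, f2 = 0.7), R)
  expect_equal(unname(est$proportions), c(0.3, 0.7), tolerance = 1e-9)
  # hand-checkable 2x2 mixture
  R2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE,
               dimnames = list(c("f1", "f2"), c("t1", "t2")))
  est2 <- deconvolve(c(f1 = 0.3, f2 = 0.65), R2)
  expect_equal(unname(est2$proportions),
               oracle_simplex_ls(R2, c(0.3, 0.65)), tolerance = 1e-3)
  expect_equal(unname(est2$proportions), c(0.25, 0.75), tolerance = 1e-3)
  expect_error(deconvolve(c(f1 = 0.5), R2), "fewer than 2")
  expect_warning(
    deconvolve(c(f1 = 0.4, f2 = 0.4, f3 = 0.4),
               matrix(0.4, 3, 2, dimnames = list(sprintf("f%d", 1:3),
                                                 c("t1", "t2")))),
    "rank-deficient")
})

test_that("active-set solutions match the simplex grid-search oracle on 3- and 4-type problems", {
  set.seed(19)
  for (p in c(3, 4)) {
    for (rep in 1:3) {
      R <- matrix(runif(10 * p), 10, p)
      w_true <- .cfmeth_rdirichlet_test(rep(1, p))
      y <- as.numeric(R %*% w_true) + rnorm(10, 0, 0.02)
      rownames(R) <- names(y) <- sprintf("f%d", 1:10)
      colnames(R) <- sprintf("t%d", seq_len(p))
      got <- deconvolve(y, R)$proportions
      want <- oracle_simplex_ls(R, y)
      expect_equal(unname(got), unname(want), tolerance = 1e-3)
      # on the simplex, and no vertex beats the solution
      expect_true(all(got >= -1e-9))
      expect_lt(abs(sum(got) - 1), 1e-6)
      obj <- function(w) sum((R %*% w - y)^2)
      for (v in seq_len(p))
        expect_lte(obj(got), obj(replace(rep(0, p), v, 1)) + 1e-9)
    }
  }
})

test_that("noisy mixtures are recovered and missing features are dropped before solving", {
  a <- toy_atlas(6, 80, margin = 0.6)
  ms <- build_mega_sites(a$meth_prob, k = 30)
  set.seed(23)
  errs <- replicate(30, {
    w <- .cfmeth_rdirichlet_test(rep(2, 6))
    y <- as.numeric(ms$reference %*% w) + rnorm(nrow(ms$reference), 0, 0.01)
    names(y) <- rownames(ms$reference)
    y[sample(length(y), 2)] <- NA   # sparse coverage
    mean(abs(deconvolve(y, ms$reference)$proportions - w))
  })
  expect_lt(mean(errs), 0.05)
})

test_that("group comparison reproduces the exact rank-sum enumeration and its symmetries", {
  expect_equal(group_compare(list(c(1, 2, 3), c(4, 5, 6))), 2 * (1 / 20))
  expect_equal(group_compare(list(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_equal(group_compare(list(c(1, 5, 2), c(4, 3, 6))),
               group_compare(list(c(4, 3, 6), c(1, 5, 2))))
  expect_equal(group_compare(list(rep(2, 3), rep(2, 4))), 1)
  # t-test route and mixture-object extraction
  g1 <- list(structure(list(proportions = c(t1 = 0.2)), class = "cfmeth_mixture"),
             structure(list(proportions = c(t1 = 0.3)), class = "cfmeth_mixture"))
  g2 <- list(structure(list(proportions = c(t1 = 0.7)), class = "cfmeth_mixture"),
             structure(list(proportions = c(t1 = 0.8)), class = "cfmeth_mixture"))
  expect_lt(group_compare(list(g1, g2), "t1", test = "t"), 0.05)
  expect_error(group_compare(list(1:3)), "two groups")
})
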