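# Ground-truth generators: atlas construction, mixed-sample call
# simulation, CNA-weighted bin counts, cohort assembly and the
# amplification/duplication model.

test_that("atlas marker sites satisfy the separation margin and builds are deterministic", {
  a <- build_reference_atlas(2, 10, marker_fraction = 1, margin = 0.8, seed = 5)
  expect_true(all(abs(a$meth_prob[, 1] - a$meth_prob[, 2]) >= 0.8))
  expect_true(all(a$meth_prob >= 0 & a$meth_prob <= 1))
  b <- build_reference_atlas(2, 10, marker_fraction = 1, margin = 0.8, seed = 5)
  expect_identical(a, b)
  # marker rows differ from all other types by >= margin for the flagged type
  big <- build_reference_atlas(5, 333, marker_fraction = 1, margin = 0.6, seed = 1)
  expect_equal(dim(big$meth_prob), c(333L, 5L))
  for (j in seq_len(10)) {
    ti <- match(big$marker_target[j], big$cell_types)
    expect_true(all(abs(big$meth_prob[j, ti] - big$meth_prob[j, -ti]) >= 0.6))
  }
  expect_error(build_reference_atlas(1, 10), "n_cell_types")
  expect_error(build_reference_atlas(2, 10, marker_fraction = 0), "marker_fraction")
})

test_that("pure mixtures reproduce the atlas column within binomial error", {
  a <- toy_atlas(2, 200, margin = 0.8)
  calls <- simulate_sample_calls(a, c(1, 0), coverage_mean = 50, seed = 2)
  prop <- calls$n_meth / (calls$n_meth + calls$n_unmeth)
  se <- sqrt(a$meth_prob[, 1] * (1 - a$meth_prob[, 1]) / 50)
  expect_true(mean(abs(prop - a$meth_prob[, 1]) <= 4 * se + 0.02) > 0.95)
  expect_error(simulate_sample_calls(a, c(0.7, 0.2)), "proportions")
  expect_error(simulate_sample_calls(a, c(1.2, -0.2)), "proportions")
})

test_that("conversion failure sets the apparent level of unmethylated sites", {
  a <- toy_atlas(2, 1000, margin = 0.8)
  a$meth_prob[] <- 0
  calls <- simulate_sample_calls(a, c(0.5, 0.5), coverage_mean = 50,
                                 conversion_failure = 0.01, seed = 3)
  total <- sum(calls$n_meth + calls$n_unmeth)
  pooled <- sum(calls$n_meth) / total
  se <- sqrt(0.01 * 0.99 / total)
  expect_lt(abs(pooled - 0.01), 3 * se)
  # mean observed coverage matches the Poisson mean
  calls2 <- simulate_sample_calls(a, c(0.5, 0.5), coverage_mean = 20, seed = 4)
  expect_true(abs(mean(calls2$n_meth + calls2$n_unmeth) - 20) <
                3 * sqrt(20 / 1000))
})

test_that("bin counts implement the tumor-fraction copy weighting exactly in expectation", {
  bins <- bin_genome(c(chr1 = 1e7), size = 1e5)
  flat <- simulate_bin_counts(bins, NULL, 0, total_reads = 1e6, seed = 1)
  expect_equal(sum(flat$counts), 1e6)
  # neutral genome: expected log2 ratio vs a flat panel is 0 everywhere
  panel <- build_panel(list(structure(list(bins = bins,
                                           counts = rep(1000L, nrow(bins)),
                                           total = 1000L * nrow(bins)),
                                      class = "cfmeth_bincounts")))
  expect_true(abs(mean(copy_ratio(flat, panel)$ratio)) < 0.005)
  # copy 4 at tumor fraction 0.5: expected weight 1.5 in the CNA region
  cna <- data.frame(chrom = "chr1", start0 = 0, end0 = 1e6, copy = 4)
  s <- simulate_bin_counts(bins, cna, 0.5, total_reads = 2e6, seed = 2)
  inside <- mean(s$counts[1:10]); outside <- mean(s$counts[11:100])
  expect_lt(abs(inside / outside - 1.5), 0.05)
  expect_error(simulate_bin_counts(bins[0, ], NULL, 0, 10), "empty bin")
  expect_error(simulate_bin_counts(bins, data.frame(chrom = "chr1", start0 = 0,
                                                    end0 = 1e5, copy = -1),
                                   0.2, 10), "copy numbers")
})

test_that("cohort simulation produces per-sample files, truth records and is byte-stable", {
  cfg <- simulation_config(n_cases = 5, n_controls = 5,
                           genome = c(chr1 = 1e6), cpg_density = 0.5,
                           coverage_mean = 10, total_reads = 2e4,
                           n_atlas_sites = 60, seed = 21)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  co <- simulate_cohort(cfg, out_dir = d1)
  expect_length(co$samples, 10L)
  expect_equal(sum(co$truth$group == "case"), 5L)
  expect_equal(length(list.files(d1, "\\.cov\\.tsv$")), 10L)
  expect_equal(length(list.files(d1, "\\.bins\\.tsv$")), 10L)
  expect_true(file.exists(file.path(d1, "truth.json")))
  # proportions on the simplex
  expect_true(all(abs(rowSums(co$truth$proportions) - 1) < 1e-9))
  expect_true(all(co$truth$proportions >= 0))
  # byte-identical rerun
  simulate_cohort(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("planted DMR deltas shift case methylation by delta times the tumor weight", {
  dmr <- data.frame(chrom = "chr1", start0 = 2e5, end0 = 2.3e5, delta = 0.3)
  cfg <- simulation_config(n_cases = 12, n_controls = 12,
                           genome = c(chr1 = 1e6), cpg_density = 2,
                           coverage_mean = 60, total_reads = 1e4,
                           conversion_failure = 0, overconversion = 0,
                           tumor_fraction_range = c(0.4, 0.4),
                           dmrs = dmr, n_atlas_sites = 40, seed = 9)
  co <- simulate_cohort(cfg)
  region <- region_set("chr1", 2e5, 2.3e5)
  lvl <- vapply(co$samples, function(s)
    summarize_regions(s$calls, region)$level, numeric(1))
  grp <- co$truth$group
  observed <- mean(lvl[grp == "case"]) - mean(lvl[grp == "control"])
  # tumor weight = tumor fraction plus the Dirichlet share of the tumor type;
  # the planted shift only moves the tumor component, clipped inside [0,1]
  tumor_w <- co$truth$proportions[grp == "case", cfg$tumor_cell_type]
  # clipping attenuates +0.3 on baselines above 0.7, so compare against the
  # realized mean shift of the planted probability track, bounded loosely
  expect_gt(observed, 0.3 * mean(tumor_w) * 0.6)
  expect_lt(observed, 0.3 * mean(tumor_w) * 1.2)
})

test_that("amplification duplicates follow molecule copy-number tails", {
  # single molecule: every read after the first is a duplicate
  ids <- simulate_amplification(1, 10, "linear", seed = 1)
  expect_equal(duplication_rate(ids), 0.9)
  # many molecules, few reads: collisions are essentially absent
  ids2 <- simulate_amplification(1e6, 100, "exponential", jitter = 1, seed = 2)
  expect_lt(duplication_rate(ids2), 0.02)
  expect_error(simulate_amplification(10, 5, "linear", mean_copies = 0.5),
               "mean_copies")
  # heavier-tailed exponential amplification duplicates more (paired means)
  dup <- vapply(1:60, function(r) {
    c(lin = duplication_rate(simulate_amplification(2000, 2000, "linear",
                                                    mean_copies = 5,
                                                    seed = 100 + r)),
      exp = duplication_rate(simulate_amplification(2000, 2000, "exponential",
                                                    mean_copies = 5, jitter = 1,
                                                    seed = 100 + r)))
  }, numeric(2))
  expect_gt(mean(dup["exp", ] - dup["lin", ]), 0)
})
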