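# Coverage-dialect parsing, coordinate conventions, window tiling and
# region-level pooling.

test_that("coverage files parse with 1-based to 0-based conversion and a coverage filter", {
  path <- withr::local_tempfile()
  writeLines(c("chr1\t101\t101\t50.0\t5\t5",
               "chr1\t201\t201\t50.0\t1\t1",
               "chr2\t11\t11\t100.0\t4\t0"), path)
  calls <- read_cpg_calls(path, min_coverage = 3)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$pos0, c(100L, 10L)[order(c("chr1", "chr2"))])
  expect_equal(calls[calls$chrom == "chr1", c("n_meth", "n_unmeth")],
               data.frame(n_meth = 5L, n_unmeth = 5L),
               ignore_attr = TRUE)
  # the (1,1) site is dropped below min_coverage = 3, kept at 0
  expect_equal(nrow(read_cpg_calls(path, min_coverage = 0)), 3L)
})

test_that("parse errors name the offending line and negative counts are rejected", {
  path <- withr::local_tempfile()
  writeLines(c("chr1\t101\t101\t50.0\t5\t5", "chr1\t201\t201"), path)
  expect_error(read_cpg_calls(path), "line 2")
  writeLines("chr1\t101\t101\t50.0\t-5\t5", path)
  expect_error(read_cpg_calls(path), "negative")
  writeLines(character(0), path)
  expect_equal(nrow(read_cpg_calls(path)), 0L)
})

test_that("write/read round-trips random tables and the coordinate bijection", {
  set.seed(7)
  n <- 1000
  calls <- cpg_calls(chrom = sample(c("chr1", "chr2"), n, TRUE),
                     pos0 = sample.int(1e6, n),
                     strand = sample(c("+", "-"), n, TRUE),
                     context = sample(c("CpG", "CHG", "CHH"), n, TRUE),
                     n_meth = rpois(n, 3), n_unmeth = rpois(n, 3))
  path <- withr::local_tempfile()
  write_cpg_calls(calls, path)
  back <- read_cpg_calls(path, min_coverage = 0)
  expect_equal(back, calls)
  # pos0 = 0 lands at file position 1
  write_cpg_calls(cpg_calls("chr1", 0L, n_meth = 1L, n_unmeth = 0L), path)
  expect_match(readLines(path)[1], "^chr1\t1\t1\t")
  # empty table round-trips
  write_cpg_calls(read_cpg_calls(path, min_coverage = 99), path)
  expect_equal(nrow(read_cpg_calls(path, 0)), 0L)
})

test_that("window tiling covers the genome with the final partial window retained", {
  w <- make_windows(c(chr1 = 10000), size = 3000)
  expect_equal(nrow(w), 4L)
  expect_equal(w$start0[4], 9000)
  expect_equal(w$end0[4], 10000)
  # overlapping sliding windows: k*1500 < 10000 -> 7 windows
  w2 <- make_windows(c(chr1 = 10000), size = 3000, step = 1500)
  expect_equal(nrow(w2), 7L)
  expect_true(any(w2$end0[-nrow(w2)] > w2$start0[-1]))
  # window larger than the chromosome
  w3 <- make_windows(c(chr1 = 2000), size = 3000)
  expect_equal(nrow(w3), 1L)
  expect_equal(c(w3$start0, w3$end0), c(0, 2000))
})

test_that("region pooling equals the coverage-weighted mean and matches a brute-force scan", {
  calls <- cpg_calls("chr1", c(10L, 20L, 40L), n_meth = c(5L, 0L, 3L),
                     n_unmeth = c(5L, 10L, 1L))
  r <- summarize_regions(calls, region_set("chr1", 0, 30))
  expect_equal(r$level, 5 / 20)
  expect_equal(r$n_sites, 2L)
  # single site: level equals the site proportion
  r1 <- summarize_regions(calls, region_set("chr1", 35, 45))
  expect_equal(r1$level, 0.75)
  # no sites: missing
  expect_true(is.na(summarize_regions(calls, region_set("chr1", 100, 200))$level))

  set.seed(11)
  n <- 400
  rc <- cpg_calls(chrom = sample(c("chr1", "chr2"), n, TRUE),
                  pos0 = sample.int(5e4, n),
                  n_meth = rpois(n, 2), n_unmeth = rpois(n, 2))
  starts <- sample.int(45e3, 60)
  regions <- region_set(chrom = sample(c("chr1", "chr2", "chr3"), 60, TRUE),
                        start0 = starts,
                        end0 = starts + sample(500:5000, 60, TRUE))
  got <- summarize_regions(rc, regions)
  want <- oracle_summarize(rc, regions)
  expect_equal(got$pooled_meth, unname(want[, "pooled_meth"]))
  expect_equal(got$pooled_unmeth, unname(want[, "pooled_unmeth"]))
  expect_equal(got$n_sites, unname(as.integer(want[, "n_sites"])))
  expect_equal(got$level, unname(want[, "level"]))
  # pooling is invariant to site order
  perm <- rc[sample.int(n), , drop = FALSE]
  expect_equal(summarize_regions(perm, regions)$level, got$level)
})

test_that("TSS regions flank 1 kb on both sides, clip at zero and preserve counts", {
  tss <- data.frame(chrom = "chr1", tss_pos0 = c(5000L, 500L),
                    strand = c("+", "-"), gene = c("g1", "g2"))
  r <- tss_regions(tss)
  expect_equal(c(r$start0[1], r$end0[1]), c(4000, 6000))
  expect_equal(c(r$start0[2], r$end0[2]), c(0, 1500))
  big <- data.frame(chrom = "chr1", tss_pos0 = seq(2000, by = 10, length.out = 500),
                    strand = "+", gene = sprintf("g%d", 1:500))
  expect_equal(nrow(tss_regions(big)), 500L)
  expect_error(tss_regions(tss, genome = c(chr9 = 1e6)), "unknown chromosome")
})

test_that("global context levels pool reads per context", {
  calls <- cpg_calls("chr1", c(1L, 2L, 3L, 4L),
                     context = c("CpG", "CpG", "CHH", "CHH"),
                     n_meth = c(3L, 7L, 0L, 0L), n_unmeth = c(7L, 3L, 5L, 5L))
  lv <- global_context_levels(calls)
  expect_equal(lv[["CpG"]], 0.5)
  expect_equal(lv[["CHH"]], 0)
  expect_false("CHG" %in% names(lv))
})

test_that("strand merging pools symmetric CpG calls onto the plus strand", {
  calls <- cpg_calls("chr1", c(10L, 11L), strand = c("+", "-"),
                     n_meth = c(3L, 2L), n_unmeth = c(1L, 4L))
  m <- merge_cpg_strands(calls)
  expect_equal(nrow(m), 1L)
  expect_equal(m$pos0, 10L)
  expect_equal(m$n_meth, 5L)
  expect_equal(m$n_unmeth, 5L)
})
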