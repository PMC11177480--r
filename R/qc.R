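# Library-complexity and coverage quality metrics: duplication rate,
# saturation curves, CpG coverage summaries, GC-bias profile, coverage
# uniformity (Lorenz/Gini) and inter-sample correlation.

# Accepts either a vector of molecule identifiers or a data.frame of read
# coordinates; a duplicate is a read repeating an earlier key.
.read_keys <- function(reads) {
  if (is.data.frame(reads)) {
    strand <- if ("strand" %in% names(reads)) reads$strand else "."
    paste(reads$chrom, reads$start0, reads$end0, strand, sep = ":")
  } else {
    as.character(reads)
  }
}

#' Library duplication rate
#'
#' Fraction of reads that repeat an already-seen key:
#' (n_reads - n_distinct) / n_reads. Keys are either molecule identifiers
#' (from \code{\link{simulate_amplification}}, the ground truth) or
#' (chrom, start, end, strand) coordinates, the standard deduplication
#' proxy.
#'
#' @param reads vector of molecule ids, or data.frame (chrom, start0,
#'   end0, strand).
#' @return duplication rate in [0, 1).
#' @export
duplication_rate <- function(reads) {
  keys <- .read_keys(reads)
  if (length(keys) == 0L) .stopf("no reads")
  (length(keys) - length(unique(keys))) / length(keys)
}

#' Saturation curve by read downsampling
#'
#' At each requested depth, reads are subsampled without replacement
#' (fixed seed) and the number of distinct keys (molecules, or covered
#' CpGs) is counted. The curve is nondecreasing in depth; early flattening
#' indicates an exhausted (low-complexity) library.
#'
#' @param reads molecule ids or read coordinate data.frame.
#' @param depths increasing vector of subsample sizes, each <= n_reads.
#' @param seed integer RNG seed.
#' @return data.frame (depth, distinct) of class \code{cfmeth_saturation}.
#' @export
saturation_curve <- function(reads, depths, seed = 1) {
  keys <- .read_keys(reads)
  if (any(depths > length(keys)))
    .stopf("depth exceeds the number of reads (%d)", length(keys))
  set.seed(seed)
  distinct <- vapply(depths, function(d)
    length(unique(sample(keys, d, replace = FALSE))), numeric(1))
  out <- data.frame(depth = depths, distinct = distinct)
  class(out) <- c("cfmeth_saturation", "data.frame")
  out
}

#' Fraction of a CpG universe covered at depth thresholds
#'
#' @param calls a call table.
#' @param site_universe data.frame (chrom, pos0) of all assayable CpGs.
#' @param thresholds coverage thresholds (default >= 1x and >= 3x).
#' @return named numeric vector of covered fractions.
#' @export
coverage_summary <- function(calls, site_universe, thresholds = c(1, 3)) {
  if (nrow(site_universe) == 0L) .stopf("empty site universe")
  uni <- .site_key(site_universe$chrom, site_universe$pos0)
  cov <- stats::setNames(calls$n_meth + calls$n_unmeth,
                         .site_key(calls$chrom, calls$pos0))
  depth <- cov[uni]
  depth[is.na(depth)] <- 0
  out <- vapply(thresholds, function(t) mean(depth >= t), numeric(1))
  stats::setNames(out, sprintf(">=%dx", thresholds))
}

#' Normalized coverage per GC stratum
#'
#' Bins are stratified into 5\%-GC buckets; each bucket's mean count is
#' divided by the global mean count, so a bias-free library sits near 1
#' across strata and amplification bias depresses the GC extremes.
#'
#' @param bin_counts a \code{cfmeth_bincounts}.
#' @param bin_gc GC fraction per bin, in [0, 1].
#' @return data.frame (gc_low, gc_high, n_bins, normalized_coverage); NA
#'   rows mark empty strata.
#' @export
gc_bias_profile <- function(bin_counts, bin_gc) {
  .check_prob(bin_gc, "bin_gc")
  counts <- bin_counts$counts
  breaks <- seq(0, 1, by = 0.05)
  stratum <- cut(bin_gc, breaks, include.lowest = TRUE, right = FALSE)
  gm <- mean(counts)
  means <- tapply(counts, stratum, mean)
  data.frame(gc_low = breaks[-length(breaks)], gc_high = breaks[-1],
             n_bins = as.integer(table(stratum)),
             normalized_coverage = as.numeric(means) / gm)
}

#' Lorenz curve and Gini coefficient of coverage uniformity
#'
#' Cumulative fraction of reads against the cumulative fraction of bins,
#' bins sorted by increasing count. Perfectly uniform coverage follows the
#' diagonal (Gini = 0); dispersion bends the curve and raises Gini.
#'
#' @param counts per-bin (or per-site) read counts.
#' @return list(curve = data.frame(frac_bins, frac_reads), gini).
#' @export
lorenz_curve <- function(counts) {
  if (length(counts) == 0L || sum(counts) == 0) .stopf("no coverage")
  s <- sort(as.numeric(counts))
  fb <- seq_along(s) / length(s)
  fr <- cumsum(s) / sum(s)
  gini <- 1 - 2 * sum((fr + c(0, fr[-length(fr)])) / 2) / length(s)
  list(curve = data.frame(frac_bins = fb, frac_reads = fr), gini = gini)
}

#' Pearson correlation of methylation levels between two samples
#'
#' Computed over the per-site methylation proportions at sites covered at
#' least \code{min_coverage} in both samples; the standard replicate
#' concordance metric.
#'
#' @param calls_a,calls_b call tables.
#' @param min_coverage joint coverage threshold (default 3).
#' @return Pearson r.
#' @export
sample_correlation <- function(calls_a, calls_b, min_coverage = 3) {
  prep <- function(x) {
    tot <- x$n_meth + x$n_unmeth
    keep <- tot >= min_coverage
    stats::setNames((x$n_meth / tot)[keep],
                    .site_key(x$chrom, x$pos0)[keep])
  }
  a <- prep(calls_a); b <- prep(calls_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 2L) .stopf("fewer than 2 shared covered sites")
  stats::cor(a[shared], b[shared])
}
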