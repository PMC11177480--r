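# Copy-number analysis from binned fragment counts: a pooled panel of
# normals as reference, per-sample log2 copy ratios, and recursive binary
# segmentation with gain/loss calling.

#' Tile a genome into copy-number bins
#'
#' Non-overlapping bins (default 100 kb, the conventional resolution for
#' low-pass cfDNA copy-number work); the final partial bin is retained.
#'
#' @param genome named chromosome-length vector.
#' @param size bin size in bp.
#' @return a region set.
#' @export
bin_genome <- function(genome, size = 1e5) {
  make_windows(genome, size = size, step = size)
}

#' Count fragments per genome bin
#'
#' Each fragment is assigned to the bin containing its midpoint (half-open
#' convention: a midpoint exactly on a boundary belongs to the bin starting
#' there), so fragments spanning bin boundaries are counted once.
#' Fragments on chromosomes absent from the bin set are tallied as
#' unassigned with a warning.
#'
#' @param fragments data.frame (chrom, start0, end0), 0-based half-open, or
#'   a BED3 file path.
#' @param bins a region set of non-overlapping bins (from
#'   \code{\link{bin_genome}}).
#' @return a \code{cfmeth_bincounts} object; \code{$unassigned} holds the
#'   off-genome tally.
#' @export
count_fragments_in_bins <- function(fragments, bins) {
  if (is.character(fragments)) {
    fragments <- utils::read.table(fragments, sep = "\t",
                                   col.names = c("chrom", "start0", "end0"),
                                   colClasses = c("character", "numeric", "numeric"))
  }
  mid <- floor((fragments$start0 + fragments$end0) / 2)
  counts <- integer(nrow(bins))
  unassigned <- 0L
  for (chr in unique(fragments$chrom)) {
    fi <- fragments$chrom == chr
    bi <- which(bins$chrom == chr)
    if (length(bi) == 0L) { unassigned <- unassigned + sum(fi); next }
    idx <- findInterval(mid[fi], bins$start0[bi])
    inside <- idx >= 1L & mid[fi] < bins$end0[bi][pmax(idx, 1L)]
    unassigned <- unassigned + sum(!inside)
    tab <- tabulate(idx[inside], nbins = length(bi))
    counts[bi] <- counts[bi] + tab
  }
  if (unassigned > 0L)
    warning(sprintf("%d fragment(s) outside the bin set left unassigned",
                    unassigned))
  structure(list(bins = bins, counts = counts, total = sum(counts),
                 unassigned = unassigned),
            class = "cfmeth_bincounts")
}

#' Build a panel of normals from control bin counts
#'
#' Counts of all normal samples are pooled into one synthetic control: the
#' reference proportion of bin b is the pooled count over the pooled total.
#' Per-bin dispersion is the standard deviation, across the individual
#' normals, of their log2 ratios against the pooled reference (0 for a
#' single normal). Bins with pooled count zero are masked.
#'
#' @param normal_bincounts list of \code{cfmeth_bincounts} over identical
#'   bins.
#' @return object of class \code{cfmeth_panel}: list(bins, proportion,
#'   dispersion, mask, n_normals).
#' @export
build_panel <- function(normal_bincounts) {
  if (length(normal_bincounts) < 1L) .stopf("need at least one normal sample")
  b0 <- normal_bincounts[[1]]$bins
  for (x in normal_bincounts)
    if (!identical(x$bins[, c("chrom", "start0", "end0")],
                   b0[, c("chrom", "start0", "end0")]))
      .stopf("bin sets differ between normal samples")
  pooled <- Reduce(`+`, lapply(normal_bincounts, function(x) as.numeric(x$counts)))
  prop <- pooled / sum(pooled)
  mask <- pooled == 0
  ratios <- vapply(normal_bincounts, function(x) {
    c_eff <- ifelse(x$counts > 0, x$counts, 0.5)
    ifelse(mask, NA_real_, log2((c_eff / sum(x$counts)) / prop))
  }, numeric(nrow(b0)))
  ratios <- matrix(ratios, nrow = nrow(b0))
  disp <- apply(ratios, 1, function(r)
    if (sum(!is.na(r)) >= 2) stats::sd(r, na.rm = TRUE) else 0)
  structure(list(bins = b0, proportion = ifelse(mask, NA_real_, prop),
                 dispersion = disp, mask = mask,
                 n_normals = length(normal_bincounts)),
            class = "cfmeth_panel")
}

#' @export
print.cfmeth_panel <- function(x, ...) {
  cat(sprintf("Panel of normals: %d samples pooled, %d/%d usable bins\n",
              x$n_normals, sum(!x$mask), length(x$mask)))
  invisible(x)
}

#' Per-bin log2 copy ratio of a sample against a panel of normals
#'
#' ratio_b = log2((count_b / total) / panel proportion_b) on unmasked bins,
#' with a pseudocount of 0.5 reads for zero sample bins so the track stays
#' dense; z_b = ratio_b / panel dispersion_b where dispersion is positive.
#' Ratios are invariant to rescaling the sample's counts.
#'
#' @param sample_bincounts a \code{cfmeth_bincounts}.
#' @param panel a \code{cfmeth_panel} over the same bins.
#' @return object of class \code{cfmeth_cnratio}: data.frame (chrom,
#'   start0, end0, count, ratio, z).
#' @export
copy_ratio <- function(sample_bincounts, panel) {
  if (!identical(sample_bincounts$bins[, c("chrom", "start0", "end0")],
                 panel$bins[, c("chrom", "start0", "end0")]))
    .stopf("sample bins do not match panel bins")
  total <- sum(sample_bincounts$counts)
  if (total == 0) .stopf("sample has zero total count")
  c_eff <- ifelse(sample_bincounts$counts > 0, sample_bincounts$counts, 0.5)
  ratio <- ifelse(panel$mask, NA_real_,
                  log2((c_eff / total) / panel$proportion))
  z <- ifelse(!is.na(ratio) & panel$dispersion > 0,
              ratio / panel$dispersion, NA_real_)
  out <- data.frame(chrom = panel$bins$chrom, start0 = panel$bins$start0,
                    end0 = panel$bins$end0,
                    count = sample_bincounts$counts, ratio = ratio, z = z,
                    stringsAsFactors = FALSE)
  class(out) <- c("cfmeth_cnratio", "data.frame")
  out
}

# best binary split of v maximizing the pooled two-sample |t|; returns
# c(position, t) or NULL when no admissible split exists
.best_split <- function(v, min_bins) {
  n <- length(v)
  if (n < 2L * min_bins) return(NULL)
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  k <- min_bins:(n - min_bins)
  n1 <- k; n2 <- n - k
  s1 <- cs[k]; s2 <- cs[n] - s1
  ss1 <- cs2[k]; ss2 <- cs2[n] - ss1
  var1 <- pmax(0, (ss1 - s1^2 / n1))
  var2 <- pmax(0, (ss2 - s2^2 / n2))
  sp <- sqrt(pmax((var1 + var2) / pmax(n - 2, 1), 1e-12))
  tstat <- abs(s1 / n1 - s2 / n2) / (sp * sqrt(1 / n1 + 1 / n2))
  i <- which.max(tstat)
  c(k[i], tstat[i])
}

.segment_vector <- function(v, min_bins, t_crit) {
  recurse <- function(lo, hi) {
    sp <- .best_split(v[lo:hi], min_bins)
    if (is.null(sp) || sp[2] < t_crit) return(matrix(c(lo, hi), 1))
    cut <- lo + sp[1] - 1L
    rbind(recurse(lo, cut), recurse(cut + 1L, hi))
  }
  recurse(1L, length(v))
}

#' Segment a copy-ratio track and call gains and losses
#'
#' Recursive binary segmentation: within each chromosome the split
#' maximizing the two-sample t-statistic of mean log2 ratio is accepted
#' while |t| >= \code{t_crit} and both children have at least
#' \code{min_bins} bins. Each final segment is called a gain if its mean
#' ratio exceeds \code{threshold}, a loss below \code{-threshold}, else
#' neutral. Masked (missing) bins are ignored.
#'
#' @param track a \code{cfmeth_cnratio}.
#' @param min_bins minimum bins per segment (default 10).
#' @param threshold |mean log2 ratio| needed to call gain/loss
#'   (default 0.15).
#' @param t_crit stopping t-statistic for accepting a split (default 5).
#' @return data.frame of class \code{cfmeth_segments}: chrom, start0,
#'   end0, n_bins, mean_ratio, state.
#' @export
segment_and_call <- function(track, min_bins = 10, threshold = 0.15,
                             t_crit = 5) {
  ok <- !is.na(track$ratio)
  if (!any(ok)) .stopf("all bins missing; cannot segment")
  segs <- list()
  for (chr in unique(track$chrom)) {
    sel <- which(track$chrom == chr & ok)
    if (length(sel) == 0L) next
    v <- track$ratio[sel]
    bounds <- if (length(sel) < min_bins) matrix(c(1L, length(sel)), 1)
              else .segment_vector(v, min_bins, t_crit)
    for (r in seq_len(nrow(bounds))) {
      i <- sel[bounds[r, 1]:bounds[r, 2]]
      m <- mean(track$ratio[i])
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chr, start0 = track$start0[min(i)], end0 = track$end0[max(i)],
        n_bins = length(i), mean_ratio = m,
        state = if (m > threshold) "gain" else if (m < -threshold) "loss"
                else "neutral",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  class(out) <- c("cfmeth_segments", "data.frame")
  out
}

#' @export
print.cfmeth_segments <- function(x, ...) {
  cat(sprintf("Copy-number segments: %d (%d gain, %d loss, %d neutral)\n",
              nrow(x), sum(x$state == "gain"), sum(x$state == "loss"),
              sum(x$state == "neutral")))
  invisible(x)
}

#' Plot a copy-ratio track with segment means
#'
#' @param x a \code{cfmeth_cnratio}.
#' @param segments optional \code{cfmeth_segments} overlay.
#' @param ... passed to \code{plot}.
#' @export
plot.cfmeth_cnratio <- function(x, segments = NULL, ...) {
  idx <- seq_len(nrow(x))
  graphics::plot(idx, x$ratio, pch = 16, cex = 0.3, col = "grey40",
                 xlab = "bin index", ylab = "log2 copy ratio", ...)
  graphics::abline(h = 0, col = "grey70")
  if (!is.null(segments)) {
    off <- 0L
    for (chr in unique(x$chrom)) {
      nb <- sum(x$chrom == chr)
      s <- segments[segments$chrom == chr, , drop = FALSE]
      for (r in seq_len(nrow(s))) {
        i0 <- off + which(x$chrom == chr & x$start0 >= s$start0[r] &
                            x$end0 <= s$end0[r]) - off
        graphics::segments(off + min(i0), s$mean_ratio[r],
                           off + max(i0), s$mean_ratio[r],
                           col = "red", lwd = 2)
      }
      off <- off + nb
    }
  }
  invisible(x)
}
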