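# Two-group differential methylation on pooled region counts: Fisher's
# exact test per region, Benjamini-Hochberg FDR control, and effect-size
# cutoffs for DMR and promoter-DMR calling.

#' Two-proportion test for one region
#'
#' Tests whether the pooled methylation proportion differs between two
#' groups, via the two-sided Fisher's exact test on the 2x2 table
#' [[meth1, unmeth1], [meth2, unmeth2]] (default), or the chi-square test
#' with continuity correction for large counts.
#'
#' @param meth1,unmeth1 pooled methylated/unmethylated counts, group 1.
#' @param meth2,unmeth2 pooled counts, group 2.
#' @param method "fisher" (default) or "chisq".
#' @return two-sided p-value; NA when either group has zero total reads.
#' @export
region_test <- function(meth1, unmeth1, meth2, unmeth2,
                        method = c("fisher", "chisq")) {
  method <- match.arg(method)
  if (any(c(meth1, unmeth1, meth2, unmeth2) < 0)) .stopf("counts must be >= 0")
  if (meth1 + unmeth1 == 0 || meth2 + unmeth2 == 0) return(NA_real_)
  tab <- matrix(c(meth1, unmeth1, meth2, unmeth2), 2, byrow = TRUE)
  if (method == "fisher") stats::fisher.test(tab)$p.value
  else suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; missing p-values
#' propagate as missing and do not enter the adjustment.
#'
#' @param p_values numeric vector in [0, 1], NA allowed.
#' @return q-values of the same length.
#' @export
adjust_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially methylated regions between two groups
#'
#' Read counts are pooled within each group per region, each region is
#' tested with \code{\link{region_test}}, p-values are BH-adjusted, and
#' regions passing both the FDR and the methylation-difference cutoff are
#' reported with their direction in group 1. The genome-wide window preset
#' uses a strict difference cutoff (> 0.15); the promoter preset uses
#' difference >= 0.12 (\code{strict_diff = FALSE}, \code{diff_cutoff =
#' 0.12}).
#'
#' @param region_meth_list list of \code{\link{summarize_regions}} outputs,
#'   one per sample, over an identical region set.
#' @param group_labels two-level vector, one label per sample; the first
#'   level encountered is "group 1".
#' @param diff_cutoff minimum |level1 - level2| (default 0.15).
#' @param fdr_cutoff FDR threshold (default 0.01).
#' @param strict_diff if TRUE (default) require difference strictly above
#'   the cutoff; if FALSE, at or above.
#' @param method test passed to \code{\link{region_test}}.
#' @return data.frame of class \code{cfmeth_dmr}: all tested regions with
#'   level_group1, level_group2, difference, p_value, q_value, direction,
#'   and logical \code{called}. The DMRs are the rows with
#'   \code{called == TRUE}.
#' @export
call_dmrs <- function(region_meth_list, group_labels, diff_cutoff = 0.15,
                      fdr_cutoff = 0.01, strict_diff = TRUE,
                      method = "fisher") {
  labs <- unique(group_labels)
  if (length(labs) != 2L)
    .stopf("exactly two groups required, got: %s", paste(labs, collapse = ", "))
  if (length(region_meth_list) != length(group_labels))
    .stopf("one sample summary per label required")
  g1 <- which(group_labels == labs[1]); g2 <- which(group_labels == labs[2])
  pool <- function(idx, col) Reduce(`+`, lapply(region_meth_list[idx],
                                                function(x) x[[col]]))
  m1 <- pool(g1, "pooled_meth"); u1 <- pool(g1, "pooled_unmeth")
  m2 <- pool(g2, "pooled_meth"); u2 <- pool(g2, "pooled_unmeth")
  l1 <- ifelse(m1 + u1 > 0, m1 / (m1 + u1), NA_real_)
  l2 <- ifelse(m2 + u2 > 0, m2 / (m2 + u2), NA_real_)
  p <- mapply(region_test, m1, u1, m2, u2,
              MoreArgs = list(method = method))
  q <- adjust_fdr(p)
  diff <- l1 - l2
  pass_diff <- if (strict_diff) abs(diff) > diff_cutoff else abs(diff) >= diff_cutoff
  called <- !is.na(q) & q < fdr_cutoff & !is.na(diff) & pass_diff
  out <- region_meth_list[[1]][, c("chrom", "start0", "end0", "name")]
  out$level_group1 <- l1; out$level_group2 <- l2
  out$difference <- diff
  out$p_value <- p; out$q_value <- q
  out$direction <- ifelse(is.na(diff), NA_character_,
                          ifelse(diff > 0, "hyper", "hypo"))
  out$called <- called
  attr(out, "groups") <- labs
  class(out) <- c("cfmeth_dmr", "data.frame")
  out
}

#' @export
print.cfmeth_dmr <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("DMR test: %d regions, %d called (%s vs %s)\n",
              nrow(x), sum(x$called, na.rm = TRUE), g[1], g[2]))
  cat(sprintf("  hyper in %s: %d, hypo: %d\n", g[1],
              sum(x$called & x$direction == "hyper", na.rm = TRUE),
              sum(x$called & x$direction == "hypo", na.rm = TRUE)))
  invisible(x)
}

#' Write called DMRs as BED-style TSV
#'
#' Columns: chrom, start, end, name, difference, strand, p, q, direction.
#' @param dmrs a \code{cfmeth_dmr} object.
#' @param path output path.
#' @param called_only write only regions passing the cutoffs (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_dmrs <- function(dmrs, path, called_only = TRUE) {
  x <- if (called_only) dmrs[dmrs$called, , drop = FALSE] else dmrs
  utils::write.table(
    data.frame(x$chrom, x$start0, x$end0, x$name, x$difference,
               rep(".", nrow(x)), x$p_value, x$q_value, x$direction),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
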