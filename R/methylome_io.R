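# Reading, writing and region-level summarization of per-CpG methylation
# calls. Internal coordinates are 0-based half-open; the on-disk coverage
# dialect is 1-based inclusive (the de facto bisulfite coverage format).

.CALL_COLS <- c("chrom", "pos0", "strand", "context", "n_meth", "n_unmeth")

#' Construct a per-CpG call table
#'
#' The atom of all methylation computation: one row per cytosine with
#' methylated / unmethylated read counts, strand and sequence context.
#'
#' @param chrom chromosome labels.
#' @param pos0 0-based positions.
#' @param strand "+", "-" or "." (unknown).
#' @param context sequence context: "CpG", "CHG" or "CHH".
#' @param n_meth,n_unmeth non-negative integer read counts.
#' @return a \code{data.frame} with columns chrom, pos0, strand, context,
#'   n_meth, n_unmeth, sorted by (chrom, pos0).
#' @export
cpg_calls <- function(chrom, pos0, strand = ".", context = "CpG",
                      n_meth, n_unmeth) {
  .check_count(n_meth, "n_meth"); .check_count(n_unmeth, "n_unmeth")
  .check_count(pos0, "pos0")
  df <- data.frame(chrom = as.character(chrom), pos0 = as.integer(pos0),
                   strand = as.character(strand),
                   context = as.character(context),
                   n_meth = as.integer(n_meth),
                   n_unmeth = as.integer(n_unmeth),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos0), , drop = FALSE]
  if (anyDuplicated(paste(df$chrom, df$pos0, df$strand)))
    .stopf("duplicate (chrom, pos0, strand) records")
  rownames(df) <- NULL
  df
}

.empty_calls <- function() {
  data.frame(chrom = character(), pos0 = integer(), strand = character(),
             context = character(), n_meth = integer(), n_unmeth = integer(),
             stringsAsFactors = FALSE)
}

#' Read a per-CpG coverage call file
#'
#' Parses the tab-separated coverage dialect: chrom, start, end (1-based
#' inclusive), methylation percent, methylated count, unmethylated count,
#' with optional 7th (strand) and 8th (context) columns. Sites below the
#' coverage threshold are dropped, mirroring the >= 3x per-CpG filter used
#' for methylation-level work (deconvolution uses \code{min_coverage = 1}).
#'
#' @param path file path.
#' @param min_coverage minimum total reads (methylated + unmethylated) a
#'   site must have to be retained; default 3.
#' @return a call table (see \code{\link{cpg_calls}}); positions converted
#'   to 0-based.
#' @export
read_cpg_calls <- function(path, min_coverage = 3) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_calls())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 6L)
  if (length(bad))
    .stopf("malformed line %d in %s: expected >= 6 tab-separated fields",
           bad[1L], path)
  m <- matrix(unlist(lapply(parts, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  pos1 <- suppressWarnings(as.integer(m[, 2L]))
  n_meth <- suppressWarnings(as.integer(m[, 5L]))
  n_unmeth <- suppressWarnings(as.integer(m[, 6L]))
  bad <- which(is.na(pos1) | is.na(n_meth) | is.na(n_unmeth))
  if (length(bad)) .stopf("malformed line %d in %s: non-numeric field",
                          bad[1L], path)
  if (any(n_meth < 0L) || any(n_unmeth < 0L))
    .stopf("negative counts in %s", path)
  strand <- if (all(nf >= 7L)) vapply(parts, `[`, "", 7L) else rep(".", nrow(m))
  context <- if (all(nf >= 8L)) vapply(parts, `[`, "", 8L) else rep("CpG", nrow(m))
  keep <- (n_meth + n_unmeth) >= min_coverage
  cpg_calls(chrom = m[keep, 1L], pos0 = pos1[keep] - 1L,
            strand = strand[keep], context = context[keep],
            n_meth = n_meth[keep], n_unmeth = n_unmeth[keep])
}

#' Write a per-CpG call table in the coverage dialect
#'
#' Inverse of \code{\link{read_cpg_calls}} at \code{min_coverage = 0}:
#' writes 1-based inclusive positions, methylation percent, counts, strand
#' and context.
#'
#' @param calls a call table.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cpg_calls <- function(calls, path) {
  total <- calls$n_meth + calls$n_unmeth
  pct <- ifelse(total > 0, 100 * calls$n_meth / total, 0)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%s",
                   calls$chrom, calls$pos0 + 1L, calls$pos0 + 1L,
                   format(pct, trim = TRUE), calls$n_meth, calls$n_unmeth,
                   calls$strand, calls$context)
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) .stopf("cannot write to %s", path)
  invisible(path)
}

#' Construct a region set
#'
#' Intervals are 0-based half-open; overlap is allowed (sliding windows).
#' @param chrom,start0,end0 interval coordinates, start0 < end0.
#' @param name,strand optional annotation columns.
#' @return a \code{data.frame} with columns chrom, start0, end0, name, strand.
#' @export
region_set <- function(chrom, start0, end0, name = NULL, strand = ".") {
  if (any(start0 >= end0)) .stopf("regions must satisfy start0 < end0")
  n <- length(chrom)
  if (is.null(name)) name <- sprintf("%s:%d-%d", chrom, start0, end0)
  data.frame(chrom = as.character(chrom), start0 = as.numeric(start0),
             end0 = as.numeric(end0), name = as.character(name),
             strand = rep_len(as.character(strand), n),
             stringsAsFactors = FALSE)
}

#' Tile a genome into windows
#'
#' Genome-wide tiling windows for region-level methylation summaries. The
#' default 3-kb non-overlapping tiles match the window size used for
#' genome-wide differential methylation; set \code{step < size} for
#' overlapping sliding windows. The final partial window is retained.
#'
#' @param genome named vector of chromosome lengths (bp).
#' @param size window size in bp (default 3000).
#' @param step distance between window starts (default \code{size}).
#' @return a region set.
#' @export
make_windows <- function(genome, size = 3000, step = size) {
  .check_genome(genome)
  if (size < 1 || step < 1) .stopf("size and step must be >= 1")
  out <- lapply(names(genome), function(chr) {
    len <- genome[[chr]]
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    region_set(chrom = chr, start0 = starts,
               end0 = pmin(starts + size, len))
  })
  do.call(rbind, out)
}

#' Promoter regions around transcription start sites
#'
#' Builds the region flanking each TSS by \code{flank} bp on both sides
#' (so 2 kb total at the 1-kb default), clipped at the chromosome start.
#' Strand is recorded but does not alter the interval.
#'
#' @param tss_table data.frame with columns chrom, tss_pos0, strand, gene.
#' @param flank half-width in bp (default 1000).
#' @param genome optional named length vector; when given, unknown
#'   chromosomes raise an error and regions are clipped to chromosome ends.
#' @return a region set named by gene.
#' @export
tss_regions <- function(tss_table, flank = 1000, genome = NULL) {
  req <- c("chrom", "tss_pos0", "gene")
  if (!all(req %in% names(tss_table)))
    .stopf("tss_table needs columns %s", paste(req, collapse = ", "))
  end <- tss_table$tss_pos0 + flank
  if (!is.null(genome)) {
    .check_genome(genome)
    unknown <- setdiff(unique(tss_table$chrom), names(genome))
    if (length(unknown)) .stopf("unknown chromosome(s): %s",
                                paste(unknown, collapse = ", "))
    end <- pmin(end, genome[tss_table$chrom])
  }
  region_set(chrom = tss_table$chrom,
             start0 = pmax(0, tss_table$tss_pos0 - flank),
             end0 = end, name = tss_table$gene,
             strand = if ("strand" %in% names(tss_table)) tss_table$strand else ".")
}

#' Pooled methylation level per region
#'
#' For every region, read counts of all contained CpG sites (pos0 in
#' [start0, end0)) are pooled, so the region level is the coverage-weighted
#' mean of per-site methylation proportions. Regions containing no covered
#' site get a missing level.
#'
#' @param calls a call table.
#' @param regions a region set (may contain overlapping intervals).
#' @param context restrict to one sequence context (default "CpG"; NULL for
#'   all contexts).
#' @return \code{regions} with added columns pooled_meth, pooled_unmeth,
#'   n_sites, level.
#' @export
summarize_regions <- function(calls, regions, context = "CpG") {
  if (!is.null(context)) calls <- calls[calls$context %in% context, , drop = FALSE]
  n <- nrow(regions)
  pm <- pu <- ns <- numeric(n)
  for (chr in unique(regions$chrom)) {
    ri <- which(regions$chrom == chr)
    sub <- calls[calls$chrom == chr, , drop = FALSE]
    if (nrow(sub) == 0L) next
    ord <- order(sub$pos0)
    pos <- sub$pos0[ord]
    cm <- c(0, cumsum(as.numeric(sub$n_meth[ord])))
    cu <- c(0, cumsum(as.numeric(sub$n_unmeth[ord])))
    # half-open [start, end): sites with start <= pos0 <= end - 1
    lo <- findInterval(regions$start0[ri] - 0.5, pos)   # sites strictly before start
    hi <- findInterval(regions$end0[ri] - 0.5, pos)     # sites before end
    pm[ri] <- cm[hi + 1L] - cm[lo + 1L]
    pu[ri] <- cu[hi + 1L] - cu[lo + 1L]
    ns[ri] <- hi - lo
  }
  tot <- pm + pu
  regions$pooled_meth <- pm
  regions$pooled_unmeth <- pu
  regions$n_sites <- as.integer(ns)
  regions$level <- ifelse(tot > 0, pm / tot, NA_real_)
  regions
}

#' Global methylation level per sequence context
#'
#' Pools reads over all sites of each context. Because non-CpG (CHG/CHH)
#' methylation is near-zero in human tissue, the apparent CHG/CHH level is
#' the standard proxy for bisulfite conversion failure.
#'
#' @param calls a call table.
#' @return named numeric vector of pooled levels, one entry per context
#'   present in the table.
#' @export
global_context_levels <- function(calls) {
  if (nrow(calls) == 0L) return(stats::setNames(numeric(0), character(0)))
  tot <- tapply(as.numeric(calls$n_meth + calls$n_unmeth), calls$context, sum)
  met <- tapply(as.numeric(calls$n_meth), calls$context, sum)
  out <- ifelse(tot > 0, met / tot, NA_real_)
  stats::setNames(as.numeric(out), names(tot))
}

#' Merge CpG calls on opposite strands of the same CpG dinucleotide
#'
#' Optional symmetric-CpG merging: a minus-strand call at pos0 = p + 1 is
#' added to the plus-strand call at p. Off by default throughout the
#' package, preserving input fidelity.
#'
#' @param calls a call table (CpG context rows only are merged).
#' @return a call table with merged counts on the plus strand.
#' @export
merge_cpg_strands <- function(calls) {
  cpg <- calls$context == "CpG"
  sub <- calls[cpg, , drop = FALSE]
  minus <- sub$strand == "-"
  anchor <- ifelse(minus, sub$pos0 - 1L, sub$pos0)
  key <- .site_key(sub$chrom, anchor)
  agg_m <- tapply(sub$n_meth, key, sum)
  agg_u <- tapply(sub$n_unmeth, key, sum)
  first <- !duplicated(key)
  merged <- cpg_calls(chrom = sub$chrom[first], pos0 = anchor[first],
                      strand = "+", context = "CpG",
                      n_meth = as.integer(agg_m[key[first]]),
                      n_unmeth = as.integer(agg_u[key[first]]))
  rbind(merged, calls[!cpg, , drop = FALSE])
}
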