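# Synthetic cfDNA methylome cohorts with known ground truth: cell-type
# reference atlases, per-CpG call files, 100-kb bin counts, planted DMRs
# and copy-number segments, bisulfite conversion error, and a linear- vs
# exponential-amplification read simulator.

#' Build a synthetic cell-type reference methylation atlas
#'
#' Marker sites carry a methylation probability for their flagged cell type
#' that differs from the (shared) value of every other type by at least
#' \code{margin}; non-marker sites have one common baseline probability
#' across types. The result stands in for curated cell-type reference
#' methylomes in simulation studies.
#'
#' @param n_cell_types number of cell types (>= 2).
#' @param n_sites number of CpG reference sites.
#' @param marker_fraction fraction of sites that are markers, in (0, 1].
#' @param margin minimum |flagged - other| probability separation.
#' @param seed integer RNG seed; fixed seed gives an identical atlas.
#' @param genome optional named chromosome-length vector over which sites
#'   are scattered uniformly; default: one synthetic chromosome with 1-kb
#'   spacing.
#' @param cell_types optional character labels (default cellA, cellB, ...).
#' @return an object of class \code{cfmeth_atlas}: list with
#'   \code{cell_types}, \code{sites} (chrom, pos0, strand), \code{meth_prob}
#'   (site x type matrix), \code{marker_target}, \code{marker_direction}.
#' @export
build_reference_atlas <- function(n_cell_types, n_sites, marker_fraction = 1,
                                  margin = 0.8, seed = 1, genome = NULL,
                                  cell_types = NULL) {
  if (n_cell_types < 2) .stopf("n_cell_types must be >= 2")
  if (n_sites < 1) .stopf("n_sites must be >= 1")
  if (marker_fraction <= 0 || marker_fraction > 1)
    .stopf("marker_fraction must be in (0, 1]")
  .check_prob(margin, "margin")
  set.seed(seed)
  if (is.null(cell_types))
    cell_types <- paste0("cell", LETTERS[seq_len(n_cell_types)])
  if (is.null(genome)) {
    sites <- data.frame(chrom = "chrR", pos0 = (seq_len(n_sites) - 1L) * 1000L,
                        strand = "+", stringsAsFactors = FALSE)
  } else {
    .check_genome(genome)
    chr <- sample(names(genome), n_sites, replace = TRUE,
                  prob = genome / sum(genome))
    pos <- floor(stats::runif(n_sites, 0, genome[chr] - 1))
    ord <- order(chr, pos)
    sites <- data.frame(chrom = chr[ord], pos0 = as.integer(pos[ord]),
                        strand = "+", stringsAsFactors = FALSE)
  }
  n_marker <- max(1L, round(marker_fraction * n_sites))
  is_marker <- seq_len(n_sites) <= n_marker
  target <- rep(NA_character_, n_sites)
  direction <- rep(NA_character_, n_sites)
  prob <- matrix(NA_real_, n_sites, n_cell_types,
                 dimnames = list(.site_key(sites$chrom, sites$pos0), cell_types))
  target[is_marker] <- cell_types[((seq_len(n_marker) - 1L) %% n_cell_types) + 1L]
  direction[is_marker] <- sample(c("hypo", "hyper"), n_marker, replace = TRUE)
  for (j in seq_len(n_sites)) {
    if (is_marker[j]) {
      ti <- match(target[j], cell_types)
      if (direction[j] == "hypo") {
        flagged <- stats::runif(1, 0, (1 - margin) * 0.5)
        other <- stats::runif(1, flagged + margin, 1)
      } else {
        flagged <- stats::runif(1, margin + (1 - margin) * 0.5, 1)
        other <- stats::runif(1, 0, flagged - margin)
      }
      prob[j, ] <- other
      prob[j, ti] <- flagged
    } else {
      prob[j, ] <- stats::runif(1, 0.2, 0.8)
    }
  }
  structure(list(cell_types = cell_types, sites = sites, meth_prob = prob,
                 marker_target = target, marker_direction = direction),
            class = "cfmeth_atlas")
}

#' @export
print.cfmeth_atlas <- function(x, ...) {
  cat(sprintf("Reference atlas: %d sites x %d cell types (%d markers)\n",
              nrow(x$meth_prob), length(x$cell_types),
              sum(!is.na(x$marker_target))))
  cat("cell types:", paste(x$cell_types, collapse = ", "), "\n")
  invisible(x)
}

.check_simplex <- function(w, n, tol = 1e-6) {
  if (length(w) != n) .stopf("proportions must have length %d", n)
  if (any(w < 0) || abs(sum(w) - 1) > tol)
    .stopf("proportions must be non-negative and sum to 1 (|sum - 1| <= %g)", tol)
  invisible(w)
}

#' Simulate per-CpG calls for one mixed sample
#'
#' Generates read counts at the atlas sites for a sample whose molecules
#' originate from the atlas cell types with the given proportions. Coverage
#' is Poisson per site (independent molecules, the linear-amplification
#' assumption); each read derives from a cell type drawn from
#' \code{proportions}, is methylated with that type's atlas probability,
#' then flipped by the two bisulfite error rates. The resulting methylated
#' count is Binomial(coverage, p) with
#' p = p_true (1 - overconversion) + (1 - p_true) conversion_failure.
#'
#' @param atlas a \code{cfmeth_atlas}.
#' @param proportions simplex vector over the atlas cell types.
#' @param coverage_mean mean reads per CpG.
#' @param conversion_failure probability an unmethylated C reads methylated.
#' @param overconversion probability a methylated C reads unmethylated.
#' @param seed integer RNG seed.
#' @return a call table over the atlas sites (context "CpG").
#' @export
simulate_sample_calls <- function(atlas, proportions, coverage_mean = 30,
                                  conversion_failure = 0, overconversion = 0,
                                  seed = 1) {
  .check_simplex(proportions, length(atlas$cell_types))
  .check_prob(conversion_failure, "conversion_failure")
  .check_prob(overconversion, "overconversion")
  set.seed(seed)
  p_true <- as.numeric(atlas$meth_prob %*% proportions)
  p_obs <- p_true * (1 - overconversion) + (1 - p_true) * conversion_failure
  n <- nrow(atlas$sites)
  cov <- stats::rpois(n, coverage_mean)
  n_meth <- stats::rbinom(n, cov, p_obs)
  cpg_calls(chrom = atlas$sites$chrom, pos0 = atlas$sites$pos0,
            strand = atlas$sites$strand, context = "CpG",
            n_meth = n_meth, n_unmeth = cov - n_meth)
}

#' Simulate binned fragment counts under copy-number alterations
#'
#' The expected relative weight of bin b is
#' 1 + tumor_fraction * (copy(b)/2 - 1) (scaled by bin width for partial
#' bins); counts are drawn multinomially so they sum exactly to
#' \code{total_reads}. This is the generative model the copy-ratio caller
#' inverts.
#'
#' @param bins a region set of genome bins.
#' @param cna_segments data.frame (chrom, start0, end0, copy) of planted
#'   segments, copy >= 0; bins are assigned by midpoint. NULL = neutral.
#' @param tumor_fraction tumor DNA fraction in [0, 1].
#' @param total_reads total fragment count.
#' @param seed integer RNG seed.
#' @return object of class \code{cfmeth_bincounts}: list(bins, counts, total).
#' @export
simulate_bin_counts <- function(bins, cna_segments = NULL, tumor_fraction = 0,
                                total_reads = 1e6, seed = 1) {
  if (is.null(bins) || nrow(bins) == 0L) .stopf("empty bin set")
  .check_prob(tumor_fraction, "tumor_fraction")
  copy <- rep(2, nrow(bins))
  if (!is.null(cna_segments) && nrow(cna_segments) > 0L) {
    if (any(cna_segments$copy < 0)) .stopf("copy numbers must be >= 0")
    mid <- (bins$start0 + bins$end0) / 2
    for (i in seq_len(nrow(cna_segments))) {
      hit <- bins$chrom == cna_segments$chrom[i] &
        mid >= cna_segments$start0[i] & mid < cna_segments$end0[i]
      copy[hit] <- cna_segments$copy[i]
    }
  }
  w <- (bins$end0 - bins$start0) * (1 + tumor_fraction * (copy / 2 - 1))
  set.seed(seed)
  counts <- as.integer(stats::rmultinom(1, total_reads, prob = w))
  structure(list(bins = bins, counts = counts, total = total_reads),
            class = "cfmeth_bincounts")
}

#' @export
print.cfmeth_bincounts <- function(x, ...) {
  cat(sprintf("Bin counts: %d bins, %s reads\n", nrow(x$bins),
              format(x$total, big.mark = ",")))
  invisible(x)
}

#' Simulate library amplification and read duplication
#'
#' Models the duplicate structure of a sequencing library. Under linear
#' amplification every template molecule is copied independently
#' (copies ~ 1 + Poisson(mean_copies - 1)); under exponential (PCR-style)
#' amplification per-molecule efficiency compounds, giving log-normal
#' copy numbers (~ exp(Normal(log mean_copies, jitter))). Reads sample
#' molecules with probability proportional to copy number; reads sharing a
#' molecule beyond the first are duplicates, so the heavier-tailed
#' exponential copy distribution raises the duplication rate at matched
#' depth.
#'
#' @param n_molecules number of template molecules.
#' @param n_reads number of sequenced reads (>= 1).
#' @param mode "linear" or "exponential".
#' @param mean_copies mean copies per molecule (>= 1).
#' @param jitter log-scale SD of exponential amplification efficiency.
#' @param seed integer RNG seed.
#' @return integer vector of length n_reads: source molecule id per read.
#' @export
simulate_amplification <- function(n_molecules, n_reads,
                                   mode = c("linear", "exponential"),
                                   mean_copies = 5, jitter = 0.5, seed = 1) {
  mode <- match.arg(mode)
  if (n_reads < 1) .stopf("n_reads must be >= 1")
  if (mean_copies < 1) .stopf("mean_copies must be >= 1")
  set.seed(seed)
  copies <- switch(mode,
    linear = 1 + stats::rpois(n_molecules, mean_copies - 1),
    exponential = exp(stats::rnorm(n_molecules, log(mean_copies), jitter)))
  sample.int(n_molecules, n_reads, replace = TRUE, prob = copies)
}

#' Simulation configuration for a synthetic cfDNA cohort
#'
#' Defaults mirror a colorectal-cancer-versus-healthy cfDNA study design:
#' 50 cases and 34 controls, neutrophil-dominated cell mixtures with
#' case-shifted immune composition, per-sample tumor fraction diluting a
#' colon/tumor component, planted 3-kb DMRs, chromosome-arm-scale copy
#' alterations, and sub-1\% bisulfite conversion error (the level reported
#' for non-CpG methylation in well-converted libraries).
#'
#' @param n_cases,n_controls cohort sizes.
#' @param genome named chromosome-length vector (bp).
#' @param cpg_density CpG sites per kb.
#' @param noncpg_density CHG/CHH sites per kb (truly unmethylated; their
#'   apparent level proxies conversion failure).
#' @param coverage_mean mean reads per CpG.
#' @param conversion_failure,overconversion bisulfite error rates.
#' @param cell_types cell-type labels; \code{tumor_cell_type} must be one.
#' @param dirichlet_alpha_control,dirichlet_alpha_case Dirichlet
#'   concentrations for mixing proportions per group.
#' @param tumor_cell_type label of the solid-tissue/tumor component.
#' @param tumor_fraction_range per-case tumor fraction drawn uniformly.
#' @param dmrs data.frame (chrom, start0, end0, delta): methylation shift
#'   applied to the tumor component inside each region (clipped to [0,1]).
#' @param cna_segments data.frame (chrom, start0, end0, copy).
#' @param bin_size copy-number bin size (bp).
#' @param total_reads fragments per sample for bin counting.
#' @param n_atlas_sites,atlas_margin marker-site count and separation for
#'   the embedded deconvolution reference atlas.
#' @param seed integer RNG seed.
#' @return object of class \code{cfmeth_simconfig} (a validated list).
#' @export
simulation_config <- function(
    n_cases = 50, n_controls = 34,
    genome = c(chr1 = 5e6, chr2 = 5e6),
    cpg_density = 1, noncpg_density = 0.3,
    coverage_mean = 30,
    conversion_failure = 0.008, overconversion = 0.005,
    cell_types = c("neutrophil", "monocyte", "cd4t", "cd8t", "bcell", "colon"),
    dirichlet_alpha_control = c(30, 8, 6, 5, 4, 2),
    dirichlet_alpha_case = c(22, 5, 10, 5, 4, 2),
    tumor_cell_type = "colon",
    tumor_fraction_range = c(0.05, 0.3),
    dmrs = NULL, cna_segments = NULL,
    bin_size = 1e5, total_reads = 2e5,
    n_atlas_sites = 333, atlas_margin = 0.6,
    seed = 1) {
  .check_genome(genome)
  .check_count(c(n_cases, n_controls), "cohort sizes")
  .check_prob(conversion_failure, "conversion_failure")
  .check_prob(overconversion, "overconversion")
  .check_prob(tumor_fraction_range, "tumor_fraction_range")
  if (!tumor_cell_type %in% cell_types)
    .stopf("tumor_cell_type '%s' not among cell_types", tumor_cell_type)
  if (length(dirichlet_alpha_control) != length(cell_types) ||
      length(dirichlet_alpha_case) != length(cell_types))
    .stopf("dirichlet alphas must have one entry per cell type")
  if (is.null(dmrs))
    dmrs <- data.frame(
      chrom = "chr1",
      start0 = seq(3e6, 3e6 + 19 * 60000, by = 60000),
      end0 = seq(3e6, 3e6 + 19 * 60000, by = 60000) + 3000,
      delta = rep(c(0.3, -0.3), 10))
  if (is.null(cna_segments))
    cna_segments <- data.frame(chrom = c("chr1", "chr2"),
                               start0 = c(0, 2e6), end0 = c(1.5e6, 3.5e6),
                               copy = c(3, 1))
  if (any(cna_segments$copy < 0)) .stopf("copy numbers must be >= 0")
  structure(list(
    n_cases = n_cases, n_controls = n_controls, genome = genome,
    cpg_density = cpg_density, noncpg_density = noncpg_density,
    coverage_mean = coverage_mean,
    conversion_failure = conversion_failure, overconversion = overconversion,
    cell_types = cell_types,
    dirichlet_alpha_control = dirichlet_alpha_control,
    dirichlet_alpha_case = dirichlet_alpha_case,
    tumor_cell_type = tumor_cell_type,
    tumor_fraction_range = tumor_fraction_range,
    dmrs = dmrs, cna_segments = cna_segments,
    bin_size = bin_size, total_reads = total_reads,
    n_atlas_sites = n_atlas_sites, atlas_margin = atlas_margin,
    seed = as.integer(seed)), class = "cfmeth_simconfig")
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a full case/control cfDNA cohort
#'
#' Generates, for every sample, a per-CpG call table (genome-wide CpGs plus
#' embedded reference-atlas marker sites plus truly-unmethylated CHG/CHH
#' sites) and 100-kb bin counts, together with the planted ground truth.
#' Cases mix a tumor component into their cell proportions
#' (w_eff = (1 - tf) w + tf e_tumor); planted DMR deltas shift the tumor
#' component's methylation only, and copy-number segments are scaled by the
#' same tumor fraction. With \code{out_dir} set, call files, bin-count TSVs,
#' the truth JSON and the config YAML are written to disk; outputs are
#' byte-identical for a fixed config.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param out_dir optional output directory.
#' @return object of class \code{cfmeth_cohort}: list with \code{samples}
#'   (per sample: calls, bins), \code{truth} (proportions, tumor fractions,
#'   planted DMRs/CNAs, labels), \code{atlas}, \code{bins}, \code{config}.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cfmeth_simconfig"))
  set.seed(config$seed)
  genome <- config$genome
  n_types <- length(config$cell_types)
  tumor_i <- match(config$tumor_cell_type, config$cell_types)

  # genome-wide site scaffold, shared across samples
  site_list <- lapply(names(genome), function(chr) {
    len <- genome[[chr]]
    n_cpg <- round(len / 1000 * config$cpg_density)
    n_non <- round(len / 1000 * config$noncpg_density)
    pos <- sort(sample.int(len, n_cpg + n_non))
    ctx <- sample(c(rep("CpG", n_cpg),
                    rep(c("CHG", "CHH"), length.out = n_non)))
    data.frame(chrom = chr, pos0 = pos - 1L, context = ctx,
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  is_cpg <- sites$context == "CpG"
  # baseline methylation: shared across cell types, ~45% genome-wide mean
  base <- ifelse(is_cpg, stats::rbeta(nrow(sites), 1.8, 2.2), 0)
  # tumor-component methylation: baseline shifted by planted DMR deltas
  tumor_base <- base
  dmr_site <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(config$dmrs))) {
    d <- config$dmrs[i, ]
    hit <- is_cpg & sites$chrom == d$chrom &
      sites$pos0 >= d$start0 & sites$pos0 < d$end0
    tumor_base[hit] <- pmin(1, pmax(0, base[hit] + d$delta))
    dmr_site <- dmr_site | hit
  }

  # embedded marker atlas on this genome (separate coordinates)
  atlas <- build_reference_atlas(
    n_cell_types = n_types, n_sites = config$n_atlas_sites,
    marker_fraction = 1, margin = config$atlas_margin,
    seed = .stage_seed(config$seed, "atlas"), genome = genome,
    cell_types = config$cell_types)

  bins <- bin_genome(genome, size = config$bin_size)
  n <- config$n_cases + config$n_controls
  labels <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  ids <- sprintf("%s%02d", ifelse(labels == "case", "case", "ctrl"),
                 stats::ave(seq_len(n), labels, FUN = seq_along))

  props <- matrix(0, n, n_types, dimnames = list(ids, config$cell_types))
  tf <- numeric(n)
  samples <- vector("list", n); names(samples) <- ids
  for (s in seq_len(n)) {
    alpha <- if (labels[s] == "case") config$dirichlet_alpha_case
             else config$dirichlet_alpha_control
    w <- .rdirichlet(alpha)
    if (labels[s] == "case") {
      tf[s] <- stats::runif(1, config$tumor_fraction_range[1],
                            config$tumor_fraction_range[2])
      w <- (1 - tf[s]) * w
      w[tumor_i] <- w[tumor_i] + tf[s]
    }
    props[s, ] <- w

    # genome-wide track: non-tumor components share the baseline, the tumor
    # component carries the DMR shifts
    p_true <- (1 - w[tumor_i]) * base + w[tumor_i] * tumor_base
    p_obs <- p_true * (1 - config$overconversion) +
      (1 - p_true) * config$conversion_failure
    cov <- stats::rpois(nrow(sites), config$coverage_mean)
    nm <- stats::rbinom(nrow(sites), cov, p_obs)
    genome_calls <- data.frame(chrom = sites$chrom, pos0 = sites$pos0,
                               strand = "+", context = sites$context,
                               n_meth = nm, n_unmeth = cov - nm,
                               stringsAsFactors = FALSE)
    marker_calls <- simulate_sample_calls(
      atlas, w, coverage_mean = config$coverage_mean,
      conversion_failure = config$conversion_failure,
      overconversion = config$overconversion,
      seed = .stage_seed(config$seed, paste0("calls", s)))
    calls <- rbind(marker_calls, genome_calls)  # marker rows win collisions
    calls <- calls[!duplicated(paste(calls$chrom, calls$pos0)), , drop = FALSE]
    calls <- calls[order(calls$chrom, calls$pos0), , drop = FALSE]
    rownames(calls) <- NULL

    bc <- simulate_bin_counts(
      bins, cna_segments = if (labels[s] == "case") config$cna_segments else NULL,
      tumor_fraction = tf[s], total_reads = config$total_reads,
      seed = .stage_seed(config$seed, paste0("bins", s)))
    samples[[s]] <- list(calls = calls, bins = bc)
  }

  truth <- list(sample_id = ids, group = labels,
                proportions = props, tumor_fraction = tf,
                dmrs = config$dmrs, cna_segments = config$cna_segments)
  out <- structure(list(samples = samples, truth = truth, atlas = atlas,
                        bins = bins, config = config),
                   class = "cfmeth_cohort")
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

#' @export
print.cfmeth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cfDNA cohort: %d cases / %d controls, %d sites/sample\n",
              x$config$n_cases, x$config$n_controls,
              nrow(x$samples[[1]]$calls)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' One coverage call file and one bin-count TSV per sample, the ground
#' truth as JSON and the configuration as YAML.
#'
#' @param cohort a \code{cfmeth_cohort}.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok) .stopf("cannot create output directory %s", out_dir)
  for (id in names(cohort$samples)) {
    write_cpg_calls(cohort$samples[[id]]$calls,
                    file.path(out_dir, paste0(id, ".cov.tsv")))
    bc <- cohort$samples[[id]]$bins
    utils::write.table(
      data.frame(bc$bins$chrom, bc$bins$start0, bc$bins$end0, bc$counts),
      file.path(out_dir, paste0(id, ".bins.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  ref <- cohort$atlas$meth_prob
  utils::write.table(
    data.frame(site = rownames(ref), ref, check.names = FALSE),
    file.path(out_dir, "atlas_reference.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  jsonlite::write_json(
    list(sample_id = tr$sample_id, group = tr$group,
         proportions = as.data.frame(tr$proportions),
         tumor_fraction = tr$tumor_fraction,
         dmrs = tr$dmrs, cna_segments = tr$cna_segments),
    file.path(out_dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  cfg <- cohort$config
  cfg_list <- lapply(unclass(cfg), function(v)
    if (is.data.frame(v)) as.list(v) else if (!is.null(names(v)) &&
      all(nzchar(names(v)))) as.list(v) else v)
  yaml::write_yaml(cfg_list, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
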