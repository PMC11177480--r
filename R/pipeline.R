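# Pipeline orchestration: validated configuration, per-stage execution
# with JSON manifests, and deterministic per-stage seed derivation, so
# every stage is runnable standalone on files conforming to the documented
# formats.

.PIPELINE_DEFAULTS <- list(
  out_dir = "cfmeth_out",
  seed = 1L,
  window_size = 3000, window_step = NULL,
  min_coverage = 3,
  dmr_diff_cutoff = 0.15, dmr_fdr_cutoff = 0.01,
  promoter_diff_cutoff = 0.12,
  bin_size = 1e5,
  segment_min_bins = 10, segment_threshold = 0.15, segment_t_crit = 5,
  k_groups = 32, knn_k = 10,
  variance_target = 0.95, train_fraction = 0.25, cv_folds = 5,
  classifier = "random_forest", drop_cell_type = NULL,
  sim = list())

#' Build and validate a pipeline configuration
#'
#' Central home of the pipeline's tunable constants; the defaults are the
#' canonical analysis settings (3-kb windows, >= 3x CpG coverage, DMR
#' cutoffs FDR < 0.01 and difference > 15\% with a 12\% promoter preset,
#' 100-kb copy-number bins, 32 dendrogram groups, k = 10 imputation, 95\%
#' PCA variance, 1:3 train:test split, 5-fold CV). Unknown keys are
#' rejected with a nearest-key suggestion; \code{sim} holds overrides for
#' \code{\link{simulation_config}}.
#'
#' @param ... named settings overriding the defaults.
#' @return object of class \code{cfmeth_config} (a validated list).
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(!nzchar(names(over)))))
    .stopf("all configuration settings must be named")
  unknown <- setdiff(names(over), names(.PIPELINE_DEFAULTS))
  if (length(unknown)) {
    key <- unknown[1]
    d <- utils::adist(key, names(.PIPELINE_DEFAULTS))
    hint <- names(.PIPELINE_DEFAULTS)[which.min(d)]
    .stopf("unknown configuration key '%s' (did you mean '%s'?)", key, hint)
  }
  cfg <- utils::modifyList(.PIPELINE_DEFAULTS, over)
  if (is.null(cfg$window_step)) cfg$window_step <- cfg$window_size
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "cfmeth_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are
#'   \code{\link{pipeline_config}} settings.
#' @return a \code{cfmeth_config}.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.manifest <- function(stage, config, params, inputs, outputs) {
  list(stage = stage,
       seed = .stage_seed(config$seed, stage),
       parameters = params,
       inputs = as.list(tools::md5sum(inputs)),
       outputs = as.list(tools::md5sum(outputs)))
}

.write_manifest <- function(m, dir) {
  jsonlite::write_json(m, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

.read_truth <- function(config) {
  path <- file.path(config$out_dir, "simulate", "truth.json")
  if (!file.exists(path)) .stopf("missing upstream output: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.cohort_files <- function(config, pattern) {
  d <- file.path(config$out_dir, "simulate")
  f <- list.files(d, pattern = pattern, full.names = TRUE)
  if (length(f) == 0L) .stopf("missing upstream outputs (%s) in %s", pattern, d)
  sort(f)
}

.read_bincounts_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t",
                         col.names = c("chrom", "start0", "end0", "count"))
  structure(list(bins = region_set(x$chrom, x$start0, x$end0),
                 counts = x$count, total = sum(x$count)),
            class = "cfmeth_bincounts")
}

.sim_genome <- function(config) {
  sim <- do.call(simulation_config,
                 utils::modifyList(list(seed = .stage_seed(config$seed, "simulate")),
                                   config$sim))
  sim$genome
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (synthetic cohort to disk), \code{summarize}
#' (window methylation matrix), \code{dmr}, \code{cnv}, \code{deconv},
#' \code{classify}, \code{qc}. Each stage reads only documented on-disk
#' formats produced by the upstream stage, writes its outputs plus a JSON
#' manifest (parameters, derived seed, input/output content hashes) to
#' \code{<out_dir>/<stage>/}, and is deterministic for a fixed
#' configuration.
#'
#' @param stage stage name.
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, the stage's primary result object.
#' @export
run_stage <- function(stage, config) {
  stopifnot(inherits(config, "cfmeth_config"))
  stages <- c("simulate", "summarize", "dmr", "cnv", "deconv", "classify", "qc")
  if (!stage %in% stages)
    .stopf("unknown stage '%s'; expected one of %s", stage,
           paste(stages, collapse = ", "))
  seed <- .stage_seed(config$seed, stage)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
         simulate = .stage_simulate(config, seed),
         summarize = .stage_summarize(config, seed),
         dmr = .stage_dmr(config, seed),
         cnv = .stage_cnv(config, seed),
         deconv = .stage_deconv(config, seed),
         classify = .stage_classify(config, seed),
         qc = .stage_qc(config, seed))
}

.stage_simulate <- function(config, seed) {
  d <- .stage_dir(config, "simulate")
  sim <- do.call(simulation_config,
                 utils::modifyList(list(seed = seed), config$sim))
  cohort <- simulate_cohort(sim, out_dir = d)
  outs <- list.files(d, full.names = TRUE)
  outs <- outs[!grepl("manifest", outs)]
  .write_manifest(.manifest("simulate", config,
                            list(n_cases = sim$n_cases,
                                 n_controls = sim$n_controls,
                                 coverage_mean = sim$coverage_mean),
                            character(0), outs), d)
  invisible(cohort)
}

.stage_summarize <- function(config, seed) {
  d <- .stage_dir(config, "summarize")
  files <- .cohort_files(config, "\\.cov\\.tsv$")
  genome <- .sim_genome(config)
  windows <- make_windows(genome, config$window_size, config$window_step)
  summaries <- lapply(files, function(f)
    summarize_regions(read_cpg_calls(f, config$min_coverage), windows))
  ids <- sub("\\.cov\\.tsv$", "", basename(files))
  lev <- vapply(summaries, `[[`, numeric(nrow(windows)), "level")
  colnames(lev) <- ids
  out <- file.path(d, "window_levels.tsv")
  utils::write.table(cbind(windows[, c("chrom", "start0", "end0")], lev),
                     out, sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_along(files))
    utils::write.table(summaries[[i]][, c("chrom", "start0", "end0",
                                          "pooled_meth", "pooled_unmeth")],
                       file.path(d, paste0(ids[i], ".windows.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  .write_manifest(.manifest("summarize", config,
                            list(window_size = config$window_size,
                                 window_step = config$window_step,
                                 min_coverage = config$min_coverage),
                            files, file.path(d, list.files(d, "\\.tsv$"))), d)
  invisible(summaries)
}

.stage_dmr <- function(config, seed) {
  d <- .stage_dir(config, "dmr")
  truth <- .read_truth(config)
  sdir <- file.path(config$out_dir, "summarize")
  files <- file.path(sdir, paste0(truth$sample_id, ".windows.tsv"))
  if (!all(file.exists(files)))
    .stopf("missing upstream output: run the summarize stage first")
  summaries <- lapply(files, function(f) {
    x <- utils::read.table(f, header = TRUE, sep = "\t")
    x$name <- sprintf("%s:%d-%d", x$chrom, x$start0, x$end0)
    x
  })
  dmrs <- call_dmrs(summaries, truth$group,
                    diff_cutoff = config$dmr_diff_cutoff,
                    fdr_cutoff = config$dmr_fdr_cutoff)
  out <- file.path(d, "dmrs.tsv")
  write_dmrs(dmrs, out)
  .write_manifest(.manifest("dmr", config,
                            list(diff_cutoff = config$dmr_diff_cutoff,
                                 fdr_cutoff = config$dmr_fdr_cutoff),
                            files, out), d)
  invisible(dmrs)
}

.stage_cnv <- function(config, seed) {
  d <- .stage_dir(config, "cnv")
  truth <- .read_truth(config)
  files <- file.path(config$out_dir, "simulate",
                     paste0(truth$sample_id, ".bins.tsv"))
  if (!all(file.exists(files))) .stopf("missing upstream bin-count files")
  bcs <- lapply(files, .read_bincounts_tsv)
  names(bcs) <- truth$sample_id
  panel <- build_panel(bcs[truth$group == "control"])
  seg_files <- character(0)
  results <- list()
  for (id in truth$sample_id[truth$group == "case"]) {
    track <- copy_ratio(bcs[[id]], panel)
    segs <- segment_and_call(track, min_bins = config$segment_min_bins,
                             threshold = config$segment_threshold,
                             t_crit = config$segment_t_crit)
    f <- file.path(d, paste0(id, ".segments.tsv"))
    utils::write.table(segs, f, sep = "\t", quote = FALSE, row.names = FALSE)
    seg_files <- c(seg_files, f)
    results[[id]] <- list(track = track, segments = segs)
  }
  .write_manifest(.manifest("cnv", config,
                            list(bin_size = config$bin_size,
                                 min_bins = config$segment_min_bins,
                                 threshold = config$segment_threshold),
                            files, seg_files), d)
  invisible(list(panel = panel, samples = results))
}

.stage_deconv <- function(config, seed) {
  d <- .stage_dir(config, "deconv")
  truth <- .read_truth(config)
  ref_file <- file.path(config$out_dir, "simulate", "atlas_reference.tsv")
  if (!file.exists(ref_file)) .stopf("missing upstream atlas reference")
  ref_df <- utils::read.table(ref_file, header = TRUE, sep = "\t",
                              check.names = FALSE)
  ref <- as.matrix(ref_df[, -1, drop = FALSE])
  rownames(ref) <- ref_df$site
  mega <- build_mega_sites(ref, k = min(config$k_groups, nrow(ref)))
  files <- file.path(config$out_dir, "simulate",
                     paste0(truth$sample_id, ".cov.tsv"))
  mat <- vapply(files, function(f)
    aggregate_sample_to_mega_sites(read_cpg_calls(f, min_coverage = 1), mega),
    numeric(length(mega$groups)))
  colnames(mat) <- truth$sample_id
  mat <- knn_impute(mat, k = config$knn_k)
  props <- t(vapply(truth$sample_id, function(id)
    deconvolve(mat[, id], mega$reference)$proportions,
    numeric(ncol(ref))))
  out <- file.path(d, "cell_proportions.tsv")
  utils::write.table(data.frame(sample = rownames(props), props),
                     out, sep = "\t", quote = FALSE, row.names = FALSE)
  .write_manifest(.manifest("deconv", config,
                            list(k_groups = config$k_groups,
                                 knn_k = config$knn_k),
                            c(ref_file, files), out), d)
  invisible(list(mega_sites = mega, proportions = props))
}

.stage_classify <- function(config, seed) {
  d <- .stage_dir(config, "classify")
  truth <- .read_truth(config)
  win_file <- file.path(config$out_dir, "summarize", "window_levels.tsv")
  prop_file <- file.path(config$out_dir, "deconv", "cell_proportions.tsv")
  for (f in c(win_file, prop_file))
    if (!file.exists(f)) .stopf("missing upstream output: %s", f)
  win <- utils::read.table(win_file, header = TRUE, sep = "\t",
                           check.names = FALSE)
  meth <- t(as.matrix(win[, truth$sample_id, drop = FALSE]))
  meth[is.na(meth)] <- mean(meth, na.rm = TRUE)
  keep <- apply(meth, 2, function(v) stats::sd(v) > 0)
  meth <- meth[, keep, drop = FALSE]
  pr <- utils::read.table(prop_file, header = TRUE, sep = "\t")
  props <- as.matrix(pr[, -1, drop = FALSE]); rownames(props) <- pr$sample
  props <- props[truth$sample_id, , drop = FALSE]

  truth_files <- file.path(config$out_dir, "simulate",
                           paste0(truth$sample_id, ".bins.tsv"))
  bcs <- lapply(truth_files, .read_bincounts_tsv)
  names(bcs) <- truth$sample_id
  labels <- factor(truth$group, levels = c("control", "case"))

  split <- split_cohort(labels, config$train_fraction,
                        seed = .stage_seed(seed, "split"))
  # panel of normals from training controls only (no test leakage)
  tr_ctrl <- intersect(split$train, which(truth$group == "control"))
  panel <- build_panel(bcs[tr_ctrl])
  cn <- t(vapply(bcs, function(b) copy_ratio(b, panel)$ratio,
                 numeric(nrow(panel$bins))))
  cn <- cn[, colSums(is.na(cn)) == 0, drop = FALSE]

  prep_block <- function(block) {
    st <- fit_standardize(block[split$train, , drop = FALSE])
    z <- apply_standardize(st, block)
    pca <- pca_reduce(z[split$train, , drop = FALSE], config$variance_target)
    sc <- apply_pca(pca, z)
    colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
    sc
  }
  blocks <- list(meth = prep_block(meth), cnv = prep_block(cn), props = props)
  drop_ct <- config$drop_cell_type
  if (is.null(drop_ct)) drop_ct <- colnames(props)[ncol(props)]
  feats <- assemble_features(blocks, drop_cell_type = drop_ct)
  model <- train_classifier(feats[split$train, , drop = FALSE],
                            labels[split$train], model = config$classifier,
                            cv_folds = config$cv_folds,
                            seed = .stage_seed(seed, "train"))
  roc <- evaluate_roc(model, feats[split$test, , drop = FALSE],
                      labels[split$test])
  metrics <- list(auc = roc$auc, n_train = length(split$train),
                  n_test = length(split$test),
                  n_features = ncol(feats),
                  best_params = model$best_params)
  out <- file.path(d, "metrics.json")
  jsonlite::write_json(metrics, out, auto_unbox = TRUE, digits = NA)
  roc_out <- file.path(d, "roc.tsv")
  utils::write.table(roc$points, roc_out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .write_manifest(.manifest("classify", config,
                            list(train_fraction = config$train_fraction,
                                 cv_folds = config$cv_folds,
                                 variance_target = config$variance_target,
                                 classifier = config$classifier),
                            c(win_file, prop_file), c(out, roc_out)), d)
  invisible(list(model = model, roc = roc, split = split))
}

.stage_qc <- function(config, seed) {
  d <- .stage_dir(config, "qc")
  files <- .cohort_files(config, "\\.cov\\.tsv$")
  res <- lapply(files, function(f) {
    calls <- read_cpg_calls(f, min_coverage = 1)
    as.list(global_context_levels(calls))
  })
  names(res) <- sub("\\.cov\\.tsv$", "", basename(files))
  corr <- if (length(files) >= 2)
    sample_correlation(read_cpg_calls(files[1], 1),
                       read_cpg_calls(files[2], 1),
                       min_coverage = config$min_coverage) else NA
  out <- file.path(d, "qc_summary.json")
  jsonlite::write_json(list(context_levels = res,
                            first_pair_correlation = corr),
                       out, auto_unbox = TRUE, digits = NA)
  .write_manifest(.manifest("qc", config, list(min_coverage = config$min_coverage),
                            files, out), d)
  invisible(res)
}

#' Run the full pipeline end to end
#'
#' Executes simulate, summarize, dmr, cnv, deconv, classify and qc in
#' order.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, a named list of stage results.
#' @export
run_pipeline <- function(config) {
  stages <- c("simulate", "summarize", "dmr", "cnv", "deconv", "classify", "qc")
  res <- lapply(stages, run_stage, config = config)
  names(res) <- stages
  invisible(res)
}
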