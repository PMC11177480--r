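#' @keywords internal
"_PACKAGE"

# Shared validators and small numeric helpers used across modules.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    .stopf("'%s' must be a probability in [0, 1]", name)
  invisible(x)
}

.check_count <- function(x, name, min = 0L) {
  if (any(!is.finite(x)) || any(x < min) || any(x != floor(x)))
    .stopf("'%s' must be an integer >= %d", name, min)
  invisible(x)
}

#' Validate a genome description
#'
#' A genome is a named numeric vector of chromosome lengths in base pairs.
#' @param genome named numeric vector, names are chromosome labels.
#' @return the genome, invisibly, after validation.
#' @keywords internal
.check_genome <- function(genome) {
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    .stopf("genome must be a named vector of chromosome lengths")
  if (any(!is.finite(genome)) || any(genome < 1))
    .stopf("chromosome lengths must be positive")
  invisible(genome)
}

# Site key used to match CpG records across tables.
.site_key <- function(chrom, pos0) paste(chrom, pos0, sep = ":")

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' Computes AUC with midrank handling of tied scores: tied case/control
#' pairs contribute 1/2, so the value equals the probability a random case
#' outscores a random control plus half the tie probability.
#'
#' @param scores numeric vector of classifier scores, larger = more case-like.
#' @param labels vector coercible to factor; the second level (or
#'   \code{positive}) is treated as the case class.
#' @param positive label of the positive (case) class; default: the last
#'   factor level.
#' @return AUC in [0, 1].
#' @examples
#' auc_score(c(0.9, 0.8, 0.1, 0.2), c("case", "case", "ctrl", "ctrl"),
#'           positive = "case")
#' @export
auc_score <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) .stopf("labels must have exactly 2 classes")
  if (is.null(positive)) positive <- levels(labels)[2L]
  if (!positive %in% levels(labels)) .stopf("positive class '%s' not in labels", positive)
  is_pos <- labels == positive
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) .stopf("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Deterministic per-stage seed derivation: global seed offset by a small
# polynomial hash of the stage name, kept inside the 32-bit integer range.
.stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(seed) + h) %% .Machine$integer.max)
}
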