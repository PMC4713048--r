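#' Construct an expression profile
#'
#' A probe-by-sample matrix of linear-scale expression values together with
#' per-sample class labels (`"treatment"` / `"control"`) and perturbagen
#' metadata. This is the unit of input for signature building: one profile
#' corresponds to one perturbation experiment (a miRNA transfection, or one
#' "instance" of a small-molecule treatment).
#'
#' @param values numeric matrix, probes in rows (rownames = probe IDs),
#'   samples in columns. Values must be finite; the amplitude and fold-change
#'   paths additionally require them strictly positive.
#' @param sample_classes character vector, one of `"treatment"`/`"control"`
#'   per column of `values`.
#' @param perturbagen_id identifier of the perturbing agent.
#' @param perturbagen_kind `"miRNA"` or `"small_molecule"`.
#' @param condition free-text experimental condition (cell line, dose, time).
#' @param source_id free-text provenance label (e.g. a series accession).
#' @param instance_id optional instance label when a molecule has several
#'   independent profiles.
#' @return an object of class `expression_profile`.
#' @export
expression_profile <- function(values, sample_classes, perturbagen_id,
                               perturbagen_kind = c("miRNA", "small_molecule"),
                               condition = "", source_id = "",
                               instance_id = NA_character_) {
  perturbagen_kind <- match.arg(perturbagen_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("`values` must carry probe IDs as rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe IDs in expression matrix")
  if (ncol(values) != length(sample_classes))
    stop("one class label per sample column is required")
  bad <- setdiff(unique(sample_classes), c("treatment", "control"))
  if (length(bad))
    stop("unknown sample class token(s): ", paste(bad, collapse = ", "))
  if (!any(sample_classes == "treatment") || !any(sample_classes == "control"))
    stop("profile needs at least one treatment and one control sample")
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  structure(
    list(values = values,
         sample_classes = sample_classes,
         perturbagen_id = as.character(perturbagen_id),
         perturbagen_kind = perturbagen_kind,
         condition = as.character(condition),
         source_id = as.character(source_id),
         instance_id = as.character(instance_id)),
    class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %s (%s)\n", x$perturbagen_id,
              x$perturbagen_kind))
  cat(sprintf("  %d probes x %d samples (%d treatment, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$sample_classes == "treatment"),
              sum(x$sample_classes == "control")))
  if (nzchar(x$condition)) cat("  condition:", x$condition, "\n")
  invisible(x)
}

#' Construct a ranked response pattern
#'
#' The full probe list of one perturbation experiment ordered from the most
#' up-regulated to the most down-regulated by a ranking statistic (a
#' log-fold-change, a SAM d, or an amplitude). Ties in the statistic are
#' broken by probe ID, lexicographically, so the ordering is deterministic
#' across platforms.
#'
#' @param probe_ids character vector of unique probe identifiers.
#' @param stat numeric ranking statistic, same length.
#' @param sort if `TRUE` (default) the pair is sorted by `stat` descending
#'   (ties by probe ID ascending); if `FALSE` the input must already be in
#'   non-increasing order and is validated, never silently reordered.
#' @return an object of class `ranked_pattern` with fields `probe_ids`,
#'   `stat`.
#' @export
ranked_pattern <- function(probe_ids, stat, sort = TRUE) {
  probe_ids <- as.character(probe_ids)
  if (length(probe_ids) != length(stat))
    stop("probe_ids and stat must have equal length")
  if (length(probe_ids) < 2L)
    stop("a ranked pattern needs at least 2 probes")
  if (anyDuplicated(probe_ids))
    stop("duplicate probe IDs in ranked pattern")
  if (any(!is.finite(stat)))
    stop("ranking statistic must be finite")
  if (sort) {
    o <- order(-stat, probe_ids, method = "radix")
    probe_ids <- probe_ids[o]
    stat <- stat[o]
  } else if (is.unsorted(-stat)) {
    stop("stat is not non-increasing; a ranked pattern is ordered most-up first")
  }
  structure(list(probe_ids = probe_ids, stat = as.numeric(stat)),
            class = "ranked_pattern")
}

#' @export
print.ranked_pattern <- function(x, ...) {
  n <- length(x$probe_ids)
  cat(sprintf("<ranked_pattern> %d probes, stat range [%.4g, %.4g]\n",
              n, x$stat[n], x$stat[1]))
  invisible(x)
}

#' Construct a response signature
#'
#' The up- and down-regulated probe sets called differentially expressed for
#' one perturbagen instance. The two sets are disjoint; either may be empty,
#' but a signature usable for enrichment scoring needs at least one member in
#' at least one direction.
#'
#' @param perturbagen_id identifier of the perturbagen.
#' @param up,down character vectors of probe IDs (treated as sets).
#' @param method the statistic that produced the calls: `"fold_change"`,
#'   `"sam"`, `"amplitude"`, `"permuted"` for resampled null signatures, or
#'   `"planted"` for the ground-truth sets of a synthetic experiment.
#' @param thresholds named list recording the cutoffs used.
#' @return an object of class `response_signature`.
#' @export
response_signature <- function(perturbagen_id, up, down,
                               method = c("fold_change", "sam", "amplitude",
                                          "permuted", "planted"),
                               thresholds = list()) {
  method <- match.arg(method)
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (length(intersect(up, down)))
    stop("up and down probe sets must be disjoint")
  structure(
    list(perturbagen_id = as.character(perturbagen_id),
         up = up, down = down, method = method, thresholds = thresholds),
    class = "response_signature")
}

#' @export
print.response_signature <- function(x, ...) {
  cat(sprintf("<response_signature> %s [%s]: %d up, %d down\n",
              x$perturbagen_id, x$method, length(x$up), length(x$down)))
  invisible(x)
}

# internal: stable integer hash of strings, for per-pair RNG streams
.string_seed <- function(...) {
  s <- paste(unlist(list(...)), collapse = "\x1f")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}
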