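#' Weighted enrichment score of a probe set against a ranked pattern
#'
#' GSEA-style running-sum statistic. Walking the ranked response pattern `L`
#' from the most up-regulated probe down, the hit fraction accumulates the
#' weights `|r_j|^p` of the probes of `S` encountered so far (normalised by
#' the total hit weight), while the miss fraction accumulates uniformly over
#' the `N - N_H` probes outside `S`. The enrichment score is the signed value
#' of `P_hit - P_miss` at the position of its maximum absolute deviation from
#' zero, and lies in `[-1, 1]`: near +1 when `S` concentrates at the top of
#' `L`, near -1 when it concentrates at the bottom.
#'
#' Probes of `S` absent from `L` are dropped before scoring (their count is
#' reported via the `n_dropped` field). With `p = 0` the statistic reduces to
#' the classic unweighted Kolmogorov-Smirnov form; if every hit weight is
#' zero under `p > 0` the unweighted form is used with a warning.
#'
#' @param S character vector of probe IDs (the probe set).
#' @param pattern a [ranked_pattern()] (the list `L`).
#' @param p weight exponent on the ranking statistic (default 1).
#' @return object of class `enrichment_result`: list with `es`,
#'   `arg_position` (1-based index in `L` of the extreme deviation),
#'   `running_sum` (per-position deviations), `n_dropped`.
#' @export
enrichment_score <- function(S, pattern, p = 1) {
  stopifnot(inherits(pattern, "ranked_pattern"))
  S <- unique(as.character(S))
  hit <- pattern$probe_ids %in% S
  n_dropped <- length(S) - sum(hit)
  N <- length(pattern$probe_ids)
  NH <- sum(hit)
  if (NH == 0L)
    stop("undefined enrichment score: probe set has no member in the pattern")
  if (NH == N)
    stop("undefined enrichment score: probe set covers the whole pattern")
  res <- .es_core(pattern$stat, hit, p)
  structure(c(res, list(n_dropped = n_dropped)), class = "enrichment_result")
}

# core running-sum walk; `hit` is a logical over pattern positions
.es_core <- function(stat, hit, p) {
  w <- abs(stat)^p
  wh <- w * hit
  total <- sum(wh)
  if (total == 0) {
    if (p != 0)
      warning("all hit weights are zero; falling back to unweighted (p = 0)")
    wh <- as.numeric(hit)
    total <- sum(wh)
  }
  dev <- cumsum(wh) / total - cumsum(!hit) / (length(hit) - sum(hit))
  hi <- max(dev); lo <- min(dev)
  # a tie in |deviation| takes the positive branch; the comparison carries a
  # small tolerance so float rounding cannot flip a mathematically exact tie
  if (hi >= -lo - 1e-12) {
    list(es = hi, arg_position = which.max(dev), running_sum = dev)
  } else {
    list(es = lo, arg_position = which.min(dev), running_sum = dev)
  }
}

# fast path used by the permutation engine: hits given as integer positions
# (already mapped into this pattern), weights precomputed as |stat|^p
.es_fast <- function(w, hit_idx, N) {
  if (!length(hit_idx) || length(hit_idx) == N) return(NA_real_)
  hit <- logical(N)
  hit[hit_idx] <- TRUE
  wh <- w * hit
  total <- sum(wh)
  if (total == 0) {
    wh <- as.numeric(hit)
    total <- sum(wh)
  }
  dev <- cumsum(wh) / total - cumsum(!hit) / (N - length(hit_idx))
  hi <- max(dev); lo <- min(dev)
  if (hi >= -lo - 1e-12) hi else lo
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> ES = %.4f at position %d\n",
              x$es, x$arg_position))
  invisible(x)
}

#' Directional enrichment scores of a signature against a pattern
#'
#' Scores the up-regulated and down-regulated probe sets of a response
#' signature separately against one ranked response pattern. A direction that
#' is empty (or loses all members when intersected with the pattern) yields
#' `NA`, a null marker the total-enrichment-score combination understands.
#'
#' @param sig a [response_signature()].
#' @param pattern a [ranked_pattern()].
#' @param p weight exponent (default 1).
#' @return list with numeric scalars `es_up` and `es_down` (either may be
#'   `NA` for an empty direction).
#' @export
directional_scores <- function(sig, pattern, p = 1) {
  stopifnot(inherits(sig, "response_signature"))
  one <- function(S) {
    if (!length(S)) return(NA_real_)
    if (!any(pattern$probe_ids %in% S)) return(NA_real_)
    enrichment_score(S, pattern, p = p)$es
  }
  out <- list(es_up = one(sig$up), es_down = one(sig$down))
  if (is.na(out$es_up) && is.na(out$es_down))
    stop("both signature directions are empty after intersection with the pattern (",
         sig$perturbagen_id, ")")
  out
}
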