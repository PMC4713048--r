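#' Amplitude of differential expression
#'
#' The connectivity-map style amplitude compares one treatment value against
#' one control value on the linear scale:
#' \deqn{a = \frac{t - c}{(t + c)/2}.}
#' It is bounded in (-2, 2) and symmetric about zero: `a > 2/3` exactly when
#' `t > 2c` (at least a twofold increase) and `a < -2/3` exactly when
#' `t < c/2` (at least a twofold decrease).
#'
#' @param t,c strictly positive linear-scale expression values (vectorised).
#' @return numeric vector of amplitudes.
#' @examples
#' amplitude(2, 1)   # exactly 2/3: the twofold-increase boundary
#' amplitude(1, 2)   # exactly -2/3
#' @export
amplitude <- function(t, c) {
  if (any(!is.finite(t)) || any(!is.finite(c)) || any(t <= 0) || any(c <= 0))
    stop("amplitude requires strictly positive, finite t and c")
  (t - c) / ((t + c) / 2)
}

# internal: collapse a profile to one treatment and one control vector,
# dropping probes with missing values (listwise per probe)
.split_classes <- function(profile) {
  stopifnot(inherits(profile, "expression_profile"))
  tr <- profile$values[, profile$sample_classes == "treatment", drop = FALSE]
  ct <- profile$values[, profile$sample_classes == "control", drop = FALSE]
  list(treat = tr, control = ct)
}

#' Fold-change response signature (unreplicated designs)
#'
#' For profiles with exactly one sample per class the per-probe ratio `t/c`
#' is the differential-expression measure: probes with ratio at or above
#' `fc_threshold` are up-regulated, at or below its reciprocal
#' down-regulated. The ranked response pattern orders all probes by
#' log2-ratio, most up-regulated first.
#'
#' @param profile an [expression_profile()] with one treatment and one
#'   control sample; values strictly positive.
#' @param fc_threshold fold-change ratio cutoff (default 2).
#' @return list with elements `signature` ([response_signature()]) and
#'   `pattern` ([ranked_pattern()]).
#' @export
fold_change_signature <- function(profile, fc_threshold = 2) {
  sp <- .split_classes(profile)
  if (ncol(sp$treat) != 1L || ncol(sp$control) != 1L)
    stop("fold_change_signature requires exactly one sample per class; ",
         "use sam_signature for replicated designs")
  t <- drop(sp$treat); c <- drop(sp$control)
  if (any(t <= 0, na.rm = TRUE) || any(c <= 0, na.rm = TRUE))
    stop("fold change requires strictly positive expression values")
  keep <- !is.na(t) & !is.na(c)
  t <- t[keep]; c <- c[keep]
  probes <- rownames(profile$values)[keep]
  ratio <- t / c
  sig <- response_signature(
    profile$perturbagen_id,
    up = probes[ratio >= fc_threshold],
    down = probes[ratio <= 1 / fc_threshold],
    method = "fold_change",
    thresholds = list(fc_threshold = fc_threshold))
  list(signature = sig,
       pattern = ranked_pattern(probes, log2(ratio)))
}

#' SAM d statistic (two-class unpaired)
#'
#' Regularised t-like statistic
#' \deqn{d = \frac{\bar{x}_T - \bar{x}_C}{s + s_0}}
#' where `s` is the pooled standard error of the mean difference and `s0` a
#' fudge constant stabilising probes with tiny variance.
#'
#' @param treat,control numeric vectors with at least 2 values each.
#' @param s0 fudge constant (>= 0).
#' @return the d statistic (scalar).
#' @export
sam_d <- function(treat, control, s0 = 0) {
  if (length(treat) < 2L || length(control) < 2L)
    stop("sam_d needs >= 2 replicates per class; ",
         "use the fold-change path for unreplicated designs")
  (mean(treat) - mean(control)) / (.sam_s(treat, control) + s0)
}

.sam_s <- function(treat, control) {
  nt <- length(treat); nc <- length(control)
  pooled <- (sum((treat - mean(treat))^2) + sum((control - mean(control))^2)) /
    (nt + nc - 2)
  sqrt((1 / nt + 1 / nc) * pooled)
}

# vectorised over probe rows; returns list(d, s)
.sam_d_matrix <- function(tr, ct, s0) {
  nt <- ncol(tr); nc <- ncol(ct)
  mt <- rowMeans(tr); mc <- rowMeans(ct)
  sst <- rowSums((tr - mt)^2)
  ssc <- rowSums((ct - mc)^2)
  s <- sqrt((1 / nt + 1 / nc) * (sst + ssc) / (nt + nc - 2))
  list(d = (mt - mc) / (s + s0), s = s)
}

#' SAM response signature (replicated designs)
#'
#' Per-probe d statistics with `s0` set to the median of the per-probe
#' standard errors; the null distribution of d comes from class-label
#' permutations, and probes are called at the least stringent symmetric
#' threshold on |d| whose estimated median false discovery rate stays at or
#' below `fdr_cutoff`. Up-regulated calls have d > 0, down-regulated d < 0.
#' The ranked response pattern orders all probes by d, descending.
#'
#' When fewer than 10 distinct label permutations exist the full set is
#' enumerated (with a warning); otherwise `n_label_perms` distinct
#' assignments are sampled.
#'
#' @param profile an [expression_profile()] with >= 2 samples per class.
#' @param fdr_cutoff target median FDR (default 0.05).
#' @param n_label_perms number of label permutations for the null (default
#'   100, capped at the number of distinct assignments).
#' @param seed optional integer seed for the permutation draw.
#' @return list with `signature`, `pattern`, and `delta` (the |d| cutoff
#'   used, `Inf` when nothing is callable at the target FDR).
#' @export
sam_signature <- function(profile, fdr_cutoff = 0.05, n_label_perms = 100,
                          seed = NULL) {
  sp <- .split_classes(profile)
  tr <- sp$treat; ct <- sp$control
  if (ncol(tr) < 2L || ncol(ct) < 2L)
    stop("sam_signature needs >= 2 samples per class; ",
         "use fold_change_signature for unreplicated designs")
  keep <- stats::complete.cases(cbind(tr, ct))
  tr <- tr[keep, , drop = FALSE]; ct <- ct[keep, , drop = FALSE]
  probes <- rownames(profile$values)[keep]

  ds <- .sam_d_matrix(tr, ct, s0 = 0)
  s0 <- stats::median(ds$s)
  X <- cbind(tr, ct)
  nt <- ncol(tr); n <- ncol(X)
  d <- (rowMeans(tr) - rowMeans(ct)) / (ds$s + s0)

  combos <- utils::combn(n, nt)
  n_distinct <- ncol(combos)
  if (n_distinct < 10L) {
    warning("only ", n_distinct,
            " distinct label permutations; enumerating all of them")
    picks <- seq_len(n_distinct)
  } else if (n_distinct <= n_label_perms) {
    picks <- seq_len(n_distinct)
  } else {
    if (!is.null(seed)) set.seed(seed)
    picks <- sample.int(n_distinct, n_label_perms)
  }

  null_abs <- lapply(picks, function(k) {
    idx <- combos[, k]
    dd <- .sam_d_matrix(X[, idx, drop = FALSE],
                        X[, -idx, drop = FALSE], s0 = s0)$d
    sort(abs(dd))
  })

  # candidate thresholds: the observed |d| values; for each, the estimated
  # FDR is median_perm #{|d*| >= delta} / #{|d| >= delta}
  cand <- sort(unique(abs(d)), decreasing = TRUE)
  obs_sorted <- sort(abs(d))
  n_obs <- length(d)
  called <- n_obs - findInterval(cand, obs_sorted, left.open = TRUE)
  null_counts <- vapply(null_abs, function(x)
    n_obs - findInterval(cand, x, left.open = TRUE),
    numeric(length(cand)))
  null_counts <- matrix(null_counts, nrow = length(cand))
  fdr <- pmin(1, apply(null_counts, 1L, stats::median) / pmax(called, 1L))

  ok <- which(fdr <= fdr_cutoff)
  if (length(ok)) {
    delta <- cand[max(ok)]  # least stringent cutoff still meeting the FDR
    call_mask <- abs(d) >= delta
  } else {
    delta <- Inf
    call_mask <- rep(FALSE, n_obs)
  }
  sig <- response_signature(
    profile$perturbagen_id,
    up = probes[call_mask & d > 0],
    down = probes[call_mask & d < 0],
    method = "sam",
    thresholds = list(fdr_cutoff = fdr_cutoff, delta = delta, s0 = s0))
  list(signature = sig, pattern = ranked_pattern(probes, d), delta = delta)
}

#' Amplitude response signature (one treatment/control vector pair)
#'
#' Converts every probe to its [amplitude()] and calls probes with
#' `a > amp_threshold` up-regulated and `a < -amp_threshold` down-regulated.
#' The default threshold 2/3 corresponds to a twofold expression change. The
#' ranked response pattern orders all probes by amplitude, descending.
#'
#' @param profile an [expression_profile()] with one treatment and one
#'   control sample; values strictly positive.
#' @param amp_threshold amplitude cutoff (default 2/3).
#' @return list with `signature` and `pattern`, as [fold_change_signature()].
#' @export
amplitude_signature <- function(profile, amp_threshold = 2 / 3) {
  sp <- .split_classes(profile)
  if (ncol(sp$treat) != 1L || ncol(sp$control) != 1L)
    stop("amplitude_signature requires exactly one sample per class")
  t <- drop(sp$treat); c <- drop(sp$control)
  keep <- !is.na(t) & !is.na(c)
  t <- t[keep]; c <- c[keep]
  probes <- rownames(profile$values)[keep]
  a <- amplitude(t, c)
  sig <- response_signature(
    profile$perturbagen_id,
    up = probes[a > amp_threshold],
    down = probes[a < -amp_threshold],
    method = "amplitude",
    thresholds = list(amp_threshold = amp_threshold))
  list(signature = sig, pattern = ranked_pattern(probes, a))
}

#' Build a response signature, dispatching on design and perturbagen kind
#'
#' Replicated designs (>= 2 samples in each class) take the SAM path.
#' Unreplicated small-molecule instances take the amplitude path (the
#' convention for connectivity-map instances); unreplicated miRNA
#' transfections take the fold-change path.
#'
#' @param profile an [expression_profile()].
#' @param fc_threshold,sam_fdr,amp_threshold method cutoffs.
#' @param n_label_perms,seed passed to [sam_signature()].
#' @return list with `signature`, `pattern`, and `method`.
#' @export
build_signature <- function(profile, fc_threshold = 2, sam_fdr = 0.05,
                            amp_threshold = 2 / 3, n_label_perms = 100,
                            seed = NULL) {
  nt <- sum(profile$sample_classes == "treatment")
  nc <- sum(profile$sample_classes == "control")
  if (nt >= 2L && nc >= 2L) {
    out <- sam_signature(profile, fdr_cutoff = sam_fdr,
                         n_label_perms = n_label_perms, seed = seed)
    out$method <- "sam"
  } else if (profile$perturbagen_kind == "small_molecule") {
    out <- .collapse_and_apply(profile, amplitude_signature,
                               amp_threshold = amp_threshold)
    out$method <- "amplitude"
  } else {
    out <- .collapse_and_apply(profile, fold_change_signature,
                               fc_threshold = fc_threshold)
    out$method <- "fold_change"
  }
  out
}

# 1-vs-many designs: average the replicated class before a 1v1 method
.collapse_and_apply <- function(profile, fn, ...) {
  sp <- .split_classes(profile)
  if (ncol(sp$treat) > 1L || ncol(sp$control) > 1L) {
    values <- cbind(treatment = rowMeans(sp$treat),
                    control = rowMeans(sp$control))
    profile <- expression_profile(values, c("treatment", "control"),
                                  profile$perturbagen_id,
                                  profile$perturbagen_kind,
                                  profile$condition, profile$source_id,
                                  profile$instance_id)
  }
  fn(profile, ...)
}
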