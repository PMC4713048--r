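# Independent brute-force oracles. These deliberately share no code with the
# package: every quantity is accumulated by explicit position-by-position
# loops so they can certify the vectorised implementations.

# enrichment score by explicit cumulative walk
oracle_es <- function(S, probe_ids, stat, p = 1) {
  hit <- probe_ids %in% S
  N <- length(probe_ids)
  NH <- sum(hit)
  stopifnot(NH > 0L, NH < N)
  wsum <- 0
  for (i in seq_len(N)) if (hit[i]) wsum <- wsum + abs(stat[i])^p
  unweighted <- wsum == 0
  ph <- 0; pm <- 0
  best <- 0; best_abs <- -1; best_pos <- NA_integer_
  for (i in seq_len(N)) {
    if (hit[i]) {
      ph <- ph + (if (unweighted) 1 / NH else abs(stat[i])^p / wsum)
    } else {
      pm <- pm + 1 / (N - NH)
    }
    dev <- ph - pm
    better <- abs(dev) > best_abs + 1e-12 ||
      (abs(abs(dev) - best_abs) <= 1e-12 && dev > best)
    if (better) { best <- dev; best_abs <- abs(dev); best_pos <- i }
  }
  list(es = best, arg_position = best_pos)
}

# KS-type association score by explicit evaluation of both maxima
oracle_ks <- function(V, n) {
  t <- length(V)
  a <- -Inf; b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - V[j] / n)
    b <- max(b, V[j] / n - (j - 1) / t)
  }
  if (a >= b) a else -b
}

# supremum distance of a sample from the U(0, 1) cdf
ks_dist_uniform <- function(x) {
  x <- sort(x)
  n <- length(x)
  i <- seq_len(n)
  max(i / n - x, x - (i - 1) / n)
}

# small deterministic profile from explicit treatment/control vectors
make_profile_1v1 <- function(t, c, id = "pert", kind = "small_molecule",
                             probes = sprintf("p%02d", seq_along(t))) {
  m <- cbind(T1 = t, C1 = c)
  rownames(m) <- probes
  expression_profile(m, c("treatment", "control"), id, kind)
}

make_profile_rep <- function(treat, control, id = "pert", kind = "miRNA",
                             probes = sprintf("p%03d", seq_len(nrow(treat)))) {
  m <- cbind(treat, control)
  colnames(m) <- c(sprintf("T%d", seq_len(ncol(treat))),
                   sprintf("C%d", seq_len(ncol(control))))
  rownames(m) <- probes
  expression_profile(m, c(rep("treatment", ncol(treat)),
                          rep("control", ncol(control))), id, kind)
}
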