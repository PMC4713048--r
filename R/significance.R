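#' Draw a size-matched random response signature from a pattern
#'
#' Samples `n_up + n_down` probes uniformly without replacement from the
#' pattern's probe universe and splits them into disjoint up and down sets of
#' exactly the requested sizes. This is the permutation-null analogue of a
#' real signature: membership is random but the signature sizes are kept
#' unchanged.
#'
#' @param pattern a [ranked_pattern()] providing the probe universe.
#' @param n_up,n_down set sizes (non-negative; their sum must not exceed the
#'   universe size).
#' @return a [response_signature()] with `method = "permuted"`. Uses the
#'   current RNG state; seed upstream for reproducibility.
#' @export
permute_signature <- function(pattern, n_up, n_down) {
  stopifnot(inherits(pattern, "ranked_pattern"))
  N <- length(pattern$probe_ids)
  if (n_up < 0L || n_down < 0L || n_up + n_down > N)
    stop("requested signature sizes exceed the pattern's probe universe")
  idx <- sample.int(N, n_up + n_down)
  response_signature("random",
                     up = pattern$probe_ids[idx[seq_len(n_up)]],
                     down = pattern$probe_ids[idx[seq_len(n_down) + n_up]],
                     method = "permuted")
}

#' Empirical p-value from a permutation null
#'
#' The fraction of null scores whose absolute value strictly exceeds the
#' absolute observed score. With `add_one = TRUE` the (obs+1)/(perm+1)
#' correction is applied so the minimum attainable p is positive.
#'
#' @param observed observed association score.
#' @param null_scores numeric vector of null scores.
#' @param add_one apply add-one smoothing (default `FALSE`).
#' @return p-value in `[0, 1]`.
#' @export
permutation_pvalue <- function(observed, null_scores, add_one = FALSE) {
  if (!length(null_scores)) stop("null_scores must be non-empty")
  k <- sum(abs(null_scores) > abs(observed))
  if (add_one) (k + 1) / (length(null_scores) + 1) else k / length(null_scores)
}

#' Permutation test for one molecule / miRNA-profile association
#'
#' For each permutation round, the miRNA signature and each of the focal
#' molecule's instance signatures are replaced by size-matched random
#' signatures drawn from their own ranked patterns ([permute_signature()]),
#' the focal instances' total enrichment scores are recomputed, the full
#' instance ranking is rebuilt with all non-focal instances held at their
#' observed scores, and the focal molecule's association score is
#' re-derived. The p-value is the fraction of the `n_perm` random scores
#' whose absolute value exceeds the observed one.
#'
#' The per-pair RNG stream is seeded from a hash of
#' `(seed, molecule_id, mirna_profile_id)`, so each pair is reproducible in
#' isolation and independent of processing order.
#'
#' @param molecule_id focal molecule.
#' @param mir list with `signature` and `pattern` for the miRNA profile.
#' @param mol_instances list of the focal molecule's instances, each a list
#'   with `signature`, `pattern`, `instance_id`.
#' @param tes_table observed instance-score table for this miRNA profile
#'   (all molecules), as produced by [pair_tes()] rows.
#' @param n_perm number of permutations (default 1000).
#' @param seed global integer seed.
#' @param rank_by `"signed"` or `"absolute"` instance ranking.
#' @param p weight exponent for the enrichment scores.
#' @param add_one passed to [permutation_pvalue()].
#' @return object of class `permutation_result`: list with `observed_as`,
#'   `null_as` (length `n_perm`), `p_value`, `n_perm`, `seed`.
#' @export
run_permutation_test <- function(molecule_id, mir, mol_instances, tes_table,
                                 n_perm = 1000, seed = 1,
                                 rank_by = c("signed", "absolute"), p = 1,
                                 add_one = FALSE) {
  rank_by <- match.arg(rank_by)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  observed <- associate(tes_table, molecule_id, rank_by = rank_by)

  N_m <- length(mir$pattern$probe_ids)
  w_mir <- abs(mir$pattern$stat)^p
  n_up_m <- length(mir$signature$up)
  n_down_m <- length(mir$signature$down)

  inst <- lapply(mol_instances, function(it) {
    list(N = length(it$pattern$probe_ids),
         w = abs(it$pattern$stat)^p,
         n_up = length(it$signature$up),
         n_down = length(it$signature$down),
         sm2mir = match(it$pattern$probe_ids, mir$pattern$probe_ids),
         mir2sm = match(mir$pattern$probe_ids, it$pattern$probe_ids))
  })
  focal_rows <- which(tes_table$molecule_id == molecule_id)
  if (length(focal_rows) != length(inst))
    stop("instance list and score table disagree for molecule ", molecule_id)
  base_tes <- tes_table$tes
  mol_key <- tes_table$molecule_id
  inst_key <- tes_table$instance_id
  n_all <- length(base_tes)
  t_focal <- length(focal_rows)

  map_hits <- function(map, idx) {
    m <- map[idx]
    m[!is.na(m)]
  }
  seed_pair <- .string_seed(seed, molecule_id,
                            mir$signature$perturbagen_id)
  set.seed(seed_pair)
  null_as <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    midx <- sample.int(N_m, n_up_m + n_down_m)
    up_m <- midx[seq_len(n_up_m)]
    down_m <- midx[seq_len(n_down_m) + n_up_m]
    tes_new <- base_tes
    for (k in seq_along(inst)) {
      it <- inst[[k]]
      sidx <- sample.int(it$N, it$n_up + it$n_down)
      up_s <- sidx[seq_len(it$n_up)]
      down_s <- sidx[seq_len(it$n_down) + it$n_up]
      es_u_s2m <- .es_fast(w_mir, map_hits(it$sm2mir, up_s), N_m)
      es_d_s2m <- .es_fast(w_mir, map_hits(it$sm2mir, down_s), N_m)
      es_u_m2s <- .es_fast(it$w, map_hits(it$mir2sm, up_m), it$N)
      es_d_m2s <- .es_fast(it$w, map_hits(it$mir2sm, down_m), it$N)
      tes_new[focal_rows[k]] <-
        (total_es(es_u_s2m, es_d_s2m) + total_es(es_u_m2s, es_d_m2s)) / 2
    }
    key <- if (rank_by == "absolute") -abs(tes_new) else -tes_new
    o <- order(key, mol_key, inst_key, method = "radix")
    V <- sort(match(focal_rows, o))
    j <- seq_len(t_focal)
    a <- max(j / t_focal - V / n_all)
    bb <- max(V / n_all - (j - 1) / t_focal)
    null_as[b] <- if (a >= bb) a else -bb
  }
  structure(
    list(observed_as = observed$as_score,
         null_as = null_as,
         p_value = permutation_pvalue(observed$as_score, null_as,
                                      add_one = add_one),
         n_perm = n_perm, seed = seed),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> AS = %.4f, p = %.4g (%d permutations)\n",
              x$observed_as, x$p_value, x$n_perm))
  invisible(x)
}
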