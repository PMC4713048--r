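#' Combine directional enrichment scores into a total enrichment score
#'
#' A perturbation's up and down probe sets should fall on opposite ends of a
#' related pattern: the combination therefore only credits sign-opposed
#' directional scores, `tes = (es_up - es_down)/2`, and returns 0 when the
#' two scores share a sign (no coherent placement). When one direction is
#' null (`NA`, an empty probe set) the surviving score carries the whole
#' signal: `tes = es_up/2` or `tes = -es_down/2`. The result lies in
#' `[-1, 1]`; positive values mean the signature mimics the pattern's
#' perturbation, negative values mean it reverses it.
#'
#' @param es_up,es_down directional enrichment scores in `[-1, 1]`, or `NA`
#'   for an empty direction. Both `NA` is an error (the pair is not
#'   scoreable).
#' @return the combined score (scalar).
#' @export
total_es <- function(es_up, es_down) {
  if (is.na(es_up) && is.na(es_down))
    stop("both directional scores are null; pair not scoreable")
  if (is.na(es_down)) return(es_up / 2)
  if (is.na(es_up)) return(-es_down / 2)
  if (sign(es_up) != sign(es_down)) (es_up - es_down) / 2 else 0
}

#' Score one molecule instance against one miRNA profile
#'
#' Computes the four directional enrichment scores — the molecule signature's
#' up and down sets walked along the miRNA's ranked pattern (`sm2mir`), and
#' the miRNA signature's up and down sets walked along the molecule
#' instance's pattern (`mir2sm`) — combines each direction pair with
#' [total_es()], and averages the two combined scores into the instance's
#' total enrichment score. Probe universes are intersected at scoring time:
#' signature members absent from the opposing pattern are dropped.
#'
#' @param sm list with `signature` and `pattern` for the molecule instance.
#' @param mir list with `signature` and `pattern` for the miRNA profile.
#' @param p weight exponent (default 1).
#' @param molecule_id,instance_id,mirna_profile_id identifiers stored in the
#'   result (default: taken from the signatures).
#' @return object of class `instance_tes`: one-row data frame with the four
#'   directional scores, `tes_sm2mir`, `tes_mir2sm` and their mean `tes`.
#' @export
pair_tes <- function(sm, mir, p = 1,
                     molecule_id = sm$signature$perturbagen_id,
                     instance_id = NA_character_,
                     mirna_profile_id = mir$signature$perturbagen_id) {
  if (!any(mir$pattern$probe_ids %in% sm$pattern$probe_ids))
    stop("no probe overlap between ", molecule_id, " and ", mirna_profile_id)
  sm2mir <- tryCatch(directional_scores(sm$signature, mir$pattern, p = p),
                     error = function(e)
                       stop("molecule signature ", molecule_id,
                            " is not scoreable against miRNA pattern ",
                            mirna_profile_id, ": ", conditionMessage(e)))
  mir2sm <- tryCatch(directional_scores(mir$signature, sm$pattern, p = p),
                     error = function(e)
                       stop("miRNA signature ", mirna_profile_id,
                            " is not scoreable against molecule pattern ",
                            molecule_id, ": ", conditionMessage(e)))
  tes_sm2mir <- total_es(sm2mir$es_up, sm2mir$es_down)
  tes_mir2sm <- total_es(mir2sm$es_up, mir2sm$es_down)
  out <- data.frame(
    molecule_id = molecule_id,
    instance_id = as.character(instance_id),
    mirna_profile_id = mirna_profile_id,
    es_up_sm2mir = sm2mir$es_up, es_down_sm2mir = sm2mir$es_down,
    es_up_mir2sm = mir2sm$es_up, es_down_mir2sm = mir2sm$es_down,
    tes_sm2mir = tes_sm2mir, tes_mir2sm = tes_mir2sm,
    tes = (tes_sm2mir + tes_mir2sm) / 2,
    stringsAsFactors = FALSE)
  class(out) <- c("instance_tes", class(out))
  out
}

#' KS-type association score from instance rank positions
#'
#' Given the rank positions `V(1) < ... < V(t)` that one molecule's `t`
#' instances occupy within the ranking of all `n` scored instances (rank 1 =
#' largest total enrichment score), the two one-sided Kolmogorov-Smirnov
#' deviations are
#' \deqn{a = \max_j \left( \frac{j}{t} - \frac{V(j)}{n} \right), \qquad
#'       b = \max_j \left( \frac{V(j)}{n} - \frac{j-1}{t} \right),}
#' and the association score is `a` when `a >= b`, else `-b`. Scores near +1
#' mean the molecule's instances cluster at the top of the ranking
#' (expression mimicry); near -1, at the bottom (expression reversal).
#'
#' @param V strictly increasing integer positions in `1..n`.
#' @param n total number of ranked instances.
#' @return association score in `(-1, 1)`.
#' @export
ks_association <- function(V, n) {
  t <- length(V)
  if (t < 1L || n < t) stop("need 1 <= length(V) <= n")
  if (any(V != as.integer(V)) || any(V < 1L) || any(V > n))
    stop("positions must be integers in 1..n")
  if (anyDuplicated(V) || is.unsorted(V, strictly = TRUE))
    stop("positions must be strictly increasing and unique")
  j <- seq_len(t)
  a <- max(j / t - V / n)
  b <- max(V / n - (j - 1) / t)
  if (a >= b) a else -b
}

#' Aggregate a molecule's instance scores into an association record
#'
#' Ranks every scored instance for one miRNA profile by total enrichment
#' score in decreasing order (`rank_by = "signed"`, the default) or by
#' absolute value (`rank_by = "absolute"`); ties are broken by
#' `(molecule_id, instance_id)` lexicographically. The focal molecule's
#' positions feed [ks_association()].
#'
#' @param tes_table data frame of instance scores for one miRNA profile
#'   (the union of [pair_tes()] rows across all molecules and instances).
#' @param molecule_id the molecule to aggregate.
#' @param rank_by `"signed"` or `"absolute"`.
#' @return list with `molecule_id`, `as_score`, `n_instances` (t), `n`
#'   (total), and `positions` (V).
#' @export
associate <- function(tes_table, molecule_id, rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  if (!molecule_id %in% tes_table$molecule_id)
    stop("molecule ", molecule_id, " has no scored instances")
  key <- if (rank_by == "absolute") -abs(tes_table$tes) else -tes_table$tes
  o <- order(key, tes_table$molecule_id, tes_table$instance_id,
             method = "radix")
  V <- sort(which(tes_table$molecule_id[o] == molecule_id))
  list(molecule_id = molecule_id,
       as_score = ks_association(V, nrow(tes_table)),
       n_instances = length(V),
       n = nrow(tes_table),
       positions = V)
}

#' Association scores for every molecule in an instance table
#'
#' @inheritParams associate
#' @return data frame with one row per molecule: `molecule_id`, `AS`,
#'   `n_instances`, ordered by molecule ID.
#' @export
associate_all <- function(tes_table, rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  mols <- sort(unique(tes_table$molecule_id))
  rows <- lapply(mols, function(m) {
    r <- associate(tes_table, m, rank_by = rank_by)
    data.frame(molecule_id = m, AS = r$as_score,
               n_instances = r$n_instances, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
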