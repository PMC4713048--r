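#' Build signatures and patterns for every profile in a cohort
#'
#' Applies [build_signature()] (fold change / SAM / amplitude, dispatched on
#' replicate structure and perturbagen kind) to the miRNA profile and every
#' molecule instance of a synthetic or assembled cohort.
#'
#' @param cohort a cohort as returned by [generate_cohort()], or any list
#'   with fields `mirna` (an [expression_profile()]) and `molecules` (named
#'   list of instance-profile lists).
#' @param fc_threshold,sam_fdr,amp_threshold,n_label_perms,seed passed to
#'   [build_signature()].
#' @return list with `mir` (list: `signature`, `pattern`, `profile_id`) and
#'   `molecules` (named list; each element a list of instances, each with
#'   `signature`, `pattern`, `instance_id`).
#' @export
build_cohort_signatures <- function(cohort, fc_threshold = 2, sam_fdr = 0.05,
                                    amp_threshold = 2 / 3,
                                    n_label_perms = 100, seed = NULL) {
  mir_built <- build_signature(cohort$mirna, fc_threshold = fc_threshold,
                               sam_fdr = sam_fdr,
                               amp_threshold = amp_threshold,
                               n_label_perms = n_label_perms, seed = seed)
  mols <- lapply(cohort$molecules, function(instances)
    lapply(instances, function(prof) {
      built <- build_signature(prof, fc_threshold = fc_threshold,
                               sam_fdr = sam_fdr,
                               amp_threshold = amp_threshold,
                               n_label_perms = n_label_perms, seed = seed)
      built$instance_id <- prof$instance_id
      built
    }))
  list(mir = list(signature = mir_built$signature,
                  pattern = mir_built$pattern,
                  profile = cohort$mirna),
       molecules = mols)
}

#' Instance-score table for one miRNA profile
#'
#' Runs [pair_tes()] for every molecule instance against the miRNA profile.
#' Instances whose signatures are not scoreable (both directions empty) are
#' skipped with a warning.
#'
#' @param built output of [build_cohort_signatures()].
#' @param p weight exponent.
#' @return data frame of instance scores (one row per scored instance).
#' @export
score_instances <- function(built, p = 1) {
  mir <- built$mir
  rows <- list()
  for (mol in names(built$molecules)) {
    for (it in built$molecules[[mol]]) {
      row <- tryCatch(
        pair_tes(it, mir, p = p, molecule_id = mol,
                 instance_id = it$instance_id,
                 mirna_profile_id = mir$signature$perturbagen_id),
        error = function(e) {
          warning("skipping ", mol, "/", it$instance_id, ": ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) stop("no scoreable instances for miRNA profile ",
                          mir$signature$perturbagen_id)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score a cohort end to end
#'
#' Builds signatures, computes the instance score table, aggregates each
#' molecule's instances into an association score, and attaches a
#' permutation p-value per molecule. The association table is sorted by
#' p-value, then by |AS| descending.
#'
#' @param cohort a cohort (see [build_cohort_signatures()]).
#' @param p weight exponent (default 1).
#' @param rank_by instance-ranking convention (`"signed"` default).
#' @param n_perm permutations per molecule/miRNA pair (default 1000).
#' @param seed global integer seed for the permutation streams.
#' @param alpha significance level used to flag records (default 0.05).
#' @param bh append a Benjamini-Hochberg adjusted p column (default FALSE).
#' @param add_one add-one smoothing of p-values (default FALSE).
#' @param fc_threshold,sam_fdr,amp_threshold signature cutoffs.
#' @return list with `associations` (data frame), `tes_table`, `built`.
#' @export
score_cohort <- function(cohort, p = 1, rank_by = c("signed", "absolute"),
                         n_perm = 1000, seed = 1, alpha = 0.05, bh = FALSE,
                         add_one = FALSE, fc_threshold = 2, sam_fdr = 0.05,
                         amp_threshold = 2 / 3) {
  rank_by <- match.arg(rank_by)
  built <- build_cohort_signatures(cohort, fc_threshold = fc_threshold,
                                   sam_fdr = sam_fdr,
                                   amp_threshold = amp_threshold,
                                   seed = seed)
  mols <- names(built$molecules)
  fda <- stats::setNames(
    as.logical(cohort$catalogue$fda_approved[
      match(mols, cohort$catalogue$perturbagen_id)]), mols)
  res <- score_built(built, fda = fda, source_id = cohort$mirna$source_id,
                     condition = cohort$mirna$condition, p = p,
                     rank_by = rank_by, n_perm = n_perm, seed = seed,
                     alpha = alpha, bh = bh, add_one = add_one)
  res$built <- built
  res
}

#' Score an already-built signature set against one miRNA profile
#'
#' The workhorse behind [score_cohort()] and the command-line `score`
#' subcommand: takes signatures and patterns that are already built (e.g.
#' read back from GMT/RNK files) and produces the association table.
#'
#' @param built list with `mir` (list: `signature`, `pattern`) and
#'   `molecules` (named list of instance lists with `signature`, `pattern`,
#'   `instance_id`), as from [build_cohort_signatures()].
#' @param fda named logical vector of FDA-approval flags per molecule
#'   (optional).
#' @param source_id,condition provenance fields copied into every record.
#' @inheritParams score_cohort
#' @return list with `associations` and `tes_table`.
#' @export
score_built <- function(built, fda = NULL, source_id = "", condition = "",
                        p = 1, rank_by = c("signed", "absolute"),
                        n_perm = 1000, seed = 1, alpha = 0.05, bh = FALSE,
                        add_one = FALSE) {
  rank_by <- match.arg(rank_by)
  tes_table <- score_instances(built, p = p)
  mols <- sort(unique(tes_table$molecule_id))
  recs <- lapply(mols, function(m) {
    scored_ids <- tes_table$instance_id[tes_table$molecule_id == m]
    insts <- Filter(function(it) it$instance_id %in% scored_ids,
                    built$molecules[[m]])
    pt <- run_permutation_test(
      m, built$mir, insts, tes_table,
      n_perm = n_perm, seed = seed, rank_by = rank_by, p = p,
      add_one = add_one)
    data.frame(small_molecule = m,
               fda_approved = isTRUE(fda[[m]]),
               mirna = built$mir$signature$perturbagen_id,
               source_id = source_id,
               condition = condition,
               AS = pt$observed_as,
               p_value = pt$p_value,
               n_instances = sum(tes_table$molecule_id == m),
               stringsAsFactors = FALSE)
  })
  assoc <- do.call(rbind, recs)
  assoc$significant <- assoc$p_value < alpha
  if (bh) assoc$p_bh <- stats::p.adjust(assoc$p_value, method = "BH")
  assoc <- assoc[order(assoc$p_value, -abs(assoc$AS), assoc$small_molecule), ]
  rownames(assoc) <- NULL
  list(associations = assoc, tes_table = tes_table)
}
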