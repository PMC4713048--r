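#' Simulation design for synthetic perturbation cohorts
#'
#' Describes a synthetic study: one miRNA-transfection experiment plus a
#' cohort of small molecules, each with several independent "instances"
#' (treatment/control profile pairs). Expression is log-normal: per-probe
#' baselines are drawn on the log2 scale from Normal(7, 1), planted signature
#' probes are shifted by `effect` log2 units in the treatment class (up
#' probes +effect, down probes -effect), each sample gets independent
#' Normal(0, `noise_sd`) log-scale noise, and values are exponentiated back
#' to the linear scale. This makes fold-change and amplitude behaviour
#' analytically predictable.
#'
#' The defaults describe a cohort of 20 molecules with 3 instances each over
#' a 1000-probe universe, planted signatures of 50 up and 50 down probes, a
#' 3-log2-unit effect and 0.3 log2 units of sample noise — a clearly
#' separated signal in an unreplicated design.
#'
#' @param n_probes probe universe size.
#' @param n_up,n_down planted signature sizes.
#' @param effect mean log2-scale shift of planted probes in treatment (>= 0).
#' @param noise_sd log2-scale per-sample noise standard deviation (> 0).
#' @param replicates samples per class in the miRNA experiment (1 routes to
#'   the fold-change path, >= 2 to the SAM path).
#' @param relation relationship of the planted molecule to the miRNA:
#'   `"mimic"` (same probes, same directions), `"reversal"` (same probes,
#'   opposite directions), `"null"` (independent random signature).
#' @param overlap fraction of the miRNA signature reused by the planted
#'   molecule (0..1).
#' @param n_instances instances per molecule.
#' @param n_molecules molecules in the cohort.
#' @param seed integer seed.
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(n_probes = 1000, n_up = 50, n_down = 50,
                              effect = 3, noise_sd = 0.3, replicates = 1,
                              relation = c("null", "mimic", "reversal"),
                              overlap = 1, n_instances = 3, n_molecules = 20,
                              seed = 1) {
  relation <- match.arg(relation)
  if (n_up + n_down > n_probes)
    stop("planted signature sizes exceed the probe universe")
  if (overlap < 0 || overlap > 1) stop("overlap must lie in [0, 1]")
  if (effect < 0) stop("effect must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (replicates < 1 || n_instances < 1 || n_molecules < 1)
    stop("replicates, n_instances and n_molecules must be >= 1")
  structure(
    list(n_probes = as.integer(n_probes), n_up = as.integer(n_up),
         n_down = as.integer(n_down), effect = effect, noise_sd = noise_sd,
         replicates = as.integer(replicates), relation = relation,
         overlap = overlap, n_instances = as.integer(n_instances),
         n_molecules = as.integer(n_molecules), seed = as.integer(seed)),
    class = "simulation_design")
}

.probe_ids <- function(n) sprintf("P%06d", seq_len(n))

# one treatment/control profile with planted shifts; RNG state is consumed
.simulate_profile <- function(design, planted_up, planted_down, id, kind,
                              n_treat, n_control, condition = "",
                              instance_id = NA_character_) {
  probes <- .probe_ids(design$n_probes)
  baseline <- stats::rnorm(design$n_probes, mean = 7, sd = 1)
  shift <- numeric(design$n_probes)
  shift[match(planted_up, probes)] <- design$effect
  shift[match(planted_down, probes)] <- -design$effect
  n_samp <- n_treat + n_control
  noise <- matrix(stats::rnorm(design$n_probes * n_samp, sd = design$noise_sd),
                  nrow = design$n_probes)
  logex <- baseline + noise
  logex[, seq_len(n_treat)] <- logex[, seq_len(n_treat), drop = FALSE] + shift
  values <- 2^logex
  colnames(values) <- c(sprintf("T%d", seq_len(n_treat)),
                        sprintf("C%d", seq_len(n_control)))
  rownames(values) <- probes
  expression_profile(values,
                     c(rep("treatment", n_treat), rep("control", n_control)),
                     perturbagen_id = id, perturbagen_kind = kind,
                     condition = condition, source_id = "SIM",
                     instance_id = instance_id)
}

#' Generate a synthetic miRNA-transfection experiment
#'
#' @param design a [simulation_design()].
#' @param mirna_id identifier for the synthetic miRNA.
#' @param seed integer seed, or `NULL` to consume the current RNG state
#'   (used when the call is part of a larger seeded generation).
#' @return an [expression_profile()]; the planted ground truth is attached as
#'   attributes `planted_up` and `planted_down`.
#' @export
generate_mirna_experiment <- function(design, mirna_id = "miR-sim-1",
                                      seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  if (!is.null(seed)) set.seed(seed)
  probes <- .probe_ids(design$n_probes)
  planted <- sample(probes, design$n_up + design$n_down)
  up <- planted[seq_len(design$n_up)]
  down <- planted[seq_len(design$n_down) + design$n_up]
  prof <- .simulate_profile(design, up, down, mirna_id, "miRNA",
                            n_treat = design$replicates,
                            n_control = design$replicates,
                            condition = "transfection")
  attr(prof, "planted_up") <- up
  attr(prof, "planted_down") <- down
  prof
}

#' Generate the instance profiles of one synthetic small molecule
#'
#' Plants a molecule signature related to a miRNA signature per the design:
#' `"mimic"` reuses `overlap * |set|` of the miRNA's planted probes in the
#' same directions, `"reversal"` in the opposite directions, `"null"` uses a
#' random signature disjoint from the miRNA's. Remaining planted slots are
#' filled with fresh random probes. All instances share the planted sets and
#' differ only in baseline and noise realisations; each instance is one
#' treatment plus one control sample (the unreplicated instance design).
#'
#' @param design a [simulation_design()].
#' @param mirna_signature a [response_signature()] holding the miRNA's
#'   planted (or called) up/down sets.
#' @param molecule_id identifier for the molecule.
#' @param relation override of `design$relation` (used by the cohort
#'   generator, where only one molecule carries the planted relation).
#' @param seed integer seed, or `NULL` to consume the current RNG state.
#' @return list of [expression_profile()] of length `design$n_instances`,
#'   with attributes `planted_up`/`planted_down` on the list.
#' @export
generate_molecule_instances <- function(design, mirna_signature,
                                        molecule_id = "SM0001",
                                        relation = design$relation,
                                        seed = NULL) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(mirna_signature, "response_signature"))
  relation <- match.arg(relation, c("null", "mimic", "reversal"))
  if (!is.null(seed)) set.seed(seed)
  probes <- .probe_ids(design$n_probes)
  mir_all <- c(mirna_signature$up, mirna_signature$down)
  k_up <- round(design$overlap * length(mirna_signature$up))
  k_down <- round(design$overlap * length(mirna_signature$down))
  if (k_up > design$n_up || k_down > design$n_down)
    stop("overlap demands more planted probes than the molecule signature holds")
  if (relation == "mimic") {
    core_up <- mirna_signature$up[seq_len(k_up)]
    core_down <- mirna_signature$down[seq_len(k_down)]
  } else if (relation == "reversal") {
    core_up <- mirna_signature$down[seq_len(k_down)]
    core_down <- mirna_signature$up[seq_len(k_up)]
  } else {
    core_up <- character(0)
    core_down <- character(0)
  }
  pool <- setdiff(probes, union(mir_all, c(core_up, core_down)))
  need <- (design$n_up - length(core_up)) + (design$n_down - length(core_down))
  if (need > length(pool))
    stop("probe universe too small for a disjoint molecule signature")
  fresh <- sample(pool, need)
  up <- c(core_up, fresh[seq_len(design$n_up - length(core_up))])
  down <- c(core_down,
            fresh[seq_len(design$n_down - length(core_down)) +
                    (design$n_up - length(core_up))])
  out <- lapply(seq_len(design$n_instances), function(i)
    .simulate_profile(design, up, down, molecule_id, "small_molecule",
                      n_treat = 1L, n_control = 1L,
                      condition = sprintf("instance %d", i),
                      instance_id = sprintf("i%d", i)))
  attr(out, "planted_up") <- up
  attr(out, "planted_down") <- down
  out
}

#' Generate a full synthetic cohort
#'
#' One miRNA-transfection experiment plus `n_molecules` small molecules with
#' `n_instances` instances each. When `design$relation` is `"mimic"` or
#' `"reversal"` the first molecule carries that planted relation to the
#' miRNA; every other molecule is null (its own random signature). The
#' catalogue lists one row per molecule instance plus one for the miRNA.
#'
#' @param design a [simulation_design()].
#' @param mirna_id identifier for the synthetic miRNA.
#' @return list with `design`, `mirna` (profile with planted attributes),
#'   `mirna_truth` (planted [response_signature()]), `molecules` (named list
#'   of instance-profile lists), `planted_molecule` (ID or `NA`), and
#'   `catalogue` (data frame).
#' @export
generate_cohort <- function(design, mirna_id = "miR-sim-1") {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  mirna <- generate_mirna_experiment(design, mirna_id, seed = NULL)
  truth <- response_signature(mirna_id,
                              up = attr(mirna, "planted_up"),
                              down = attr(mirna, "planted_down"),
                              method = "planted")
  ids <- sprintf("SM%04d", seq_len(design$n_molecules))
  planted_molecule <- if (design$relation == "null") NA_character_ else ids[1L]
  molecules <- lapply(seq_along(ids), function(k) {
    rel <- if (!is.na(planted_molecule) && k == 1L) design$relation else "null"
    generate_molecule_instances(design, truth, molecule_id = ids[k],
                                relation = rel, seed = NULL)
  })
  names(molecules) <- ids
  cat_rows <- do.call(rbind, lapply(ids, function(m)
    data.frame(perturbagen_id = m, kind = "small_molecule",
               condition = sprintf("instance %d", seq_len(design$n_instances)),
               source_id = "SIM", fda_approved = "FALSE",
               stringsAsFactors = FALSE)))
  catalogue <- rbind(
    cat_rows,
    data.frame(perturbagen_id = mirna_id, kind = "miRNA",
               condition = "transfection", source_id = "SIM",
               fda_approved = "FALSE", stringsAsFactors = FALSE))
  list(design = design, mirna = mirna, mirna_truth = truth,
       molecules = molecules, planted_molecule = planted_molecule,
       catalogue = catalogue)
}
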