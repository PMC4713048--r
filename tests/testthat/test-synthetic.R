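test_that("generators are bit-identical under a fixed seed", {
  d <- simulation_design(n_probes = 200, seed = 123)
  p1 <- generate_mirna_experiment(d)
  p2 <- generate_mirna_experiment(d)
  expect_identical(p1$values, p2$values)
  expect_identical(attr(p1, "planted_up"), attr(p2, "planted_up"))
  c1 <- generate_cohort(d)
  c2 <- generate_cohort(d)
  expect_identical(c1$molecules[["SM0003"]][[2]]$values,
                   c2$molecules[["SM0003"]][[2]]$values)
})

test_that("a zero effect leaves planted probes indistinguishable", {
  d <- simulation_design(n_probes = 1000, effect = 0, seed = 9)
  prof <- generate_mirna_experiment(d)
  out <- fold_change_signature(prof)
  called <- length(out$signature$up) + length(out$signature$down)
  # |log2 ratio| > 1 under N(0, 0.3*sqrt(2)) noise is rare: background rate
  expect_lte(called / 1000, 0.05)
  planted <- c(attr(prof, "planted_up"), attr(prof, "planted_down"))
  hits <- sum(planted %in% c(out$signature$up, out$signature$down))
  expect_lte(hits / length(planted), 0.1)
})

test_that("a 3-log2-unit effect is recovered by fold change in 1v1 designs", {
  frac <- vapply(1:20, function(s) {
    d <- simulation_design(effect = 3, noise_sd = 0.3, replicates = 1,
                           seed = s)
    prof <- generate_mirna_experiment(d)
    out <- fold_change_signature(prof, fc_threshold = 2)
    mean(c(attr(prof, "planted_up") %in% out$signature$up,
           attr(prof, "planted_down") %in% out$signature$down))
  }, 0)
  expect_gte(median(frac), 0.95)
})

test_that("replicated designs route the miRNA profile to the SAM path", {
  d <- simulation_design(n_probes = 400, replicates = 3, seed = 31)
  prof <- generate_mirna_experiment(d)
  expect_identical(ncol(prof$values), 6L)
  built <- build_signature(prof, seed = 1)
  expect_identical(built$method, "sam")
  planted_up <- attr(prof, "planted_up")
  expect_gte(mean(planted_up %in% built$signature$up), 0.9)
})

test_that("molecule instances share planted sets and differ only in noise", {
  d <- simulation_design(n_probes = 300, n_instances = 3, seed = 5)
  truth <- response_signature("m", sprintf("P%06d", 1:20),
                              sprintf("P%06d", 21:40), method = "planted")
  insts <- generate_molecule_instances(d, truth, relation = "mimic",
                                       seed = 11)
  expect_length(insts, 3)
  expect_false(identical(insts[[1]]$values, insts[[2]]$values))
  expect_identical(attr(insts, "planted_up")[1:20], truth$up)
  # reversal with full overlap flips the planted directions
  rev_insts <- generate_molecule_instances(d, truth, relation = "reversal",
                                           seed = 11)
  expect_identical(attr(rev_insts, "planted_up")[1:20], truth$down)
  # overlap demanding more probes than the signature holds is rejected
  big_truth <- response_signature("m", sprintf("P%06d", 1:60),
                                  sprintf("P%06d", 61:120),
                                  method = "planted")
  expect_error(
    generate_molecule_instances(d, big_truth, relation = "mimic", seed = 1),
    "overlap demands")
})

test_that("planted reversal instances score negative; null instances centre at 0", {
  d <- simulation_design(n_probes = 500, n_up = 30, n_down = 30,
                         relation = "reversal", overlap = 1, effect = 3,
                         noise_sd = 0.3, n_instances = 5, seed = 41)
  co <- generate_cohort(d)
  built <- build_cohort_signatures(co)
  tes <- score_instances(built)
  planted <- tes$tes[tes$molecule_id == co$planted_molecule]
  expect_true(all(planted < 0))

  d0 <- simulation_design(n_probes = 500, n_up = 30, n_down = 30,
                          relation = "null", n_instances = 100,
                          n_molecules = 1, seed = 43)
  co0 <- generate_cohort(d0)
  tes0 <- score_instances(build_cohort_signatures(co0))
  expect_identical(nrow(tes0), 100L)
  expect_lte(abs(mean(tes0$tes)), 0.1)
})

test_that("cohorts have the declared shape and catalogue", {
  d <- simulation_design(n_molecules = 20, n_instances = 3, n_probes = 200,
                         seed = 3)
  co <- generate_cohort(d)
  expect_length(co$molecules, 20)
  expect_identical(sum(lengths(co$molecules)), 60L)
  expect_identical(nrow(co$catalogue), 61L)   # 60 instances + 1 miRNA row
  expect_identical(nrow(candidate_pairs(co$catalogue)), 20L)
})

test_that("planted |AS| grows with effect size and signature overlap", {
  grid <- expand.grid(effect = c(1, 2, 3), overlap = c(0.5, 1))
  med_as <- vapply(seq_len(nrow(grid)), function(g) {
    vals <- vapply(1:5, function(s) {
      d <- simulation_design(n_probes = 400, n_up = 30, n_down = 30,
                             relation = "reversal",
                             effect = grid$effect[g],
                             overlap = grid$overlap[g],
                             n_molecules = 8, n_instances = 3,
                             noise_sd = 0.3, seed = 600 + s)
      co <- generate_cohort(d)
      tes <- score_instances(build_cohort_signatures(co))
      abs(associate(tes, co$planted_molecule)$as_score)
    }, 0)
    median(vals)
  }, 0)
  m <- matrix(med_as, nrow = 3)  # rows: effect, cols: overlap
  expect_true(all(diff(m[, 1]) >= 0))
  expect_true(all(diff(m[, 2]) >= 0))
  expect_true(all(m[, 2] - m[, 1] >= 0))
})
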