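test_that("amplitude hits the twofold boundaries and is antisymmetric", {
  expect_equal(amplitude(2, 1), 2 / 3)
  expect_equal(amplitude(1, 2), -2 / 3)
  expect_equal(amplitude(5, 5), 0)
  expect_error(amplitude(0, 1), "positive")
  expect_error(amplitude(1, -2), "positive")

  set.seed(11)
  t <- rlnorm(500); c <- rlnorm(500)
  expect_equal(amplitude(t, c), -amplitude(c, t))
  # bounded in (-2, 2)
  expect_true(all(abs(amplitude(t, c)) < 2))
  # direction agreement with fold change: t/c >= 2 <=> a >= 2/3
  expect_identical(t / c >= 2, amplitude(t, c) >= 2 / 3)
  expect_identical(t / c <= 0.5, amplitude(t, c) <= -2 / 3)
})

test_that("fold-change signatures call at the symmetric ratio thresholds", {
  prof <- make_profile_1v1(t = c(4, 2, 1, 0.5, 0.25), c = rep(1, 5),
                           kind = "miRNA",
                           probes = c("pa", "pb", "pc", "pd", "pe"))
  out <- fold_change_signature(prof, fc_threshold = 2)
  expect_setequal(out$signature$up, c("pa", "pb"))
  expect_setequal(out$signature$down, c("pd", "pe"))
  expect_identical(out$pattern$probe_ids, c("pa", "pb", "pc", "pd", "pe"))
  expect_equal(out$pattern$stat, log2(c(4, 2, 1, 0.5, 0.25)))

  # sub-threshold ratios: empty signature, full-length pattern
  flat <- make_profile_1v1(t = rep(1.5, 4), c = rep(1, 4), kind = "miRNA")
  out2 <- fold_change_signature(flat)
  expect_length(out2$signature$up, 0)
  expect_length(out2$signature$down, 0)
  expect_length(out2$pattern$probe_ids, 4)

  rep_prof <- make_profile_rep(matrix(rlnorm(20), 10), matrix(rlnorm(20), 10))
  expect_error(fold_change_signature(rep_prof), "one sample per class")
  neg <- make_profile_1v1(t = c(1, -1), c = c(1, 1), kind = "miRNA")
  expect_error(fold_change_signature(neg), "positive")
})

test_that("sam_d matches its closed form and scaling identities", {
  expect_equal(sam_d(c(3, 3, 3), c(1, 1, 1), s0 = 0.5), 4)  # s = 0
  expect_equal(sam_d(c(2, 4), c(1, 5), s0 = 1), 0)          # equal means
  d1 <- sam_d(c(3, 3, 3), c(1, 1, 1), s0 = 0.5)
  d2 <- sam_d(c(3, 3, 3), c(1, 1, 1), s0 = 1.0)
  expect_equal(d2, d1 / 2)                                  # doubling s0 halves d
  expect_error(sam_d(3, c(1, 2)), "fold-change path")
})

test_that("sam_signature pattern statistic is probe-wise sam_d", {
  set.seed(5)
  tr <- matrix(rnorm(60, mean = 1), 20)
  ct <- matrix(rnorm(60), 20)
  prof <- make_profile_rep(tr, ct)
  out <- sam_signature(prof, seed = 5)
  s0 <- out$signature$thresholds$s0
  d_direct <- vapply(seq_len(20), function(i) sam_d(tr[i, ], ct[i, ], s0 = s0),
                     0)
  names(d_direct) <- rownames(prof$values)
  expect_equal(out$pattern$stat,
               unname(d_direct[out$pattern$probe_ids]))
  expect_false(is.unsorted(-out$pattern$stat))
})

test_that("sam_signature controls false calls on null data", {
  # 2v2 null: only 6 distinct label permutations exist -> enumeration warning
  frac <- vapply(1:8, function(s) {
    set.seed(s)
    n <- 400
    m <- matrix(rnorm(4 * n), n)
    rownames(m) <- sprintf("g%04d", seq_len(n))
    colnames(m) <- c("T1", "T2", "C1", "C2")
    prof <- expression_profile(m, rep(c("treatment", "control"), each = 2),
                               "null", "miRNA")
    sg <- expect_warning(sam_signature(prof, fdr_cutoff = 0.05, seed = s),
                         "distinct label permutations")
    (length(sg$signature$up) + length(sg$signature$down)) / n
  }, 0)
  expect_lte(mean(frac), 0.05)
})

test_that("sam_signature recovers planted shifts at FDR 0.05", {
  recovered <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 1000
    tr <- matrix(rnorm(3 * n), n)
    ct <- matrix(rnorm(3 * n), n)
    tr[1:20, ] <- tr[1:20, ] + 5  # +5 sd shift in 20 probes
    prof <- make_profile_rep(tr, ct, probes = sprintf("g%04d", seq_len(n)))
    sg <- sam_signature(prof, fdr_cutoff = 0.05, seed = s)
    sum(sprintf("g%04d", 1:20) %in% sg$signature$up)
  }, 0)
  expect_gte(median(recovered), 18)
})

test_that("amplitude signatures call strictly beyond the 2/3 boundary", {
  a_target <- c(1.0, 0.7, 0.0, -0.7, -1.0)
  t <- (2 + a_target) / (2 - a_target)  # amplitudes against c = 1
  prof <- make_profile_1v1(t = t, c = rep(1, 5),
                           probes = c("p1", "p2", "p3", "p4", "p5"))
  out <- amplitude_signature(prof)
  expect_equal(unname(out$pattern$stat), a_target)
  expect_setequal(out$signature$up, c("p1", "p2"))
  expect_setequal(out$signature$down, c("p4", "p5"))

  flat <- make_profile_1v1(t = rep(2, 4), c = rep(2, 4))
  out0 <- amplitude_signature(flat)
  expect_length(out0$signature$up, 0)
  expect_length(out0$signature$down, 0)

  # swapping t and c reverses the pattern and swaps the direction sets
  swapped <- make_profile_1v1(t = rep(1, 5), c = t,
                              probes = c("p1", "p2", "p3", "p4", "p5"))
  rev_out <- amplitude_signature(swapped)
  expect_equal(rev_out$pattern$stat, rev(-out$pattern$stat))
  expect_setequal(rev_out$signature$up, out$signature$down)
  expect_setequal(rev_out$signature$down, out$signature$up)
})

test_that("build_signature dispatches on replicates and perturbagen kind", {
  p_mir <- make_profile_1v1(t = rlnorm(30, 5), c = rlnorm(30, 5),
                            kind = "miRNA")
  expect_identical(build_signature(p_mir)$method, "fold_change")
  p_sm <- make_profile_1v1(t = rlnorm(30, 5), c = rlnorm(30, 5),
                           kind = "small_molecule")
  expect_identical(build_signature(p_sm)$method, "amplitude")
  set.seed(2)
  p_rep <- make_profile_rep(matrix(rnorm(90), 30), matrix(rnorm(90), 30))
  expect_identical(build_signature(p_rep, seed = 1)$method, "sam")
})

test_that("signature members always appear in their own ranked pattern", {
  set.seed(21)
  for (i in 1:20) {
    prof <- make_profile_1v1(t = rlnorm(100, 5), c = rlnorm(100, 5),
                             kind = sample(c("miRNA", "small_molecule"), 1),
                             probes = sprintf("P%03d", 1:100))
    out <- build_signature(prof)
    members <- c(out$signature$up, out$signature$down)
    expect_true(all(members %in% out$pattern$probe_ids))
    # with a strictly monotone statistic, up members rank above down members
    if (length(out$signature$up) && length(out$signature$down)) {
      pos <- match(members, out$pattern$probe_ids)
      expect_lt(max(pos[seq_along(out$signature$up)]),
                min(pos[-seq_along(out$signature$up)]))
    }
  }
})
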