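test_that("total ES credits sign-opposed directions and halves single ones", {
  expect_equal(total_es(0.8, -0.6), 0.7)
  expect_equal(total_es(0.5, 0.4), 0)     # same sign: no coherent placement
  expect_equal(total_es(0, 0), 0)
  expect_equal(total_es(-0.4, 0.2), -0.3)
  expect_equal(total_es(0.6, NA), 0.3)    # down direction empty
  expect_equal(total_es(NA, -0.6), 0.3)   # up direction empty
  expect_error(total_es(NA, NA), "not scoreable")
})

test_that("pair_tes separates planted mimicry from planted reversal", {
  set.seed(13)
  probes <- sprintf("P%04d", 1:400)
  stat <- sort(rnorm(400, sd = 2), decreasing = TRUE)
  pat <- ranked_pattern(probes, stat, sort = FALSE)
  sig <- response_signature("mirX", up = probes[1:30], down = probes[371:400])
  mir <- list(signature = sig, pattern = pat)

  # identical construction: strongly positive
  sm_same <- list(signature = response_signature("smA", sig$up, sig$down),
                  pattern = pat)
  tes_same <- pair_tes(sm_same, mir)
  expect_gte(tes_same$tes, 0.5)

  # exact reversal: up/down swapped, pattern negated
  rev_pat <- ranked_pattern(rev(probes), rev(-stat), sort = FALSE)
  sm_rev <- list(signature = response_signature("smB", up = sig$down,
                                                down = sig$up),
                 pattern = rev_pat)
  tes_rev <- pair_tes(sm_rev, mir)
  expect_lte(tes_rev$tes, -0.5)

  # the stored mean identity holds exactly
  for (row in list(tes_same, tes_rev))
    expect_identical(row$tes, (row$tes_sm2mir + row$tes_mir2sm) / 2)

  alien <- list(signature = response_signature("smC", "Z1", "Z2"),
                pattern = ranked_pattern(c("Z1", "Z2", "Z3"), c(1, 0, -1),
                                         sort = FALSE))
  expect_error(pair_tes(alien, mir), "no probe overlap")
})

test_that("ks_association evaluates both one-sided maxima correctly", {
  expect_equal(ks_association(1, 10), 0.9)
  expect_equal(ks_association(c(5, 6), 6), -5 / 6)
  expect_equal(ks_association(c(1, 2), 6), 2 / 3)
  expect_error(ks_association(c(2, 2), 6), "strictly increasing")
  expect_error(ks_association(c(0, 3), 6), "1..n")
  expect_error(ks_association(c(3, 9), 6), "1..n")
  expect_error(ks_association(c(1.5, 3), 6), "integers")
})

test_that("ks_association equals the explicit two-maxima oracle exhaustively", {
  for (n in 1:8) {
    for (mask in seq_len(2^n - 1)) {
      V <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      expect_equal(ks_association(V, n), oracle_ks(V, n), tolerance = 0)
    }
  }
})

test_that("moving an instance up in rank never decreases the score", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(4:25, 1)
    t <- sample(seq_len(n - 1), 1)
    V <- sort(sample(n, t))
    j <- sample(t, 1)
    lower <- if (j == 1) 1L else V[j - 1] + 1L
    if (V[j] == lower) next  # no free rank above this instance
    V2 <- V
    V2[j] <- V[j] - 1L
    expect_gte(ks_association(V2, n), ks_association(V, n))
  }
})

test_that("associate ranks instances and recovers closed-form top-block AS", {
  set.seed(17)
  # molecule holding the top t ranks of n: AS = 1 - t/n
  for (t in c(1, 2, 4)) {
    n <- 20
    tes <- data.frame(
      molecule_id = c(rep("top", t), sprintf("m%02d", seq_len(n - t))),
      instance_id = sprintf("i%d", seq_len(n)),
      tes = seq(1, -1, length.out = n))
    r <- associate(tes, "top")
    expect_equal(r$as_score, 1 - t / n)
    expect_identical(r$positions, seq_len(t))
  }
  # single instance in the exact middle: small |AS|
  n <- 21
  tes <- data.frame(molecule_id = c(sprintf("m%02d", 1:10), "mid",
                                    sprintf("q%02d", 1:10)),
                    instance_id = sprintf("i%d", seq_len(n)),
                    tes = seq(1, -1, length.out = n))
  expect_lte(abs(associate(tes, "mid")$as_score), 0.5 + 1 / n)
  expect_error(associate(tes, "absent"), "no scored instances")
})

test_that("association scores are independent of processing order", {
  set.seed(23)
  tes <- data.frame(
    molecule_id = rep(sprintf("m%02d", 1:8), each = 3),
    instance_id = rep(sprintf("i%d", 1:3), times = 8),
    tes = rnorm(24))
  all1 <- associate_all(tes)
  shuffled <- tes[sample(nrow(tes)), ]
  all2 <- associate_all(shuffled)
  expect_equal(all1, all2)
  # absolute ranking variant is accepted and stays within bounds
  all3 <- associate_all(tes, rank_by = "absolute")
  expect_true(all(abs(all3$AS) < 1))
})

test_that("rank ties break deterministically by molecule then instance id", {
  tes <- data.frame(
    molecule_id = c("b", "a", "c", "a"),
    instance_id = c("i1", "i2", "i1", "i1"),
    tes = c(0.5, 0.5, 0.5, 0.5))
  # all tied: order is a/i1, a/i2, b/i1, c/i1
  r <- associate(tes, "a")
  expect_identical(r$positions, 1:2)
})
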