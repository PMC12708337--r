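# a small site-loglik matrix where tree1 is clearly best
toy_sitell <- function(n = 100, gap = 0.3, seed = 2) {
  with_seed(seed, {
    base <- rnorm(n, -1.4, 0.3)
    cbind(best = base, worse = base - rexp(n, 1 / gap))
  })
}

test_that("rell_resample is seeded, shaped and totals-consistent", {
  m <- toy_sitell()
  R1 <- rell_resample(m, B = 200, seed = 9)
  R2 <- rell_resample(m, B = 200, seed = 9)
  R3 <- rell_resample(m, B = 200, seed = 10)
  expect_identical(R1, R2)
  expect_false(identical(R1, R3))
  expect_equal(dim(R1), c(200L, 2L))
  # replicate totals are means-consistent with the observed totals
  expect_equal(unname(colMeans(R1)), unname(colSums(m)), tolerance = 0.05 *
                 abs(sum(m[, 1])))
  # scale 0.5 resamples half the sites
  Rh <- rell_resample(m, B = 50, scale = 0.5, seed = 1)
  expect_lt(mean(Rh[, 1]), sum(m[, 1]) * 0.45)
})

test_that("KH/SH p-values match a brute-force reference on a 2-site space", {
  # with 2 sites and scale 1, a RELL replicate is one of 4 equally likely
  # index pairs; expectations over replicates are exactly enumerable
  m <- matrix(c(-1, -2, -1.5, -1.6), 2, 2,
              dimnames = list(NULL, c("t1", "t2")))
  draws <- expand.grid(1:2, 1:2)
  totals <- apply(draws, 1, function(ix) colSums(m[unlist(ix), , drop = FALSE]))
  d <- totals[1, ] - totals[2, ]         # replicate differences (t1 - t2)
  L <- colSums(m)
  delta <- max(L) - min(L)
  p_exact <- mean((d - mean(d)) >= delta - 1e-12)
  p_got <- kh_test(m, B = 40000, seed = 3)
  expect_equal(unname(p_got["t2"]), p_exact, tolerance = 0.01)
  expect_equal(unname(p_got["t1"]), 1)   # the best tree is never rejected
})

test_that("SH is never more liberal than KH; weighted variants are valid", {
  m <- toy_sitell(gap = 0.05)
  m <- cbind(m, third = m[, 1] - with_seed(5, rexp(nrow(m), 8)))
  B <- 3000
  R <- rell_resample(m, B = B, seed = 11)
  kh <- mitocong:::kh_from_replicates(m, R, weighted = FALSE)
  sh <- mitocong:::sh_from_replicates(m, R, weighted = FALSE)
  wkh <- mitocong:::kh_from_replicates(m, R, weighted = TRUE)
  wsh <- mitocong:::sh_from_replicates(m, R, weighted = TRUE)
  expect_true(all(sh >= kh - 1e-12))
  expect_true(all(c(kh, sh, wkh, wsh) >= 0 & c(kh, sh, wkh, wsh) <= 1))
  # the ML tree always has p = 1 under KH centering and p >= any other
  best <- which.max(colSums(m))
  expect_equal(unname(kh[best]), 1)
})

test_that("identical site-likelihood vectors are never rejected", {
  m <- toy_sitell()
  mm <- cbind(a = m[, 1], b = m[, 1])
  expect_equal(unname(kh_test(mm, B = 500, seed = 1)), c(1, 1))
  expect_equal(unname(kh_test(mm, B = 500, seed = 1, weighted = TRUE)),
               c(1, 1))
  expect_equal(unname(sh_test(mm, B = 500, seed = 1, weighted = TRUE)),
               c(1, 1))
  w <- elw(mm, B = 500, seed = 1)
  expect_equal(unname(w), c(0.5, 0.5))
})

test_that("expected likelihood weights sum to 1 and rank by likelihood", {
  m <- toy_sitell(gap = 0.1)
  w <- elw(m, B = 2000, seed = 7)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_gt(w["best"], w["worse"])
})

test_that("AU recovers the signed distance and curvature from its own model", {
  scales <- seq(0.5, 1.4, by = 0.1)
  B <- 1e6   # nominal count only used for clamping
  for (dc in list(c(1.2, 0.3), c(0.4, 0.8), c(-0.5, 0.6))) {
    d <- dc[1]; c <- dc[2]
    bp <- matrix(pnorm(-(d * sqrt(scales) + c / sqrt(scales))), ncol = 1)
    p <- mitocong:::au_from_bp(bp, scales, B, "t")
    expect_equal(as.numeric(p), 1 - pnorm(d - c), tolerance = 1e-6)
    expect_false(attr(p, "flag"))
  }
  # degenerate input (all-zero proportions) falls back and is flagged
  bp0 <- matrix(0, length(scales), 1)
  p0 <- mitocong:::au_from_bp(bp0, scales, B, "t")
  expect_true(attr(p0, "flag"))
  expect_equal(as.numeric(p0), 0)
})

test_that("topology_tests battery emits all seven statistics coherently", {
  m <- toy_sitell(gap = 0.15)
  tb <- topology_tests(m, B = 2000, seed = 13)
  expect_s3_class(tb, "test_battery")
  expect_setequal(tb$tree, c("best", "worse"))
  for (ts in c("bp_rell", "p_kh", "p_wkh", "p_sh", "p_wsh", "c_elw", "p_au"))
    expect_true(all(tb[[ts]] >= 0 & tb[[ts]] <= 1))
  expect_equal(sum(tb$bp_rell), 1, tolerance = 1e-12)
  expect_equal(sum(tb$c_elw), 1, tolerance = 1e-12)
  b <- tb[tb$tree == "best", ]
  w <- tb[tb$tree == "worse", ]
  expect_gt(b$p_kh, w$p_kh)
  expect_true(all(w[c("p_sh")] >= w[c("p_kh")] - 1e-12))
  rej <- mitocong:::reject_tree(w, alpha = 0.5)
  expect_type(rej, "logical")
  expect_length(rej, 7)
})

test_that("topology_tests with au = FALSE skips AU and leaves the rest intact", {
  m <- toy_sitell(gap = 0.15)
  tb <- topology_tests(m, B = 2000, seed = 13)
  nb <- topology_tests(m, B = 2000, seed = 13, au = FALSE)
  expect_true(all(is.na(nb$p_au)))
  expect_true(all(is.na(nb$au_flag)))
  for (ts in c("bp_rell", "p_kh", "p_wkh", "p_sh", "p_wsh", "c_elw"))
    expect_identical(nb[[ts]], tb[[ts]])
})

test_that("ILD is exact on engineered partitions", {
  # two partitions simulated on very different trees give a large D and a
  # small p; the same partition against itself gives p near 1
  mp <- model_params(pinv = 0, alpha = 10)
  trA <- sample_species_tree(8, seed = 31, target_depth = 1.5)
  trB <- perturb_tree(trA, 6, "SPR", seed = 32)
  a <- simulate_alignment(trA, mp, 150, seed = 33)
  b <- simulate_alignment(trB, mp, 150, seed = 34)
  bad <- ild_test(a, b, R = 49, seed = 35)
  expect_s3_class(bad, "ild_result")
  expect_gt(bad$D, 0)
  expect_lte(bad$p_value, 0.05)
  good <- ild_test(a[, 1:75], a[, 76:150], R = 49, seed = 36)
  expect_gt(good$p_value, 0.1)
  # p is a valid permutation p-value: at least 1/(R+1)
  expect_gte(bad$p_value, 1 / 50)
})

test_that("ILD handles invariant partitions with a warning", {
  a <- matrix("A", 4, 10, dimnames = list(paste0("t", 1:4), NULL))
  b <- matrix(c("A", "C", "G", "T"), 4, 10,
              dimnames = list(paste0("t", 1:4), NULL))
  expect_warning(res <- ild_test(a, b, R = 9), "no variable sites")
  expect_equal(res$p_value, 1)
})

test_that("reciprocal_congruence classifies planted cases correctly", {
  mp <- model_params(pinv = 0, alpha = 1)
  tr <- sample_species_tree(6, seed = 41, target_depth = 1.5)
  ctrl <- ml_control(restarts = 1, tol = 1e-3, max_rounds = 5)
  a1 <- simulate_alignment(tr, mp, 700, seed = 42)
  a2 <- simulate_alignment(tr, mp, 700, seed = 43)
  same <- reciprocal_congruence(a1, a2, B = 400, seed = 44, control = ctrl)
  expect_s3_class(same, "congruence_comparison")
  expect_true(all(same$decision == "congruent"))
  tr2 <- perturb_tree(tr, 4, "SPR", seed = 45)
  a3 <- simulate_alignment(tr2, mp, 700, seed = 46)
  diff <- reciprocal_congruence(a1, a3, B = 400, seed = 47, control = ctrl)
  expect_true(any(diff$decision == "incongruent"))
  expect_identical(diff$decision[["p_kh"]], "incongruent")
  # AU rejects in the stable direction; the other direction of this small
  # fixture is near-degenerate (all resampled proportions ~0/1), where the
  # multiscale extrapolation is intentionally conservative
  expect_lt(diff$p_reject_B_on_A[["p_au"]], 0.05)
})
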