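test_that("TIM2 generator has the required structure", {
  mp <- model_params(ac_at = 2.5, ag = 6, ct = 11,
                     bf = c(0.31, 0.24, 0.12, 0.33), alpha = 0.7, pinv = 0.1)
  Q <- build_rate_matrix(mp)
  pi <- attr(Q, "pi")
  # exchangeability constraints: AC = AT, CG = GT
  S <- sweep(Q, 2, pi, "/")
  expect_equal(S["A", "C"], S["A", "T"])
  expect_equal(S["C", "G"], S["G", "T"])
  # rows sum to zero, off-diagonals positive
  expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-12)
  expect_true(all(Q[upper.tri(Q)] > 0))
  # unit expected rate: -sum pi_i q_ii = 1
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  # detailed balance (reversibility): pi_i q_ij = pi_j q_ji
  flow <- sweep(Q, 1, pi, "*")
  expect_equal(flow, t(flow), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("transition probabilities are proper and satisfy semigroup laws", {
  mp <- model_params()
  Q <- build_rate_matrix(mp)
  for (t in c(0, 0.01, 0.3, 2)) {
    P <- transition_probabilities(Q, t)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
  expect_equal(transition_probabilities(Q, 0), diag(4),
               tolerance = 1e-12, ignore_attr = TRUE)
  # Chapman-Kolmogorov: P(s + t) = P(s) P(t)
  expect_equal(transition_probabilities(Q, 0.7),
               transition_probabilities(Q, 0.3) %*%
                 transition_probabilities(Q, 0.4),
               tolerance = 1e-10)
  # long-time limit is the stationary distribution
  expect_equal(unname(transition_probabilities(Q, 500)[1, ]),
               unname(mp$bf), tolerance = 1e-8)
})

test_that("discrete gamma categories match phangorn and have mean 1", {
  for (alpha in c(0.3, 0.5, 1.2)) {
    g <- gamma_categories(alpha, 4L)
    expect_equal(sum(g$rates * g$weights), 1, tolerance = 1e-12)
    ph <- phangorn::discrete.gamma(alpha, 4L)
    expect_equal(g$rates, ph / mean(ph), tolerance = 1e-9)
  }
  expect_equal(gamma_categories(0.5, 1L)$rates, 1)
})

test_that("pruning equals exhaustive state enumeration on small fixtures", {
  mp <- model_params(ac_at = 1.7, ag = 5, ct = 9,
                     bf = c(0.35, 0.2, 0.15, 0.3), alpha = 0.6, pinv = 0.15)
  for (n in c(4, 5, 6)) {
    fx <- fixture_alignment(n_taxa = n, nsite = 15, seed = 10 + n, params = mp)
    aln <- fx$aln
    aln[1, 1] <- "N"      # missing data path
    aln[2, 2] <- "R"      # ambiguity path
    got <- site_log_likelihoods(fx$tree, aln, mp)
    want <- enum_site_loglik(fx$tree, aln, mp)
    expect_equal(got$sitell, want, tolerance = 1e-8)
    expect_equal(got$total, sum(want), tolerance = 1e-8)
  }
})

test_that("pruning matches phangorn pml when the conventions coincide", {
  # phangorn rescales gamma rates by 1/(1 - pinv); at pinv = 0 the two
  # conventions are identical
  mp <- model_params(ac_at = 1.4, ag = 4.2, ct = 7.7,
                     bf = c(0.28, 0.26, 0.17, 0.29), alpha = 0.8, pinv = 0)
  fx <- fixture_alignment(n_taxa = 7, nsite = 120, seed = 21, params = mp)
  got <- site_log_likelihoods(fx$tree, fx$aln, mp)$total
  # TIM2 rates in phangorn's GTR order (AC, AG, AT, CG, CT, GT), scaled so
  # GT = 1 as in our parameterization
  ph <- phangorn::pml(fx$tree, as_phydat(fx$aln), bf = mp$bf,
                      Q = c(mp$ac_at, mp$ag, mp$ac_at, mp$cg_gt, mp$ct,
                            mp$cg_gt),
                      k = 4, shape = mp$alpha, inv = 0)
  expect_equal(got, ph$logLik, tolerance = 1e-6)
})

test_that("TIM2 collapses to JC and HKY special cases", {
  fx <- fixture_alignment(n_taxa = 5, nsite = 40, seed = 31)
  # JC: all exchangeabilities 1, uniform frequencies, no rate heterogeneity
  jc <- model_params(ac_at = 1, ag = 1, ct = 1, bf = rep(0.25, 4),
                     alpha = 1, pinv = 0, ncat = 1L)
  got <- site_log_likelihoods(fx$tree, fx$aln, jc)$sitell
  # closed-form JC transition probability
  jc_p <- function(t) {
    e <- exp(-4 * t / 3)
    function(i, j) if (i == j) 0.25 + 0.75 * e else 0.25 - 0.25 * e
  }
  want <- enum_site_loglik(fx$tree, fx$aln, jc)
  expect_equal(got, want, tolerance = 1e-8)
  P <- transition_probabilities(build_rate_matrix(jc), 0.3)
  f <- jc_p(0.3)
  expect_equal(P[1, 1], f(1, 1), tolerance = 1e-12)
  expect_equal(P[1, 2], f(1, 2), tolerance = 1e-12)
  # HKY: transversions all equal (ac_at = cg_gt = 1), transitions ag = ct
  kappa <- 5
  hky <- model_params(ac_at = 1, ag = kappa, ct = kappa,
                      bf = c(0.3, 0.2, 0.2, 0.3), alpha = 1, pinv = 0,
                      ncat = 1L)
  Qh <- build_rate_matrix(hky)
  S <- sweep(Qh, 2, attr(Qh, "pi"), "/")
  expect_equal(S["A", "G"] / S["A", "C"], kappa, tolerance = 1e-12)
  expect_equal(S["C", "T"] / S["C", "G"], kappa, tolerance = 1e-12)
  expect_equal(S["A", "C"], S["A", "T"])
  expect_equal(S["A", "C"], S["C", "G"])
})

test_that("likelihood is invariant to root placement and edge order", {
  mp <- model_params(alpha = 0.7, pinv = 0.1)
  fx <- fixture_alignment(n_taxa = 6, nsite = 50, seed = 41, params = mp)
  base <- site_log_likelihoods(fx$tree, fx$aln, mp)
  for (node in c(1, 3, 5)) {
    rer <- ape::unroot(ape::root(fx$tree, outgroup = fx$tree$tip.label[node],
                                 resolve.root = TRUE))
    got <- site_log_likelihoods(rer, fx$aln, mp)
    expect_equal(got$total, base$total, tolerance = 1e-8)
    expect_equal(got$sitell, base$sitell, tolerance = 1e-8)
  }
})

test_that("optimize_parameters recovers branch lengths and improves likelihood", {
  mp <- model_params()
  fx <- fixture_alignment(n_taxa = 6, nsite = 800, seed = 51, params = mp)
  start <- fx$tree
  start$edge.length <- rep(0.3, length(start$edge.length))
  fit <- optimize_parameters(start, fx$aln, params = mp,
                             control = ml_control(restarts = 1,
                                                  opt_model = FALSE))
  expect_s3_class(fit, "ml_fit")
  truth_ll <- site_log_likelihoods(fx$tree, fx$aln, mp)$total
  # optimized branch lengths on the true topology reach at least the
  # true-parameter likelihood
  expect_gte(fit$loglik, truth_ll - 1e-6)
  start_ll <- site_log_likelihoods(start, fx$aln, mp)$total
  expect_gt(fit$loglik, start_ll)
})

test_that("empirical base frequencies are positive and sum to one", {
  aln <- matrix(c("A", "A", "C", "G", "T", "N", "-", "A"), 2, 4,
                dimnames = list(c("t1", "t2"), NULL))
  bf <- empirical_base_freq(aln)
  expect_equal(sum(bf), 1, tolerance = 1e-12)
  expect_true(all(bf > 0))
  expect_gt(bf["A"], bf["C"])
})

test_that("site_loglik objects serialize and model_params validates", {
  expect_error(model_params(ag = -1), "positive")
  expect_error(model_params(bf = c(0.5, 0.5, 0.2, -0.2)))
  expect_error(model_params(pinv = 1.2))
  mp <- model_params()
  mp2 <- modify_params(mp, alpha = 0.9)
  expect_equal(mp2$alpha, 0.9)
  expect_equal(mp2$ag, mp$ag)
  fx <- fixture_alignment(n_taxa = 4, nsite = 10, seed = 61)
  sll <- site_log_likelihoods(fx$tree, fx$aln, mp)
  f <- tempfile(fileext = ".tsv")
  write_site_loglik(sll, f)
  got <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(got), 10)
  expect_equal(sum(got[[2]]), sll$total, tolerance = 1e-9)
  unlink(f)
})
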