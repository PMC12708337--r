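# Likelihood-based topology tests on per-site log-likelihood vectors
# (bp-RELL, KH, SH, weighted KH/SH, expected likelihood weights, AU) and the
# parsimony-based incongruence length difference (ILD) permutation test.

as_sitell_matrix <- function(site_ll) {
  if (is.list(site_ll) && !is.data.frame(site_ll) && !is.matrix(site_ll)) {
    vecs <- lapply(site_ll, function(x)
      if (inherits(x, "site_loglik")) x$sitell else as.numeric(x))
    n <- unique(vapply(vecs, length, 1L))
    if (length(n) != 1L)
      stop("site log-likelihood vectors differ in length across trees")
    m <- do.call(cbind, vecs)
    if (is.null(colnames(m)))
      colnames(m) <- paste0("tree", seq_len(ncol(m)))
    m
  } else {
    m <- as.matrix(site_ll)
    if (is.null(colnames(m))) colnames(m) <- paste0("tree", seq_len(ncol(m)))
    m
  }
}

#' RELL bootstrap of per-site log-likelihoods
#'
#' Resampling Estimated Log-Likelihoods: each replicate draws
#' `round(scale * n)` site indices with replacement (the same indices for
#' every tree) and sums the per-site log-likelihoods. This is the shared
#' resampling engine of all the likelihood-based topology tests.
#'
#' @param site_ll sites x trees matrix of per-site log-likelihoods, or a list
#'   of equal-length vectors / `site_loglik` objects.
#' @param B number of replicates.
#' @param scale resample-size fraction (`> 0`).
#' @param seed integer seed.
#' @return `B` x trees matrix of replicate log-likelihood totals.
#' @export
rell_resample <- function(site_ll, B = 10000L, scale = 1, seed = 1L) {
  m <- as_sitell_matrix(site_ll)
  n <- nrow(m)
  if (n < 1L || B < 1L || scale <= 0) stop("need n >= 1, B >= 1, scale > 0")
  size <- max(1L, round(scale * n))
  out <- with_seed(seed, c_rell(m, as.integer(B), size))
  colnames(out) <- colnames(m)
  out
}

# winners with ties split equally: B x M matrix -> proportion per tree
max_proportions <- function(R) {
  mx <- do.call(pmax, as.data.frame(R))
  win <- sweep(R, 1, mx, ">=")
  share <- win / rowSums(win)
  colMeans(share)
}

# SE of the total log-likelihood difference between tree columns k and m
pair_se <- function(m) {
  n <- nrow(m)
  M <- ncol(m)
  s <- matrix(0, M, M)
  for (k in seq_len(M))
    for (j in seq_len(M))
      if (k != j) s[k, j] <- sd(m[, k] - m[, j]) * sqrt(n)
  s
}

#' Kishino-Hasegawa test (and weighted variant)
#'
#' One-sided KH test of each tree against the ML (best observed) tree using
#' centered RELL replicate differences: for tree m the observed statistic is
#' `L_best - L_m`; the null distribution is the replicate differences minus
#' their replicate mean; `p` is the proportion of the centered null at least
#' the observed value. The weighted variant standardizes both sides by the
#' standard error of the per-site difference. Identical site-likelihood
#' vectors give `p = 1` (a zero-variance difference cannot reject).
#'
#' @inheritParams rell_resample
#' @param weighted compute the weighted (standardized) variant.
#' @return Named numeric vector of p-values, one per tree.
#' @export
kh_test <- function(site_ll, B = 10000L, seed = 1L, weighted = FALSE) {
  m <- as_sitell_matrix(site_ll)
  R <- rell_resample(m, B = B, scale = 1, seed = seed)
  kh_from_replicates(m, R, weighted)
}

kh_from_replicates <- function(m, R, weighted) {
  L <- colSums(m)
  best <- which.max(L)
  p <- setNames(numeric(ncol(m)), colnames(m))
  for (j in seq_len(ncol(m))) {
    delta <- L[best] - L[j]
    d <- R[, best] - R[, j]
    cent <- d - mean(d)
    if (weighted) {
      s <- sd(m[, best] - m[, j]) * sqrt(nrow(m))
      if (s < 1e-12) {
        p[j] <- if (delta <= 1e-12) 1 else 0
        next
      }
      delta <- delta / s
      cent <- cent / s
    }
    p[j] <- mean(cent >= delta - 1e-12)
  }
  p
}

#' Shimodaira-Hasegawa test (and weighted variant)
#'
#' Multiple-comparison-safe test over a candidate tree set: each tree's
#' replicate totals are centered by their own mean; the null statistic for
#' tree m in replicate b is the maximum centered total over trees minus tree
#' m's centered total, compared against the observed `L_max - L_m`. The
#' weighted variant standardizes every pairwise difference by its standard
#' error. `p_sh >= p_kh` for every tree by construction.
#'
#' @inheritParams kh_test
#' @return Named numeric vector of p-values, one per tree.
#' @export
sh_test <- function(site_ll, B = 10000L, seed = 1L, weighted = FALSE) {
  m <- as_sitell_matrix(site_ll)
  R <- rell_resample(m, B = B, scale = 1, seed = seed)
  sh_from_replicates(m, R, weighted)
}

sh_from_replicates <- function(m, R, weighted) {
  L <- colSums(m)
  C <- sweep(R, 2, colMeans(R))
  M <- ncol(m)
  p <- setNames(numeric(M), colnames(m))
  if (!weighted) {
    rmax <- do.call(pmax, as.data.frame(C))
    for (j in seq_len(M)) {
      obs <- max(L) - L[j]
      p[j] <- mean((rmax - C[, j]) >= obs - 1e-12)
    }
  } else {
    s <- pair_se(m)
    for (j in seq_len(M)) {
      ks <- setdiff(seq_len(M), j)
      obs_terms <- null_terms <- NULL
      obs <- -Inf
      null <- rep(-Inf, nrow(R))
      any_usable <- FALSE
      for (k in ks) {
        if (s[k, j] < 1e-12) {
          dkj <- L[k] - L[j]
          term_obs <- if (abs(dkj) <= 1e-12) 0 else sign(dkj) * Inf
          term_null <- rep(0, nrow(R))
        } else {
          any_usable <- TRUE
          term_obs <- (L[k] - L[j]) / s[k, j]
          term_null <- (C[, k] - C[, j]) / s[k, j]
        }
        obs <- max(obs, term_obs)
        null <- pmax(null, term_null)
      }
      if (!any_usable && obs <= 0) {
        p[j] <- 1
        next
      }
      p[j] <- mean(null >= obs - 1e-12)
    }
  }
  p
}

#' Expected likelihood weights
#'
#' Mean over RELL replicates of each tree's normalized likelihood weight
#' `exp(total_m - logsumexp(totals))`; the weights sum to 1 and form a
#' confidence set over the candidate trees.
#'
#' @inheritParams kh_test
#' @return Named numeric vector of weights summing to 1.
#' @export
elw <- function(site_ll, B = 10000L, seed = 1L) {
  m <- as_sitell_matrix(site_ll)
  R <- rell_resample(m, B = B, scale = 1, seed = seed)
  elw_from_replicates(R)
}

elw_from_replicates <- function(R) {
  mx <- do.call(pmax, as.data.frame(R))
  W <- exp(R - mx)
  W <- W / rowSums(W)
  colMeans(W)
}

#' Approximately unbiased (AU) test
#'
#' Multiscale RELL bootstrap: at each scale `r` the bootstrap proportion
#' `bp_r` that tree m attains the maximum is computed, probit-transformed,
#' and the model `qnorm(1 - bp_r) = d*sqrt(r) + c/sqrt(r)` fitted by
#' weighted least squares with binomial weights; `p_au = 1 - pnorm(d - c)`.
#' Proportions are clamped to `[1/(2B), 1 - 1/(2B)]` before the probit. When
#' fewer than two scales carry non-degenerate proportions the p-value falls
#' back to 0/1 according to the scale-1 bootstrap proportion and is flagged.
#'
#' @inheritParams kh_test
#' @param scales resample-size fractions of the multiscale bootstrap.
#' @return Named numeric vector of p-values with attribute `flag` marking
#'   degenerate fallbacks.
#' @export
au_test <- function(site_ll, B = 10000L,
                    scales = seq(0.5, 1.4, by = 0.1), seed = 1L) {
  m <- as_sitell_matrix(site_ll)
  M <- ncol(m)
  bp <- matrix(NA_real_, length(scales), M)
  for (i in seq_along(scales)) {
    R <- rell_resample(m, B = B, scale = scales[i],
                       seed = derive_seed(seed, paste0("au_scale", i)))
    bp[i, ] <- max_proportions(R)
  }
  au_from_bp(bp, scales, B, colnames(m))
}

au_from_bp <- function(bp, scales, B, tree_names) {
  M <- ncol(bp)
  p <- setNames(numeric(M), tree_names)
  flag <- setNames(logical(M), tree_names)
  lo <- 1 / (2 * B)
  for (j in seq_len(M)) {
    raw <- bp[, j]
    usable <- sum(raw > 0 & raw < 1)
    b <- pmin(pmax(raw, lo), 1 - lo)
    if (usable < 2L) {
      near1 <- raw[which.min(abs(scales - 1))]
      p[j] <- if (near1 >= 0.5) 1 else 0
      flag[j] <- TRUE
      next
    }
    z <- qnorm(1 - b)
    X <- cbind(sqrt(scales), 1 / sqrt(scales))
    w <- B * dnorm(z)^2 / (b * (1 - b))
    XtW <- t(X * w)
    beta <- solve(XtW %*% X, XtW %*% z)
    p[j] <- min(1, max(0, 1 - pnorm(beta[1] - beta[2])))
  }
  attr(p, "flag") <- flag
  p
}

LIKELIHOOD_TESTS <- c("bp_rell", "p_kh", "p_wkh", "p_sh", "p_wsh", "c_elw",
                      "p_au")

#' Run the full battery of likelihood topology tests
#'
#' Computes bp-RELL, p-KH, p-wKH, p-SH, p-wSH, c-ELW and p-AU for every
#' candidate tree from one set of per-site log-likelihood vectors, reusing a
#' single scale-1 RELL resample for all but the AU test.
#'
#' @inheritParams au_test
#' @param au compute the AU test. The AU multiscale bootstrap resamples at
#'   every scale and is by far the most expensive statistic in the battery;
#'   with `au = FALSE` its columns are `NA` and only the single scale-1
#'   resample shared by the other tests is drawn. The remaining statistics
#'   are bit-identical either way.
#' @return An object of class `test_battery`: data.frame with one row per
#'   tree and one column per test, plus attributes `B`, `seed`, `scales`.
#' @export
topology_tests <- function(site_ll, B = 10000L,
                           scales = seq(0.5, 1.4, by = 0.1), seed = 1L,
                           au = TRUE) {
  m <- as_sitell_matrix(site_ll)
  R <- rell_resample(m, B = B, scale = 1, seed = derive_seed(seed, "rell"))
  au <- if (isTRUE(au))
    au_test(m, B = B, scales = scales, seed = derive_seed(seed, "au"))
  else
    structure(rep(NA_real_, ncol(m)), flag = rep(NA, ncol(m)))
  out <- data.frame(
    tree = colnames(m),
    bp_rell = max_proportions(R),
    p_kh = kh_from_replicates(m, R, weighted = FALSE),
    p_wkh = kh_from_replicates(m, R, weighted = TRUE),
    p_sh = sh_from_replicates(m, R, weighted = FALSE),
    p_wsh = sh_from_replicates(m, R, weighted = TRUE),
    c_elw = elw_from_replicates(R),
    p_au = as.numeric(au),
    au_flag = attr(au, "flag"),
    row.names = NULL)
  structure(out, class = c("test_battery", "data.frame"),
            B = B, seed = seed, scales = scales)
}

# rejection rule per test: p-values reject below alpha, as do the
# bootstrap-proportion-style statistics (bp-RELL, c-ELW confidence weights)
reject_tree <- function(battery_row, alpha, tests = LIKELIHOOD_TESTS) {
  vapply(tests, function(ts) battery_row[[ts]] < alpha, logical(1))
}

#' Incongruence length difference (ILD) test
#'
#' Parsimony-based partition-homogeneity test: the observed statistic is
#' `D = L(combined) - [L(partA) + L(partB)]` in parsimony steps, each length
#' obtained by heuristic search with identical settings. Site columns are
#' then permuted between two pseudo-partitions of the original sizes `R`
#' times; `p = (1 + #{D* >= D}) / (R + 1)`. Heuristic-search noise can make
#' a length difference marginally negative; differences are clamped at 0.
#'
#' @param partA,partB character alignment matrices over the same taxa.
#' @param R number of permutations.
#' @param seed integer seed.
#' @param control an [ml_control]; `restarts` sets the search effort used
#'   for every length evaluation.
#' @return An object of class `ild_result`: list with `D`, `perm_D`, `R`,
#'   `p_value`.
#' @export
ild_test <- function(partA, partB, R = 99L, seed = 1L,
                     control = ml_control(restarts = 1L)) {
  if (!setequal(rownames(partA), rownames(partB)))
    stop("partitions must share a taxon set")
  partB <- partB[rownames(partA), , drop = FALSE]
  if (count_variable_sites(partA) < 1L || count_variable_sites(partB) < 1L) {
    warning("partition has no variable sites; ILD p set to 1")
    return(structure(list(D = 0, perm_D = numeric(0), R = 0L, p_value = 1),
                     class = "ild_result"))
  }
  comb <- cbind(partA, partB)
  nA <- ncol(partA)
  plen <- function(aln, lab)
    parsimony_search(aln, seed = derive_seed(seed, lab),
                     control = control)$score
  Lcomb <- plen(comb, "ild_comb")   # permutation-invariant
  D <- Lcomb - plen(partA, "ild_A") - plen(partB, "ild_B")
  if (D < -1e-9) warning("heuristic searches produced negative D; clamped to 0")
  D <- max(0, D)
  perm_D <- numeric(R)
  for (j in seq_len(R)) {
    ix <- with_seed(derive_seed(seed, paste0("ild_perm", j)),
                    sample.int(ncol(comb)))
    pA <- comb[, ix[seq_len(nA)], drop = FALSE]
    pB <- comb[, ix[-seq_len(nA)], drop = FALSE]
    dj <- Lcomb - plen(pA, paste0("ild_pA", j)) - plen(pB, paste0("ild_pB", j))
    perm_D[j] <- max(0, dj)
  }
  p <- (1 + sum(perm_D >= D - 1e-9)) / (R + 1)
  structure(list(D = D, perm_D = perm_D, R = R, p_value = p),
            class = "ild_result")
}

#' @export
print.ild_result <- function(x, ...) {
  cat("ILD test: D =", x$D, "steps,", x$R, "permutations, p =",
      format(x$p_value, digits = 4), "\n")
  invisible(x)
}

count_variable_sites <- function(aln) {
  enc <- encode_alignment(aln)
  sum(apply(enc, 2, function(col) {
    obs <- unique(col[col %in% c(1L, 2L, 4L, 8L)])
    length(obs) > 1L
  }))
}

#' Reciprocal congruence test between two gene alignments
#'
#' The paper-style reciprocal design: infer a tree from each gene, evaluate
#' both topologies against each gene's alignment (re-optimizing branch
#' lengths and model per topology), and run the topology-test battery. A
#' test calls the pair *incongruent* when each gene significantly rejects
#' the other's tree, *congruent* when neither does, and *ambiguous* when
#' only one direction rejects.
#'
#' @param alnA,alnB character alignment matrices over the same taxa.
#' @param alpha rejection level.
#' @param B RELL replicates.
#' @param seed integer seed.
#' @param control an [ml_control] governing searches and refits.
#' @param scales AU test scales.
#' @param fitA,fitB optional pre-computed `ml_fit`/`search_result` objects
#'   for the two genes (to reuse cached searches).
#' @return An object of class `congruence_comparison`: list with `decision`
#'   (named character per test), `p_reject_B_on_A`, `p_reject_A_on_B`,
#'   `battery_A`, `battery_B`, `trees`.
#' @export
reciprocal_congruence <- function(alnA, alnB, alpha = 0.05, B = 1000L,
                                  seed = 1L, control = ml_control(),
                                  scales = seq(0.5, 1.4, by = 0.1),
                                  fitA = NULL, fitB = NULL) {
  if (!setequal(rownames(alnA), rownames(alnB)))
    stop("genes must share a taxon set")
  alnB <- alnB[rownames(alnA), , drop = FALSE]
  if (is.null(fitA))
    fitA <- ml_search(alnA, control = control,
                      seed = derive_seed(seed, "searchA"))
  if (is.null(fitB))
    fitB <- ml_search(alnB, control = control,
                      seed = derive_seed(seed, "searchB"))
  tA <- fitA$tree; tB <- fitB$tree
  identical_topo <- canonical_key(tA) == canonical_key(tB)
  if (identical_topo) {
    unit <- data.frame(tree = c("own", "other"), bp_rell = 0.5, p_kh = 1,
                       p_wkh = 1, p_sh = 1, p_wsh = 1, c_elw = 0.5, p_au = 1,
                       au_flag = FALSE)
    decision <- setNames(rep("congruent", length(LIKELIHOOD_TESTS)),
                         LIKELIHOOD_TESTS)
    return(structure(list(
      decision = decision,
      p_reject_B_on_A = unit[2, LIKELIHOOD_TESTS],
      p_reject_A_on_B = unit[2, LIKELIHOOD_TESTS],
      battery_A = unit, battery_B = unit,
      trees = list(A = tA, B = tB), alpha = alpha, seed = seed,
      identical_topologies = TRUE), class = "congruence_comparison"))
  }
  eval_on <- function(aln, own_fit, other_tree, lab) {
    own_ll <- site_log_likelihoods(own_fit$tree, aln, own_fit$params)
    refit <- optimize_parameters(other_tree, aln, params = own_fit$params,
                                 control = control)
    other_ll <- site_log_likelihoods(refit$tree, aln, refit$params)
    m <- cbind(own = own_ll$sitell, other = other_ll$sitell)
    topology_tests(m, B = B, scales = scales,
                   seed = derive_seed(seed, lab))
  }
  battery_A <- eval_on(alnA, fitA, tB, "evalA")
  battery_B <- eval_on(alnB, fitB, tA, "evalB")
  rej_B_on_A <- reject_tree(battery_A[battery_A$tree == "other", ], alpha)
  rej_A_on_B <- reject_tree(battery_B[battery_B$tree == "other", ], alpha)
  decision <- ifelse(rej_B_on_A & rej_A_on_B, "incongruent",
                     ifelse(!rej_B_on_A & !rej_A_on_B, "congruent",
                            "ambiguous"))
  names(decision) <- LIKELIHOOD_TESTS
  structure(list(decision = decision,
                 p_reject_B_on_A = battery_A[battery_A$tree == "other",
                                             LIKELIHOOD_TESTS],
                 p_reject_A_on_B = battery_B[battery_B$tree == "other",
                                             LIKELIHOOD_TESTS],
                 battery_A = battery_A, battery_B = battery_B,
                 trees = list(A = tA, B = tB), alpha = alpha, seed = seed,
                 identical_topologies = FALSE),
            class = "congruence_comparison")
}

#' @export
print.congruence_comparison <- function(x, ...) {
  cat("Reciprocal congruence comparison (alpha =", x$alpha, ")\n")
  print(x$decision)
  invisible(x)
}
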