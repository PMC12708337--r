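# TIM2+G+I substitution model: constrained exchangeabilities, discrete-gamma
# rate heterogeneity with an invariant-site class, transition probabilities,
# per-site log-likelihoods (pruning, in C++) and parameter optimization.

#' Substitution model parameters (TIM2+G+I)
#'
#' The TIM2 model constrains the six GTR exchangeabilities to four classes:
#' the transversions AC = AT and CG = GT, and the two free transitions AG and
#' CT. One class (CG = GT) is fixed to 1 for identifiability. Rate
#' heterogeneity is a discrete gamma (`ncat` mean-of-quantile categories,
#' shape `alpha`) plus a proportion `pinv` of invariant sites.
#'
#' @param ac_at,ag,cg_gt,ct exchangeability classes, all `> 0`.
#' @param bf base frequencies (A, C, G, T), positive, summing to 1.
#' @param alpha gamma shape, `> 0`.
#' @param pinv proportion of invariant sites in `[0, 1)`.
#' @param ncat number of gamma categories.
#' @return An object of class `model_params`.
#' @export
#' @examples
#' model_params(ac_at = 1, ag = 4, ct = 8, bf = c(.33, .22, .13, .32))
model_params <- function(ac_at = 1, ag = 4, cg_gt = 1, ct = 8,
                         bf = c(0.33, 0.22, 0.13, 0.32),
                         alpha = 0.5, pinv = 0.2, ncat = 4L) {
  if (any(c(ac_at, ag, cg_gt, ct) <= 0))
    stop("exchangeability classes must be positive")
  if (length(bf) != 4L || any(bf <= 0))
    stop("base frequencies must be 4 positive values")
  bf <- bf / sum(bf)
  if (alpha <= 0) stop("gamma shape alpha must be positive")
  if (pinv < 0 || pinv >= 1) stop("pinv must lie in [0, 1)")
  if (ncat < 1L) stop("ncat must be >= 1")
  structure(list(ac_at = ac_at, ag = ag, cg_gt = cg_gt, ct = ct,
                 bf = setNames(as.numeric(bf), c("A", "C", "G", "T")),
                 alpha = alpha, pinv = pinv, ncat = as.integer(ncat)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("TIM2+G+I model\n")
  cat(sprintf("  rate classes: AC=AT=%.4g AG=%.4g CG=GT=%.4g CT=%.4g\n",
              x$ac_at, x$ag, x$cg_gt, x$ct))
  cat(sprintf("  base freq: A=%.3f C=%.3f G=%.3f T=%.3f\n",
              x$bf[1], x$bf[2], x$bf[3], x$bf[4]))
  cat(sprintf("  gamma alpha=%.4g (%d categories), pinv=%.4g\n",
              x$alpha, x$ncat, x$pinv))
  invisible(x)
}

#' Build the scaled TIM2 rate matrix
#'
#' Constructs the reversible generator `Q` with `q_ij = s_ij * pi_j`
#' (`s` under the TIM2 constraints), zero row sums, and scaled so that
#' `-sum(pi_i * q_ii) = 1` (one expected substitution per unit branch length
#' over the variable fraction of sites; no additional `1/(1-pinv)` rescale).
#'
#' @param params a [model_params].
#' @return 4x4 generator with `dimnames` ACGT and attributes `pi` and
#'   `eigen` (its symmetrized spectral decomposition).
#' @export
build_rate_matrix <- function(params) {
  stopifnot(inherits(params, "model_params"))
  pi <- params$bf
  s <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  s["A", "C"] <- s["A", "T"] <- params$ac_at
  s["A", "G"] <- params$ag
  s["C", "G"] <- s["G", "T"] <- params$cg_gt
  s["C", "T"] <- params$ct
  s <- s + t(s)
  Q <- s * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  eig <- q_eigen(Q, pi)
  attr(Q, "pi") <- pi
  attr(Q, "eigen") <- eig
  Q
}

# eigendecomposition of the scaled TIM2 generator straight from its
# parameters (hot path of the model optimizer)
tim2_eigen <- function(ac_at, ag, cg_gt, ct, pi) {
  s <- matrix(0, 4, 4)
  s[1, 2] <- s[1, 4] <- ac_at
  s[1, 3] <- ag
  s[2, 3] <- s[3, 4] <- cg_gt
  s[2, 4] <- ct
  s <- s + t(s)
  Q <- s * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(pi * diag(Q)))
  q_eigen(Q, pi)
}

# spectral decomposition of a reversible generator via symmetrization
q_eigen <- function(Q, pi) {
  d <- sqrt(pi)
  B <- (d %o% (1 / d)) * unclass(Q)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(evec = (1 / d) * e$vectors,          # rows scaled by 1/sqrt(pi)
       ievec = t(e$vectors * d),            # columns scaled by sqrt(pi)
       eval = e$values)
}

#' Discrete gamma rate categories
#'
#' Mean-of-quantile discretization of a Gamma(shape = `alpha`, rate =
#' `alpha`) distribution: equal weights `1/ncat`, category rates equal to the
#' conditional mean within each quantile bin, renormalized so the weighted
#' mean rate is exactly 1.
#'
#' @param alpha gamma shape, `> 0`.
#' @param ncat number of categories, `>= 1`.
#' @return List with `rates` (non-decreasing) and `weights`.
#' @export
#' @examples
#' gamma_categories(0.5, 4)
gamma_categories <- function(alpha, ncat = 4L) {
  if (alpha <= 0) stop("alpha must be positive")
  if (ncat < 1L) stop("ncat must be >= 1")
  if (ncat == 1L) return(list(rates = 1, weights = 1))
  b <- qgamma(seq(0, 1, length.out = ncat + 1L), shape = alpha, rate = alpha)
  r <- ncat * diff(pgamma(b, shape = alpha + 1, rate = alpha))
  r <- r / sum(r / ncat)
  list(rates = r, weights = rep(1 / ncat, ncat))
}

#' Transition probability matrix
#'
#' `P(t, r) = expm(Q * t * r)` computed from the spectral decomposition of
#' the reversible generator.
#'
#' @param Q generator from [build_rate_matrix()].
#' @param t branch length, `>= 0`.
#' @param r rate multiplier.
#' @return 4x4 row-stochastic matrix.
#' @export
transition_probabilities <- function(Q, t, r = 1) {
  if (t < 0) stop("branch length t must be >= 0")
  eig <- attr(Q, "eigen")
  if (is.null(eig)) {
    pi <- attr(Q, "pi")
    if (is.null(pi)) {
      ns <- Re(eigen(t(unclass(Q)))$vectors[, 4])
      pi <- ns / sum(ns)
    }
    eig <- q_eigen(unclass(Q), pi)
  }
  P <- eig$evec %*% (exp(eig$eval * t * r) * eig$ievec)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

# contrast matrix: IUPAC code (1..15) -> partial likelihood over ACGT
iupac_contrast <- function() {
  ct <- matrix(0, 15, 4)
  for (code in 1:15)
    for (b in 1:4)
      if (bitwAnd(code, bitwShiftL(1L, b - 1L)) != 0L) ct[code, b] <- 1
  ct
}

# reorder tree edges postorder and keep metadata used by the C engine
prep_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tr <- ape::reorder.phylo(tree, "postorder")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0.1, nrow(tr$edge))
  tr
}

# shared argument assembly for the C engine
engine_args <- function(tree, aln, params) {
  if (!setequal(tree$tip.label, rownames(aln))) {
    miss <- setdiff(tree$tip.label, rownames(aln))
    extra <- setdiff(rownames(aln), tree$tip.label)
    stop("tree/alignment label mismatch; missing from alignment: ",
         paste(miss, collapse = ", "), "; not in tree: ",
         paste(extra, collapse = ", "))
  }
  enc <- encode_alignment(aln)
  cp <- compress_patterns(enc[tree$tip.label, , drop = FALSE])
  g <- gamma_categories(params$alpha, params$ncat)
  Q <- build_rate_matrix(params)
  eig <- attr(Q, "eigen")
  tr <- prep_tree(tree)
  list(tree = tr, tip = t(cp$patterns), weights = cp$weights,
       index = cp$index, rates = g$rates, gwts = g$weights, eig = eig)
}

#' Per-site log-likelihoods by pruning
#'
#' Felsenstein pruning under TIM2+G+I. Each site's likelihood is
#' `pinv * I(site can be invariant with base b) * pi_b + (1 - pinv) *
#' mean over gamma categories of the pruning likelihood at that category's
#' rate`. Ambiguity codes are partial observations (1 for each compatible
#' base); gaps are fully missing.
#'
#' @param tree an [ape::phylo] tree whose tip labels equal the alignment's
#'   taxon labels.
#' @param aln character alignment matrix.
#' @param params a [model_params].
#' @return An object of class `site_loglik`: list with `sitell` (per-site
#'   vector), `total`, and `tree_id` (the tree's Newick string).
#' @export
site_log_likelihoods <- function(tree, aln, params = model_params()) {
  a <- engine_args(tree, aln, params)
  res <- c_site_loglik(a$tree$edge, a$tree$edge.length, length(a$tree$tip.label),
                       a$tip, iupac_contrast(), unname(params$bf),
                       a$rates, a$gwts, params$pinv,
                       a$eig$evec, a$eig$ievec, a$eig$eval, a$weights)
  sitell <- res$sitell[a$index]
  structure(list(sitell = sitell, total = sum(sitell),
                 tree_id = ape::write.tree(a$tree)),
            class = "site_loglik")
}

#' @export
print.site_loglik <- function(x, ...) {
  cat("Site log-likelihoods:", length(x$sitell), "sites, total =",
      format(x$total, digits = 10), "\n")
  invisible(x)
}

#' Export per-site log-likelihoods as TSV
#' @param sll a `site_loglik` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_site_loglik <- function(sll, path) {
  stopifnot(inherits(sll, "site_loglik"))
  write.table(data.frame(site = seq_along(sll$sitell), logL = sll$sitell),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Empirical base frequencies
#'
#' Counts of unambiguous A/C/G/T over the alignment, floored at 1e-6 and
#' renormalized (standard empirical-frequency default; maximum-likelihood
#' frequency estimation is deliberately not used).
#'
#' @param aln character alignment matrix.
#' @return Named numeric 4-vector.
#' @export
empirical_base_freq <- function(aln) {
  tab <- table(factor(as.vector(aln), levels = c("A", "C", "G", "T")))
  f <- as.numeric(tab)
  if (sum(f) == 0) f <- rep(1, 4)
  f <- pmax(f / sum(f), 1e-6)
  setNames(f / sum(f), c("A", "C", "G", "T"))
}

#' Control settings for likelihood fitting and tree search
#'
#' @param tol log-likelihood gain below which coordinate ascent stops.
#' @param max_rounds maximum optimization rounds.
#' @param bl_sweeps branch-length optimization sweeps per round.
#' @param opt_model optimize alpha, pinv and the free TIM2 classes
#'   (otherwise only branch lengths).
#' @param empirical_bf use empirical base frequencies from the evaluation
#'   alignment.
#' @param bl_min,bl_max branch-length bounds.
#' @param restarts random restarts for tree searches.
#' @param seed default RNG seed for searches.
#' @return List of class `ml_control`.
#' @export
ml_control <- function(tol = 1e-4, max_rounds = 20L, bl_sweeps = 3L,
                       opt_model = TRUE, empirical_bf = TRUE,
                       bl_min = 1e-8, bl_max = 10, restarts = 3L, seed = 1L) {
  structure(list(tol = tol, max_rounds = as.integer(max_rounds),
                 bl_sweeps = as.integer(bl_sweeps), opt_model = opt_model,
                 empirical_bf = empirical_bf, bl_min = bl_min,
                 bl_max = bl_max, restarts = as.integer(restarts),
                 seed = as.integer(seed)),
            class = "ml_control")
}

# total log-likelihood for fixed tree and params
total_loglik <- function(tree, aln, params) {
  a <- engine_args(tree, aln, params)
  c_site_loglik(a$tree$edge, a$tree$edge.length, length(a$tree$tip.label),
                a$tip, iupac_contrast(), unname(params$bf), a$rates, a$gwts,
                params$pinv, a$eig$evec, a$eig$ievec, a$eig$eval,
                a$weights)$total
}


#' Fit model parameters and branch lengths on a fixed topology
#'
#' Coordinate ascent: branch lengths by per-edge Brent line searches with
#' cached pruning partials (in C++), then bounded 1-D line searches over the
#' gamma shape, the invariant proportion, and the free TIM2 exchangeability
#' classes, repeated until the log-likelihood gain falls below `control$tol`
#' or `control$max_rounds` is reached. Base frequencies default to empirical
#' counts from `aln`.
#'
#' @param tree starting tree ([ape::phylo]; branch lengths are re-optimized).
#' @param aln character alignment matrix.
#' @param params starting [model_params] (`NULL` for defaults).
#' @param control an [ml_control].
#' @return An object of class `ml_fit`: list with `tree` (optimized branch
#'   lengths), `params`, `loglik`, `trace` (per-round log-likelihoods).
#' @export
optimize_parameters <- function(tree, aln, params = NULL,
                                control = ml_control()) {
  if (is.null(params)) params <- model_params(alpha = 1, pinv = 0.05)
  if (control$empirical_bf) {
    bf <- empirical_base_freq(aln)
    params <- modify_params(params, bf = bf)
  }
  # cache tip-pattern compression once: only model pieces change below
  if (!setequal(tree$tip.label, rownames(aln)))
    stop("tree/alignment label mismatch: ",
         paste(c(setdiff(tree$tip.label, rownames(aln)),
                 setdiff(rownames(aln), tree$tip.label)), collapse = ", "))
  enc <- encode_alignment(aln)
  cp <- compress_patterns(enc[tree$tip.label, , drop = FALSE])
  tip <- t(cp$patterns)
  contrast <- iupac_contrast()
  tree <- prep_tree(tree)
  ntip <- length(tree$tip.label)
  bfu <- unname(params$bf)
  ncat <- params$ncat
  # lean evaluator used inside the numerical optimizer: same model, no
  # constructor validation per call
  eval_raw <- function(alpha, pinv, ac_at, ag, ct, el) {
    g <- gamma_categories(alpha, ncat)
    eig <- tim2_eigen(ac_at, ag, params$cg_gt, ct, bfu)
    c_site_loglik(tree$edge, el, ntip, tip, contrast, bfu, g$rates,
                  g$weights, pinv, eig$evec, eig$ievec, eig$eval,
                  cp$weights)$total
  }
  eval_total <- function(p, el = tree$edge.length)
    eval_raw(p$alpha, p$pinv, p$ac_at, p$ag, p$ct, el)
  cur <- eval_total(params)
  trace <- cur
  for (round in seq_len(control$max_rounds)) {
    before <- cur
    # branch lengths
    g <- gamma_categories(params$alpha, params$ncat)
    eig <- attr(build_rate_matrix(params), "eigen")
    bl <- c_optim_bl(tree$edge, tree$edge.length, ntip, tip, contrast,
                     unname(params$bf), g$rates, g$weights, params$pinv,
                     eig$evec, eig$ievec, eig$eval, cp$weights,
                     control$bl_sweeps, control$tol / 10, control$bl_min,
                     control$bl_max, integer(0))
    if (bl$total >= cur - 1e-9) {
      tree$edge.length <- bl$el
      cur <- max(cur, bl$total)
    }
    if (control$opt_model) {
      # joint search over (log alpha, logit pinv, log free TIM2 classes,
      # log branch-length scale): alpha, pinv and tree length are strongly
      # correlated, so 1-D passes converge slowly
      unpack <- function(v)
        modify_params(params, alpha = exp(v[1]),
                      pinv = 0.99 * plogis(v[2]), ac_at = exp(v[3]),
                      ag = exp(v[4]), ct = exp(v[5]))
      v0 <- c(log(params$alpha),
              qlogis(min(0.999, max(1e-6, params$pinv / 0.99))),
              log(params$ac_at), log(params$ag), log(params$ct), 0)
      el0 <- tree$edge.length
      negll <- function(v)
        -eval_raw(exp(v[1]), 0.99 * plogis(v[2]), exp(v[3]), exp(v[4]),
                  exp(v[5]),
                  pmin(control$bl_max,
                       pmax(control$bl_min, el0 * exp(v[6]))))
      opt <- stats::optim(v0, negll, method = "Nelder-Mead",
                          control = list(maxit = if (round == 1L) 300 else 120,
                                         reltol = 1e-8))
      if (-opt$value > cur + 1e-9) {
        params <- unpack(opt$par)
        tree$edge.length <- pmin(control$bl_max,
                                 pmax(control$bl_min, el0 * exp(opt$par[6])))
        cur <- -opt$value
      }
    }
    trace <- c(trace, cur)
    if (!is.finite(cur)) stop("non-finite log-likelihood during optimization")
    if (cur - before < control$tol) break
  }
  structure(list(tree = tree, params = params, loglik = cur, trace = trace),
            class = "ml_fit")
}

modify_params <- function(params, ...) {
  upd <- list(...)
  if (length(upd) == 1L && is.list(upd[[1]]) && !is.null(names(upd[[1]])))
    upd <- upd[[1]]
  for (nm in names(upd)) params[[nm]] <- upd[[nm]]
  model_params(ac_at = params$ac_at, ag = params$ag, cg_gt = params$cg_gt,
               ct = params$ct, bf = params$bf, alpha = params$alpha,
               pinv = params$pinv, ncat = params$ncat)
}

#' @export
print.ml_fit <- function(x, ...) {
  cat("ML fit: logL =", format(x$loglik, digits = 10), "on",
      length(x$tree$tip.label), "taxa\n")
  print(x$params)
  invisible(x)
}
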