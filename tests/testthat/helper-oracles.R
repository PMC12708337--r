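# Shared independent oracles and small fixtures for the test suite.

# Exhaustive-enumeration site log-likelihoods: sums over every assignment of
# internal-node states, mirroring only the model definition (stationary root,
# P(t*r) per branch, gamma mixture, invariant class) and none of the pruning
# engine's code paths.
enum_site_loglik <- function(tree, aln, params) {
  Q <- build_rate_matrix(params)
  g <- gamma_categories(params$alpha, params$ncat)
  pi <- params$bf
  tr <- mitocong:::prep_tree(tree)
  edge <- tr$edge
  ntip <- length(tr$tip.label)
  nodes <- sort(unique(as.vector(edge)))
  internal <- setdiff(nodes, seq_len(ntip))
  root <- setdiff(edge[, 1], edge[, 2])
  stopifnot(length(root) == 1)
  aln <- aln[tr$tip.label, , drop = FALSE]
  enc <- mitocong:::encode_alignment(aln)
  nsite <- ncol(enc)
  # per-category transition matrices per edge
  Pcat <- lapply(seq_along(g$rates), function(c)
    lapply(seq_len(nrow(edge)), function(e)
      transition_probabilities(Q, tr$edge.length[e], g$rates[c])))
  state_sets <- lapply(1:15, function(code) which(bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0))
  combos <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  out <- numeric(nsite)
  for (s in seq_len(nsite)) {
    # invariant-class likelihood: a single state shared by all tips
    codes <- enc[, s]
    m <- Reduce(bitwAnd, c(list(15L), as.list(codes)))
    linv <- if (m == 0) 0 else sum(pi[state_sets[[m]]])
    lvar <- 0
    for (c in seq_along(g$rates)) {
      lc <- 0
      for (r in seq_len(nrow(combos))) {
        st <- integer(max(nodes))
        st[internal] <- combos[r, ]
        pr <- pi[st[root]]
        for (e in seq_len(nrow(edge))) {
          a <- edge[e, 1]; b <- edge[e, 2]
          P <- Pcat[[c]][[e]]
          if (b <= ntip) {
            pr <- pr * sum(P[st[a], state_sets[[codes[b]]]])
          } else {
            pr <- pr * P[st[a], st[b]]
          }
          if (pr == 0) break
        }
        lc <- lc + pr
      }
      lvar <- lvar + g$weights[c] * lc
    }
    out[s] <- log(params$pinv * linv + (1 - params$pinv) * lvar)
  }
  out
}

# Normal-equations OLS oracle for simple linear regression.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}

# deterministic tiny alignment fixture
fixture_alignment <- function(n_taxa = 5, nsite = 60, seed = 42,
                              depth = 1, params = model_params()) {
  tr <- sample_species_tree(n_taxa, seed = seed, target_depth = depth)
  list(tree = tr, aln = simulate_alignment(tr, params, nsite, seed = seed + 1))
}

# character alignment -> phangorn phyDat
as_phydat <- function(aln) phangorn::phyDat(tolower(aln), type = "DNA")
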