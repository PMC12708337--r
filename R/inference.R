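# Tree search: maximum likelihood (random start + NNI hill climbing with
# branch-length re-optimization) and Fitch parsimony (stepwise random
# addition + NNI hill climbing), both seed-deterministic and anytime-monotone.

# likelihood-evaluation context reused across a search (tip numbering is
# stable under NNI swaps, so pattern compression happens once)
make_ml_ctx <- function(aln, tip_order, params) {
  enc <- encode_alignment(aln)
  cp <- compress_patterns(enc[tip_order, , drop = FALSE])
  g <- gamma_categories(params$alpha, params$ncat)
  eig <- attr(build_rate_matrix(params), "eigen")
  list(tip = t(cp$patterns), weights = cp$weights, index = cp$index,
       rates = g$rates, gwts = g$weights, eig = eig,
       bf = unname(params$bf), pinv = params$pinv,
       contrast = iupac_contrast())
}

ctx_optim_bl <- function(edge, el, ntip, ctx, nsweep, control,
                         opt_edges = integer(0)) {
  c_optim_bl(edge, el, ntip, ctx$tip, ctx$contrast, ctx$bf, ctx$rates,
             ctx$gwts, ctx$pinv, ctx$eig$evec, ctx$eig$ievec, ctx$eig$eval,
             ctx$weights, nsweep, control$tol / 10, control$bl_min,
             control$bl_max, as.integer(opt_edges))
}

# edge rows re-optimized after an NNI swap: the two swapped edges, the
# central internal edge, its sibling/children and the parent edge
local_edges <- function(edge, sw) {
  u <- edge[sw[1], 1]; v <- edge[sw[2], 1]
  unique(c(sw, which(edge[, 1] %in% c(u, v) | edge[, 2] %in% c(u, v))))
}

#' Maximum-likelihood tree search
#'
#' Hill-climbing search: a stepwise-addition parsimony starting tree built
#' with a seeded random addition order (even-numbered restarts use a
#' uniformly random topology instead, for start diversity),
#' full model and branch-length optimization, then NNI hill climbing where
#' every neighbor is scored after a fast branch-length re-optimization sweep
#' and the best strictly improving neighbor is accepted (ties broken by
#' canonical topology key for reproducibility), followed by a final full
#' [optimize_parameters()] pass. `control$restarts` independent restarts are
#' run and the best final tree kept.
#'
#' @param aln character alignment matrix (>= 4 taxa).
#' @param params optional starting [model_params].
#' @param control an [ml_control].
#' @param seed integer seed.
#' @param start_tree optional starting topology for the first restart.
#' @return An object of class `search_result`: list with `tree`, `score`
#'   (log-likelihood), `params`, `moves` (accepted NNIs), `seed`, `trace`.
#' @export
ml_search <- function(aln, params = NULL, control = ml_control(),
                      seed = control$seed, start_tree = NULL) {
  labels <- rownames(aln)
  if (length(labels) < 4L) stop("need >= 4 taxa for tree search")
  best <- NULL
  ps_ctrl <- control
  ps_ctrl$restarts <- 1L
  for (r in seq_len(max(1L, control$restarts))) {
    tree <- if (r == 1L && !is.null(start_tree)) {
      start_tree
    } else if (r %% 2L == 1L) {
      # stepwise-addition parsimony start (random addition order): NNI-only
      # climbing from a uniformly random topology stalls in poor optima on
      # larger trees, so odd restarts begin from a parsimony tree
      ps <- parsimony_search(aln, seed = derive_seed(seed, paste0("ps", r)),
                             control = ps_ctrl)
      t0 <- ps$tree
      t0$edge.length <- rep(0.1, nrow(t0$edge))
      t0
    } else {
      random_tree(labels, derive_seed(seed, paste0("start", r)))
    }
    fit <- optimize_parameters(tree, aln, params, control)
    tree <- fit$tree
    cur <- fit$loglik
    ctx <- make_ml_ctx(aln, tree$tip.label, fit$params)
    ntip <- length(labels)
    moves <- 0L
    trace <- cur
    repeat {
      swaps <- all_nni_swaps(tree$edge, ntip)
      cand_tot <- rep(-Inf, length(swaps))
      cand <- vector("list", length(swaps))
      for (i in seq_along(swaps)) {
        e2 <- apply_swap(tree$edge, swaps[[i]])
        res <- ctx_optim_bl(e2, tree$edge.length, ntip, ctx, 1L, control,
                            opt_edges = local_edges(e2, swaps[[i]]))
        cand_tot[i] <- res$total
        cand[[i]] <- list(edge = e2, el = res$el)
      }
      top <- max(cand_tot)
      if (top <= cur + control$tol / 10) break
      ties <- which(cand_tot >= top - 1e-9)
      if (length(ties) > 1L) {
        keys <- vapply(ties, function(i)
          split_key(cand[[i]]$edge, ntip, labels), "")
        pick <- ties[order(keys)[1]]
      } else pick <- ties
      tree$edge <- cand[[pick]]$edge
      tree$edge.length <- cand[[pick]]$el
      cur <- cand_tot[pick]
      moves <- moves + 1L
      trace <- c(trace, cur)
    }
    final <- optimize_parameters(tree, aln, fit$params, control)
    if (final$loglik >= cur - 1e-9) {
      tree <- final$tree
      cur <- max(cur, final$loglik)
      fit$params <- final$params
    }
    trace <- c(trace, cur)
    if (is.null(best) || cur > best$score + 1e-9 ||
        (cur > best$score - 1e-9 &&
         canonical_key(tree) < canonical_key(best$tree))) {
      best <- list(tree = tree, score = cur, params = fit$params,
                   moves = moves, seed = seed, trace = trace)
    }
  }
  structure(best, class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("Tree search:", length(x$tree$tip.label), "taxa, score =",
      format(x$score, digits = 10), ",", x$moves, "accepted moves\n")
  invisible(x)
}

#' Fitch parsimony length
#'
#' Sum over sites of the minimum number of state changes under Fitch's
#' set-union algorithm. Ambiguity codes and gaps contribute their
#' compatible-state sets (a fully missing state never forces a change).
#'
#' @param tree an [ape::phylo] tree.
#' @param aln character alignment matrix with the tree's taxa.
#' @return Parsimony length (numeric, integer-valued).
#' @export
fitch_length <- function(tree, aln) {
  if (!setequal(tree$tip.label, rownames(aln)))
    stop("tree/alignment label mismatch: ",
         paste(c(setdiff(tree$tip.label, rownames(aln)),
                 setdiff(rownames(aln), tree$tip.label)), collapse = ", "))
  enc <- encode_alignment(aln)
  cp <- compress_patterns(enc[tree$tip.label, , drop = FALSE])
  c_fitch(tree$edge, length(tree$tip.label), t(cp$patterns), cp$weights)
}

# attach leaf x by splitting edge row j; w is the new internal node id
attach_leaf <- function(edge, j, x, w) {
  q <- edge[j, 2]
  edge[j, 2] <- w
  rbind(edge, c(w, q), c(w, x))
}

#' Parsimony tree search
#'
#' Stepwise random-addition start (each leaf, in a seeded random order, is
#' attached at the edge minimizing the Fitch length) followed by NNI hill
#' climbing; ties among equally short neighbors are broken by canonical
#' topology key. `control$restarts` restarts are run.
#'
#' @param aln character alignment matrix (>= 4 taxa).
#' @param seed integer seed.
#' @param control an [ml_control]; only `restarts` is used.
#' @return An object of class `search_result` with `score` = parsimony
#'   length (tree has no branch lengths).
#' @export
parsimony_search <- function(aln, seed = 1L, control = ml_control()) {
  labels <- rownames(aln)
  n <- length(labels)
  if (n < 4L) stop("need >= 4 taxa for tree search")
  enc <- encode_alignment(aln)
  cp <- compress_patterns(enc)           # tip i = labels[i]
  tip <- t(cp$patterns)
  w <- cp$weights
  flen <- function(edge) c_fitch(edge, n, tip, w)
  best <- NULL
  for (r in seq_len(max(1L, control$restarts))) {
    ord <- with_seed(derive_seed(seed, paste0("addorder", r)), sample.int(n))
    root <- n + 1L
    edge <- cbind(rep(root, 3L), ord[1:3])
    nextnode <- n + 2L
    for (k in 4:n) {
      x <- ord[k]
      sc <- vapply(seq_len(nrow(edge)), function(j)
        flen(attach_leaf(edge, j, x, nextnode)), 0)
      jbest <- which.min(sc)            # first minimum: deterministic
      edge <- attach_leaf(edge, jbest, x, nextnode)
      nextnode <- nextnode + 1L
    }
    cur <- flen(edge)
    moves <- 0L
    repeat {
      swaps <- all_nni_swaps(edge, n)
      sc <- vapply(swaps, function(sw) flen(apply_swap(edge, sw)), 0)
      top <- min(sc)
      if (top >= cur) break
      ties <- which(sc <= top)
      if (length(ties) > 1L) {
        keys <- vapply(ties, function(i)
          split_key(apply_swap(edge, swaps[[i]]), n, labels), "")
        pick <- ties[order(keys)[1]]
      } else pick <- ties
      edge <- apply_swap(edge, swaps[[pick]])
      cur <- top
      moves <- moves + 1L
    }
    if (is.null(best) || cur < best$score - 1e-9 ||
        (cur < best$score + 1e-9 &&
         split_key(edge, n, labels) < split_key(best$tree$edge, n, labels))) {
      tr <- structure(list(edge = edge, Nnode = max(edge) - n,
                           tip.label = labels), class = "phylo")
      best <- list(tree = tr, score = cur, params = NULL, moves = moves,
                   seed = seed, trace = cur)
    }
  }
  structure(best, class = "search_result")
}
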