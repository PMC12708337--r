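# Tree utilities on ape 'phylo' objects and raw edge matrices: uniform random
# topologies, NNI neighborhoods, SPR moves, bipartitions, Robinson-Foulds
# distance and canonical topology keys used for deterministic tie-breaking.

#' Uniform random unrooted topology
#'
#' Random sequential addition (each new leaf attached to a uniformly chosen
#' edge), which makes all labelled unrooted binary topologies equiprobable.
#' Branch lengths are set to 1.
#'
#' @param labels character tip labels (at least 4).
#' @param seed integer seed.
#' @return An unrooted binary [ape::phylo] with unit branch lengths.
#' @export
random_tree <- function(labels, seed = 1L) {
  if (length(labels) < 4L) stop("need at least 4 labels")
  if (anyDuplicated(labels)) stop("duplicate labels")
  tr <- with_seed(seed, ape::rtopology(length(labels), rooted = FALSE))
  tr$tip.label <- labels[as.integer(sub("^t", "", tr$tip.label))]
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# ---- edge-matrix helpers ----------------------------------------------------

# list of (i, j) edge-row pairs whose child entries are exchanged to produce
# each NNI neighbor; 2 per internal edge
all_nni_swaps <- function(edge, ntip) {
  swaps <- list()
  internal <- which(edge[, 2] > ntip)
  for (i in internal) {
    u <- edge[i, 1]; v <- edge[i, 2]
    j <- which(edge[, 1] == u)
    j <- j[j != i][1]                   # designated sibling edge at u
    ks <- which(edge[, 1] == v)         # the two child edges of v
    swaps[[length(swaps) + 1L]] <- c(j, ks[1])
    swaps[[length(swaps) + 1L]] <- c(j, ks[2])
  }
  swaps
}

apply_swap <- function(edge, sw) {
  tmp <- edge[sw[1], 2]
  edge[sw[1], 2] <- edge[sw[2], 2]
  edge[sw[2], 2] <- tmp
  edge
}

# canonical topology key: sorted non-trivial splits, each written as the
# sorted tip side not containing the alphabetically smallest label
split_key <- function(edge, ntip, labels) {
  anchor <- order(labels)[1]
  desc <- postorder_descendants(edge, ntip)
  keys <- character(0)
  for (e in seq_len(nrow(edge))) {
    v <- edge[e, 2]
    if (v <= ntip) next
    side <- desc[[v]]
    if (anchor %in% side) side <- setdiff(seq_len(ntip), side)
    if (length(side) < 2L || length(side) > ntip - 2L) next
    keys <- c(keys, paste(sort(labels[side]), collapse = ","))
  }
  paste(sort(keys), collapse = "|")
}

# fast postorder descendant sets (tip index vectors) per node
postorder_descendants <- function(edge, ntip) {
  nnode <- max(edge)
  desc <- vector("list", nnode)
  for (v in seq_len(ntip)) desc[[v]] <- v
  kids <- split(edge[, 2], edge[, 1])
  haspar <- logical(nnode)
  haspar[edge[, 2]] <- TRUE
  root <- edge[!haspar[edge[, 1]], 1][1]
  rec <- function(v) {
    if (v <= ntip) return(v)
    out <- integer(0)
    for (w in kids[[as.character(v)]]) out <- c(out, rec(w))
    desc[[v]] <<- out
    out
  }
  rec(root)
  desc
}

#' Canonical topology key
#'
#' A string identifying an unrooted topology up to tip relabeling order:
#' the sorted list of non-trivial splits, each written as the
#' lexicographically sorted smaller side. Two trees over the same taxa are
#' topologically identical iff their keys are equal.
#'
#' @param tree a `phylo` tree.
#' @return A character scalar.
#' @export
canonical_key <- function(tree) {
  split_key(tree$edge, length(tree$tip.label), tree$tip.label)
}

#' Robinson-Foulds distance
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' unrooted topologies.
#'
#' @param t1,t2 [ape::phylo] trees over the same leaf set.
#' @return Integer RF distance.
#' @export
rf_dist <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share a leaf set")
  s1 <- strsplit(canonical_key(t1), "|", fixed = TRUE)[[1]]
  s2 <- strsplit(canonical_key(t2), "|", fixed = TRUE)[[1]]
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' NNI neighborhood of an unrooted binary tree
#'
#' All nearest-neighbor-interchange neighbors: exactly `2 * (ntip - 3)`
#' trees, each obtained by exchanging two subtrees across an internal edge.
#' Branch lengths are carried over unchanged.
#'
#' @param tree an [ape::phylo] tree (unrooted binary).
#' @return List of [ape::phylo] trees.
#' @export
nni_neighbors <- function(tree) {
  tree <- ape::unroot(tree)
  swaps <- all_nni_swaps(tree$edge, length(tree$tip.label))
  lapply(swaps, function(sw) {
    tr2 <- tree
    tr2$edge <- apply_swap(tree$edge, sw)
    tr2
  })
}

# one random NNI move on a phylo (seeded by caller's RNG state)
nni_move <- function(tree) {
  swaps <- all_nni_swaps(tree$edge, length(tree$tip.label))
  sw <- swaps[[sample.int(length(swaps), 1L)]]
  tree$edge <- apply_swap(tree$edge, sw)
  tree
}

# one random SPR move (prune + regraft); returns NULL if no valid target
spr_move <- function(tree) {
  edge <- tree$edge
  el <- tree$edge.length
  if (is.null(el)) el <- rep(1, nrow(edge))
  ntip <- length(tree$tip.label)
  haspar <- logical(max(edge)); haspar[edge[, 2]] <- TRUE
  root <- edge[!haspar[edge[, 1]], 1][1]
  prunable <- which(edge[, 1] != root)
  if (!length(prunable)) return(NULL)
  i <- prunable[sample.int(length(prunable), 1L)]
  u <- edge[i, 1]; v <- edge[i, 2]
  # nodes inside the pruned subtree: v and everything below it
  below <- nodes_below(edge, v, ntip)
  sib_row <- which(edge[, 1] == u & seq_len(nrow(edge)) != i)
  par_row <- which(edge[, 2] == u)
  s <- edge[sib_row, 2]
  pu <- edge[par_row, 1]
  # collapse u: (pu,u)+(u,s) -> (pu,s)
  keep <- setdiff(seq_len(nrow(edge)), c(i, sib_row))
  edge2 <- edge[keep, , drop = FALSE]
  el2 <- el[keep]
  pr <- which(edge2[, 1] == pu & edge2[, 2] == u)
  edge2[pr, 2] <- s
  el2[pr] <- el2[pr] + el[sib_row]
  # regraft targets: any edge not inside the subtree and not the collapsed edge
  bad <- edge2[, 2] %in% below | edge2[, 1] %in% below |
    (edge2[, 1] == pu & edge2[, 2] == s)
  targets <- which(!bad)
  if (!length(targets)) return(NULL)
  j <- targets[sample.int(length(targets), 1L)]
  p <- edge2[j, 1]; q <- edge2[j, 2]; lj <- el2[j]
  edge2[j, 2] <- u
  el2[j] <- lj / 2
  edge2 <- rbind(edge2, c(u, q), c(u, v))
  el2 <- c(el2, lj / 2, el[i])
  tree$edge <- edge2
  tree$edge.length <- el2
  tree
}

nodes_below <- function(edge, v, ntip) {
  out <- v
  frontier <- v
  while (length(frontier)) {
    nxt <- edge[edge[, 1] %in% frontier, 2]
    out <- c(out, nxt)
    frontier <- nxt[nxt > ntip]
  }
  unique(out)
}

#' Perturb a tree by random NNI or SPR moves
#'
#' Applies `k_moves` random topology moves, the mechanism used to plant
#' gene-tree discordance in simulations. If an SPR move has no valid regraft
#' target the move falls back to an NNI (with a message).
#'
#' @param tree an [ape::phylo] tree.
#' @param k_moves number of moves, `>= 0`.
#' @param move_kind `"NNI"` (local) or `"SPR"` (stronger discordance).
#' @param seed integer seed.
#' @param distinct_moves if `TRUE`, the walk is self-avoiding: a move that
#'   lands on a topology already visited (including the start) is redrawn,
#'   so `k` moves cannot cancel back to an earlier tree. Each move redraws
#'   at most 50 times before being accepted as-is.
#' @return A tree over the same leaf set.
#' @export
perturb_tree <- function(tree, k_moves, move_kind = c("NNI", "SPR"),
                         seed = 1L, distinct_moves = FALSE) {
  move_kind <- match.arg(move_kind)
  if (k_moves < 0) stop("k_moves must be >= 0")
  if (k_moves == 0) return(tree)
  one_move <- function(tr) {
    if (move_kind == "NNI") return(nni_move(tr))
    t2 <- spr_move(tr)
    if (is.null(t2)) {
      message("no valid SPR target; falling back to NNI")
      t2 <- nni_move(tr)
    }
    t2
  }
  with_seed(seed, {
    seen <- canonical_key(tree)
    for (m in seq_len(k_moves)) {
      t2 <- one_move(tree)
      if (distinct_moves) {
        tries <- 0L
        while (canonical_key(t2) %in% seen && tries < 50L) {
          t2 <- one_move(tree)
          tries <- tries + 1L
        }
        seen <- c(seen, canonical_key(t2))
      }
      tree <- t2
    }
    tree
  })
}
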