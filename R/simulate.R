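# Synthetic partitioned mitogenome datasets with known congruence structure:
# Yule species trees, planted gene-tree discordance (uniform, block, or
# OR-distance gradient) and sequence simulation under TIM2+G+I.

#' Sample a species tree
#'
#' Yule (pure-birth, unit rate) tree, unrooted, with branch lengths rescaled
#' so the median tip-to-tip path length is `target_depth` expected
#' substitutions/site (informative but unsaturated alignments at mitogenome
#' gene lengths).
#'
#' @param n_taxa number of taxa, `>= 4`.
#' @param seed integer seed.
#' @param target_depth median tip-to-tip path length after rescaling.
#' @return An unrooted binary [ape::phylo] with positive branch lengths.
#' @export
sample_species_tree <- function(n_taxa, seed = 1L, target_depth = 0.5) {
  if (n_taxa < 4L) stop("n_taxa must be >= 4")
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  tr <- ape::unroot(tr)
  tr$tip.label <- sprintf("taxon%02d", seq_len(n_taxa))
  d <- ape::cophenetic.phylo(tr)
  med <- stats::median(d[upper.tri(d)])
  tr$edge.length <- tr$edge.length * target_depth / med
  tr$edge.length[tr$edge.length <= 0] <- 1e-6
  tr
}

#' Define a simulation scenario
#'
#' The scenario fixes the study conditions of a synthetic dataset: taxon
#' count, genome layout template, how gene trees deviate from the species
#' tree, and the substitution model.
#'
#' * `congruent`: every gene tree is the species tree.
#' * `block_discordant`: the genes in `discordant_genes` are perturbed by
#'   `lambda` topology moves each; all others match the species tree.
#' * `or_gradient`: gene g is perturbed by `Poisson(lambda * d_g / d_max)`
#'   moves, where `d_g` is its replication distance from its strand's origin
#'   and `d_max` the largest distance on that strand (restrict with
#'   `gradient_strand`).
#'
#' @param n_taxa taxa, `>= 4` (default 20, comparable to the smallest real
#'   matrices).
#' @param layout a [genome_layout] or template name (`"vertebrate"`,
#'   `"insect"`).
#' @param scenario `"congruent"`, `"block_discordant"` or `"or_gradient"`.
#' @param lambda discordance intensity: expected moves for the most
#'   perturbed gene, `>= 0`.
#' @param discordant_genes genes perturbed under `block_discordant`.
#' @param move_kind `"NNI"` or `"SPR"` perturbation moves.
#' @param rate_multipliers per-gene branch-length multipliers (single value
#'   or named vector; neutral default 1).
#' @param model a [model_params] used to simulate sequences.
#' @param length_scale multiplies template gene lengths (1 = full lengths).
#' @param gradient_strand strand(s) carrying the planted gradient
#'   (`"both"`, `"majority"`, `"minority"`).
#' @param gradient_draws how `or_gradient` converts the per-gene mean
#'   `lambda * d_g / d_max` into a move count: `"poisson"` (random draw, the
#'   default) or `"deterministic"` (`round(mean)`; a variance-free plant
#'   useful for validating gradient recovery).
#' @param distinct_moves passed to [perturb_tree()]: make the perturbation
#'   walk self-avoiding so moves cannot cancel.
#' @param tree_depth median tip-to-tip path length of the species tree;
#'   larger values give longer (more resolvable) internal branches.
#' @param seed integer master seed.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_taxa = 20L, layout = "vertebrate",
                                scenario = c("congruent", "block_discordant",
                                             "or_gradient"),
                                lambda = 0, discordant_genes = c("ND4", "ND5"),
                                move_kind = "NNI", rate_multipliers = 1,
                                model = model_params(), length_scale = 1,
                                gradient_strand = "both",
                                gradient_draws = c("poisson", "deterministic"),
                                distinct_moves = FALSE,
                                tree_depth = 0.5, seed = 1L) {
  gradient_draws <- match.arg(gradient_draws)
  scenario <- match.arg(scenario)
  if (is.character(layout)) layout <- genome_layout_template(layout)
  stopifnot(inherits(layout, "genome_layout"))
  if (n_taxa < 4L) stop("n_taxa must be >= 4")
  if (lambda < 0) stop("lambda must be >= 0")
  if (any(rate_multipliers <= 0)) stop("rate multipliers must be positive")
  unknown <- setdiff(discordant_genes, layout$genes$gene)
  if (length(unknown))
    stop("unknown gene(s) in discordant set: ", paste(unknown, collapse = ", "))
  rm_full <- setNames(rep(1, 15), layout$genes$gene)
  if (!is.null(names(rate_multipliers)))
    rm_full[names(rate_multipliers)] <- rate_multipliers
  else rm_full[] <- rate_multipliers
  structure(list(n_taxa = as.integer(n_taxa), layout = layout,
                 scenario = scenario, lambda = lambda,
                 discordant_genes = discordant_genes, move_kind = move_kind,
                 rate_multipliers = rm_full, model = model,
                 length_scale = length_scale,
                 gradient_strand = gradient_strand,
                 gradient_draws = gradient_draws,
                 distinct_moves = distinct_moves,
                 tree_depth = tree_depth,
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' Assign per-gene true trees under a scenario
#'
#' Plants the scenario's discordance structure: returns one tree per gene
#' plus a truth record (species tree, per-gene perturbation counts) for
#' parameter-recovery checks.
#'
#' @param species_tree an [ape::phylo] species tree.
#' @param layout a [genome_layout].
#' @param scn a [simulation_scenario].
#' @return List with `gene_trees` (named list), `truth` (class
#'   `truth_record`).
#' @export
assign_gene_trees <- function(species_tree, layout, scn) {
  genes <- layout$genes$gene
  kmoves <- setNames(integer(length(genes)), genes)
  if (scn$scenario == "block_discordant") {
    kmoves[scn$discordant_genes] <- as.integer(round(scn$lambda))
  } else if (scn$scenario == "or_gradient" && scn$lambda > 0) {
    dist <- gene_distances(layout)
    for (s in unique(dist$strand)) {
      if (!(scn$gradient_strand %in% c("both", s))) next
      rows <- dist$strand == s
      dmax <- max(dist$distance[rows])
      mu <- scn$lambda * dist$distance[rows] / dmax
      kmoves[dist$gene[rows]] <-
        if (identical(scn$gradient_draws, "deterministic"))
          as.integer(round(mu))
        else
          with_seed(derive_seed(scn$seed, paste0("gradient_", s)),
                    rpois(sum(rows), mu))
    }
  }
  gene_trees <- vector("list", length(genes))
  names(gene_trees) <- genes
  for (g in genes) {
    gene_trees[[g]] <- if (kmoves[[g]] > 0)
      perturb_tree(species_tree, kmoves[[g]], scn$move_kind,
                   seed = derive_seed(scn$seed, paste0("perturb_", g)),
                   distinct_moves = isTRUE(scn$distinct_moves))
    else species_tree
  }
  truth <- structure(list(species_tree = species_tree,
                          gene_trees = gene_trees,
                          perturbations = kmoves, scenario = scn),
                     class = "truth_record")
  list(gene_trees = gene_trees, truth = truth)
}

#' Simulate an alignment along a tree
#'
#' Standard simulation under the analysis model (TIM2+G+I): each site
#' independently joins the invariant class with probability `pinv`
#' (no substitutions anywhere) or draws one of the discrete gamma rate
#' categories; the root state is drawn from the stationary frequencies and
#' states evolve down each branch with `P(t * r)`.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param model a [model_params].
#' @param length number of sites, `>= 1`.
#' @param seed integer seed.
#' @return Character alignment matrix (taxa x sites).
#' @export
simulate_alignment <- function(tree, model = model_params(), length, seed = 1L) {
  if (length < 1L) stop("length must be >= 1")
  stopifnot(inherits(model, "model_params"))
  Q <- build_rate_matrix(model)
  g <- gamma_categories(model$alpha, model$ncat)
  tr <- prep_tree(tree)
  ntip <- length(tr$tip.label)
  nnode <- max(tr$edge)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    inv <- runif(length) < model$pinv
    cat_ix <- sample.int(model$ncat, length, replace = TRUE)
    rate <- ifelse(inv, 0, g$rates[cat_ix])
    states <- matrix(0L, nnode, length)
    root <- tr$edge[nrow(tr$edge), 1]
    states[root, ] <- sample.int(4L, length, replace = TRUE, prob = model$bf)
    # preorder: reverse postorder
    for (e in rev(seq_len(nrow(tr$edge)))) {
      p <- tr$edge[e, 1]; v <- tr$edge[e, 2]
      t_e <- tr$edge.length[e]
      child <- states[p, ]
      for (ci in seq_len(model$ncat)) {
        sel <- which(!inv & cat_ix == ci)
        if (!length(sel)) next
        P <- transition_probabilities(Q, t_e, g$rates[ci])
        for (x in 1:4) {
          sx <- sel[states[p, sel] == x]
          if (!length(sx)) next
          child[sx] <- sample.int(4L, length(sx), replace = TRUE,
                                  prob = P[x, ])
        }
      }
      states[v, ] <- child
    }
    aln <- matrix(bases[states[seq_len(ntip), , drop = FALSE]], ntip, length)
    rownames(aln) <- tr$tip.label
    aln
  })
}

#' Generate a full synthetic mitogenome dataset
#'
#' Samples a species tree, plants the scenario's gene-tree structure,
#' simulates one alignment per gene (length = template length x
#' `length_scale`, branch lengths x the gene's rate multiplier) and
#' concatenates them into a partitioned alignment matching the layout's
#' charsets. With `dir` set, also writes per-gene FASTA files, a combined
#' NEXUS with charsets, truth Newick files, the gene-map TSV, and a JSON
#' manifest.
#'
#' @param scn a [simulation_scenario].
#' @param dir optional output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return An object of class `mito_dataset`: list with `pa`
#'   (a [partitioned_alignment]), `layout`, `truth`.
#' @export
generate_dataset <- function(scn, dir = NULL, overwrite = FALSE) {
  stopifnot(inherits(scn, "simulation_scenario"))
  layout <- scn$layout
  sp <- sample_species_tree(scn$n_taxa, seed = derive_seed(scn$seed, "sptree"),
                            target_depth = scn$tree_depth)
  at <- assign_gene_trees(sp, layout, scn)
  gl <- gene_lengths(layout)
  lens <- setNames(pmax(2L, as.integer(round(gl * scn$length_scale))),
                   names(gl))
  genes <- layout$genes$gene
  alns <- vector("list", length(genes))
  names(alns) <- genes
  for (g in genes) {
    tr <- at$gene_trees[[g]]
    tr$edge.length <- tr$edge.length * scn$rate_multipliers[[g]]
    alns[[g]] <- simulate_alignment(tr, scn$model, lens[[g]],
                                    seed = derive_seed(scn$seed,
                                                       paste0("sim_", g)))
  }
  seqmat <- do.call(cbind, alns)
  ends <- cumsum(lens[genes])
  starts <- ends - lens[genes] + 1L
  pa <- partitioned_alignment(
    seqmat, data.frame(gene = genes, start = starts, end = ends))
  ds <- structure(list(pa = pa, layout = layout, truth = at$truth,
                       scenario = scn), class = "mito_dataset")
  if (!is.null(dir)) write_dataset(ds, dir, overwrite = overwrite)
  ds
}

#' @export
print.mito_dataset <- function(x, ...) {
  cat("Synthetic mitogenome dataset (", x$scenario$scenario, " scenario)\n",
      sep = "")
  print(x$pa)
  k <- x$truth$perturbations
  if (any(k > 0))
    cat("perturbed genes:",
        paste(sprintf("%s(%d)", names(k)[k > 0], k[k > 0]), collapse = " "),
        "\n")
  invisible(x)
}

#' Write a dataset to disk
#'
#' @param ds a `mito_dataset`.
#' @param dir output directory.
#' @param overwrite allow existing files to be replaced.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) && !overwrite)
    stop("output directory ", dir, " is not empty; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(ds$pa$parts))
    write_fasta(extract_partition(ds$pa, g),
                file.path(dir, paste0(gsub("[^A-Za-z0-9]", "_", g), ".fasta")))
  write_nexus(ds$pa, file.path(dir, "combined.nex"))
  write_gene_map(ds$layout, file.path(dir, "gene_map.tsv"))
  write_newick(ds$truth$species_tree, file.path(dir, "species_tree.nwk"))
  for (g in names(ds$truth$gene_trees))
    write_newick(ds$truth$gene_trees[[g]],
                 file.path(dir, paste0("true_",
                                       gsub("[^A-Za-z0-9]", "_", g), ".nwk")))
  scn <- ds$scenario
  manifest <- list(scenario = scn$scenario, n_taxa = scn$n_taxa,
                   lambda = scn$lambda,
                   discordant_genes = scn$discordant_genes,
                   move_kind = scn$move_kind,
                   length_scale = scn$length_scale,
                   gradient_strand = scn$gradient_strand, seed = scn$seed,
                   perturbations = as.list(ds$truth$perturbations))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
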