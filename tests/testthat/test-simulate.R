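test_that("species trees are unrooted, scaled and seeded", {
  tr <- sample_species_tree(12, seed = 3, target_depth = 0.8)
  expect_false(ape::is.rooted(tr))
  expect_equal(length(tr$tip.label), 12)
  d <- ape::cophenetic.phylo(tr)
  expect_equal(median(d[upper.tri(d)]), 0.8, tolerance = 1e-9)
  expect_identical(ape::write.tree(sample_species_tree(12, seed = 3,
                                                       target_depth = 0.8)),
                   ape::write.tree(tr))
})

test_that("simulated alignments match the model's base frequencies", {
  mp <- model_params(bf = c(0.4, 0.1, 0.1, 0.4), alpha = 1, pinv = 0)
  tr <- sample_species_tree(6, seed = 5)
  aln <- simulate_alignment(tr, mp, 4000, seed = 6)
  expect_equal(dim(aln), c(6L, 4000L))
  obs <- table(factor(as.vector(aln), levels = c("A", "C", "G", "T")))
  n <- sum(obs)
  # 4-sigma binomial band per base
  for (b in c("A", "C", "G", "T")) {
    p <- mp$bf[b]
    expect_lt(abs(obs[[b]] - n * p), 4 * sqrt(n * p * (1 - p)))
  }
})

test_that("pinv produces at least the expected share of constant sites", {
  mp <- model_params(pinv = 0.5, alpha = 1)
  tr <- sample_species_tree(8, seed = 7, target_depth = 2)
  aln <- simulate_alignment(tr, mp, 2000, seed = 8)
  const <- sum(apply(aln, 2, function(col) length(unique(col)) == 1))
  # invariant-class sites are constant by construction; variable-class sites
  # add a few more constants by chance
  expect_gt(const / 2000, 0.45)
  mp0 <- model_params(pinv = 0, alpha = 1)
  aln0 <- simulate_alignment(tr, mp0, 2000, seed = 8)
  const0 <- sum(apply(aln0, 2, function(col) length(unique(col)) == 1))
  expect_lt(const0, const)
})

test_that("identical seeds regenerate byte-identical datasets", {
  scn <- simulation_scenario(n_taxa = 6, scenario = "block_discordant",
                             discordant_genes = "ND5", lambda = 3,
                             length_scale = 0.05, seed = 11)
  d1 <- generate_dataset(scn)
  d2 <- generate_dataset(scn)
  expect_identical(d1$pa$seq, d2$pa$seq)
  expect_identical(lapply(d1$truth$gene_trees, canonical_key),
                   lapply(d2$truth$gene_trees, canonical_key))
  d3 <- generate_dataset(simulation_scenario(n_taxa = 6,
                                             scenario = "block_discordant",
                                             discordant_genes = "ND5",
                                             lambda = 3, length_scale = 0.05,
                                             seed = 12))
  expect_false(identical(d1$pa$seq, d3$pa$seq))
})

test_that("datasets carry the layout's scaled gene partitions", {
  scn <- simulation_scenario(n_taxa = 5, layout = "insect",
                             scenario = "congruent", length_scale = 0.1,
                             seed = 13)
  ds <- generate_dataset(scn)
  expect_s3_class(ds$pa, "partitioned_alignment")
  gl <- gene_lengths(scn$layout)
  expect_equal(unname(lengths(ds$pa$parts)[names(gl)]),
               unname(pmax(2L, as.integer(round(gl * 0.1)))))
  expect_setequal(names(ds$pa$parts), MITO_GENES)
  # congruent scenario: every gene tree equals the species tree
  expect_true(all(vapply(ds$truth$gene_trees, rf_dist, 0,
                         t2 = ds$truth$species_tree) == 0))
})

test_that("or_gradient move counts follow Poisson(lambda * d / d_max)", {
  ly <- genome_layout_template("insect")
  lam <- 8
  reps <- 200
  sums <- NULL
  for (s in seq_len(reps)) {
    scn <- simulation_scenario(n_taxa = 4, layout = "insect",
                               scenario = "or_gradient", lambda = lam,
                               gradient_strand = "minority",
                               length_scale = 0.01, seed = 4000 + s)
    k <- mitocong:::assign_gene_trees(
      sample_species_tree(4, seed = s), ly, scn)$truth$perturbations
    sums <- rbind(sums, k)
  }
  d <- gene_distances(ly, strand = "minority")
  mu <- lam * d$distance / max(d$distance)
  names(mu) <- d$gene
  for (g in d$gene) {
    se <- sqrt(mu[g] / reps)
    expect_lt(abs(mean(sums[, g]) - mu[g]), 3 * se + 1e-9)
  }
  # majority-strand genes are untouched when the gradient is minority-only
  maj <- setdiff(colnames(sums), d$gene)
  expect_true(all(sums[, maj] == 0))
})

test_that("deterministic gradient draws round the Poisson mean", {
  ly <- genome_layout_template("insect")
  scn <- simulation_scenario(n_taxa = 4, layout = "insect",
                             scenario = "or_gradient", lambda = 2.2,
                             gradient_strand = "minority",
                             gradient_draws = "deterministic", seed = 15)
  k <- mitocong:::assign_gene_trees(sample_species_tree(4, seed = 15), ly,
                                    scn)$truth$perturbations
  d <- gene_distances(ly, strand = "minority")
  want <- as.integer(round(2.2 * d$distance / max(d$distance)))
  expect_equal(unname(k[d$gene]), want)
})

test_that("write_dataset emits the documented files", {
  scn <- simulation_scenario(n_taxa = 4, scenario = "congruent",
                             length_scale = 0.02, seed = 17)
  ds <- generate_dataset(scn)
  dir <- tempfile("ds")
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "combined.nex")))
  expect_true(file.exists(file.path(dir, "gene_map.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "COX1.fasta")))
  expect_true(file.exists(file.path(dir, "species_tree.nwk")))
  pa <- read_nexus(file.path(dir, "combined.nex"))
  expect_identical(pa$seq, ds$pa$seq)
  expect_identical(pa$parts, ds$pa$parts)
  expect_error(write_dataset(ds, dir), "overwrite")
  unlink(dir, recursive = TRUE)
})
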