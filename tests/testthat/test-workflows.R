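# small fixture: a 6-taxon partitioned alignment with 3 genes, the third
# simulated on a distant topology so at least one pair is incongruent
wf_fixture <- function() {
  mp <- model_params(pinv = 0, alpha = 1)
  tr <- sample_species_tree(6, seed = 201, target_depth = 1.5)
  tr2 <- perturb_tree(tr, 4, "SPR", seed = 202)
  a <- simulate_alignment(tr, mp, 600, seed = 203)
  b <- simulate_alignment(tr, mp, 600, seed = 204)
  c <- simulate_alignment(tr2, mp, 600, seed = 205)
  seq <- cbind(a, b, c)
  colnames(seq) <- NULL
  pa <- partitioned_alignment(seq, list(gA = 1:600, gB = 601:1200,
                                        gC = 1201:1800))
  list(pa = pa, tr = tr, tr2 = tr2)
}

wf_config <- function(B = 400, seed = 1, ...) {
  congr_config(B = B, seed = seed,
               control = ml_control(restarts = 1, tol = 1e-3, max_rounds = 5),
               ...)
}

test_that("pairwise_matrix has the documented structure and finds the planted pair", {
  fx <- wf_fixture()
  cm <- pairwise_matrix(fx$pa, wf_config())
  expect_s3_class(cm, "congruence_matrix")
  expect_identical(cm$partitions, c("gA", "gB", "gC"))
  # seven likelihood-based statistics per comparison
  expect_length(cm$tests, 7L)
  expect_identical(dim(cm$p), c(3L, 3L, 7L))
  # the diagonal is congruent with p = 1
  for (g in cm$partitions) {
    expect_true(all(cm$decision[g, g, ] == "congruent"))
    expect_true(all(cm$p[g, g, ] == 1))
  }
  # decisions are symmetric even though p-values are directional
  for (ts in cm$tests)
    expect_identical(cm$decision[, , ts], t(cm$decision[, , ts]))
  # planted structure: gA/gB congruent, gC incongruent with both
  expect_true(all(cm$decision["gA", "gB", ] == "congruent"))
  expect_true(any(cm$decision["gA", "gC", ] == "incongruent"))
  expect_true(any(cm$decision["gB", "gC", ] == "incongruent"))
  # long-format view covers every unordered pair x test
  df <- as.data.frame(cm)
  expect_equal(nrow(df), 3 * 7)
  expect_true(all(df$p_reject_B_on_A >= 0 & df$p_reject_B_on_A <= 1,
                  na.rm = TRUE))

  # rows= computes exactly the named rows (bit-identical to the full
  # matrix, common random numbers per pair) and leaves the rest NA
  cr <- pairwise_matrix(fx$pa, wf_config(), rows = "gA")
  expect_identical(cr$decision["gA", , ], cm$decision["gA", , ])
  expect_identical(cr$p["gA", , ], cm$p["gA", , ])
  expect_true(all(is.na(cr$decision["gB", "gC", ])))
  expect_error(pairwise_matrix(fx$pa, wf_config(), rows = "nope"),
               "unknown partition")
})

test_that("congruent_proportion arithmetic is exact", {
  genes <- c("a", "b", "c", "d")
  dec <- array("congruent", c(4, 4, 1), dimnames = list(genes, genes, "p_au"))
  dec["a", "b", 1] <- dec["b", "a", 1] <- "incongruent"
  dec["c", "d", 1] <- dec["d", "c", 1] <- "ambiguous"
  cm <- structure(list(partitions = genes, tests = "p_au", decision = dec),
                  class = "congruence_matrix")
  expect_equal(unname(congruent_proportion(cm, "p_au")), 4 / 6)
  expect_equal(unname(congruent_proportion(cm, "p_au", "incongruent")), 1 / 6)
  expect_equal(unname(congruent_proportion(cm, "p_au", "ambiguous")), 1 / 6)
  # ordered denominator doubles the cells but not the proportions
  expect_equal(unname(congruent_proportion(cm, "p_au", ordered = TRUE)), 4 / 6)
})

test_that("antigene_matrices is NA on self pairs and shares randomness across rows", {
  fx <- wf_fixture()
  ar <- antigene_matrices(fx$pa, wf_config(seed = 3))
  expect_s3_class(ar, "antigene_result")
  expect_identical(dim(ar$decision), c(3L, 3L, 7L))
  for (g in ar$removed) expect_true(all(is.na(ar$decision[g, g, ])))
  # each removed gene is compared against the other singles
  expect_true(all(!is.na(ar$decision["gA", c("gB", "gC"), ])))
  # removing the discordant gC leaves a clean gA-vs-gB backbone: its
  # congruent fraction is at least that of removing a concordant gene
  fr <- antigene_congruent_fraction(ar, test = LIKELIHOOD_TESTS)
  expect_gte(fr[["gC"]], max(fr[["gA"]], fr[["gB"]]))
  # fraction pools over requested tests and lies in [0, 1]
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("category_matrix concatenates genes into the four categories", {
  mp <- model_params(pinv = 0, alpha = 1)
  tr <- sample_species_tree(5, seed = 301, target_depth = 1)
  scn <- simulation_scenario(n_taxa = 5, scenario = "congruent",
                             length_scale = 0.05, seed = 302)
  ds <- generate_dataset(scn)
  cm <- category_matrix(ds$pa, wf_config(B = 200, seed = 5))
  expect_s3_class(cm, "congruence_matrix")
  expect_setequal(cm$partitions, unique(MITO_CATEGORIES))
  expect_identical(dim(cm$decision), c(4L, 4L, 7L))
  # unknown gene names are rejected
  pa_bad <- ds$pa
  names(pa_bad$parts)[1] <- "NOT_A_GENE"
  expect_error(category_matrix(pa_bad, wf_config()), "without a category")
})

test_that("subsample_experiment draws taxa per fraction and skips tiny ones", {
  scn <- simulation_scenario(n_taxa = 12, scenario = "congruent",
                             length_scale = 0.04, seed = 401)
  ds <- generate_dataset(scn)
  pa <- subset_genes(ds$pa, c("COX1", "CYTB", "ND2"))
  cfg <- wf_config(B = 200, seed = 7)
  expect_warning(rep <- subsample_experiment(pa, fractions = c(1, 0.5, 0.1),
                                             config = cfg, draws = 2),
                 "skipped")
  expect_s3_class(rep, "subsample_report")
  # fraction 1 runs once; fraction 0.5 gets both draws; 0.1 (1 taxon) skipped
  expect_equal(sort(unique(rep$fraction)), c(0.5, 1))
  expect_equal(sum(rep$fraction == 1 & rep$test == "p_au"), 1L)
  expect_equal(sum(rep$fraction == 0.5 & rep$test == "p_au"), 2L)
  expect_true(all(rep$n_taxa[rep$fraction == 0.5] == 6))
  # category shares sum to 1 per row
  expect_equal(rep$congruent + rep$ambiguous + rep$incongruent,
               rep(1, nrow(rep)))
  taxa <- attr(rep, "taxa")
  expect_length(taxa[["frac_0.5_draw_1"]], 6L)
  expect_false(identical(sort(taxa[["frac_0.5_draw_1"]]),
                         sort(taxa[["frac_0.5_draw_2"]])))
})

test_that("congr_config tests= restricts the battery without changing it", {
  fx <- wf_fixture()
  sub <- c("bp_rell", "p_kh", "p_wkh", "p_sh", "p_wsh", "c_elw")
  cm <- pairwise_matrix(fx$pa, wf_config())
  cs <- pairwise_matrix(fx$pa, wf_config(tests = sub))
  expect_identical(cs$tests, sub)
  expect_identical(dim(cs$p)[3], 6L)
  # the RELL-based statistics are bit-identical to the full battery's
  expect_identical(cs$p[, , sub], cm$p[, , sub])
  expect_identical(cs$decision[, , sub], cm$decision[, , sub])
  expect_error(congr_config(tests = c("p_kh", "nope")), "subset")
  expect_error(congr_config(tests = character(0)), "subset")
})
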