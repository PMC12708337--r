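test_that("gene_distances measures circular arcs along replication direction", {
  ly <- genome_layout_template("insect")
  d <- gene_distances(ly)
  expect_setequal(d$gene, MITO_GENES)
  expect_true(all(d$distance >= 0 & d$distance < ly$genome_length))
  # hand check one majority gene: arc from its strand's OR to its 5' end
  g <- ly$genes[ly$genes$gene == "COX1", ]
  want <- (g$start - ly$or_position["majority"]) %% ly$genome_length
  expect_equal(d$distance[d$gene == "COX1"], unname(want))
  # strand filter restricts rows
  dm <- gene_distances(ly, strand = "minority")
  expect_true(all(dm$strand == "minority"))
  # midpoint anchor differs from 5' anchor for a typical gene
  d2 <- gene_distances(ly, anchor = "midpoint")
  expect_false(all(d2$distance == d$distance))
})

test_that("unscaled_measure counts row decisions and pools over tests", {
  genes <- c("g1", "g2", "g3")
  tests <- c("p_au", "p_kh")
  dec <- array("congruent", c(3, 3, 2), dimnames = list(genes, genes, tests))
  dec["g1", "g2", "p_au"] <- dec["g2", "g1", "p_au"] <- "incongruent"
  dec["g1", "g3", ] <- dec["g3", "g1", ] <- "incongruent"
  cm <- structure(list(partitions = genes, tests = tests, decision = dec),
                  class = "congruence_matrix")
  m1 <- unscaled_measure(cm, test = "p_au")
  expect_identical(m1, c(g1 = 2L, g2 = 1L, g3 = 1L))
  # pooling both tests adds the per-test counts
  m2 <- unscaled_measure(cm, test = tests)
  expect_identical(m2, c(g1 = 3L, g2 = 1L, g3 = 2L))
  mc <- unscaled_measure(cm, test = "p_au", orientation = "congruent")
  expect_identical(unname(m1 + mc), rep(2L, 3))
})

test_that("regress_gradient is exact on a planted line", {
  d <- data.frame(gene = paste0("g", 1:5), strand = "minority",
                  distance = c(100, 300, 800, 1500, 4000))
  y <- setNames(2 * d$distance + 1, d$gene)
  # lm warns about the "essentially perfect fit"; that is the point here
  rg <- suppressWarnings(regress_gradient(d, y, "minority"))
  expect_s3_class(rg, "gradient_regression")
  expect_equal(rg$slope, 2, tolerance = 1e-10)
  expect_equal(rg$intercept, 1, tolerance = 1e-8)
  expect_equal(rg$r_squared, 1, tolerance = 1e-12)
  expect_identical(rg$slope_sign, "P")
  down <- suppressWarnings(
    regress_gradient(d, setNames(-0.5 * d$distance, d$gene), "minority"))
  expect_identical(down$slope_sign, "N")
})

test_that("regress_gradient matches the normal equations on noisy data", {
  for (s in 1:5) {
    d <- with_seed(s, data.frame(gene = paste0("g", 1:8), strand = "majority",
                                 distance = runif(8, 0, 10000)))
    y <- with_seed(s + 50, setNames(rpois(8, 3), d$gene))
    if (var(as.numeric(y)) == 0) next
    rg <- regress_gradient(d, y, "majority")
    ora <- ols_oracle(d$distance, as.numeric(y))
    expect_equal(rg$slope, ora$slope, tolerance = 1e-10)
    expect_equal(rg$intercept, ora$intercept, tolerance = 1e-10)
    expect_equal(rg$r_squared, ora$r_squared, tolerance = 1e-10)
  }
})

test_that("degenerate regressions are handled explicitly", {
  d <- data.frame(gene = c("a", "b"), strand = "minority",
                  distance = c(10, 20))
  few <- regress_gradient(d, c(a = 1, b = 2), "minority")
  expect_true(is.na(few$slope))
  expect_match(few$na_reason, "need >= 3")
  d3 <- data.frame(gene = c("a", "b", "c"), strand = "minority",
                   distance = c(10, 20, 30))
  flat <- regress_gradient(d3, c(a = 2, b = 2, c = 2), "minority")
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$p_value, 1)
  expect_identical(flat$slope_sign, "0")
})

test_that("gradient_report covers both strands and orientations", {
  ly <- genome_layout_template("insect")
  genes <- MITO_GENES
  dec <- array("congruent", c(15, 15, 2),
               dimnames = list(genes, genes, c("p_au", "p_kh")))
  # plant rising incongruence along the minority strand
  dm <- gene_distances(ly, strand = "minority")
  ranked <- dm$gene[order(dm$distance)]
  for (i in seq_along(ranked)) {
    k <- i - 1L
    others <- setdiff(genes, ranked[i])[seq_len(min(k, 14L))]
    for (h in others) {
      dec[ranked[i], h, "p_au"] <- "incongruent"
      dec[h, ranked[i], "p_au"] <- "incongruent"
    }
  }
  cm <- structure(list(partitions = genes, tests = c("p_au", "p_kh"),
                       decision = dec),
                  class = "congruence_matrix")
  rep <- gradient_report(cm, ly, test = "p_au")
  expect_equal(nrow(rep), 4L)
  expect_setequal(rep$strand, c("majority", "minority"))
  expect_setequal(rep$orientation, c("congruent", "incongruent"))
  min_inc <- rep[rep$strand == "minority" & rep$orientation == "incongruent", ]
  expect_identical(min_inc$slope_sign, "P")
  expect_gt(min_inc$R2, 0.8)
  # congruent orientation of the same planted pattern slopes the other way
  min_con <- rep[rep$strand == "minority" & rep$orientation == "congruent", ]
  expect_identical(min_con$slope_sign, "N")
  # pooled-test label join and scatter attachment
  rep2 <- gradient_report(cm, ly, test = c("p_au", "p_kh"))
  expect_true(all(rep2$test == "p_au+p_kh"))
  sc <- attr(rep, "scatter")
  expect_true(all(c("gene", "strand", "distance", "measure",
                    "orientation") %in% names(sc)))
  expect_equal(nrow(sc), 30L)
})
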