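# The four experiment designs: pairwise gene-by-gene congruence matrices,
# leave-one-out antigene comparisons, functional-category comparisons and
# taxon-subsampling, all built on the reciprocal topology-test design.

#' Configuration for congruence workflows
#'
#' @param alpha rejection level of every test.
#' @param B RELL replicates per battery (10,000 reproduces the usual
#'   convention; 1,000 is the fast profile).
#' @param scales AU multiscale bootstrap scales.
#' @param ild also run the parsimony ILD test per pair.
#' @param R_ild ILD permutations.
#' @param control [ml_control] for searches and per-topology refits (one
#'   search restart by default: workflow conclusions are driven by the
#'   reciprocal test battery, not search depth).
#' @param refit_model re-optimize the substitution model per topology when
#'   evaluating the other gene's tree; the default keeps the model fitted on
#'   the evaluation alignment (with its own ML tree) and re-optimizes branch
#'   lengths only, the usual practice when scoring a candidate tree set.
#' @param params optional [model_params] used as the starting model for
#'   every per-partition search. Combined with
#'   `control = ml_control(opt_model = FALSE)` this fixes the substitution
#'   model at known values (for example, the generating model in a
#'   simulation study) so searches optimize topology and branch lengths
#'   only.
#' @param tests subset of the likelihood battery to compute and report
#'   (default: all seven statistics). Dropping `"p_au"` skips the AU
#'   multiscale bootstrap — much the most expensive statistic — and leaves
#'   every other statistic bit-identical, so large simulation designs whose
#'   summaries pool over tests can run on the RELL-based battery alone.
#' @param seed master seed; every stage derives named sub-seeds from it.
#' @return List of class `congr_config`.
#' @export
congr_config <- function(alpha = 0.05, B = 1000L,
                         scales = seq(0.5, 1.4, by = 0.1), ild = FALSE,
                         R_ild = 99L, control = ml_control(restarts = 1L),
                         refit_model = FALSE, params = NULL,
                         tests = LIKELIHOOD_TESTS, seed = 1L) {
  if (!length(tests) || !all(tests %in% LIKELIHOOD_TESTS))
    stop("tests must be a non-empty subset of: ",
         paste(LIKELIHOOD_TESTS, collapse = ", "))
  structure(list(alpha = alpha, B = as.integer(B), scales = scales,
                 ild = isTRUE(ild), R_ild = as.integer(R_ild),
                 control = control, refit_model = isTRUE(refit_model),
                 params = params, tests = tests, seed = as.integer(seed)),
            class = "congr_config")
}

ALL_TESTS <- c(LIKELIHOOD_TESTS, "p_ild")

# fit + own-alignment site log-likelihoods for one partition; NULL when the
# partition has no variable sites (degenerate)
fit_partition <- function(aln, config, lab) {
  if (count_variable_sites(aln) < 1L) return(NULL)
  fit <- ml_search(aln, params = config$params, control = config$control,
                   seed = derive_seed(config$seed, paste0("search_", lab)))
  ownll <- site_log_likelihoods(fit$tree, aln, fit$params)
  list(fit = fit, ownll = ownll, key = canonical_key(fit$tree))
}

# reciprocal battery between two fitted partitions; returns p-values for
# rejecting the other's tree in each direction plus per-test decisions
pair_cell <- function(alnA, fA, alnB, fB, config, lab) {
  tests <- config$tests
  if (is.null(fA) || is.null(fB)) {
    na <- setNames(rep(NA_real_, length(tests)), tests)
    return(list(p_BonA = na, p_AonB = na,
                decision = setNames(rep("ambiguous", length(tests)), tests),
                degenerate = TRUE))
  }
  if (fA$key == fB$key) {
    one <- setNames(rep(1, length(tests)), tests)
    one[intersect(c("bp_rell", "c_elw"), tests)] <- 0.5
    return(list(p_BonA = one, p_AonB = one,
                decision = setNames(rep("congruent", length(tests)), tests),
                degenerate = FALSE))
  }
  eval_on <- function(aln, own, other_tree, sub) {
    ownll <- own$ownll
    ctrl <- config$control
    if (!config$refit_model) ctrl$opt_model <- FALSE
    refit <- optimize_parameters(other_tree, aln, params = own$fit$params,
                                 control = ctrl)
    otherll <- site_log_likelihoods(refit$tree, aln, refit$params)
    m <- cbind(own = ownll$sitell, other = otherll$sitell)
    topology_tests(m, B = config$B, scales = config$scales,
                   seed = derive_seed(config$seed, paste0(lab, "_", sub)),
                   au = "p_au" %in% tests)
  }
  bA <- eval_on(alnA, fA, fB$fit$tree, "evalA")
  bB <- eval_on(alnB, fB, fA$fit$tree, "evalB")
  rowA <- bA[bA$tree == "other", ]
  rowB <- bB[bB$tree == "other", ]
  rejA <- reject_tree(rowA, config$alpha, tests) # A's data reject B's tree
  rejB <- reject_tree(rowB, config$alpha, tests)
  decision <- ifelse(rejA & rejB, "incongruent",
                     ifelse(!rejA & !rejB, "congruent", "ambiguous"))
  names(decision) <- tests
  list(p_BonA = setNames(as.numeric(rowA[tests]), tests),
       p_AonB = setNames(as.numeric(rowB[tests]), tests),
       decision = decision, degenerate = FALSE)
}

#' Pairwise gene-by-gene congruence matrix
#'
#' Runs the reciprocal congruence design on every unordered pair of
#' partitions: a tree is inferred once per partition, then for each pair
#' both topologies are evaluated against both alignments and the seven-test
#' battery applied. The matrix diagonal is congruent by construction
#' (self-comparisons) and the off-diagonal is symmetric. Optionally adds the
#' ILD test per pair. Partitions with no variable sites yield ambiguous
#' cells with a warning.
#'
#' @param pa a [partitioned_alignment].
#' @param config a [congr_config].
#' @param rows optional character vector of partition names: only cells in
#'   those rows (i.e. pairs involving at least one named partition) are
#'   computed, the rest stay `NA`. The computed rows are identical to the
#'   full matrix — each named partition is still compared against every
#'   other partition — so per-partition measures over those rows are
#'   unaffected; this only skips comparisons among the unnamed partitions.
#' @return An object of class `congruence_matrix` with p-value and decision
#'   arrays `[partition, partition, test]`.
#' @export
pairwise_matrix <- function(pa, config = congr_config(), rows = NULL) {
  genes <- names(pa$parts)
  if (length(genes) < 2L) stop("need at least 2 partitions")
  if (!is.null(rows) && !all(rows %in% genes))
    stop("unknown partition(s) in rows: ",
         paste(setdiff(rows, genes), collapse = ", "))
  alns <- lapply(genes, function(g) extract_partition(pa, g))
  names(alns) <- genes
  fits <- lapply(genes, function(g) fit_partition(alns[[g]], config, g))
  names(fits) <- genes
  if (any(vapply(fits, is.null, TRUE)))
    warning("partition(s) without variable sites marked ambiguous: ",
            paste(genes[vapply(fits, is.null, TRUE)], collapse = ", "))
  tests <- if (config$ild) c(config$tests, "p_ild") else config$tests
  G <- length(genes)
  p_arr <- array(NA_real_, c(G, G, length(tests)),
                 dimnames = list(genes, genes, tests))
  dec <- array(NA_character_, c(G, G, length(tests)),
               dimnames = list(genes, genes, tests))
  for (i in seq_len(G)) {
    dec[i, i, ] <- "congruent"
    p_arr[i, i, ] <- 1
  }
  for (i in seq_len(G - 1L)) {
    for (j in (i + 1L):G) {
      if (!is.null(rows) && !(genes[i] %in% rows) && !(genes[j] %in% rows))
        next
      lab <- paste0("pair_", genes[i], "_", genes[j])
      cell <- pair_cell(alns[[i]], fits[[i]], alns[[j]], fits[[j]], config,
                        lab)
      p_arr[i, j, config$tests] <- cell$p_BonA
      p_arr[j, i, config$tests] <- cell$p_AonB
      dec[i, j, config$tests] <- cell$decision
      dec[j, i, config$tests] <- cell$decision
      if (config$ild) {
        if (cell$degenerate) {
          dec[i, j, "p_ild"] <- dec[j, i, "p_ild"] <- "ambiguous"
        } else {
          ild <- ild_test(alns[[i]], alns[[j]], R = config$R_ild,
                          seed = derive_seed(config$seed, lab),
                          control = config$control)
          p_arr[i, j, "p_ild"] <- p_arr[j, i, "p_ild"] <- ild$p_value
          d <- if (ild$p_value < config$alpha) "incongruent" else "congruent"
          dec[i, j, "p_ild"] <- dec[j, i, "p_ild"] <- d
        }
      }
    }
  }
  structure(list(partitions = genes, tests = tests, p = p_arr,
                 decision = dec, alpha = config$alpha,
                 seed = config$seed, B = config$B,
                 trees = lapply(fits, function(f)
                   if (is.null(f)) NULL else f$fit$tree)),
            class = "congruence_matrix")
}

#' @export
print.congruence_matrix <- function(x, ...) {
  cat("Congruence matrix:", length(x$partitions), "partitions, alpha =",
      x$alpha, "\n")
  cat("congruent proportion (unordered off-diagonal pairs):\n")
  print(round(congruent_proportion(x), 3))
  invisible(x)
}

#' Long-format table of a congruence matrix
#' @param x a `congruence_matrix`.
#' @param ... unused.
#' @return data.frame with columns `partA`, `partB`, `test`,
#'   `p_reject_B_on_A`, `p_reject_A_on_B`, `decision`.
#' @export
as.data.frame.congruence_matrix <- function(x, ...) {
  g <- x$partitions
  rows <- list()
  for (i in seq_along(g))
    for (j in seq_along(g))
      if (i < j)
        for (ts in x$tests)
          rows[[length(rows) + 1L]] <- data.frame(
            partA = g[i], partB = g[j], test = ts,
            p_reject_B_on_A = x$p[i, j, ts],
            p_reject_A_on_B = x$p[j, i, ts],
            decision = x$decision[i, j, ts])
  do.call(rbind, rows)
}

#' Proportion of congruent pairs
#'
#' Fraction of off-diagonal cells called congruent, per test, over unordered
#' pairs (the reciprocal design is symmetric). Ambiguous cells count in the
#' denominator but not as congruent (they are reported separately).
#'
#' @param cm a `congruence_matrix`.
#' @param test test name(s); default all.
#' @param orientation `"congruent"`, `"incongruent"` or `"ambiguous"`.
#' @param ordered use ordered-pair denominator instead of unordered.
#' @return Named numeric vector of proportions.
#' @export
congruent_proportion <- function(cm, test = cm$tests,
                                 orientation = "congruent",
                                 ordered = FALSE) {
  stopifnot(inherits(cm, "congruence_matrix"))
  G <- length(cm$partitions)
  sel <- if (ordered) which(row(diag(G)) != col(diag(G)))
         else which(upper.tri(diag(G)))
  out <- vapply(test, function(ts) {
    cells <- cm$decision[, , ts][sel]
    mean(cells == orientation, na.rm = FALSE)
  }, 0)
  setNames(out, test)
}

#' Antigene (leave-one-out) congruence analysis
#'
#' For each gene g, builds the "anti-g" matrix (concatenation of the other
#' 14 partitions), infers its tree, and runs the reciprocal battery against
#' every single gene h != g: 15 antigenes x 14 comparisons. A gene whose
#' removal raises the congruent fraction is a culprit contributing
#' incongruence to the whole-genome matrix.
#'
#' @param pa a [partitioned_alignment] (15 partitions for a full mitogenome).
#' @param config a [congr_config].
#' @param removed genes to remove (default: all).
#' @param singles single genes to compare against (default: all).
#' @return An object of class `antigene_result` with decision and p arrays
#'   `[removed, gene, test]` (NA on the self row/column pairing).
#' @export
antigene_matrices <- function(pa, config = congr_config(),
                              removed = names(pa$parts),
                              singles = names(pa$parts)) {
  genes <- names(pa$parts)
  stopifnot(all(removed %in% genes), all(singles %in% genes))
  tests <- config$tests
  single_aln <- lapply(singles, function(g) extract_partition(pa, g))
  names(single_aln) <- singles
  single_fit <- lapply(singles, function(g)
    fit_partition(single_aln[[g]], config, paste0("single_", g)))
  names(single_fit) <- singles
  dec <- array(NA_character_, c(length(removed), length(singles),
                                length(tests)),
               dimnames = list(removed, singles, tests))
  p_arr <- array(NA_real_, dim(dec), dimnames = dimnames(dec))
  for (g in removed) {
    anti_aln <- extract_partition(pa, setdiff(genes, g))
    anti_fit <- fit_partition(anti_aln, config, paste0("anti_", g))
    for (h in setdiff(singles, g)) {
      # the resampling seed label deliberately omits the removed gene g:
      # the same single gene h then sees identical RELL randomness in every
      # antigene row (common random numbers), so cross-row comparisons of
      # congruent fractions are not blurred by Monte Carlo flips
      cell <- pair_cell(anti_aln, anti_fit, single_aln[[h]], single_fit[[h]],
                        config, paste0("anti_vs_", h))
      dec[g, h, ] <- cell$decision
      p_arr[g, h, ] <- cell$p_BonA     # single gene's tree judged by anti-g
    }
  }
  structure(list(removed = removed, singles = singles, tests = tests,
                 decision = dec, p = p_arr, alpha = config$alpha,
                 seed = config$seed),
            class = "antigene_result")
}

#' @export
print.antigene_result <- function(x, ...) {
  cat("Antigene analysis:", length(x$removed), "antigene matrices x",
      length(x$singles) - 1L, "comparisons\n")
  ts <- if ("p_au" %in% x$tests) "p_au" else x$tests
  cat("congruent fraction per removed gene (",
      paste(ts, collapse = ", "), "):\n", sep = "")
  print(round(antigene_congruent_fraction(x, ts), 3))
  invisible(x)
}

#' Congruent fraction per removed gene
#'
#' Fraction of (gene, test) cells in each removed-gene row whose reciprocal
#' decision is "congruent". Passing several test names pools the fraction
#' over them, which damps borderline single-test flips.
#'
#' @param ar an `antigene_result`.
#' @param test character vector of test names to pool over.
#' @return Named numeric vector over removed genes.
#' @export
antigene_congruent_fraction <- function(ar, test = "p_au") {
  vapply(ar$removed, function(g) {
    cells <- ar$decision[g, , test]
    mean(cells[!is.na(cells)] == "congruent")
  }, 0)
}

#' Functional-category congruence matrix
#'
#' Concatenates genes into the four functional categories (CO, ND, AT,
#' rRNA) and runs the pairwise reciprocal design among the category
#' alignments (4x4 matrix, 6 unique off-diagonal pairs).
#'
#' @param pa a [partitioned_alignment] of the 15 canonical genes.
#' @param config a [congr_config].
#' @param categories named character vector gene -> category.
#' @return A `congruence_matrix` over categories.
#' @export
category_matrix <- function(pa, config = congr_config(),
                            categories = MITO_CATEGORIES) {
  genes <- names(pa$parts)
  miss <- setdiff(genes, names(categories))
  if (length(miss))
    stop("genes without a category: ", paste(miss, collapse = ", "))
  cats <- unique(categories[genes])
  parts <- lapply(cats, function(cc) {
    idx <- unlist(pa$parts[genes[categories[genes] == cc]], use.names = FALSE)
    if (!length(idx)) stop("empty category: ", cc)
    sort(idx)
  })
  names(parts) <- cats
  pairwise_matrix(partitioned_alignment(pa$seq, parts), config)
}

#' Taxon-subsampling experiment
#'
#' Randomly culls taxa to each requested fraction of the dataset (without
#' replacement, independent draws per fraction), recomputes the full
#' pairwise congruence matrix on each reduced dataset, and reports the
#' congruent proportion per test — the design used to ask whether congruence
#' rises as datasets shrink.
#'
#' @param pa a [partitioned_alignment].
#' @param fractions fractions of taxa to retain.
#' @param config a [congr_config].
#' @param draws independent taxon draws per fraction (a fraction retaining
#'   every taxon is computed once regardless).
#' @param seed seed for the taxon draws.
#' @return An object of class `subsample_report`: data.frame with columns
#'   `fraction`, `draw`, `n_taxa`, `test`, `congruent`, `ambiguous`,
#'   `incongruent`; retained taxa in `attr(, "taxa")`.
#' @export
subsample_experiment <- function(pa, fractions = c(1, 0.5, 0.25, 0.10),
                                 config = congr_config(), draws = 1L,
                                 seed = config$seed) {
  n <- nrow(pa$seq)
  out <- list()
  taxa_kept <- list()
  for (f in fractions) {
    m <- round(f * n)
    if (m < 4L) {
      warning("fraction ", f, " yields ", m, " taxa (< 4); skipped")
      next
    }
    ndraw <- if (m == n) 1L else as.integer(draws)
    for (dr in seq_len(ndraw)) {
      tag <- paste0("frac_", f, "_draw_", dr)
      taxa <- if (m == n) rownames(pa$seq)
              else with_seed(derive_seed(seed, tag),
                             sample(rownames(pa$seq), m))
      sub <- partitioned_alignment(pa$seq[taxa, , drop = FALSE], pa$parts)
      cfg <- config
      cfg$seed <- derive_seed(seed, paste0("cm_", tag))
      cm <- pairwise_matrix(sub, cfg)
      out[[length(out) + 1L]] <- data.frame(
        fraction = f, draw = dr, n_taxa = m, test = cm$tests,
        congruent = congruent_proportion(cm, orientation = "congruent"),
        ambiguous = congruent_proportion(cm, orientation = "ambiguous"),
        incongruent = congruent_proportion(cm, orientation = "incongruent"),
        row.names = NULL)
      taxa_kept[[tag]] <- taxa
    }
  }
  rep <- do.call(rbind, out)
  attr(rep, "taxa") <- taxa_kept
  class(rep) <- c("subsample_report", "data.frame")
  rep
}
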