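# End-to-end orchestration: configuration, stage sequencing, manifests and
# TSV/JSON outputs for the full analysis.

#' Full-run configuration
#'
#' Ties the pipeline stages together. Input is either a simulation scenario
#' or a NEXUS file with charsets; every stochastic stage receives a named
#' sub-seed derived from the master seed ([derive_seed()]), so toggling one
#' stage never shifts another's random stream.
#'
#' @param scenario a [simulation_scenario], or `NULL` when reading `input`.
#' @param input path to a NEXUS alignment with charsets (used when
#'   `scenario` is `NULL`).
#' @param stages which stages to run, in dependency order.
#' @param out output directory.
#' @param config a [congr_config] (tests, alpha, B, ILD permutations,
#'   search control).
#' @param gradient_test test feeding the gradient measure.
#' @param fractions subsampling fractions.
#' @param seed master seed.
#' @param profile `"desk"` (defaults), `"ci"` (fast: B = 1000, 1 restart)
#'   or `"full"` (B = 10000, 3 restarts).
#' @param overwrite allow writing into a non-empty output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(scenario = NULL, input = NULL,
                       stages = c("simulate", "pairwise", "antigene",
                                  "categories", "subsample", "gradient"),
                       out = "mitocong_out", config = congr_config(),
                       gradient_test = "p_au",
                       fractions = c(1, 0.5, 0.25, 0.10), seed = 1L,
                       profile = c("desk", "ci", "full"), overwrite = FALSE) {
  profile <- match.arg(profile)
  if (is.null(scenario) && is.null(input))
    stop("provide a simulation scenario or an input NEXUS path")
  if (profile == "ci") {
    config$B <- 1000L
    config$control$restarts <- 1L
  } else if (profile == "full") {
    config$B <- 10000L
    config$control$restarts <- 3L
  }
  config$seed <- as.integer(seed)
  structure(list(scenario = scenario, input = input, stages = stages,
                 out = out, config = config, gradient_test = gradient_test,
                 fractions = fractions, seed = as.integer(seed),
                 profile = profile, overwrite = overwrite),
            class = "run_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the pipeline
#'
#' Executes the requested stages in dependency order (simulate/ingest,
#' per-gene trees + pairwise tests, antigene, categories, subsample,
#' gradient), writing long-format TSV tables per stage plus a JSON manifest
#' (configuration, seeds, stage status, wall-clock). A failed stage leaves
#' earlier outputs in place and is recorded in the manifest.
#'
#' @param rc a [run_config].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  if (dir.exists(rc$out) && length(dir(rc$out)) && !rc$overwrite)
    stop("output directory ", rc$out, " is not empty; set overwrite = TRUE")
  dir.create(rc$out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  results <- list()
  status <- list()
  run_stage <- function(name, fun) {
    if (!name %in% rc$stages) return(invisible(NULL))
    message("[mitocong] stage: ", name)
    res <- tryCatch(fun(), error = function(e) {
      warning("stage ", name, " failed: ", conditionMessage(e))
      structure(list(message = conditionMessage(e)), class = "stage_error")
    })
    status[[name]] <<- if (inherits(res, "stage_error"))
      paste("failed:", res$message) else "ok"
    results[[name]] <<- res
    invisible(res)
  }

  # ingest / simulate
  if (!is.null(rc$scenario)) {
    ds <- generate_dataset(rc$scenario)
    if ("simulate" %in% rc$stages) {
      ddir <- file.path(rc$out, "dataset")
      write_dataset(ds, ddir, overwrite = rc$overwrite)
      status$simulate <- "ok"
    }
    pa <- ds$pa
    layout <- ds$layout
    results$dataset <- ds
  } else {
    pa <- read_nexus(rc$input)
    layout <- tryCatch(genome_layout_template("vertebrate"),
                       error = function(e) NULL)
  }

  cfgseed <- function(lab) {
    cfg <- rc$config
    cfg$seed <- derive_seed(rc$seed, lab)
    cfg
  }

  cm <- run_stage("pairwise", function() {
    cm <- pairwise_matrix(pa, cfgseed("pairwise"))
    write_tsv(as.data.frame(cm), file.path(rc$out, "pairwise.tsv"))
    cm
  })
  run_stage("antigene", function() {
    ar <- antigene_matrices(pa, cfgseed("antigene"))
    long <- do.call(rbind, lapply(ar$removed, function(g)
      do.call(rbind, lapply(setdiff(ar$singles, g), function(h)
        data.frame(removed = g, gene = h, test = ar$tests,
                   p_reject_gene = ar$p[g, h, ],
                   decision = ar$decision[g, h, ], row.names = NULL)))))
    write_tsv(long, file.path(rc$out, "antigene.tsv"))
    ar
  })
  run_stage("categories", function() {
    km <- category_matrix(pa, cfgseed("categories"))
    write_tsv(as.data.frame(km), file.path(rc$out, "categories.tsv"))
    km
  })
  run_stage("subsample", function() {
    sr <- subsample_experiment(pa, rc$fractions, cfgseed("subsample"))
    write_tsv(sr, file.path(rc$out, "subsample.tsv"))
    sr
  })
  run_stage("gradient", function() {
    if (is.null(cm) || inherits(cm, "stage_error"))
      stop("gradient stage needs the pairwise stage")
    if (is.null(layout)) stop("gradient stage needs a genome layout")
    gr <- gradient_report(cm, layout, test = rc$gradient_test)
    write_tsv(gr, file.path(rc$out, "gradient.tsv"))
    write_tsv(attr(gr, "scatter"), file.path(rc$out, "gradient_scatter.tsv"))
    gr
  })

  cfg_plain <- list(profile = rc$profile, seed = rc$seed,
                    stages = rc$stages, alpha = rc$config$alpha,
                    B = rc$config$B, R_ild = rc$config$R_ild,
                    restarts = rc$config$control$restarts,
                    gradient_test = rc$gradient_test,
                    fractions = rc$fractions,
                    seed_derivation = "derive_seed(master, stage_label)")
  cfgfile <- tempfile()
  writeLines(paste(deparse(cfg_plain), collapse = ""), cfgfile)
  manifest <- list(
    config = cfg_plain,
    config_hash = unname(tools::md5sum(cfgfile)),
    stage_status = status,
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(rc$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = results, manifest = manifest))
}
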