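#' Run the analysis pipeline from a configuration
#'
#' Orchestrates the stages end to end: `simulate` (virtual cohort + sparse
#' trial), `fit` (final-model estimation after BLLoQ discard), `select`
#' (stepwise covariate selection from the base model), `bootstrap`, `vpc`,
#' `forecast` (MAP exposure table) and `pta` (dose-optimization grid). Every
#' stochastic stage derives its seed from the global seed by a fixed offset,
#' each artifact is written under the output directory, and a manifest
#' (inputs, seeds, stage outputs, MD5 checksums) makes identical configs
#' yield identical checksums.
#'
#' @param config a list, or the path of a YAML file, with fields: `seed`
#'   (required), `outdir`, `stages` (subset of the names above, in
#'   dependency order), `n_per_stratum`, `n_sim` (VPC), `n_boot`,
#'   `n_patients` / `n_rep` (PTA), and optional `model` overrides (named
#'   scalars: `theta.cl_ind`, `sigma_add`, ...).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must provide a `seed`", call. = FALSE)
  all_stages <- c("simulate", "fit", "select", "bootstrap", "vpc", "forecast", "pta")
  stages <- if (is.null(config$stages)) all_stages else as.character(config$stages)
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  # every stage except simulate needs the simulated dataset in this run
  stages <- all_stages[all_stages %in% stages]
  seed <- as.integer(config$seed)
  outdir <- if (is.null(config$outdir)) "pzapk_run" else config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  offsets <- c(
    simulate = 1L, fit = 0L, select = 2L, bootstrap = 3L, vpc = 4L,
    forecast = 5L, pta = 6L
  )
  model <- apply_model_overrides(pza_model(), config$model)
  n_per_stratum <- config$n_per_stratum %||% 160L
  spec <- cohort_spec(n_per_stratum = n_per_stratum)
  manifest <- list(
    seed = seed, stages = stages, n_per_stratum = n_per_stratum,
    stage_seeds = as.list(offsets[stages] + seed), outputs = list()
  )
  paths <- character()
  dataset <- NULL
  fit_res <- NULL

  if ("simulate" %in% stages) {
    cohort <- sample_covariates(spec, seed = seed + offsets[["simulate"]])
    dataset <- simulate_trial(model, cohort,
      design = sampling_design(),
      seed = seed + offsets[["simulate"]]
    )
    p <- file.path(outdir, "dataset.csv")
    write_nm_csv(dataset, p)
    paths <- c(paths, p)
  }
  need_data <- function() {
    if (is.null(dataset)) {
      stop("stage requires the `simulate` stage (or a prior dataset)", call. = FALSE)
    }
    apply_blloq_policy(dataset)
  }
  if ("fit" %in% stages) {
    fit_res <- fit(model, need_data())
    p <- file.path(outdir, "fit_summary.txt")
    write_fit_summary(fit_res, p)
    paths <- c(paths, p)
  }
  if ("select" %in% stages) {
    base <- pza_model(covariates = list())
    sel <- stepwise_selection(base, default_covariate_effects_initial(), need_data())
    p <- file.path(outdir, "selection_trace.csv")
    utils::write.csv(sel$trace, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if ("bootstrap" %in% stages) {
    n_boot <- config$n_boot %||% 200L
    m <- if (!is.null(fit_res)) fit_res$model else model
    bs <- bootstrap(m, need_data(),
      n_resamples = n_boot,
      seed = seed + offsets[["bootstrap"]]
    )
    p <- file.path(outdir, "bootstrap.csv")
    utils::write.csv(bs$summary, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if ("vpc" %in% stages) {
    n_sim <- config$n_sim %||% 500L
    m <- if (!is.null(fit_res)) fit_res$model else model
    v <- pc_vpc(m, need_data(), n_sim = n_sim, seed = seed + offsets[["vpc"]])
    p <- file.path(outdir, "vpc.csv")
    utils::write.csv(v[[1]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if ("forecast" %in% stages) {
    m <- if (!is.null(fit_res)) fit_res$model else model
    et <- exposure_table(m, need_data())
    p <- file.path(outdir, "exposures.csv")
    utils::write.csv(et, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if ("pta" %in% stages) {
    grid <- pta_grid(model,
      spec = spec,
      n_patients = config$n_patients %||% 1000L,
      n_rep = config$n_rep %||% 200L,
      seed = seed + offsets[["pta"]]
    )
    p <- file.path(outdir, "pta_grid.csv")
    utils::write.csv(grid, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest$outputs <- lapply(stats::setNames(paths, basename(paths)), function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# candidate set for the selection stage: the two diabetes effects, starting
# from a null effect size
default_covariate_effects_initial <- function() {
  cands <- default_covariate_effects()
  lapply(cands, function(ef) {
    ef$value <- 0
    ef
  })
}

apply_model_overrides <- function(model, overrides) {
  if (is.null(overrides)) return(model)
  for (nm in names(overrides)) {
    val <- as.numeric(overrides[[nm]])
    if (grepl("^theta\\.", nm)) {
      model$theta[[sub("^theta\\.", "", nm)]] <- val
    } else if (grepl("^omega2\\.", nm)) {
      model$omega2[[sub("^omega2\\.", "", nm)]] <- val
    } else if (nm == "sigma_add") {
      model$sigma_add <- val
    } else {
      stop("unknown model override: ", nm, call. = FALSE)
    }
  }
  model
}
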