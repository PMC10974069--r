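#' Derive a deterministic sub-seed from a root seed and a stage tag
#'
#' Stable 31-base polynomial hash of the tag folded with the root seed into
#' `[0, 2^31)`; used so cohort generation, GA repeats and fold shuffles draw
#' from reproducible, stage-specific streams.
#'
#' @param root integer root seed.
#' @param tag character stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(root, tag) {
  h <- 0
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(root) + h) %% 2147483647)
}

#' Pipeline run configuration
#'
#' @param cohort a [cohort_config()], or `NULL` when `spectra_path` /
#'   `soil_path` point at existing CSV inputs.
#' @param spectra_path,soil_path optional input CSVs in the
#'   [write_cohort()] dialect; used instead of generation when supplied.
#' @param transforms transforms to sweep (default all eight).
#' @param metals metals to model (default both).
#' @param ga a [ga_config()]; its seed is re-derived from `seed`.
#' @param cutoff_nm,sg_window,sg_polyorder pre-processing parameters.
#' @param max_ncomp component cap (default `min(10, n_modeling - 2)`).
#' @param output_dir directory for report files.
#' @param seed root seed governing every stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       spectra_path = NULL, soil_path = NULL,
                       transforms = TRANSFORM_NAMES,
                       metals = c("cd", "as"),
                       ga = ga_config(),
                       cutoff_nm = 380, sg_window = 11, sg_polyorder = 2,
                       max_ncomp = NULL,
                       output_dir = tempfile("gaplsr_run_"),
                       seed = 1L) {
  if (length(transforms) == 0 || length(metals) == 0)
    stop("transforms and metals must be nonempty")
  structure(
    list(cohort = cohort, spectra_path = spectra_path, soil_path = soil_path,
         transforms = transforms, metals = metals, ga = ga,
         cutoff_nm = cutoff_nm, sg_window = sg_window,
         sg_polyorder = sg_polyorder, max_ncomp = max_ncomp,
         output_dir = output_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full estimation pipeline
#'
#' Orchestrates generate (or load) -> preprocess -> split -> GA select ->
#' PLSR fit -> evaluate for every configured (metal, transform) pair, and
#' writes: `report.csv` (one row per metal/transform/method),
#' `report.json` (report plus selected band lists), one GA
#' selection-frequency CSV per pair, one fitted-model JSON per pair, and
#' `manifest.json` (config echo, package version, derived seeds). The run is
#' a pure function of the configuration.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return Invisibly, the [compare_models()] result with an added
#'   `output_dir`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$spectra_path)) {
    if (is.null(config$soil_path) || !file.exists(config$spectra_path) ||
        !file.exists(config$soil_path))
      stop("stage input: spectra/soil CSV paths must both exist")
    say("stage input: reading cohort from %s", config$spectra_path)
    cohort <- read_cohort(config$spectra_path, config$soil_path)
  } else {
    ccfg <- config$cohort
    ccfg$seed <- derive_seed(config$seed, "cohort")
    say("stage generate: %d sites, seed %d", ccfg$n_sites, ccfg$seed)
    cohort <- tryCatch(generate_cohort(ccfg),
                       error = function(e) stop("stage generate: ",
                                                conditionMessage(e)))
  }

  ga <- config$ga
  ga$seed <- derive_seed(config$seed, "ga")
  res <- tryCatch(
    compare_models(cohort$spectra, cohort$soil,
                   transforms = config$transforms, metals = config$metals,
                   ga = ga, cutoff_nm = config$cutoff_nm,
                   window = config$sg_window, polyorder = config$sg_polyorder,
                   max_ncomp = config$max_ncomp),
    error = function(e) stop("stage model/evaluate: ", conditionMessage(e)))

  out <- config$output_dir
  utils::write.csv(format_report(res$report), file.path(out, "report.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(report = res$report,
         percent_change = res$percent_change,
         selected_wavelengths_nm = lapply(res$masks, function(m)
           res$wavelength[m])),
    file.path(out, "report.json"), digits = NA, auto_unbox = TRUE)

  sp <- split_one_in_four(length(cohort$spectra$site_id))
  for (key in names(res$frequencies)) {
    utils::write.csv(
      data.frame(wavelength_nm = res$wavelength,
                 selection_frequency = res$frequencies[[key]],
                 selected = res$masks[[key]]),
      file.path(out, paste0("ga_frequency_", key, ".csv")),
      row.names = FALSE, quote = FALSE)
    say("stage report: %s -> %d bands selected", key, sum(res$masks[[key]]))
  }
  write_final_models(cohort, res, config, out)

  manifest <- list(
    package_version = as.character(utils::packageVersion("gaplsr")),
    r_version = R.version.string,
    seed = config$seed,
    derived_seeds = list(cohort = derive_seed(config$seed, "cohort"),
                         ga = derive_seed(config$seed, "ga")),
    config = config_to_list(config),
    n_modeling = length(sp$modeling), n_validation = length(sp$validation))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  res$output_dir <- out
  invisible(res)
}

format_report <- function(report) {
  num <- vapply(report, is.numeric, logical(1))
  report[num] <- lapply(report[num], function(x) signif(x, 10))
  report
}

write_final_models <- function(cohort, res, config, out) {
  ord <- order(cohort$spectra$site_id)
  spectra <- subset_spectra(cohort$spectra, sites = ord)
  soil <- cohort$soil[ord, ]
  base <- sg_smooth(trim_low_bands(spectra, config$cutoff_nm),
                    config$sg_window, config$sg_polyorder)
  sp <- split_one_in_four(length(base$site_id))
  for (key in names(res$masks)) {
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    metal <- parts[1]; tr <- parts[2]
    msc_ref <- if (tr == "MSC")
      msc_fit(subset_spectra(base, sites = sp$modeling)) else NULL
    X <- apply_transform(base, tr, msc_ref = msc_ref)$reflectance
    mask <- res$masks[[key]]
    row <- res$report[res$report$metal == metal &
                      res$report$transform == tr &
                      res$report$method == "GA-PLSR", ]
    fit <- fit_plsr(X[sp$modeling, mask, drop = FALSE],
                    soil[[metal]][sp$modeling], row$pc[1])
    plsr_to_json(fit, file.path(out, paste0("model_", key, ".json")))
  }
  invisible(NULL)
}

config_to_list <- function(config) {
  cl <- unclass(config)
  cl$cohort <- if (is.null(cl$cohort)) NULL else unclass(cl$cohort)
  cl$ga <- unclass(cl$ga)
  cl
}

#' Read a JSON run configuration file
#'
#' Flat JSON mirroring the [run_config()] fields, with nested `cohort` and
#' `ga` objects mirroring [cohort_config()] / [ga_config()].
#'
#' @param path JSON file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort <- if (!is.null(j$cohort)) do.call(cohort_config, j$cohort)
            else if (is.null(j$spectra_path)) cohort_config() else NULL
  ga <- if (!is.null(j$ga)) do.call(ga_config, j$ga) else ga_config()
  args <- j[setdiff(names(j), c("cohort", "ga"))]
  do.call(run_config, c(list(cohort = cohort, ga = ga), args))
}
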