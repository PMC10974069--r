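#' One-in-four modeling/validation split
#'
#' Samples ordered by the stated sort key (ascending site id) are split by
#' taking every 4th sample for validation (1-based positions 4, 8, 12, ...);
#' the remainder form the modeling set. For n = 22 this yields 17 modeling and
#' 5 validation samples.
#'
#' @param n number of samples (>= 4).
#' @return A list with integer index vectors `modeling` and `validation`.
#' @export
split_one_in_four <- function(n) {
  n <- as.integer(n)
  if (n < 4) stop("need at least 4 samples for a one-in-four split")
  validation <- seq(4L, n, by = 4L)
  list(modeling = setdiff(seq_len(n), validation), validation = validation)
}

#' Error and agreement metrics
#'
#' `rmse()` is the root mean squared error; `r2()` is `1 - SSE/SST` computed
#' against the observed values' own mean.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return A scalar.
#' @export
rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  sqrt(mean((observed - predicted)^2))
}

#' @rdname rmse
#' @export
r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  sst <- sum((observed - mean(observed))^2)
  if (sst < 1e-24) stop("observed values have zero variance; R2 undefined")
  1 - sum((observed - predicted)^2) / sst
}

#' Ratio of performance to deviation
#'
#' Standard deviation (n - 1 denominator) of the observed validation values
#' divided by the external-validation RMSE.
#'
#' @param observed,predicted validation observations and predictions
#'   (>= 3 values, nonzero observed variance).
#' @return The RPD (dimensionless, > 0).
#' @export
rpd <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  s <- stats::sd(observed)
  if (s < 1e-12) stop("observed validation values have zero variance")
  s / rmse(observed, predicted)
}

#' Williams five-level RPD interpretation
#'
#' `> 3.00` excellent; `(2.50, 3.00]` good; `(2.00, 2.50]` approximate
#' quantitative estimation; `(1.50, 2.00]` distinguishes high from low values;
#' `<= 1.50` poor. Interior boundaries are assigned to the lower tier's open
#' end so every positive RPD maps to exactly one tier.
#'
#' @param x RPD value(s), > 0.
#' @return Character vector of tier labels.
#' @export
classify_rpd <- function(x) {
  if (any(x <= 0)) stop("RPD must be positive")
  cut(x, breaks = c(0, 1.5, 2, 2.5, 3, Inf),
      labels = c("poor", "distinguishes high/low", "approximate quantitative",
                 "good", "excellent"),
      right = TRUE) |> as.character()
}

eval_report_row <- function(metal, transform, n_bands, ncomp, cv, obs_ev,
                            pred_ev, method) {
  data.frame(
    metal = metal, transform = transform, method = method,
    n_bands = n_bands, pc = ncomp,
    r2_cv = cv$r2_cv, rmse_cv = cv$rmse_cv,
    r2_ev = r2(obs_ev, pred_ev), rmse_ev = rmse(obs_ev, pred_ev),
    rpd = rpd(obs_ev, pred_ev),
    rpd_category = classify_rpd(rpd(obs_ev, pred_ev)),
    stringsAsFactors = FALSE
  )
}

#' Compare GA-PLSR against full-band PLSR across transforms and metals
#'
#' For each (metal, transform) pair: trim and smooth all spectra, apply the
#' one-in-four split, fit any transform reference (MSC) on the modeling set
#' only, run full-band PLSR cross-validation and GA band selection + PLSR
#' cross-validation on the modeling set, refit final models on the modeling
#' set, and evaluate both on the held-out validation set. No validation
#' sample influences the MSC reference, autoscaling, GA search, or component
#' choice.
#'
#' @param spectra a raw `spectra_set`.
#' @param soil the matching `soil_table`.
#' @param transforms character vector of [TRANSFORM_NAMES].
#' @param metals subset of `c("cd", "as")`.
#' @param ga a [ga_config()].
#' @param cutoff_nm,window,polyorder pre-processing parameters.
#' @param max_ncomp component cap for cross-validation (default
#'   `min(10, n_modeling - 2)`).
#' @return A list with `report` (one data.frame row per metal, transform and
#'   method), `masks` (named list of GA masks), and `frequencies` (named list
#'   of per-channel GA selection frequencies).
#' @export
compare_models <- function(spectra, soil, transforms = TRANSFORM_NAMES,
                           metals = c("cd", "as"), ga = ga_config(),
                           cutoff_nm = 380, window = 11, polyorder = 2,
                           max_ncomp = NULL) {
  stopifnot(inherits(spectra, "spectra_set"))
  check_cohort_alignment(spectra, soil)
  transforms <- match.arg(transforms, TRANSFORM_NAMES, several.ok = TRUE)
  metals <- match.arg(metals, c("cd", "as"), several.ok = TRUE)

  ord <- order(spectra$site_id)
  spectra <- subset_spectra(spectra, sites = ord)
  soil <- soil[ord, ]

  base <- sg_smooth(trim_low_bands(spectra, cutoff_nm), window, polyorder)
  sp <- split_one_in_four(length(base$site_id))

  rows <- list(); masks <- list(); freqs <- list()
  for (tr in transforms) {
    msc_ref <- if (tr == "MSC")
      msc_fit(subset_spectra(base, sites = sp$modeling)) else NULL
    Xall <- apply_transform(base, tr, msc_ref = msc_ref)$reflectance
    Xm <- Xall[sp$modeling, , drop = FALSE]
    Xv <- Xall[sp$validation, , drop = FALSE]
    for (metal in metals) {
      y <- soil[[metal]]
      ym <- y[sp$modeling]; yv <- y[sp$validation]
      nm <- length(ym)
      mc <- if (is.null(max_ncomp)) min(10L, nm - 2L) else max_ncomp
      folds <- cv_folds(nm, "loo")

      cv_full <- cross_validate(Xm, ym, max_ncomp = mc, folds = folds)
      fit_full <- fit_plsr(Xm, ym, cv_full$chosen_ncomp)
      rows[[length(rows) + 1L]] <- eval_report_row(
        metal, tr, ncol(Xm), cv_full$chosen_ncomp, cv_full,
        yv, predict(fit_full, Xv), "PLSR")

      sel <- select_bands(Xm, ym, config = ga, folds = folds, max_ncomp = mc)
      Xms <- Xm[, sel$mask, drop = FALSE]
      cv_ga <- cross_validate(Xms, ym,
                              max_ncomp = min(mc, sum(sel$mask)),
                              folds = folds)
      fit_ga <- fit_plsr(Xms, ym, cv_ga$chosen_ncomp)
      key <- paste(metal, tr, sep = "_")
      masks[[key]] <- sel$mask
      freqs[[key]] <- sel$selection_frequency
      rows[[length(rows) + 1L]] <- eval_report_row(
        metal, tr, sum(sel$mask), cv_ga$chosen_ncomp, cv_ga,
        yv, predict(fit_ga, Xv[, sel$mask, drop = FALSE]), "GA-PLSR")
    }
  }
  report <- do.call(rbind, rows)
  list(report = report, masks = masks, frequencies = freqs,
       wavelength = base$wavelength,
       percent_change = percent_change_summary(report))
}

# 100*(GA - full)/full for R2cv and 100*(full - GA)/full for RMSEcv, per
# (metal, transform): positive numbers mean the GA improved the model.
percent_change_summary <- function(report) {
  keys <- unique(report[, c("metal", "transform")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- report[report$metal == keys$metal[i] &
                  report$transform == keys$transform[i], ]
    full <- sub[sub$method == "PLSR", ]
    gap <- sub[sub$method == "GA-PLSR", ]
    if (nrow(full) != 1 || nrow(gap) != 1) return(NULL)
    data.frame(metal = keys$metal[i], transform = keys$transform[i],
               r2_cv_change_pct = 100 * (gap$r2_cv - full$r2_cv) / full$r2_cv,
               rmse_cv_change_pct = 100 * (full$rmse_cv - gap$rmse_cv) / full$rmse_cv)
  })
  do.call(rbind, out)
}
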