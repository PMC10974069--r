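#' Spectra container
#'
#' A `spectra_set` holds a sample-by-wavelength matrix of leaf spectra together
#' with its wavelength grid (nm) and sample identifiers. Raw (untransformed)
#' spectra are reflectance fractions in (0, 1]; transformed spectra (derivative,
#' absorbance, ...) may take any finite value.
#'
#' @param reflectance numeric matrix, one row per site, one column per channel.
#' @param wavelength strictly increasing numeric vector of channel centres (nm).
#' @param site_id character vector of unique site identifiers.
#' @param raw logical; if `TRUE` values are checked to lie in (0, 1].
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(reflectance, wavelength, site_id, raw = TRUE) {
  reflectance <- as.matrix(reflectance)
  wavelength <- as.numeric(wavelength)
  site_id <- as.character(site_id)
  if (ncol(reflectance) != length(wavelength))
    stop("number of columns must match length of wavelength grid")
  if (nrow(reflectance) != length(site_id))
    stop("number of rows must match number of site ids")
  if (anyDuplicated(site_id))
    stop("site ids must be unique")
  if (length(wavelength) >= 2 && any(diff(wavelength) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (!all(is.finite(reflectance)))
    stop("reflectance must be finite")
  if (raw && (any(reflectance <= 0) || any(reflectance > 1)))
    stop("raw reflectance must lie in (0, 1]")
  dimnames(reflectance) <- list(site_id, format_wl(wavelength))
  structure(
    list(reflectance = reflectance, wavelength = wavelength, site_id = site_id),
    class = "spectra_set"
  )
}

format_wl <- function(wl) formatC(wl, format = "g", digits = 10)

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf(
    "<spectra_set> %d sites x %d channels, %.1f-%.1f nm\n",
    nrow(x$reflectance), ncol(x$reflectance),
    min(x$wavelength), max(x$wavelength)
  ))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$reflectance)

#' Subset a spectra_set by sites and/or channels
#'
#' @param x a `spectra_set`.
#' @param sites integer or logical index over rows.
#' @param channels integer or logical index over wavelength channels.
#' @return A `spectra_set` with the selected rows/columns.
#' @export
subset_spectra <- function(x, sites = NULL, channels = NULL) {
  stopifnot(inherits(x, "spectra_set"))
  if (is.null(sites)) sites <- seq_along(x$site_id)
  if (is.null(channels)) channels <- seq_along(x$wavelength)
  spectra_set(
    x$reflectance[sites, channels, drop = FALSE],
    x$wavelength[channels], x$site_id[sites], raw = FALSE
  )
}

#' Soil table constructor
#'
#' Per-site soil measurements: pH and heavy-metal concentrations (mg/kg).
#'
#' @param site_id character vector of unique site identifiers.
#' @param ph numeric vector of soil pH values.
#' @param cd,as numeric vectors of Cd and As concentrations (mg/kg), > 0.
#' @return A `data.frame` with class `soil_table` prepended.
#' @export
soil_table <- function(site_id, ph, cd, as) {
  site_id <- as.character(site_id)
  if (anyDuplicated(site_id)) stop("site ids must be unique")
  if (any(cd <= 0) || any(as <= 0)) stop("metal concentrations must be positive")
  structure(
    data.frame(site_id = site_id, ph = ph, cd = cd, as = as,
               stringsAsFactors = FALSE),
    class = c("soil_table", "data.frame")
  )
}

check_cohort_alignment <- function(spectra, soil) {
  if (!identical(spectra$site_id, soil$site_id))
    stop("site ids of spectra and soil table do not match (order matters)")
  invisible(TRUE)
}

#' Write a cohort to CSV files
#'
#' The spectra CSV has header `site_id,<wl1>,<wl2>,...` (wavelengths in nm) and
#' one row per site; the soil CSV has header `site_id,ph,cd_mg_kg,as_mg_kg`.
#' Files round-trip losslessly through [read_cohort()].
#'
#' @param spectra a `spectra_set`.
#' @param soil a `soil_table` with matching site ids in the same order.
#' @param spectra_path,soil_path output file paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_cohort <- function(spectra, soil, spectra_path, soil_path) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (nrow(spectra$reflectance) == 0L) stop("refusing to write an empty cohort")
  check_cohort_alignment(spectra, soil)
  # %.17g so doubles round-trip exactly through read_cohort()
  num17 <- function(x) formatC(x, format = "g", digits = 17)
  sp <- data.frame(site_id = spectra$site_id,
                   matrix(num17(spectra$reflectance),
                          nrow = nrow(spectra$reflectance)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(sp) <- c("site_id", num17(spectra$wavelength))
  utils::write.csv(sp, spectra_path, row.names = FALSE, quote = FALSE)
  so <- data.frame(site_id = soil$site_id, ph = num17(soil$ph),
                   cd_mg_kg = num17(soil$cd), as_mg_kg = num17(soil$as))
  utils::write.csv(so, soil_path, row.names = FALSE, quote = FALSE)
  invisible(c(spectra = spectra_path, soil = soil_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param spectra_path,soil_path file paths as written by [write_cohort()].
#' @param raw logical; passed to [spectra_set()] value validation.
#' @return A list with elements `spectra` (a `spectra_set`) and `soil`
#'   (a `soil_table`).
#' @export
read_cohort <- function(spectra_path, soil_path, raw = TRUE) {
  sp <- utils::read.csv(spectra_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  wl <- as.numeric(names(sp)[-1])
  spectra <- spectra_set(as.matrix(sp[, -1, drop = FALSE]), wl,
                         sp$site_id, raw = raw)
  so <- utils::read.csv(soil_path, stringsAsFactors = FALSE)
  soil <- soil_table(so$site_id, so$ph, so$cd_mg_kg, so$as_mg_kg)
  check_cohort_alignment(spectra, soil)
  list(spectra = spectra, soil = soil)
}
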