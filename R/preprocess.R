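#' Spectral transforms
#'
#' The eight pre-processing variants applied to smoothed reflectance spectra:
#' raw reflectance (`R`), first and second derivatives (`FD`, `SD`),
#' absorbance `log10(1/R)` (`AT`), first and second derivatives of absorbance
#' (`AFD`, `ASD`), multiplicative scatter correction (`MSC`) and standard
#' normal variate (`SNV`).
#'
#' @name transforms
#' @export
TRANSFORM_NAMES <- c("R", "FD", "SD", "AT", "AFD", "ASD", "MSC", "SNV")

#' Strip noisy low-wavelength edge bands
#'
#' @param spectra a `spectra_set`.
#' @param cutoff_nm channels with wavelength `>= cutoff_nm` are retained.
#' @return A trimmed `spectra_set`.
#' @export
trim_low_bands <- function(spectra, cutoff_nm = 380) {
  stopifnot(inherits(spectra, "spectra_set"))
  keep <- spectra$wavelength >= cutoff_nm
  if (!any(keep)) stop("no channel survives the wavelength cutoff")
  subset_spectra(spectra, channels = keep)
}

# SG convolution coefficients for the derivative-0 filter of half-width h.
sg_coefficients <- function(window, polyorder) {
  h <- (window - 1L) %/% 2L
  A <- outer(-h:h, 0:polyorder, `^`)
  # first row of (A'A)^-1 A' = least-squares value at the window centre
  drop(solve(crossprod(A), t(A))[1L, ])
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing with a symmetric moving window. Near the
#' two edges, where the full window does not fit, the polynomial is fit on the
#' truncated window and evaluated at the target channel, so the grid length is
#' preserved.
#'
#' @param spectra a `spectra_set`.
#' @param window odd window length in channels.
#' @param polyorder polynomial order, `< window`.
#' @return A smoothed `spectra_set` on the same grid.
#' @export
sg_smooth <- function(spectra, window = 11, polyorder = 2) {
  stopifnot(inherits(spectra, "spectra_set"))
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  p <- ncol(spectra$reflectance)
  if (window > p) stop("window larger than channel count")
  h <- (window - 1L) %/% 2L
  cf <- sg_coefficients(window, polyorder)
  X <- spectra$reflectance
  out <- X
  # interior: plain convolution
  if (p >= window) {
    sm <- t(apply(X, 1L, function(x) stats::filter(x, cf, sides = 2)))
    idx <- (h + 1L):(p - h)
    out[, idx] <- sm[, idx]
  }
  # edges: truncated-window polynomial fit evaluated at the channel
  for (i in c(seq_len(h), (p - h + 1L):p)) {
    win <- max(1L, i - h):min(p, i + h)
    A <- outer(win - i, 0:polyorder, `^`)
    w <- drop(solve(crossprod(A), t(A))[1L, ])
    out[, i] <- X[, win, drop = FALSE] %*% w
  }
  spectra_set(out, spectra$wavelength, spectra$site_id, raw = FALSE)
}

#' Absorbance transform: log10(1/R)
#'
#' @param spectra a `spectra_set` with strictly positive values.
#' @return The absorbance `spectra_set`.
#' @export
absorbance <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (any(spectra$reflectance <= 0))
    stop("absorbance requires strictly positive reflectance")
  spectra_set(-log10(spectra$reflectance), spectra$wavelength,
              spectra$site_id, raw = FALSE)
}

#' Spectral derivative with respect to wavelength
#'
#' Central finite differences on interior channels, using the grid's actual
#' per-interval spacing, with one-sided stencils at the two edges so the
#' output keeps the full grid. Units are per nm (order 1) or per nm^2
#' (order 2).
#'
#' @param spectra a `spectra_set` with at least 3 channels.
#' @param order 1 (first derivative) or 2 (second derivative).
#' @param keep_edges if `FALSE`, the two edge channels are dropped instead of
#'   using one-sided stencils.
#' @return A `spectra_set` of derivative values.
#' @export
derivative <- function(spectra, order = 1, keep_edges = TRUE) {
  stopifnot(inherits(spectra, "spectra_set"), order %in% c(1, 2))
  wl <- spectra$wavelength
  p <- length(wl)
  if (p < 3) stop("derivative requires at least 3 channels")
  X <- spectra$reflectance
  D <- matrix(0, nrow(X), p)
  il <- 2:(p - 1)
  if (order == 1) {
    D[, il] <- sweep(X[, il + 1, drop = FALSE] - X[, il - 1, drop = FALSE],
                     2, wl[il + 1] - wl[il - 1], "/")
    D[, 1] <- (X[, 2] - X[, 1]) / (wl[2] - wl[1])
    D[, p] <- (X[, p] - X[, p - 1]) / (wl[p] - wl[p - 1])
  } else {
    # 3-point second derivative (slope-difference form: exact zero on
    # constants, exact for quadratics on non-uniform grids)
    h1 <- wl[il] - wl[il - 1]
    h2 <- wl[il + 1] - wl[il]
    slope_right <- sweep(X[, il + 1, drop = FALSE] - X[, il, drop = FALSE],
                         2, h2, "/")
    slope_left <- sweep(X[, il, drop = FALSE] - X[, il - 1, drop = FALSE],
                        2, h1, "/")
    D[, il] <- sweep(slope_right - slope_left, 2, (h1 + h2) / 2, "/")
    D[, 1] <- D[, 2]      # one-sided: 3-point stencil on channels 1..3
    D[, p] <- D[, p - 1]  # one-sided: 3-point stencil on channels p-2..p
  }
  if (!keep_edges) {
    D <- D[, il, drop = FALSE]
    wl <- wl[il]
  }
  spectra_set(D, wl, spectra$site_id, raw = FALSE)
}

#' Multiplicative scatter correction
#'
#' `msc_fit()` stores the channelwise mean of a calibration set as the MSC
#' reference; `msc_apply()` regresses each spectrum on `(1, reference)` by
#' ordinary least squares and returns `(x - a) / b`. Keeping the fitted
#' reference allows validation spectra to be corrected without leaking them
#' into the reference.
#'
#' @param calibration a `spectra_set` with at least 2 spectra.
#' @return `msc_fit()`: an object of class `msc_reference`.
#' @export
msc_fit <- function(calibration) {
  stopifnot(inherits(calibration, "spectra_set"))
  if (nrow(calibration$reflectance) < 2)
    stop("MSC reference requires at least 2 calibration spectra")
  structure(
    list(reference = colMeans(calibration$reflectance),
         wavelength = calibration$wavelength),
    class = "msc_reference"
  )
}

#' @rdname msc_fit
#' @param spectra a `spectra_set` on the reference's wavelength grid.
#' @param ref an `msc_reference` from `msc_fit()`.
#' @return `msc_apply()`: the corrected `spectra_set`.
#' @export
msc_apply <- function(spectra, ref) {
  stopifnot(inherits(spectra, "spectra_set"), inherits(ref, "msc_reference"))
  if (!isTRUE(all.equal(spectra$wavelength, ref$wavelength)))
    stop("wavelength grid does not match the MSC reference")
  m <- ref$reference
  mc <- m - mean(m)
  denom <- sum(mc^2)
  X <- spectra$reflectance
  b <- as.vector(X %*% mc) / denom            # OLS slope on (1, reference)
  a <- rowMeans(X) - b * mean(m)
  bad <- abs(b) < 1e-12
  if (any(bad))
    stop("MSC slope numerically zero for sample(s): ",
         paste(spectra$site_id[bad], collapse = ", "))
  spectra_set((X - a) / b, spectra$wavelength, spectra$site_id, raw = FALSE)
}

#' Standard normal variate transform
#'
#' Each spectrum is centred to its own mean and scaled to its own standard
#' deviation (denominator n - 1).
#'
#' @param spectra a `spectra_set`; every spectrum must have nonzero
#'   within-spectrum standard deviation.
#' @return The standardized `spectra_set`.
#' @export
snv <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  X <- spectra$reflectance
  s <- apply(X, 1L, stats::sd)
  if (any(s < 1e-12))
    stop("SNV undefined for constant spectrum: ",
         paste(spectra$site_id[s < 1e-12], collapse = ", "))
  spectra_set((X - rowMeans(X)) / s, spectra$wavelength, spectra$site_id,
              raw = FALSE)
}

#' Apply a named spectral transform
#'
#' Dispatches one of [TRANSFORM_NAMES] on (already trimmed and smoothed)
#' reflectance spectra. For `MSC`, if `msc_ref` is `NULL` the input itself is
#' used as the calibration set; supplying the reference fitted on the modeling
#' set is what prevents validation leakage.
#'
#' @param spectra a `spectra_set`.
#' @param name one of `"R"`, `"FD"`, `"SD"`, `"AT"`, `"AFD"`, `"ASD"`,
#'   `"MSC"`, `"SNV"`.
#' @param msc_ref optional `msc_reference` (MSC only).
#' @return The transformed `spectra_set`.
#' @export
apply_transform <- function(spectra, name, msc_ref = NULL) {
  stopifnot(inherits(spectra, "spectra_set"))
  name <- match.arg(name, TRANSFORM_NAMES)
  switch(name,
    R = spectra,
    FD = derivative(spectra, 1),
    SD = derivative(spectra, 2),
    AT = absorbance(spectra),
    AFD = derivative(absorbance(spectra), 1),
    ASD = derivative(absorbance(spectra), 2),
    MSC = msc_apply(spectra, if (is.null(msc_ref)) msc_fit(spectra) else msc_ref),
    SNV = snv(spectra)
  )
}

#' Standard pre-processing pipeline: trim, smooth, transform
#'
#' Fixed order: strip edge bands below `cutoff_nm`, Savitzky-Golay smooth,
#' then apply the requested transform.
#'
#' @inheritParams apply_transform
#' @inheritParams sg_smooth
#' @inheritParams trim_low_bands
#' @return The pre-processed `spectra_set`.
#' @export
preprocess <- function(spectra, name = "R", cutoff_nm = 380,
                       window = 11, polyorder = 2, msc_ref = NULL) {
  sm <- sg_smooth(trim_low_bands(spectra, cutoff_nm), window, polyorder)
  apply_transform(sm, name, msc_ref = msc_ref)
}
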