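#' Configuration for the synthetic leaf-spectra / soil-metal cohort
#'
#' Defaults reproduce the field campaign the package emulates: 22 paddy sites,
#' a 301-1145 nm grid at 3.3 nm resolution, soil Cd 0.13-0.97 (mean 0.29)
#' mg/kg, soil As 3.23-9.32 (mean 5.64) mg/kg, Cd-As Pearson correlation 0.33
#' and mean soil pH 5.86. Metal stress is expressed in the spectra through two
#' pathways: Cd depresses the 450/670 nm chlorophyll absorption wells and As
#' depresses the near-infrared plateau, each linearly and with additive
#' Gaussian noise. Per-spectrum affine scatter (multiplicative gain + offset)
#' and i.i.d. channel noise emulate instrument/illumination effects.
#'
#' @param n_sites number of sampling sites.
#' @param wavelength_start_nm,wavelength_step_nm,wavelength_end_nm arithmetic
#'   wavelength grid `start + k*step <= end` (nm).
#' @param cd_mean,cd_range mean and `c(min, max)` of soil Cd (mg/kg).
#' @param as_mean,as_range mean and `c(min, max)` of soil As (mg/kg).
#' @param cd_as_corr target Pearson correlation between Cd and As, in (-1, 1).
#' @param ph_mean,ph_sd,ph_halfwidth soil pH: truncated normal with the given
#'   mean/sd, truncated symmetrically to `ph_mean +/- ph_halfwidth` so the
#'   truncated mean equals `ph_mean` exactly.
#' @param stress_slope_cd chlorophyll-well depression per mg/kg Cd
#'   (dimensionless fraction of well depth, applied to centred Cd).
#' @param stress_slope_as NIR-plateau depression per mg/kg As (fraction of
#'   plateau level, applied to centred As).
#' @param chl_noise_sd,nir_noise_sd sd of the additive noise on the two latent
#'   stress indices (dimensionless).
#' @param scatter_sd_add,scatter_sd_mult per-spectrum additive offset sd
#'   (reflectance units) and multiplicative gain sd (dimensionless).
#' @param channel_noise_sd i.i.d. per-channel noise sd (reflectance units).
#' @param seed integer seed; the whole cohort is a pure function of the config.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_sites = 22,
                          wavelength_start_nm = 301,
                          wavelength_step_nm = 3.3,
                          wavelength_end_nm = 1145,
                          cd_mean = 0.29, cd_range = c(0.13, 0.97),
                          as_mean = 5.64, as_range = c(3.23, 9.32),
                          cd_as_corr = 0.33,
                          ph_mean = 5.86, ph_sd = 0.35, ph_halfwidth = 1.4,
                          stress_slope_cd = 0.5,
                          stress_slope_as = 0.04,
                          chl_noise_sd = 0.02,
                          nir_noise_sd = 0.02,
                          scatter_sd_add = 0.01,
                          scatter_sd_mult = 0.03,
                          channel_noise_sd = 0.002,
                          seed = 1L) {
  cfg <- list(
    n_sites = as.integer(n_sites),
    wavelength_start_nm = wavelength_start_nm,
    wavelength_step_nm = wavelength_step_nm,
    wavelength_end_nm = wavelength_end_nm,
    cd_mean = cd_mean, cd_range = as.numeric(cd_range),
    as_mean = as_mean, as_range = as.numeric(as_range),
    cd_as_corr = cd_as_corr,
    ph_mean = ph_mean, ph_sd = ph_sd, ph_halfwidth = ph_halfwidth,
    stress_slope_cd = stress_slope_cd, stress_slope_as = stress_slope_as,
    chl_noise_sd = chl_noise_sd, nir_noise_sd = nir_noise_sd,
    scatter_sd_add = scatter_sd_add, scatter_sd_mult = scatter_sd_mult,
    channel_noise_sd = channel_noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_sites < 1) stop("n_sites must be positive")
    if (wavelength_step_nm <= 0) stop("wavelength step must be positive")
    if (!(cd_range[1] < cd_mean && cd_mean < cd_range[2]))
      stop("cd_mean must lie strictly inside cd_range (moment calibration infeasible)")
    if (!(as_range[1] < as_mean && as_mean < as_range[2]))
      stop("as_mean must lie strictly inside as_range (moment calibration infeasible)")
    if (cd_range[1] <= 0 || as_range[1] <= 0)
      stop("metal ranges must be positive")
    if (abs(cd_as_corr) >= 1) stop("cd_as_corr must lie in (-1, 1)")
    wl <- wavelength_grid(cfg)
    if (sum(wl >= 380) < 50)
      stop("grid must retain at least 50 channels at >= 380 nm")
  })
  invisible(cfg)
}

wavelength_grid <- function(cfg) {
  k <- 0:floor((cfg$wavelength_end_nm - cfg$wavelength_start_nm) /
                 cfg$wavelength_step_nm)
  cfg$wavelength_start_nm + cfg$wavelength_step_nm * k
}

## --- truncated log-normal marginal, calibrated to (mean, range) -------------

# The printed range is read as the 0.5th/99.5th percentile pair of the
# untruncated log-normal (fixing sigma); mu is then solved so that the mean of
# the [lo, hi]-truncated distribution equals the printed mean.
calibrate_trunc_lnorm <- function(mean, range, p_tail = 0.005) {
  lo <- range[1]; hi <- range[2]
  if (!(lo < mean && mean < hi)) stop("mean must lie inside range")
  sigma <- (log(hi) - log(lo)) / (2 * stats::qnorm(1 - p_tail))
  tmean <- function(mu) {
    a <- (log(lo) - mu) / sigma
    b <- (log(hi) - mu) / sigma
    exp(mu + sigma^2 / 2) *
      (stats::pnorm(b - sigma) - stats::pnorm(a - sigma)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  mu <- stats::uniroot(function(m) tmean(m) - mean,
                       lower = log(lo), upper = log(hi),
                       extendInt = "upX", tol = 1e-12)$root
  list(mu = mu, sigma = sigma, lo = lo, hi = hi)
}

# Quantile of the [lo, hi]-truncated log-normal at probability p.
qtrunc_lnorm <- function(p, par) {
  pa <- stats::pnorm((log(par$lo) - par$mu) / par$sigma)
  pb <- stats::pnorm((log(par$hi) - par$mu) / par$sigma)
  exp(par$mu + par$sigma * stats::qnorm(pa + p * (pb - pa)))
}

## --- Gaussian copula correlation inversion (deterministic quadrature) -------

gauss_hermite <- function(n) {
  # Golub-Welsch for the Hermite weight exp(-x^2); nodes/weights for
  # E[f(Z)] = sum w_i f(sqrt(2) x_i) / sqrt(pi), Z ~ N(0,1).
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- diag(0, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(z = sqrt(2) * e$values, w = (e$vectors[1, ])^2)
}

# Pearson correlation of the two truncated-log-normal margins when coupled by
# a Gaussian copula with latent correlation rho.
copula_pearson <- function(rho, par1, par2, gh) {
  g1 <- qtrunc_lnorm(stats::pnorm(gh$z), par1)
  m1 <- sum(gh$w * g1); s1 <- sqrt(sum(gh$w * (g1 - m1)^2))
  g2fun <- function(z) qtrunc_lnorm(stats::pnorm(z), par2)
  g2 <- g2fun(gh$z)
  m2 <- sum(gh$w * g2); s2 <- sqrt(sum(gh$w * (g2 - m2)^2))
  zz <- outer(gh$z, gh$z, function(z1, z2) rho * z1 + sqrt(1 - rho^2) * z2)
  exy <- sum(outer(gh$w, gh$w) * (g1 %o% rep(1, length(gh$z))) * g2fun(zz))
  (exy - m1 * m2) / (s1 * s2)
}

invert_copula_corr <- function(target, par1, par2, n_nodes = 48) {
  gh <- gauss_hermite(n_nodes)
  stats::uniroot(function(r) copula_pearson(r, par1, par2, gh) - target,
                 lower = -0.995, upper = 0.995, tol = 1e-8)$root
}

## --- spectrum model ----------------------------------------------------------

# Deterministic base reflectance for one sample given its two stress factors:
# chl in ~[0,1.3] scales the chlorophyll well depths, nir_level is the NIR
# plateau reflectance. Vegetation shape: blue/red absorption wells at 450 and
# 670 nm, green relative peak at 550 nm, logistic red edge near 718 nm, flat
# high-reflectance NIR plateau.
base_leaf_spectrum <- function(wl, chl = 1, nir_level = 0.48) {
  vis <- 0.10 +
    0.09 * exp(-(wl - 550)^2 / (2 * 32^2)) -
    chl * 0.050 * exp(-(wl - 450)^2 / (2 * 28^2)) -
    chl * 0.070 * exp(-(wl - 670)^2 / (2 * 20^2))
  edge <- 1 / (1 + exp(-(wl - 718) / 11))
  vis * (1 - edge) + nir_level * edge
}

#' Generate a synthetic cohort of paired leaf spectra and soil metals
#'
#' Soil Cd and As are drawn from truncated log-normal marginals, moment
#' calibrated to the configured (mean, range), and coupled through a Gaussian
#' copula whose latent correlation is numerically inverted (by Gauss-Hermite
#' quadrature, no Monte Carlo) so that the output Pearson correlation matches
#' `cd_as_corr`. Each leaf spectrum is a vegetation-shaped base curve whose
#' chlorophyll absorption wells shallow linearly with Cd and whose NIR plateau
#' drops linearly with As (both around the configured means, each with
#' additive Gaussian noise), followed by per-spectrum affine scatter and
#' i.i.d. channel noise; reflectance is clipped to (1e-4, 1].
#'
#' @param config a [cohort_config()].
#' @return A list with elements `spectra` (a [spectra_set()]) and `soil`
#'   (a [soil_table()]); attribute `"copula_rho"` records the calibrated
#'   latent correlation.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  cfg <- config
  n <- cfg$n_sites
  wl <- wavelength_grid(cfg)

  par_cd <- calibrate_trunc_lnorm(cfg$cd_mean, cfg$cd_range)
  par_as <- calibrate_trunc_lnorm(cfg$as_mean, cfg$as_range)
  rho <- if (abs(cfg$cd_as_corr) < 1e-12) 0 else
    invert_copula_corr(cfg$cd_as_corr, par_cd, par_as)

  set.seed(cfg$seed)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cd <- qtrunc_lnorm(stats::pnorm(z1), par_cd)
  as_ <- qtrunc_lnorm(stats::pnorm(z2), par_as)

  # symmetric truncation => truncated mean == ph_mean
  lo <- stats::pnorm(-cfg$ph_halfwidth / cfg$ph_sd)
  u <- stats::runif(n, lo, 1 - lo)
  ph <- cfg$ph_mean + cfg$ph_sd * stats::qnorm(u)

  chl_stress <- cfg$stress_slope_cd * (cd - cfg$cd_mean) +
    stats::rnorm(n, 0, cfg$chl_noise_sd)
  nir_stress <- cfg$stress_slope_as * (as_ - cfg$as_mean) +
    stats::rnorm(n, 0, cfg$nir_noise_sd)
  chl <- pmin(pmax(1 - chl_stress, 0.05), 1.35)
  nir <- 0.48 * pmin(pmax(1 - nir_stress, 0.1), 1.35)

  gain <- 1 + stats::rnorm(n, 0, cfg$scatter_sd_mult)
  offset <- stats::rnorm(n, 0, cfg$scatter_sd_add)

  refl <- matrix(0, n, length(wl))
  for (i in seq_len(n)) {
    r <- base_leaf_spectrum(wl, chl = chl[i], nir_level = nir[i])
    r <- gain[i] * r + offset[i]
    refl[i, ] <- r
  }
  if (cfg$channel_noise_sd > 0)
    refl <- refl + matrix(stats::rnorm(n * length(wl), 0, cfg$channel_noise_sd),
                          n, length(wl))
  refl <- pmin(pmax(refl, 1e-4), 1)

  ids <- sprintf("S%03d", seq_len(n))
  out <- list(
    spectra = spectra_set(refl, wl, ids, raw = TRUE),
    soil = soil_table(ids, ph, cd, as_)
  )
  attr(out, "copula_rho") <- rho
  out
}
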