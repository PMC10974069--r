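# Small deterministic fixtures built in code.

# Tiny spectra_set on an arbitrary grid.
toy_spectra <- function(n = 5, p = 20, seed = 1, wl = NULL, raw = TRUE) {
  set.seed(seed)
  if (is.null(wl)) wl <- seq(400, by = 10, length.out = p)
  X <- matrix(runif(n * p, 0.05, 0.6), n, p)
  spectra_set(X, wl, sprintf("T%02d", seq_len(n)), raw = raw)
}

# Noise-free cohort config: every stochastic spectral term switched off.
quiet_config <- function(...) {
  args <- list(stress_slope_cd = 0, stress_slope_as = 0,
               chl_noise_sd = 0, nir_noise_sd = 0,
               scatter_sd_add = 0, scatter_sd_mult = 0,
               channel_noise_sd = 0)
  do.call(cohort_config, utils::modifyList(args, list(...)))
}

# Planted-signal regression data: y depends on `informative` columns of an
# i.i.d. Gaussian X, plus noise.
planted_xy <- function(n, p, informative, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- numeric(p)
  beta[informative] <- 1
  y <- drop(X %*% beta) + rnorm(n, 0, noise_sd)
  list(X = X, y = y, informative = informative)
}
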