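test_that("trim_low_bands keeps channels at or above the cutoff", {
  s <- toy_spectra(n = 2, p = 4, wl = c(301, 379.9, 380, 1145))
  tr <- trim_low_bands(s)
  expect_identical(tr$wavelength, c(380, 1145))
  expect_identical(trim_low_bands(s, 0)$wavelength, s$wavelength)
  expect_error(trim_low_bands(s, 2000), "no channel")
  # default generator grid: exactly the channels with 301 + 3.3k >= 380
  g <- generate_cohort(cohort_config(n_sites = 2, seed = 1))
  k <- 0:255
  expect_identical(trim_low_bands(g$spectra)$wavelength,
                   (301 + 3.3 * k)[301 + 3.3 * k >= 380])
})

test_that("Savitzky-Golay reproduces polynomials and matches brute force", {
  wl <- seq(400, 700, by = 10)
  p <- length(wl)
  const <- spectra_set(matrix(0.4, 1, p), wl, "a")
  expect_equal(sg_smooth(const)$reflectance, const$reflectance)
  # exact quadratic in channel index is invariant under polyorder-2 SG,
  # including the truncated-window edges
  quad <- 0.2 + 0.01 * seq_len(p) + 3e-4 * seq_len(p)^2
  sq <- spectra_set(rbind(quad), wl, "q", raw = FALSE)
  expect_equal(sg_smooth(sq, 11, 2)$reflectance[1, ], quad,
               tolerance = 1e-12, ignore_attr = TRUE)
  # random spectrum equals the direct least-squares oracle everywhere
  set.seed(42)
  x <- runif(p, 0.1, 0.5)
  sr <- spectra_set(rbind(x), wl, "r")
  for (w in c(5, 11)) {
    got <- sg_smooth(sr, w, 2)$reflectance[1, ]
    expect_equal(got, sg_bruteforce(x, w, 2), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_error(sg_smooth(sr, 10, 2), "odd")
  expect_error(sg_smooth(sr, 5, 5), "polyorder")
  expect_error(sg_smooth(sr, 2 * p + 1, 2), "window larger")
})

test_that("absorbance is log10(1/R) and rejects nonpositive input", {
  s <- spectra_set(rbind(c(1, 0.1, 0.5)), c(400, 500, 600), "a")
  expect_equal(absorbance(s)$reflectance[1, ], c(0, 1, 0.3010),
               tolerance = 1e-4, ignore_attr = TRUE)
  bad <- spectra_set(rbind(c(1, 0.5, 0.2)), c(400, 500, 600), "a")
  bad$reflectance[1, 2] <- -0.1
  expect_error(absorbance(bad), "positive")
})

test_that("derivatives handle constants, lines and cubics correctly", {
  wl <- seq(400, 700, by = 3.3)
  p <- length(wl)
  const <- spectra_set(matrix(0.3, 1, p), wl, "c")
  expect_true(all(derivative(const, 1)$reflectance == 0))
  expect_true(all(derivative(const, 2)$reflectance == 0))
  lin <- spectra_set(rbind(0.1 + 0.002 * wl), wl, "l", raw = FALSE)
  expect_equal(derivative(lin, 1)$reflectance[1, ], rep(0.002, p),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(derivative(lin, 2)$reflectance[1, ], rep(0, p),
               tolerance = 1e-12, ignore_attr = TRUE)
  # cubic: interior central differences are O(h^2) accurate
  f <- function(x) 1e-7 * x^3 - 2e-4 * x^2 + 0.05 * x
  cub <- spectra_set(rbind(f(wl)), wl, "q", raw = FALSE)
  il <- 2:(p - 1)
  fd <- derivative(cub, 1)$reflectance[1, il]
  sd2 <- derivative(cub, 2)$reflectance[1, il]
  # central differences: O(h^2 f''') ~ 2e-6 absolute error at 3.3 nm spacing
  expect_lt(max(abs(fd - (3e-7 * wl[il]^2 - 4e-4 * wl[il] + 0.05))), 5e-6)
  expect_lt(max(abs(sd2 - (6e-7 * wl[il] - 4e-4))), 1e-8)
  expect_error(derivative(spectra_set(rbind(c(.1, .2)), c(1, 2), "x"), 1),
               "3 channels")
})

test_that("derivative operators are linear and support edge dropping", {
  s1 <- toy_spectra(n = 3, p = 15, seed = 1)
  s2 <- toy_spectra(n = 3, p = 15, seed = 2)
  for (ord in 1:2) {
    lhs <- derivative(spectra_set(2 * s1$reflectance - 3 * s2$reflectance,
                                  s1$wavelength, s1$site_id, raw = FALSE), ord)
    rhs <- 2 * derivative(s1, ord)$reflectance -
      3 * derivative(s2, ord)$reflectance
    expect_equal(lhs$reflectance, rhs, tolerance = 1e-12)
  }
  dropped <- derivative(s1, 1, keep_edges = FALSE)
  expect_identical(dim(dropped$reflectance), c(3L, 13L))
  expect_equal(dropped$reflectance,
               derivative(s1, 1)$reflectance[, 2:14], tolerance = 1e-15,
               ignore_attr = TRUE)
})

test_that("MSC inverts affine distortion against the stored reference", {
  s <- toy_spectra(n = 6, p = 25, seed = 3)
  ref <- msc_fit(s)
  # correcting the reference itself returns the reference
  rs <- spectra_set(rbind(ref$reference), s$wavelength, "ref", raw = FALSE)
  expect_equal(msc_apply(rs, ref)$reflectance[1, ], ref$reference,
               tolerance = 1e-12, ignore_attr = TRUE)
  # an affine shift of the reference is recovered exactly
  shifted <- spectra_set(rbind(0.2 + 1.5 * ref$reference), s$wavelength,
                         "sh", raw = FALSE)
  expect_equal(msc_apply(shifted, ref)$reflectance[1, ], ref$reference,
               tolerance = 1e-12, ignore_attr = TRUE)
  # per-sample (a, b) match a generic least-squares solver
  set.seed(4)
  X <- matrix(runif(5 * 20, 0.1, 0.8), 5, 20)
  cal <- spectra_set(X, seq(400, 590, 10), sprintf("m%d", 1:5))
  r2 <- msc_fit(cal)
  corrected <- msc_apply(cal, r2)$reflectance
  for (i in 1:5) {
    ab <- stats::coef(stats::lm(X[i, ] ~ r2$reference))
    expect_equal(corrected[i, ], (X[i, ] - ab[1]) / ab[2],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  flat <- spectra_set(rbind(rep(0.3, 25)), s$wavelength, "flat")
  expect_error(msc_apply(flat, ref), "flat")
})

test_that("SNV standardizes each spectrum and is affine invariant", {
  s <- toy_spectra(n = 4, p = 30, seed = 5)
  z <- snv(s)$reflectance
  expect_equal(rowMeans(z), rep(0, 4), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(apply(z, 1, stats::sd), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  shifted <- spectra_set(0.05 + 0.7 * s$reflectance, s$wavelength,
                         s$site_id, raw = FALSE)
  expect_equal(snv(shifted)$reflectance, z, tolerance = 1e-10)
  expect_equal(snv(spectra_set(rbind(c(0.1, 0.2, 0.3)), 1:3, "x"))$reflectance[1, ],
               c(-1, 0, 1), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(snv(spectra_set(rbind(rep(0.2, 5)), 1:5, "k")), "constant")
})

test_that("apply_transform dispatches all eight transforms consistently", {
  s <- toy_spectra(n = 5, p = 40, seed = 6)
  expect_identical(apply_transform(s, "R"), s)
  expect_equal(apply_transform(s, "AFD")$reflectance,
               derivative(absorbance(s), 1)$reflectance, tolerance = 1e-15)
  expect_equal(apply_transform(s, "ASD")$reflectance,
               derivative(absorbance(s), 2)$reflectance, tolerance = 1e-15)
  shapes <- vapply(TRANSFORM_NAMES, function(nm)
    dim(apply_transform(s, nm)$reflectance), integer(2))
  expect_true(all(shapes[1, ] == 5L))
  expect_true(all(shapes[2, ] == 40L))
  expect_error(apply_transform(s, "WAVELET"))
})

test_that("pipeline order is trim then smooth (not interchangeable)", {
  g <- generate_cohort(cohort_config(n_sites = 3, seed = 8))
  a <- sg_smooth(trim_low_bands(g$spectra))
  b <- trim_low_bands(sg_smooth(g$spectra))
  expect_identical(a$wavelength, b$wavelength)
  # edge channels near the cut differ because smoothing-before-trim sees
  # the stripped <380 nm channels
  expect_gt(max(abs(a$reflectance[, 1:5] - b$reflectance[, 1:5])), 1e-6)
  expect_equal(preprocess(g$spectra, "R")$reflectance, a$reflectance,
               tolerance = 1e-15)
})

test_that("MSC equalizes pure affine scatter across samples", {
  g <- generate_cohort(quiet_config(n_sites = 8, seed = 10,
                                    scatter_sd_add = 0.005,
                                    scatter_sd_mult = 0.05))
  # no clipping occurred, so the scatter is exactly affine
  expect_gt(min(g$spectra$reflectance), 1e-4)
  corrected <- msc_apply(g$spectra, msc_fit(g$spectra))$reflectance
  expect_lt(max(apply(corrected, 2L, function(x) max(x) - min(x))), 1e-8)
})
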