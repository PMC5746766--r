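# Independent single-expression oracle for the activity-to-intensity
# conversion, coded directly from the formula with hc/k = 1.4387769 cm K.
oracle_intensity <- function(S, nu, nu0 = 1e7 / 532, T = 293.15, f = 1e-12) {
  f * S * (nu0 - nu)^4 / (nu * (1 - exp(-1.4387769 * nu / T)))
}

test_that("wavelength-to-wavenumber conversion matches the printed excitation value", {
  expect_equal(round(nm_to_wavenumber(532), 2), 18796.99)
  expect_equal(nm_to_wavenumber(1e7), 1)
  expect_equal(nm_to_wavenumber(1000), 10000)
  expect_error(nm_to_wavenumber(0), "wavelength")
  expect_error(nm_to_wavenumber(-5), "wavelength")
})

test_that("intensity conversion agrees with the brute-force oracle to 12 significant digits", {
  set.seed(101)
  S <- runif(1000, 0, 1000)
  nu <- runif(1000, 100, 4000)
  got <- raman_intensity(S, nu, intensity_params())
  want <- oracle_intensity(S, nu)
  expect_true(all(abs(got - want) <= 1e-12 * pmax(abs(want), .Machine$double.xmin)))
})

test_that("intensity conversion limits and domain behave as the formula dictates", {
  p <- intensity_params()
  expect_equal(raman_intensity(0, 1000, p), 0)
  expect_equal(raman_intensity(0, 350, p), 0)
  # vanishes as the mode approaches the excitation line (fourth-power factor)
  near <- raman_intensity(10, p$excitation_wavenumber - 1e-3, p)
  expect_lt(near, raman_intensity(10, 1000, p) * 1e-10)
  # strictly increasing in activity at fixed wavenumber
  S <- seq(1, 100, by = 1)
  expect_true(all(diff(raman_intensity(S, 700, p)) > 0))
  # low-temperature limit: Boltzmann bracket -> 1
  cold <- intensity_params(temperature = 1e-3)
  nu <- c(300, 1000, 1700)
  expect_equal(raman_intensity(5, nu, cold),
               cold$norm_factor * 5 * (cold$excitation_wavenumber - nu)^4 / nu,
               tolerance = 1e-12)
  expect_error(raman_intensity(1, 0, p), "wavenumber")
  expect_error(raman_intensity(1, 2e4, p), "excitation")
  expect_error(raman_intensity(-1, 1000, p), "activity")
})

test_that("frequency scaling moves positions only and is invertible", {
  tab <- mode_table(c(100, 200), c(3, 4), assignment = c("a", "b"))
  expect_identical(scale_frequencies(tab, 1)$modes, tab$modes)
  scaled <- scale_frequencies(tab, 0.98)
  expect_equal(scaled$modes$wavenumber, c(98, 196))
  expect_identical(scaled$modes$activity, tab$modes$activity)
  expect_identical(scaled$modes$assignment, tab$modes$assignment)
  back <- scale_frequencies(scaled, 1 / 0.98)
  expect_equal(back$modes$wavenumber, tab$modes$wavenumber, tolerance = 1e-12)
  expect_error(scale_frequencies(tab, 0), "scale factor")
})

test_that("a synthesized single line has the configured width and position", {
  sp <- single_line_spectrum(center = 1000, fwhm = 7, step = 0.1)
  half <- max(sp$intensity) / 2
  above <- range(sp$grid[sp$intensity >= half])
  expect_equal(diff(above), 7, tolerance = 0.1 + 1e-9)
  expect_equal(sp$grid[which.max(sp$intensity)], 1000, tolerance = 0.1)
  # scaled placement: band lands at the scaled position, intensity from unscaled
  sp2 <- synthesize_spectrum(mode_table(1000, 100),
                             intensity_params(scale_factor = 0.98),
                             900, 1100, 0.1)
  expect_equal(sp2$grid[which.max(sp2$intensity)], 980, tolerance = 0.1)
  expect_equal(sp2$meta$line_intensities,
               raman_intensity(100, 1000, intensity_params()))
})

test_that("unit-area line shapes make the spectrum integrate to the summed intensities", {
  set.seed(11)
  tab <- mode_table(c(900, 1000, 1100), runif(3, 10, 100))
  p <- intensity_params(scale_factor = 1)
  sp <- synthesize_spectrum(tab, p, 400, 1600, 0.2)
  total <- sum(raman_intensity(tab$modes$activity, tab$modes$wavenumber, p))
  integral <- sum((sp$intensity[-1] + sp$intensity[-length(sp$intensity)]) / 2) * 0.2
  expect_equal(integral, total, tolerance = 0.01)
})

test_that("synthesis is linear in the mode table", {
  set.seed(12)
  a <- random_mode_table(4)
  b <- random_mode_table(5)
  both <- mode_table(c(a$modes$wavenumber, b$modes$wavenumber),
                     c(a$modes$activity, b$modes$activity))
  p <- intensity_params()
  args <- list(params = p, grid_min = 200, grid_max = 1800, grid_step = 1)
  sum_ab <- do.call(synthesize_spectrum, c(list(a), args))$intensity +
    do.call(synthesize_spectrum, c(list(b), args))$intensity
  expect_equal(do.call(synthesize_spectrum, c(list(both), args))$intensity,
               sum_ab, tolerance = 1e-12)
})

test_that("synthesized spectra are finite, non-negative, and warn when empty", {
  set.seed(13)
  for (i in 1:5) {
    sp <- synthesize_spectrum(random_mode_table(8), intensity_params())
    expect_true(all(is.finite(sp$intensity)))
    expect_true(all(sp$intensity >= 0))
  }
  far <- mode_table(5000, 10)
  expect_warning(zero <- synthesize_spectrum(far, intensity_params(), 200, 1800, 1),
                 "zero spectrum")
  expect_true(all(zero$intensity == 0))
  normed <- synthesize_spectrum(mode_table(1000, 5), intensity_params(),
                                normalize_max = TRUE)
  expect_equal(max(normed$intensity), 1)
  expect_equal(normed$meta$normalized, "max")
})
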