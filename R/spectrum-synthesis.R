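#' Intensity-conversion and broadening parameters
#'
#' Bundles the constants of the activity-to-intensity conversion and of the
#' Lorentzian broadening step. The defaults reproduce the reference
#' configuration used throughout this package: 532 nm excitation
#' (18,796.99 cm^-1), 293.15 K, normalization factor 1e-12, harmonic
#' frequency scaling 0.98, and 7 cm^-1 full width at half maximum. The second
#' radiation constant hc/k is fixed at its CODATA value 1.4387769 cm K; it is
#' the only route through which h, c and k enter the formula.
#'
#' @param excitation_wavenumber laser excitation wavenumber nu0 (cm^-1).
#' @param temperature sample temperature T (K).
#' @param norm_factor dimensionless normalization factor f applied to every
#'   line intensity.
#' @param scale_factor multiplicative harmonic frequency scaling applied to
#'   band positions (not to the intensity conversion); must lie in (0, 1.2].
#' @param fwhm Lorentzian full width at half maximum (cm^-1).
#' @return A list of class `intensity_params`.
#' @export
intensity_params <- function(excitation_wavenumber = nm_to_wavenumber(532),
                             temperature = 293.15,
                             norm_factor = 1e-12,
                             scale_factor = 0.98,
                             fwhm = 7) {
  if (excitation_wavenumber <= 0) stop("excitation wavenumber must be > 0", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  if (scale_factor <= 0 || scale_factor > 1.2) {
    stop("scale factor must lie in (0, 1.2]", call. = FALSE)
  }
  structure(
    list(
      excitation_wavenumber = excitation_wavenumber,
      temperature = temperature,
      norm_factor = norm_factor,
      scale_factor = scale_factor,
      fwhm = fwhm,
      second_radiation_constant = 1.4387769
    ),
    class = "intensity_params"
  )
}

#' Convert a laser wavelength to a wavenumber
#'
#' @param wavelength_nm wavelength in nanometres, `> 0`.
#' @return The wavenumber 1e7 / wavelength in cm^-1 (532 nm gives
#'   18,796.99 cm^-1 to two decimals).
#' @export
nm_to_wavenumber <- function(wavelength_nm) {
  if (any(wavelength_nm <= 0)) {
    stop("wavelength must be > 0", call. = FALSE)
  }
  1e7 / wavelength_nm
}

#' Convert Raman activity to relative Raman intensity
#'
#' Implements the standard conversion from the Raman scattering activity S_i
#' (A^4/amu, as printed by quantum-chemistry codes) to a relative Raman
#' intensity for Stokes scattering:
#'
#' \deqn{I_i = f \, S_i \, (\nu_0-\nu_i)^4 \; / \;
#'       \{\nu_i [1 - \exp(-h c \nu_i / k T)]\}}
#'
#' with nu0 the excitation wavenumber, T the temperature and f a
#' normalization factor. The Boltzmann bracket accounts for the thermal
#' population of the vibrational ground state; the fourth-power factor for
#' the scattered-frequency dependence of Raman intensity. Only the Stokes
#' branch is modeled, so `wavenumber` must lie strictly between 0 and the
#' excitation wavenumber.
#'
#' @param activity Raman activity S_i (A^4/amu), `>= 0`. Vectorized.
#' @param wavenumber mode wavenumber nu_i (cm^-1), `0 < nu_i < nu0`.
#' @param params an [intensity_params()] object.
#' @return Relative intensity, same length as the inputs; zero exactly when
#'   the activity is zero.
#' @export
raman_intensity <- function(activity, wavenumber, params = intensity_params()) {
  stopifnot(inherits(params, "intensity_params"))
  if (any(activity < 0)) stop("activity must be >= 0", call. = FALSE)
  if (any(wavenumber <= 0)) {
    stop("wavenumber must be > 0 (Boltzmann term singular at 0)", call. = FALSE)
  }
  if (any(wavenumber >= params$excitation_wavenumber)) {
    stop("wavenumber must be below the excitation wavenumber (anti-Stokes not modeled)",
         call. = FALSE)
  }
  nu0 <- params$excitation_wavenumber
  c2 <- params$second_radiation_constant
  boltz <- 1 - exp(-c2 * wavenumber / params$temperature)
  params$norm_factor * activity * (nu0 - wavenumber)^4 / (wavenumber * boltz)
}

#' Scale the frequencies of a mode table
#'
#' Multiplies every wavenumber by a uniform harmonic scaling factor (0.98 by
#' default via [intensity_params()]); activities, assignments and mode order
#' are untouched. Uniform scaling is the standard correction for the
#' systematic overestimation of harmonic DFT frequencies.
#'
#' @param table a [mode_table()].
#' @param factor dimensionless scaling in (0, 1.2].
#' @return A `mode_table` with scaled wavenumbers.
#' @export
scale_frequencies <- function(table, factor = 0.98) {
  stopifnot(inherits(table, "mode_table"))
  if (factor <= 0 || factor > 1.2) {
    stop("scale factor must lie in (0, 1.2]", call. = FALSE)
  }
  out <- table
  out$modes$wavenumber <- out$modes$wavenumber * factor
  out
}

#' Raman spectra on a uniform wavenumber grid
#'
#' @param grid strictly increasing, uniformly spaced wavenumbers (cm^-1).
#' @param intensity non-negative intensities, same length as `grid`.
#' @param meta named list of provenance information.
#' @return An object of class `raman_spectrum` with elements `grid`,
#'   `intensity` and `meta`.
#' @export
raman_spectrum <- function(grid, intensity, meta = list()) {
  if (length(grid) != length(intensity)) {
    stop("grid and intensity must have the same length", call. = FALSE)
  }
  if (length(grid) >= 2L) {
    steps <- diff(grid)
    if (any(steps <= 0)) stop("grid must be strictly increasing", call. = FALSE)
    if (diff(range(steps)) > 1e-8 * stats::median(steps)) {
      stop("grid must be uniformly spaced", call. = FALSE)
    }
  }
  if (any(!is.finite(intensity))) stop("intensities must be finite", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(
    list(grid = as.numeric(grid), intensity = as.numeric(intensity), meta = meta),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %g-%g cm-1 (step %g), max intensity %.4g\n",
              length(x$grid), min(x$grid), max(x$grid),
              if (length(x$grid) > 1) x$grid[2] - x$grid[1] else NA_real_,
              max(x$intensity)))
  invisible(x)
}

grid_step <- function(spec) {
  if (length(spec$grid) < 2L) return(NA_real_)
  spec$grid[2] - spec$grid[1]
}

#' Synthesize a broadened Raman spectrum from a mode table
#'
#' Converts each mode's activity to a relative intensity (using the unscaled
#' wavenumber, see Details), places a Lorentzian of the configured FWHM at the
#' scaled wavenumber, and sums the lines on a uniform grid. Lorentzians are
#' parameterized as unit-area, so each line integrates to its relative
#' intensity and the trapezoidal integral of the spectrum approximates the sum
#' of line intensities.
#'
#' @details The harmonic scaling factor corrects a systematic error of the
#' computed positions, so it is applied only to band positions; the intensity
#' conversion (fourth-power and Boltzmann factors) uses the unscaled
#' wavenumbers. Modes whose scaled position falls farther than `10 * fwhm`
#' outside the grid are skipped as numerically irrelevant; if every mode is out
#' of range a zero spectrum is returned with a warning.
#'
#' @param table a [mode_table()] (unscaled wavenumbers).
#' @param params an [intensity_params()].
#' @param grid_min,grid_max,grid_step grid limits and step in cm^-1; the
#'   defaults cover the 200-1800 cm^-1 fingerprint window at 1 cm^-1.
#' @param normalize_max if `TRUE`, rescale the result to unit maximum
#'   (recorded in `meta$normalized`).
#' @return A [raman_spectrum()]; `meta` records the parameters, the source
#'   label and the scaled line positions (`meta$line_positions`) with their
#'   relative intensities (`meta$line_intensities`).
#' @export
synthesize_spectrum <- function(table, params = intensity_params(),
                                grid_min = 200, grid_max = 1800,
                                grid_step = 1, normalize_max = FALSE) {
  stopifnot(inherits(table, "mode_table"), inherits(params, "intensity_params"))
  if (n_modes(table) == 0L) stop("mode table is empty", call. = FALSE)
  if (grid_min >= grid_max) stop("grid_min must be < grid_max", call. = FALSE)
  if (grid_step <= 0) stop("grid_step must be > 0", call. = FALSE)

  grid <- seq(grid_min, grid_max, by = grid_step)
  m <- table$modes[!table$modes$imaginary, , drop = FALSE]
  ok <- m$wavenumber > 0 & m$wavenumber < params$excitation_wavenumber
  m <- m[ok, , drop = FALSE]

  pos <- m$wavenumber * params$scale_factor
  inten <- if (nrow(m) > 0) {
    raman_intensity(m$activity, m$wavenumber, params)
  } else {
    numeric(0)
  }

  margin <- 10 * params$fwhm
  keep <- pos >= grid_min - margin & pos <= grid_max + margin
  signal <- numeric(length(grid))
  if (!any(keep)) {
    warning("no mode falls inside the spectral window; returning a zero spectrum",
            call. = FALSE)
  } else {
    gamma <- params$fwhm / 2
    for (i in which(keep)) {
      # unit-area Lorentzian: integrates to 1, height I/(pi*gamma)
      signal <- signal +
        inten[i] * (gamma / pi) / ((grid - pos[i])^2 + gamma^2)
    }
  }
  normalized <- "none"
  if (normalize_max && max(signal) > 0) {
    signal <- signal / max(signal)
    normalized <- "max"
  }
  raman_spectrum(
    grid, signal,
    meta = list(
      source = table$label,
      params = unclass(params),
      line_positions = pos[keep],
      line_intensities = inten[keep],
      normalized = normalized
    )
  )
}
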