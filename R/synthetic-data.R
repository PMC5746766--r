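#' Noise model for synthetic SERS time series
#'
#' Describes the stochastic structure of a simulated SERS acquisition:
#' additive Gaussian detector noise (i.i.d. per grid point), a multiplicative
#' per-spectrum intensity factor with a lognormal distribution of unit mean
#' (the simplest model of SERS hot-spot, spot-to-spot intensity fluctuation
#' that series averaging exists to suppress), and an optional linear
#' background.
#'
#' @param additive_sd standard deviation of the additive noise, in intensity
#'   units; `NULL` (the default) resolves at generation time to 5% of the
#'   clean spectrum maximum — the moderate noise level used throughout this
#'   package's validation runs.
#' @param intensity_jitter_sd sdlog of the lognormal per-spectrum factor
#'   (unit mean); default 0.2, i.e. roughly 20% spot-to-spot fluctuation.
#' @param baseline_slope linear background slope in intensity units per
#'   cm^-1, applied as `slope * (wavenumber - grid minimum)`; default 0 (no
#'   baseline correction is modeled by default).
#' @param seed integer seed driving all draws.
#' @return An object of class `series_noise_model`.
#' @export
series_noise_model <- function(additive_sd = NULL, intensity_jitter_sd = 0.2,
                               baseline_slope = 0, seed = 1L) {
  if (!is.null(additive_sd) && additive_sd < 0) {
    stop("additive_sd must be >= 0", call. = FALSE)
  }
  if (intensity_jitter_sd < 0) stop("intensity_jitter_sd must be >= 0", call. = FALSE)
  structure(
    list(additive_sd = additive_sd,
         intensity_jitter_sd = intensity_jitter_sd,
         baseline_slope = baseline_slope,
         seed = as.integer(seed)),
    class = "series_noise_model"
  )
}

synthetic_band_positions <- list(
  # free-molecule dominant bands of the ionic forms, and the marker sets of
  # the adsorbed quinone and zwitterion-like forms
  DA_minus = c(640, 750, 780, 930, 1150, 1280, 1530, 1610),
  DA_plus = c(580, 800, 820, 1180, 1330, 1390, 1480, 1640),
  quinone = c(950, 1360, 1510),
  DA_pm = c(1280, 1640)
)

#' Generate a mock vibrational mode table for a dopamine form
#'
#' Returns the published band positions of the requested molecular form with
#' pseudo-random Raman activities drawn log-uniformly in \[1, 100\] under the
#' given seed. `DA0` uses the 19 calculated reference bands of neutral
#' dopamine ([dopamine_calc_modes()]); `DA_minus` and `DA_plus` use the eight
#' dominant free-molecule bands of the anionic and cationic forms; `quinone`
#' and `DA_pm` use their marker sets (950/1360/1510 and 1280/1640 cm^-1).
#'
#' Positions are on the observed scale (they already reflect any harmonic
#' correction), so spectra synthesized from these tables should use a scale
#' factor of 1 — [generate_sers_series()] does so by default. Activities are
#' synthetic by construction (none are published) and carry no ground truth;
#' only positions do.
#'
#' @param form_id one of [dopamine_form_ids()].
#' @param seed integer seed for the activity draws.
#' @return A [mode_table()] labelled with the form id.
#' @export
generate_mode_table <- function(form_id, seed = 1L) {
  form_id <- match.arg(form_id, dopamine_form_ids())
  pos <- if (form_id == "DA0") {
    dopamine_calc_modes()$modes$wavenumber
  } else {
    synthetic_band_positions[[form_id]]
  }
  acts <- with_seed(seed, 10^stats::runif(length(pos), 0, 2))
  mode_table(pos, acts, label = form_id,
             source = sprintf("synthetic [seed %d]", as.integer(seed)))
}

# run code under a temporary RNG state so generators are reproducible
# without clobbering the caller's stream
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate noisy SERS time series with ground truth
#'
#' Emulates a multi-spot SERS acquisition: the clean spectrum of the given
#' mode table is synthesized once, then each simulated spectrum is
#' `jitter * clean + baseline + additive noise` (clipped at zero), with all
#' draws taken from one generator seeded by `noise$seed` so the output is
#' bitwise reproducible. The reference acquisition scheme is eight series of
#' fifty 200-ms spectra (400 spectra total).
#'
#' The returned ground truth records the clean spectrum's clearly detectable
#' band positions: peaks of the noise-free spectrum with prominence at least
#' `truth_prominence_frac` of its maximum. Recovery of these positions from
#' the averaged noisy data is the generator's end-to-end validation surface.
#'
#' @param table a [mode_table()] with positions on the observed scale (see
#'   [generate_mode_table()]).
#' @param n_series,n_spectra number of series and spectra per series.
#' @param params an [intensity_params()]; the default uses a scale factor of
#'   1 because synthetic tables already hold observed-scale positions.
#' @param noise a [series_noise_model()].
#' @param grid_min,grid_max,grid_step synthesis grid (cm^-1).
#' @param truth_prominence_frac prominence threshold (fraction of maximum)
#'   defining which clean peaks constitute ground truth.
#' @return A list with `series` (list of [time_series()]), `truth` (a
#'   [peak_list()]), `clean` (the noise-free [raman_spectrum()]) and `noise`
#'   (the resolved noise model, with `additive_sd` made explicit).
#' @export
generate_sers_series <- function(table, n_series = 8L, n_spectra = 50L,
                                 params = intensity_params(scale_factor = 1),
                                 noise = series_noise_model(),
                                 grid_min = 200, grid_max = 1800, grid_step = 1,
                                 truth_prominence_frac = 0.05) {
  stopifnot(inherits(table, "mode_table"), inherits(noise, "series_noise_model"))
  if (n_series < 1L || n_spectra < 1L) {
    stop("n_series and n_spectra must be >= 1", call. = FALSE)
  }
  clean <- synthesize_spectrum(table, params, grid_min, grid_max, grid_step)
  truth <- detect_peaks(clean, min_prominence_frac = truth_prominence_frac)
  truth$source <- sprintf("truth:%s", table$label)
  if (is.null(noise$additive_sd)) {
    noise$additive_sd <- 0.05 * max(clean$intensity)
  }
  baseline <- noise$baseline_slope * (clean$grid - grid_min)
  npt <- length(clean$grid)
  sdlog <- noise$intensity_jitter_sd
  series <- with_seed(noise$seed, {
    lapply(seq_len(n_series), function(si) {
      spectra <- lapply(seq_len(n_spectra), function(k) {
        jitter <- if (sdlog > 0) {
          stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # unit mean
        } else 1
        eps <- if (noise$additive_sd > 0) {
          stats::rnorm(npt, 0, noise$additive_sd)
        } else 0
        raman_spectrum(clean$grid,
                       pmax(jitter * clean$intensity + baseline + eps, 0),
                       meta = list(series = si, index = k))
      })
      time_series(spectra, integration_time = 0.2,
                  series_id = sprintf("%s-series-%02d", table$label, si))
    })
  })
  list(series = series, truth = truth, clean = clean, noise = noise)
}

#' Peak recovery rate against ground truth
#'
#' Fraction of ground-truth positions for which a detected peak lies within
#' `tol` cm^-1.
#'
#' @param detected a [peak_list()] (or numeric positions).
#' @param truth a [peak_list()] (or numeric positions) of true positions.
#' @param tol matching radius in cm^-1.
#' @return A fraction in \[0, 1\] (`NaN` for empty truth).
#' @export
peak_recovery <- function(detected, truth, tol = 2) {
  det <- if (inherits(detected, "peak_list")) detected$positions else as.numeric(detected)
  tru <- if (inherits(truth, "peak_list")) truth$positions else as.numeric(truth)
  if (length(tru) == 0L) return(NaN)
  mean(vapply(tru, function(p) any(abs(det - p) <= tol), logical(1)))
}
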