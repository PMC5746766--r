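# Shared fixtures, built in code.

# Gaussian-09-style frequency block text for the given wavenumber/activity
# vectors, three modes per block. Extra property lines mimic real logs.
qm_log_text <- function(wavenumber, activity, job_header = TRUE) {
  stopifnot(length(wavenumber) == length(activity))
  out <- character(0)
  if (job_header) {
    out <- c(out, " Harmonic frequencies (cm**-1), IR intensities (KM/Mole), Raman scattering", " activities (A**4/AMU)...")
  }
  idx <- seq_along(wavenumber)
  for (start in seq(1, length(wavenumber), by = 3)) {
    cols <- start:min(start + 2, length(wavenumber))
    out <- c(
      out,
      paste0("                    ", paste(sprintf("%-20d", idx[cols]), collapse = "")),
      paste0("                       ", paste(rep("A'", length(cols)), collapse = "                   ")),
      paste0(" Frequencies --  ", paste(sprintf("%10.4f", wavenumber[cols]), collapse = "  ")),
      paste0(" Red. masses --  ", paste(sprintf("%10.4f", rep(1.1, length(cols))), collapse = "  ")),
      paste0(" Raman Activ --  ", paste(sprintf("%10.4f", activity[cols]), collapse = "  "))
    )
  }
  out
}

# random valid mode table for property tests
random_mode_table <- function(n = 10, label = "rand") {
  wn <- sort(stats::runif(n, 250, 1750))
  wn <- wn + seq_len(n) * 1e-6  # guarantee strictly increasing
  mode_table(
    wavenumber = wn,
    activity = stats::runif(n, 0, 1000),
    assignment = ifelse(stats::runif(n) < 0.5, NA_character_,
                        paste0("mode-", seq_len(n))),
    label = label
  )
}

# a single-line spectrum for detector tests
single_line_spectrum <- function(center = 1000, activity = 100, fwhm = 7,
                                 grid_min = center - 100, grid_max = center + 100,
                                 step = 0.1) {
  synthesize_spectrum(
    mode_table(center, activity),
    intensity_params(scale_factor = 1, fwhm = fwhm),
    grid_min, grid_max, step
  )
}
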