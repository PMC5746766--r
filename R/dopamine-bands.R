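#' Reference band table for neutral dopamine
#'
#' Returns the packaged reference table of the main dopamine vibrational
#' bands: the scaled calculated wavenumbers of neutral dopamine (harmonic
#' B3LYP frequencies multiplied by 0.98), the measured Raman positions of
#' dopamine powder where observed, and the tentative assignment of each mode.
#' Rows with only a calculated value are theory-only predictions; the single
#' measured-only row (1209 cm^-1, CO stretching) has no calculated
#' counterpart within the matching tolerance.
#'
#' No Raman activities accompany these published positions, so
#' [dopamine_calc_modes()] attaches a uniform activity of 1 to every mode:
#' positions, not intensities, are the reference surface.
#'
#' @return A data frame with columns `calculated`, `measured` (cm^-1; `NA`
#'   where a column is blank) and `assignment`.
#' @export
dopamine_band_table <- function() {
  path <- system.file("extdata", "dopamine_table1.tsv", package = "ramanforms",
                      mustWork = TRUE)
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  get <- function(f, i) if (length(f) >= i && nzchar(trimws(f[i]))) trimws(f[i]) else NA_character_
  data.frame(
    calculated = as.numeric(vapply(fields, get, character(1), 1L)),
    measured = as.numeric(vapply(fields, get, character(1), 2L)),
    assignment = vapply(fields, get, character(1), 3L),
    stringsAsFactors = FALSE
  )
}

#' Calculated dopamine modes as a mode table
#'
#' The calculated column of [dopamine_band_table()] as a [mode_table()] with
#' uniform unit activities (no published activities exist for these bands)
#' and the tabulated assignments.
#'
#' @return A [mode_table()] with 19 modes from 381 to 1634 cm^-1.
#' @export
dopamine_calc_modes <- function() {
  tab <- dopamine_band_table()
  keep <- !is.na(tab$calculated)
  mode_table(
    wavenumber = tab$calculated[keep],
    activity = rep(1, sum(keep)),
    assignment = tab$assignment[keep],
    label = "DA0",
    source = "dopamine_table1.tsv [reference]"
  )
}
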