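#' Read an experimental spectrum from two-column text
#'
#' Accepts comma-, tab- or whitespace-separated text with one wavenumber and
#' one intensity column (an optional non-numeric header line is skipped).
#' Rows are sorted by wavenumber and exact duplicate wavenumbers are averaged.
#' If the resulting grid is not uniform, the spectrum is resampled by linear
#' interpolation onto a uniform grid whose step is the median spacing, and
#' `meta$resampled` is set to `TRUE`.
#'
#' @param source path to a file, or a character vector of lines.
#' @return A [raman_spectrum()]; `meta$resampled` records whether
#'   interpolation occurred.
#' @export
read_spectrum <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- read_text_lines(source)
    src_name <- basename(source)
  } else {
    lines <- unlist(strsplit(as.character(source), "\n", fixed = TRUE))
    src_name <- "<text>"
  }
  lines <- lines[nzchar(trimws(lines))]
  parse_row <- function(ln) {
    parts <- strsplit(trimws(ln), "[,\t ]+")[[1]]
    parts[nzchar(parts)]
  }
  start <- 1L
  if (length(lines) >= 1L) {
    first <- suppressWarnings(as.numeric(parse_row(lines[[1]])))
    if (anyNA(first)) start <- 2L  # header line
  }
  body <- lines[seq.int(start, length.out = max(0L, length(lines) - start + 1L))]
  if (length(body) < 2L) {
    stop("a spectrum needs at least 2 data rows", call. = FALSE)
  }
  wn <- inten <- numeric(length(body))
  for (k in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(parse_row(body[[k]])))
    if (length(vals) < 2L || anyNA(vals[1:2])) {
      stop(sprintf("non-numeric cell at line %d", k + start - 1L), call. = FALSE)
    }
    wn[k] <- vals[1]
    inten[k] <- vals[2]
  }
  o <- order(wn)
  wn <- wn[o]; inten <- inten[o]
  if (anyDuplicated(wn)) {
    inten <- as.numeric(tapply(inten, wn, mean))
    wn <- sort(unique(wn))
  }
  steps <- diff(wn)
  resampled <- FALSE
  if (diff(range(steps)) > 1e-6 * stats::median(steps)) {
    step <- stats::median(steps)
    ugrid <- seq(wn[1], wn[length(wn)], by = step)
    inten <- stats::approx(wn, inten, xout = ugrid)$y
    wn <- ugrid
    resampled <- TRUE
  }
  raman_spectrum(wn, pmax(inten, 0),
                 meta = list(source = src_name, resampled = resampled))
}

#' SERS time series
#'
#' Groups consecutively recorded spectra that share one wavenumber grid, with
#' the per-spectrum integration time kept as metadata (the reference
#' acquisitions used 200 ms per spectrum).
#'
#' @param spectra non-empty list of [raman_spectrum()] objects on one grid.
#' @param integration_time seconds per spectrum (metadata only).
#' @param series_id free-text identifier.
#' @return An object of class `time_series`.
#' @export
time_series <- function(spectra, integration_time = 0.2, series_id = "") {
  if (length(spectra) == 0L) stop("a time series needs at least one spectrum", call. = FALSE)
  ref <- spectra[[1]]$grid
  for (k in seq_along(spectra)) {
    s <- spectra[[k]]
    stopifnot(inherits(s, "raman_spectrum"))
    if (length(s$grid) != length(ref) || any(abs(s$grid - ref) > 1e-9)) {
      stop(sprintf("spectrum %d is not on the shared grid", k), call. = FALSE)
    }
  }
  structure(
    list(spectra = spectra, integration_time = integration_time,
         series_id = series_id),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %s: %d spectra x %d points, %.3g s each\n",
              if (nzchar(x$series_id)) x$series_id else "(unnamed)",
              length(x$spectra), length(x$spectra[[1]]$grid),
              x$integration_time))
  invisible(x)
}

#' Average SERS time series
#'
#' Pointwise arithmetic mean over every member spectrum of every series,
#' mirroring the practice of averaging hundreds of short acquisitions from
#' different sample spots to suppress the spot-to-spot intensity fluctuations
#' inherent to SERS hot spots. Averaging is done on the spectra as given
#' (raw, unless the caller normalized them first).
#'
#' @param series a `time_series` or a list of them.
#' @return A [raman_spectrum()]; `meta$n_series` and `meta$n_spectra_total`
#'   record the averaging set.
#' @export
average_series <- function(series) {
  if (inherits(series, "time_series")) series <- list(series)
  if (length(series) == 0L) stop("no series to average", call. = FALSE)
  ref <- series[[1]]$spectra[[1]]$grid
  total <- numeric(length(ref))
  n <- 0L
  for (si in seq_along(series)) {
    s <- series[[si]]
    stopifnot(inherits(s, "time_series"))
    g <- s$spectra[[1]]$grid
    if (length(g) != length(ref) || any(abs(g - ref) > 1e-9)) {
      stop(sprintf("series %d ('%s') is not on the shared grid",
                   si, s$series_id), call. = FALSE)
    }
    for (sp in s$spectra) {
      total <- total + sp$intensity
      n <- n + 1L
    }
  }
  raman_spectrum(ref, total / n,
                 meta = list(n_series = length(series), n_spectra_total = n))
}

#' Normalize a spectrum
#'
#' @param spec a [raman_spectrum()].
#' @param mode `"max"` (peak intensity 1), `"area"` (trapezoidal integral 1)
#'   or `"none"` (identity).
#' @return A [raman_spectrum()] with `meta$normalized` recording the mode.
#' @export
normalize_spectrum <- function(spec, mode = c("max", "area", "none")) {
  stopifnot(inherits(spec, "raman_spectrum"))
  mode <- match.arg(mode)
  if (mode == "none") return(spec)
  if (all(spec$intensity == 0)) {
    stop("cannot normalize an all-zero spectrum", call. = FALSE)
  }
  denom <- switch(mode,
    max = max(spec$intensity),
    area = trapz_integral(spec$grid, spec$intensity)
  )
  out <- spec
  out$intensity <- spec$intensity / denom
  out$meta$normalized <- mode
  out
}

trapz_integral <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Subtract an estimated baseline
#'
#' `"rolling_min"` estimates the baseline as a running minimum over a window
#' (in cm^-1) followed by a running mean of the same width to smooth the
#' staircase; `"poly"` fits a polynomial of the given degree to the intensity
#' by iteratively reweighted least squares in which points far above the fit
#' (peaks) are excluded at each pass. The estimated baseline is subtracted and
#' the result clipped at zero.
#'
#' @param spec a [raman_spectrum()].
#' @param method `"none"`, `"rolling_min"` or `"poly"`.
#' @param window window width in cm^-1 for `rolling_min`.
#' @param degree polynomial degree for `poly`.
#' @return A [raman_spectrum()] with `meta$baseline` recording method and
#'   parameters.
#' @export
subtract_baseline <- function(spec, method = c("none", "rolling_min", "poly"),
                              window = 100, degree = 1) {
  stopifnot(inherits(spec, "raman_spectrum"))
  method <- match.arg(method)
  if (method == "none") return(spec)
  n <- length(spec$grid)
  base <- switch(method,
    rolling_min = {
      half_pts <- floor(window / (2 * grid_step(spec)))
      if (2 * half_pts + 1 > n) {
        stop("baseline window exceeds the grid span", call. = FALSE)
      }
      rmin <- running_extreme(spec$intensity, half_pts, min)
      running_mean(rmin, half_pts)
    },
    poly = {
      if (degree >= n) stop("polynomial degree too high for grid length", call. = FALSE)
      x <- spec$grid - mean(spec$grid)
      y <- spec$intensity
      X <- cbind(1, stats::poly(x, degree, raw = TRUE))
      keep <- rep(TRUE, n)
      fit_vals <- y
      for (pass in 1:5) {
        coef <- stats::lm.fit(X[keep, , drop = FALSE], y[keep])$coefficients
        coef[is.na(coef)] <- 0
        fit_vals <- as.numeric(X %*% coef)
        resid_sd <- stats::sd(y[keep] - fit_vals[keep])
        if (!is.finite(resid_sd) || resid_sd == 0) break
        keep_new <- y <= fit_vals + 2 * resid_sd
        if (sum(keep_new) <= degree + 1 || identical(keep_new, keep)) break
        keep <- keep_new
      }
      fit_vals
    }
  )
  out <- spec
  out$intensity <- pmax(spec$intensity - base, 0)
  out$meta$baseline <- list(method = method, window = window, degree = degree)
  out
}

running_extreme <- function(y, half, fun) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    fun(y[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

running_mean <- function(y, half) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}
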