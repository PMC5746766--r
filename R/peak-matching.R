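#' Peak lists
#'
#' @param positions peak positions in cm^-1, strictly increasing.
#' @param heights peak heights (intensity units).
#' @param prominences peak prominences, `<= heights`.
#' @param source free-text label.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(positions, heights = rep(NA_real_, length(positions)),
                      prominences = heights, source = "") {
  if (length(heights) != length(positions) ||
      length(prominences) != length(positions)) {
    stop("positions, heights and prominences must have equal length", call. = FALSE)
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    o <- order(positions)
    positions <- positions[o]; heights <- heights[o]; prominences <- prominences[o]
    if (anyDuplicated(positions)) {
      stop("peak positions must be distinct", call. = FALSE)
    }
  }
  if (any(prominences > heights, na.rm = TRUE)) {
    stop("prominences cannot exceed heights", call. = FALSE)
  }
  structure(
    list(positions = as.numeric(positions), heights = as.numeric(heights),
         prominences = as.numeric(prominences), source = source),
    class = "peak_list"
  )
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peak%s", length(x$positions),
              if (length(x$positions) == 1) "" else "s"))
  if (length(x$positions) > 0) {
    cat(": ", paste(sprintf("%.1f", x$positions), collapse = ", "), " cm-1", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Detect peaks in a spectrum
#'
#' Finds local maxima whose topographic prominence is at least
#' `min_prominence_frac` times the spectrum maximum, enforcing a minimum
#' separation (keeping the higher of two close peaks). Each retained peak
#' position is refined to sub-grid accuracy by fitting a parabola through the
#' three samples around the maximum — exact for a symmetric peak sampled near
#' its apex.
#'
#' Prominence is measured as in topography: from a peak, walk left and right
#' to the nearest sample at least as high; the prominence is the peak height
#' minus the higher of the two valley minima encountered (grid edges count as
#' valleys).
#'
#' @param spec a [raman_spectrum()].
#' @param min_prominence_frac minimum prominence as a fraction of the
#'   spectrum maximum, in (0, 1].
#' @param min_separation minimum distance between retained peaks (cm^-1).
#' @return A [peak_list()]; empty (not an error) for a flat spectrum.
#' @export
detect_peaks <- function(spec, min_prominence_frac = 0.02,
                         min_separation = 10) {
  stopifnot(inherits(spec, "raman_spectrum"))
  if (min_prominence_frac <= 0 || min_prominence_frac > 1) {
    stop("min_prominence_frac must lie in (0, 1]", call. = FALSE)
  }
  y <- spec$intensity
  x <- spec$grid
  n <- length(y)
  top <- max(y)
  if (n < 3L || top == 0 || diff(range(y)) == 0) {
    return(peak_list(numeric(0), numeric(0), numeric(0), source = "flat"))
  }
  # interior strict local maxima (plateau: leftmost point of the plateau top)
  cand <- which(diff(c(-Inf, y)) > 0 & diff(c(y, -Inf)) <= 0)
  cand <- cand[cand > 1L & cand < n]
  if (length(cand) == 0L) {
    return(peak_list(numeric(0), numeric(0), numeric(0), source = spec$meta$source %||% ""))
  }
  prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
  keep <- prom >= min_prominence_frac * top
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0L) {
    return(peak_list(numeric(0), numeric(0), numeric(0), source = spec$meta$source %||% ""))
  }
  # enforce separation: accept in decreasing height order
  o <- order(y[cand], decreasing = TRUE)
  accepted <- integer(0)
  acc_prom <- numeric(0)
  for (k in o) {
    i <- cand[k]
    if (all(abs(x[i] - x[accepted]) >= min_separation)) {
      accepted <- c(accepted, i)
      acc_prom <- c(acc_prom, prom[k])
    }
  }
  ord <- order(x[accepted])
  accepted <- accepted[ord]; acc_prom <- acc_prom[ord]
  pos <- vapply(accepted, function(i) parabolic_vertex(x, y, i), numeric(1))
  peak_list(pos, y[accepted], pmin(acc_prom, y[accepted]),
            source = spec$meta$source %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

peak_prominence <- function(y, i) {
  n <- length(y)
  h <- y[i]
  left_min <- h
  j <- i - 1L
  while (j >= 1L && y[j] < h) {
    left_min <- min(left_min, y[j]); j <- j - 1L
  }
  if (j < 1L) left_min <- min(left_min, min(y[1:i]))
  right_min <- h
  j <- i + 1L
  while (j <= n && y[j] < h) {
    right_min <- min(right_min, y[j]); j <- j + 1L
  }
  if (j > n) right_min <- min(right_min, min(y[i:n]))
  h - max(left_min, right_min)
}

parabolic_vertex <- function(x, y, i) {
  if (i <= 1L || i >= length(y)) return(x[i])
  ym1 <- y[i - 1L]; y0 <- y[i]; yp1 <- y[i + 1L]
  denom <- ym1 - 2 * y0 + yp1
  if (denom >= 0) return(x[i])  # not curved downward; keep the grid point
  delta <- 0.5 * (ym1 - yp1) / denom
  x[i] + delta * (x[i + 1L] - x[i])
}

#' Match calculated to measured peak positions
#'
#' Computes a one-to-one pairing between two position lists that first
#' maximizes the number of pairs within `tolerance` and, among such pairings,
#' minimizes the total absolute residual (ties broken towards pairing lower
#' wavenumbers). Because both lists are sorted and the cost is the absolute
#' position difference, an optimal pairing is non-crossing, so it is found
#' exactly by dynamic programming over the two sorted lists. Leftover
#' positions on either side are reported as unmatched.
#'
#' @param calc a [peak_list()] (or numeric vector) of calculated positions.
#' @param meas a [peak_list()] (or numeric vector) of measured positions.
#' @param tolerance maximum |calculated - measured| for a pair (cm^-1). The
#'   default of 20 comfortably exceeds the typical scaled-DFT-versus-SERS
#'   discrepancy (about 10 cm^-1) while staying below the spacing at which
#'   distinct bands could cross-pair.
#' @return An object of class `match_table`: a list with `pairs` (data frame
#'   with columns `calc`, `meas`, `residual` = calc - meas), `unmatched_calc`,
#'   `unmatched_meas`, `mean_abs_residual`, `sd_abs_residual`,
#'   `tolerance_used`, `n_pairs`.
#' @export
match_peaks <- function(calc, meas, tolerance = 20) {
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  a <- if (inherits(calc, "peak_list")) calc$positions else sort(as.numeric(calc))
  b <- if (inherits(meas, "peak_list")) meas$positions else sort(as.numeric(meas))
  na <- length(a); nb <- length(b)

  # dp over prefixes: value = (pairs, -total cost); non-crossing optimality
  # holds for sorted lists under |a_i - b_j| cost
  pairs_dp <- matrix(0L, na + 1L, nb + 1L)
  cost_dp <- matrix(0, na + 1L, nb + 1L)
  move <- matrix(0L, na + 1L, nb + 1L)  # 1 = skip a, 2 = skip b, 3 = pair
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      # default: skip calc i
      best_p <- pairs_dp[i, j + 1L]; best_c <- cost_dp[i, j + 1L]; best_m <- 1L
      p <- pairs_dp[i + 1L, j]; cc <- cost_dp[i + 1L, j]
      if (p > best_p || (p == best_p && cc < best_c)) {
        best_p <- p; best_c <- cc; best_m <- 2L
      }
      d <- abs(a[i] - b[j])
      if (d <= tolerance) {
        p <- pairs_dp[i, j] + 1L
        cc <- cost_dp[i, j] + d
        if (p > best_p || (p == best_p && cc < best_c)) {
          best_p <- p; best_c <- cc; best_m <- 3L
        }
      }
      pairs_dp[i + 1L, j + 1L] <- best_p
      cost_dp[i + 1L, j + 1L] <- best_c
      move[i + 1L, j + 1L] <- best_m
    }
  }
  ia <- na; ib <- nb
  pc <- pm <- numeric(0)
  while (ia > 0L && ib > 0L) {
    m <- move[ia + 1L, ib + 1L]
    if (m == 3L) {
      pc <- c(a[ia], pc); pm <- c(b[ib], pm)
      ia <- ia - 1L; ib <- ib - 1L
    } else if (m == 2L) {
      ib <- ib - 1L
    } else {
      ia <- ia - 1L
    }
  }
  residual <- pc - pm
  abs_res <- abs(residual)
  structure(
    list(
      pairs = data.frame(calc = pc, meas = pm, residual = residual),
      unmatched_calc = setdiff(a, pc),
      unmatched_meas = setdiff(b, pm),
      mean_abs_residual = if (length(abs_res)) mean(abs_res) else NA_real_,
      sd_abs_residual = if (length(abs_res) > 1) stats::sd(abs_res) else NA_real_,
      tolerance_used = tolerance,
      n_pairs = length(pc)
    ),
    class = "match_table"
  )
}

#' @export
print.match_table <- function(x, ...) {
  cat(sprintf("<match_table> %d pair%s (tolerance %g cm-1), %d calc-only, %d meas-only\n",
              x$n_pairs, if (x$n_pairs == 1) "" else "s", x$tolerance_used,
              length(x$unmatched_calc), length(x$unmatched_meas)))
  if (x$n_pairs > 0) {
    cat(sprintf("mean |residual| = %.2f cm-1, sd = %.2f cm-1\n",
                x$mean_abs_residual, x$sd_abs_residual))
  }
  invisible(x)
}

#' Discrepancy statistics of a match table
#'
#' @param m a [match_peaks()] result with at least one pair.
#' @return A named list with `mean_abs_residual` and `sd_abs_residual`
#'   (arithmetic mean and sample standard deviation of |calc - meas|),
#'   computed in full precision.
#' @export
discrepancy_stats <- function(m) {
  stopifnot(inherits(m, "match_table"))
  if (m$n_pairs < 1L) {
    stop("discrepancy statistics are undefined without matched pairs", call. = FALSE)
  }
  abs_res <- abs(m$pairs$residual)
  list(
    mean_abs_residual = mean(abs_res),
    sd_abs_residual = if (length(abs_res) > 1) stats::sd(abs_res) else NA_real_
  )
}

#' Assignment report in the printed-table layout
#'
#' Combines a match table with the assignments of the calculated mode table
#' into rows of (calculated, measured-or-blank, assignment), ordered by
#' wavenumber, including calculated-only and measured-only rows — the layout
#' of a theory-versus-experiment vibrational assignment table.
#'
#' @param m a [match_peaks()] result.
#' @param calc_table a [mode_table()] whose (possibly scaled) wavenumbers
#'   correspond to the calculated positions in `m`.
#' @param position_tol how close a calc position must lie to a mode's
#'   wavenumber to inherit its assignment (cm^-1).
#' @return A data frame with columns `calculated`, `measured`, `assignment`;
#'   blanks are `NA`.
#' @export
assignment_report <- function(m, calc_table, position_tol = 0.5) {
  stopifnot(inherits(m, "match_table"), inherits(calc_table, "mode_table"))
  lookup <- function(pos) {
    d <- abs(calc_table$modes$wavenumber - pos)
    i <- which.min(d)
    if (length(i) == 1L && d[i] <= position_tol) calc_table$modes$assignment[i] else NA_character_
  }
  rows <- data.frame(
    calculated = c(m$pairs$calc, m$unmatched_calc, rep(NA_real_, length(m$unmatched_meas))),
    measured = c(m$pairs$meas, rep(NA_real_, length(m$unmatched_calc)), m$unmatched_meas),
    assignment = NA_character_
  )
  has_calc <- !is.na(rows$calculated)
  rows$assignment[has_calc] <- vapply(rows$calculated[has_calc], lookup, character(1))
  key <- ifelse(is.na(rows$calculated), rows$measured, rows$calculated)
  rows <- rows[order(key), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Rebuild a match table from an assignment report
#'
#' Inverse of [assignment_report()]: rows with both values become pairs, rows
#' with a single value become the corresponding unmatched entries.
#'
#' @param report a data frame with columns `calculated` and `measured`.
#' @param tolerance the tolerance to record on the rebuilt table.
#' @return A `match_table`.
#' @export
report_to_match_table <- function(report, tolerance = 20) {
  both <- !is.na(report$calculated) & !is.na(report$measured)
  pc <- report$calculated[both]
  pm <- report$measured[both]
  residual <- pc - pm
  abs_res <- abs(residual)
  structure(
    list(
      pairs = data.frame(calc = pc, meas = pm, residual = residual),
      unmatched_calc = report$calculated[!is.na(report$calculated) & is.na(report$measured)],
      unmatched_meas = report$measured[is.na(report$calculated) & !is.na(report$measured)],
      mean_abs_residual = if (length(abs_res)) mean(abs_res) else NA_real_,
      sd_abs_residual = if (length(abs_res) > 1) stats::sd(abs_res) else NA_real_,
      tolerance_used = tolerance,
      n_pairs = sum(both)
    ),
    class = "match_table"
  )
}
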