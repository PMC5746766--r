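test_that("a single synthesized line is detected at its position", {
  sp <- single_line_spectrum(center = 1000, step = 0.1)
  pk <- detect_peaks(sp)
  expect_length(pk$positions, 1L)
  expect_equal(pk$positions, 1000, tolerance = 0.5)
  expect_true(all(pk$prominences <= pk$heights))
})

test_that("well-separated lines resolve and close lines merge", {
  p <- intensity_params(scale_factor = 1)
  resolved <- synthesize_spectrum(mode_table(c(750, 795), c(50, 50)), p,
                                  650, 900, 0.2)
  pk <- detect_peaks(resolved)
  expect_length(pk$positions, 2L)
  expect_equal(pk$positions, c(750, 795), tolerance = 0.5)
  # 3 cm-1 apart with 7 cm-1 width: sum of line shapes has a single maximum
  merged <- synthesize_spectrum(mode_table(c(1000, 1003), c(50, 50)), p,
                                900, 1100, 0.1)
  expect_length(detect_peaks(merged, min_separation = 1)$positions, 1L)
})

test_that("noise-free sums of well-separated unit-area lines give one peak per line", {
  set.seed(21)
  p <- intensity_params(scale_factor = 1)
  for (i in 1:5) {
    n <- sample(3:6, 1)
    centers <- sort(200 + cumsum(runif(n, 120, 250)))
    centers <- centers[centers < 1750]
    sp <- synthesize_spectrum(mode_table(centers, runif(length(centers), 30, 100)),
                              p, 200, 1800, 0.5)
    pk <- detect_peaks(sp, min_prominence_frac = 0.01)
    expect_length(pk$positions, length(centers))
    expect_equal(pk$positions, centers, tolerance = 0.5)
  }
})

test_that("flat spectra yield an empty peak list, not an error", {
  flat <- raman_spectrum(1:100, rep(2, 100))
  expect_length(detect_peaks(flat)$positions, 0L)
})

test_that("matching identical lists pairs everything with zero residual", {
  x <- c(300, 500, 900, 1400)
  m <- match_peaks(x, x, tolerance = 20)
  expect_equal(m$n_pairs, 4L)
  expect_true(all(m$pairs$residual == 0))
  expect_equal(m$mean_abs_residual, 0)
  expect_length(m$unmatched_calc, 0L)
})

test_that("disjoint lists leave everything unmatched", {
  m <- match_peaks(c(300, 600), c(900, 1300), tolerance = 20)
  expect_equal(m$n_pairs, 0L)
  expect_equal(m$unmatched_calc, c(300, 600))
  expect_equal(m$unmatched_meas, c(900, 1300))
  expect_true(is.na(m$mean_abs_residual))
  expect_error(discrepancy_stats(m), "undefined")
})

test_that("the reference band table reproduces the printed pairing structure", {
  tab <- dopamine_band_table()
  m <- match_peaks(tab$calculated[!is.na(tab$calculated)],
                   tab$measured[!is.na(tab$measured)], tolerance = 20)
  expect_equal(m$n_pairs, 12L)
  expect_true(any(m$pairs$calc == 744 & m$pairs$meas == 750))
  expect_true(any(m$pairs$calc == 782 & m$pairs$meas == 795))
  expect_equal(sort(m$unmatched_calc),
               c(1029, 1060, 1321, 1355, 1387, 1631, 1634))
  expect_equal(m$unmatched_meas, 1209)
})

test_that("discrepancy statistics are sign-insensitive and match a hand-summed oracle", {
  m0 <- match_peaks(c(100, 200, 300), c(100, 200, 300), 20)
  expect_equal(unlist(discrepancy_stats(m0)),
               c(mean_abs_residual = 0, sd_abs_residual = 0))
  m1 <- match_peaks(c(100, 206), c(106, 200), 20)
  expect_equal(discrepancy_stats(m1)$mean_abs_residual, 6)
  # hand-summed oracle over the printed reference cells
  tab <- dopamine_band_table()
  both <- !is.na(tab$calculated) & !is.na(tab$measured)
  abs_res <- abs(tab$calculated[both] - tab$measured[both])
  want_mean <- sum(abs_res) / length(abs_res)
  want_sd <- sqrt(sum((abs_res - want_mean)^2) / (length(abs_res) - 1))
  m <- match_peaks(tab$calculated[!is.na(tab$calculated)],
                   tab$measured[!is.na(tab$measured)], 20)
  st <- discrepancy_stats(m)
  expect_equal(st$mean_abs_residual, want_mean)
  expect_equal(st$sd_abs_residual, want_sd)
  # consistency with the reported 10 +/- 2 average discrepancy
  expect_lte(st$mean_abs_residual, 10)
  expect_gte(st$mean_abs_residual, 10 - 2)
})

test_that("swapping the inputs negates every residual", {
  set.seed(22)
  a <- sort(runif(8, 200, 1800))
  b <- a + runif(8, -9, 9)
  m_ab <- match_peaks(a, b, 20)
  m_ba <- match_peaks(b, a, 20)
  expect_equal(m_ab$pairs$residual, -m_ba$pairs$residual)
})

test_that("matching never exceeds tolerance nor pairs a position twice", {
  set.seed(23)
  for (i in 1:20) {
    a <- sort(runif(sample(3:12, 1), 200, 1800))
    b <- sort(runif(sample(3:12, 1), 200, 1800))
    m <- match_peaks(a, b, tolerance = 30)
    expect_true(all(abs(m$pairs$residual) <= 30))
    expect_false(anyDuplicated(m$pairs$calc) > 0)
    expect_false(anyDuplicated(m$pairs$meas) > 0)
    expect_equal(m$n_pairs + length(m$unmatched_calc), length(a))
    expect_equal(m$n_pairs + length(m$unmatched_meas), length(b))
  }
})

test_that("jittered copies of a well-spaced list are re-paired exactly", {
  set.seed(24)
  tol <- 20
  for (i in 1:100) {
    n <- sample(5:15, 1)
    truth <- 200 + cumsum(runif(n, 2 * tol + 1, 120))
    jit <- truth + runif(n, -tol / 2 + 1e-6, tol / 2 - 1e-6)
    m <- match_peaks(truth, jit, tolerance = tol)
    expect_equal(m$n_pairs, n)
    expect_equal(m$pairs$calc, truth)
    expect_equal(m$pairs$meas, sort(jit))
  }
})

test_that("the assignment report reproduces the printed layout and round-trips", {
  tab <- dopamine_band_table()
  m <- match_peaks(tab$calculated[!is.na(tab$calculated)],
                   tab$measured[!is.na(tab$measured)], 20)
  rep_tab <- assignment_report(m, dopamine_calc_modes())
  expect_equal(nrow(rep_tab), 20L)
  expect_equal(sum(!is.na(rep_tab$calculated) & !is.na(rep_tab$measured)), 12L)
  expect_equal(sum(is.na(rep_tab$measured)), 7L)
  expect_equal(rep_tab$measured[is.na(rep_tab$calculated)], 1209)
  # wavenumber-ordered as printed, with assignments carried over
  key <- ifelse(is.na(rep_tab$calculated), rep_tab$measured, rep_tab$calculated)
  expect_false(is.unsorted(key))
  row744 <- rep_tab[which(rep_tab$calculated == 744), ]
  expect_match(row744$assignment, "two band response")
  # round trip back to a match table
  m2 <- report_to_match_table(rep_tab, tolerance = m$tolerance_used)
  expect_equal(m2$pairs[order(m2$pairs$calc), ], m$pairs[order(m$pairs$calc), ])
  expect_equal(sort(m2$unmatched_calc), sort(m$unmatched_calc))
  expect_equal(m2$unmatched_meas, m$unmatched_meas)
})

test_that("an empty match against a nonempty table reports all rows measured-blank", {
  m <- match_peaks(numeric(0), numeric(0), 20)
  modes <- dopamine_calc_modes()
  m$unmatched_calc <- modes$modes$wavenumber
  rep_tab <- assignment_report(m, modes)
  expect_equal(nrow(rep_tab), 19L)
  expect_true(all(is.na(rep_tab$measured)))
})
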