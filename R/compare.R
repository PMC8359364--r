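# Agreement between two modalities' respiratory phase series: resampling to
# a common grid, normalized cross-correlation with lag search (phase delay),
# breathing-cycle mismatch arithmetic, and boxplot-style amplitude summaries.

#' Resample a phase series onto a uniform grid
#'
#' Resamples the bin series onto a `target_fs` grid spanning the phase
#' series' time range. A phase series produced by [assign_phase_bins()]
#' carries its extremum times, and the piecewise-linear phase ramp they
#' define is evaluated exactly at the grid times -- the same way
#' reconstruction labels acquisition events by the phase of the gating
#' signal at the event time. Without that metadata the integer bins are
#' resampled nearest-neighbour, which at a 2 Hz navigator staircases the
#' ramps. Grid points with no phase (bin 0) are marked unassigned and carry
#' no weight in the correlation.
#'
#' @param phase A `resp_phase` tibble from [assign_phase_bins()].
#' @param target_fs Target grid rate in Hz (20 by default so camera and
#'   navigator series share a 50 ms grid).
#' @return A tibble with `time_s`, `bin`, `assigned`.
#' @export
resample_phase <- function(phase, target_fs = 20) {
  keep <- phase$bin > 0L
  if (sum(keep) < 2L) abort("phase series has fewer than 2 assigned samples.")
  t0 <- min(phase$time_s); t1 <- max(phase$time_s)
  grid <- seq(t0, t1, by = 1 / target_fs)
  ext <- attr(phase, "extrema", exact = TRUE)
  if (!is.null(ext)) {
    bin <- eval_phase_bins(ext$t, ext$kind, grid, ext$method %||% "segment")
  } else {
    near <- vapply(grid, function(g) which.min(abs(phase$time_s - g)), integer(1))
    bin <- phase$bin[near]
  }
  tibble(time_s = grid, bin = bin, assigned = bin > 0L)
}

#' Cross-correlation and phase delay of two phase series
#'
#' Resamples both series to a common `target_fs` grid over their overlapping
#' time range and computes the mean-removed, norm-normalized cross-correlation
#' over integer lags within `lag_window_ms`. Only grid points assigned in both
#' series at the given alignment enter each lag's correlation. Returns the
#' peak correlation `C_phase` and the lag at the peak as the phase delay
#' `d_phase_ms` (positive = second series lags the first); ties between lags
#' take the smallest `|lag|`.
#'
#' @param phase_a,phase_b `resp_phase` tibbles (e.g. camera and navigator).
#' @param lag_window_ms Half-width of the lag search window, ms.
#' @param target_fs Common grid rate, Hz.
#' @return A one-row tibble `C_phase`, `d_phase_ms`, `lag_window_ms`,
#'   `n_overlap`.
#' @export
phase_cross_correlation <- function(phase_a, phase_b, lag_window_ms = 2000,
                                    target_fs = 20) {
  ra <- resample_phase(phase_a, target_fs)
  rb <- resample_phase(phase_b, target_fs)
  t0 <- max(min(ra$time_s), min(rb$time_s))
  t1 <- min(max(ra$time_s), max(rb$time_s))
  if (t1 - t0 <= 0) abort("phase series do not overlap in time.")
  grid <- seq(t0, t1, by = 1 / target_fs)
  a <- approx(ra$time_s, ra$bin, xout = grid, method = "constant", rule = 2)$y
  av <- approx(ra$time_s, as.numeric(ra$assigned), grid, method = "constant", rule = 2)$y > 0
  b <- approx(rb$time_s, rb$bin, xout = grid, method = "constant", rule = 2)$y
  bv <- approx(rb$time_s, as.numeric(rb$assigned), grid, method = "constant", rule = 2)$y > 0

  K <- floor(lag_window_ms / 1000 * target_fs)
  lags <- seq(-K, K)
  lags <- lags[order(abs(lags), lags)] # so ties at the max keep smallest |lag|
  n <- length(grid)
  best_c <- -Inf; best_lag <- NA_integer_; any_defined <- FALSE
  for (k in lags) {
    ia <- seq(max(1L, 1L - k), min(n, n - k))
    ib <- ia + k
    ok <- av[ia] & bv[ib]
    if (sum(ok) < 3L) next
    x <- a[ia][ok]; y <- b[ib][ok]
    sx <- x - mean(x); sy <- y - mean(y)
    den <- sqrt(sum(sx^2) * sum(sy^2))
    if (den == 0) next
    any_defined <- TRUE
    r <- sum(sx * sy) / den
    if (r > best_c) { best_c <- r; best_lag <- k }
  }
  if (!any_defined) abort("correlation undefined: constant or empty overlap.")
  tibble(
    C_phase = best_c,
    d_phase_ms = best_lag / target_fs * 1000,
    lag_window_ms = lag_window_ms,
    n_overlap = sum(av & bv)
  )
}

#' Phase mismatch implied by a gating-signal delay
#'
#' Expresses a time delay between two gating signals as a percentage of the
#' breathing cycle: `100 * |delay_ms| / (60000 / rate_bpm)`. A 63 ms delay at
#' 40 breaths/minute (1500 ms cycle) is a 4.2% mismatch, and 2.1% at 20
#' breaths/minute.
#'
#' @param delay_ms Delay in milliseconds.
#' @param rate_bpm Breathing rate in breaths per minute, > 0.
#' @return Mismatch as a percentage of the breathing cycle (not rounded).
#' @examples
#' mismatch_percent(63, 40)
#' @export
mismatch_percent <- function(delay_ms, rate_bpm) {
  if (any(rate_bpm <= 0)) abort("`rate_bpm` must be > 0.")
  100 * abs(delay_ms) / (60000 / rate_bpm)
}

#' Relative difference as a percentage
#'
#' `100 * difference / reference`, the arithmetic used to put mean flow-volume
#' differences in relation to their reference value (e.g. a 1.4 ml difference
#' against a 15.8 ml mean backward flow is an 8.9% relative difference).
#'
#' @param difference Difference in metric units.
#' @param reference Reference value in the same units, nonzero.
#' @return Percentage (not rounded).
#' @examples
#' round(relative_difference_percent(1.4, 15.8), 1)
#' @export
relative_difference_percent <- function(difference, reference) {
  if (any(reference == 0)) abort("`reference` must be nonzero.")
  100 * difference / reference
}

#' Boxplot-style amplitude summary of a signal
#'
#' Five-number summary plus the 1.5 x IQR whisker bounds
#' `W_low = Q1 - 1.5 (Q3 - Q1)` and `W_up = Q3 + 1.5 (Q3 - Q1)`. Quartiles use
#' the linear-interpolation convention (`stats::quantile` type 7); min/max run
#' over all samples including outliers, which is what makes min-max ranges far
#' more outlier-sensitive than whisker ranges.
#'
#' @param signal A `resp_signal` (or any data frame with `amplitude`).
#' @return A one-row tibble: `subject_id`, `modality`, `min`, `q1`, `q2`,
#'   `q3`, `max`, `w_low`, `w_up`.
#' @export
summarize_signal <- function(signal) {
  y <- signal$amplitude
  if (length(y) < 4L) abort("need at least 4 samples to summarise.")
  q <- unname(quantile(y, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  tibble(
    subject_id = attr(signal, "subject_id", exact = TRUE) %||% NA_character_,
    modality = attr(signal, "modality", exact = TRUE) %||% NA_character_,
    min = min(y), q1 = q[1], q2 = q[2], q3 = q[3], max = max(y),
    w_low = q[1] - 1.5 * iqr, w_up = q[3] + 1.5 * iqr
  )
}

#' Cohort range ratios between two modalities
#'
#' Compares pooled amplitude ranges of one modality against another: the
#' ratio of cohort-mean whisker ranges `(W_up - W_low)` and of cohort-mean
#' min-max ranges. A much larger min-max ratio than whisker ratio flags
#' outlier spikes that inflate extremes but not the bulk of the signal.
#'
#' @param summaries_a,summaries_b Tibbles of per-subject [summarize_signal()]
#'   rows, same number of rows.
#' @return A one-row tibble `whisker_range_ratio`, `minmax_range_ratio`.
#' @export
range_ratios <- function(summaries_a, summaries_b) {
  if (nrow(summaries_a) != nrow(summaries_b)) {
    abort("the two cohorts must have the same size.")
  }
  wa <- mean(summaries_a$w_up - summaries_a$w_low)
  wb <- mean(summaries_b$w_up - summaries_b$w_low)
  ma <- mean(summaries_a$max - summaries_a$min)
  mb <- mean(summaries_b$max - summaries_b$min)
  if (wb == 0 || mb == 0) abort("zero range in the denominator cohort.")
  tibble(whisker_range_ratio = wa / wb, minmax_range_ratio = ma / mb)
}
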