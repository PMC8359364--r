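# Respiratory phase binning. The chain mirrors the retrospective gating
# procedure used for whole-heart 4D flow reconstructions: rescale the raw
# trace to zero median, smooth over 1 s, detect breathing extrema in two
# passes (minimal peak distance from a 45 bpm ceiling, then a prominence
# threshold of one fourth of the median trough-to-peak swing), enforce
# min/max alternation, and map each sample to one of 100 phase bins -- 1-40
# over the trough-to-peak (inspiration) segment, 41-100 over the
# peak-to-trough (expiration) segment. Bins 41-100 are accepted, which
# realises the 60% expiration acceptance under a physiologic 40:60
# inspiration:expiration time split.

#' Rescale a trace to zero median
#'
#' @param signal A `resp_signal` tibble (or any data frame with `time_s`,
#'   `amplitude`).
#' @return The signal with `median(amplitude) == 0`.
#' @export
rescale_to_zero_median <- function(signal) {
  if (nrow(signal) < 1L) abort("cannot rescale an empty trace.")
  out <- dplyr::mutate(signal, amplitude = .data$amplitude - median(.data$amplitude))
  restamp_signal(out, signal)
}

#' Smooth a trace with a centred moving average
#'
#' Window length is `round(window_s * fs)` samples (at least 1). Odd windows
#' use equal weights; even windows use the standard symmetric centred form
#' with half weights on the two end samples (n + 1 taps), so the smoother
#' never introduces a half-sample time shift -- this matters at the
#' navigator's low sampling rate, where a one-sided 2-sample average would
#' advance the whole trace by a quarter second. Near the trace ends the
#' window shrinks to the available taps (weights renormalised), so constant
#' signals pass through unchanged.
#'
#' @param signal A `resp_signal` tibble.
#' @param window_s Smoothing window in seconds.
#' @return The smoothed signal.
#' @export
smooth_signal <- function(signal, window_s = 1.0) {
  if (window_s <= 0) abort("`window_s` must be > 0.")
  fs <- signal_fs(signal)
  n <- max(1L, as.integer(round(window_s * fs)))
  y <- signal$amplitude
  N <- length(y)
  wts <- if (n %% 2L == 1L) rep(1, n) else c(0.5, rep(1, n - 1L), 0.5)
  half <- (length(wts) - 1L) %/% 2L
  sm <- vapply(seq_len(N), function(i) {
    lo <- max(1L, i - half)
    hi <- min(N, i + half)
    w <- wts[(lo - i + half + 1L):(hi - i + half + 1L)]
    sum(w * y[lo:hi]) / sum(w)
  }, numeric(1))
  out <- dplyr::mutate(signal, amplitude = sm)
  restamp_signal(out, signal)
}

#' Minimal distance between same-sign peaks
#'
#' Converts the highest expected breathing rate into a minimum peak-to-peak
#' separation in samples: `floor((60 / max_rate_bpm) * fs)`, at least 1.
#' Flooring (rather than rounding) guarantees the constraint is never
#' violated at low sampling rates.
#'
#' @param fs Sampling rate in Hz, > 0.
#' @param max_rate_bpm Highest expected breathing rate, breaths/minute.
#' @return Integer number of samples.
#' @examples
#' min_peak_distance_samples(20) # 26 samples = 1.3 s
#' min_peak_distance_samples(2)  # 2 samples
#' @export
min_peak_distance_samples <- function(fs, max_rate_bpm = 45) {
  if (fs <= 0) abort("`fs` must be > 0.")
  max(1L, as.integer(floor(60 / max_rate_bpm * fs)))
}

# indices of strict local maxima; plateau points take the first sample
local_max_candidates <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# topographic prominence of maxima at idx: height above the higher of the two
# key saddles (lowest point between the peak and the nearest higher terrain on
# each side; trace ends act as open boundaries)
peak_prominence <- function(y, idx) {
  n <- length(y)
  vapply(idx, function(i) {
    h <- y[i]
    higher_l <- which(y[seq_len(i - 1L)] > h)
    from <- if (length(higher_l)) max(higher_l) else 1L
    sad_l <- min(y[from:i])
    higher_r <- which(y[i:n] > h)
    to <- if (length(higher_r)) i - 1L + min(higher_r) else n
    sad_r <- min(y[i:to])
    h - max(sad_l, sad_r)
  }, numeric(1))
}

# enforce a minimal separation between peaks, keeping the higher peak on
# conflict (processed in descending height order)
enforce_min_distance <- function(idx, y, min_distance) {
  if (length(idx) < 2L) return(idx)
  ord <- idx[order(-y[idx], idx)]
  kept <- integer()
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_distance)) kept <- c(kept, i)
  }
  sort(kept)
}

find_peaks <- function(y, min_distance, min_prominence = NULL) {
  idx <- local_max_candidates(y)
  if (!is.null(min_prominence) && length(idx)) {
    idx <- idx[peak_prominence(y, idx) >= min_prominence]
  }
  enforce_min_distance(idx, y, min_distance)
}

# sub-sample extremum time by parabolic interpolation through the extremum
# sample and its two neighbours; essential at the navigator's 2 Hz, where
# whole-sample extremum times would shift every phase ramp by up to a
# quarter second
refine_extremum_time <- function(t, y, idx) {
  vapply(idx, function(i) {
    if (i <= 1L || i >= length(y)) return(t[i])
    denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
    if (denom == 0) return(t[i])
    p <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
    p <- max(min(p, 0.5), -0.5)
    t[i] + p * (t[min(i + 1L, length(t))] - t[i])
  }, numeric(1))
}

#' Detect breathing extrema in two passes
#'
#' Pass 1 finds local maxima, and minima on the negated trace, honouring
#' `min_distance`. The prominence threshold is then set to one fourth of the
#' median amplitude swing between consecutive minima and following maxima of
#' pass 1, and pass 2 repeats the detection keeping only extrema whose
#' topographic prominence reaches that threshold.
#'
#' @param signal A smoothed, zero-median `resp_signal`.
#' @param min_distance Minimal same-sign peak separation in samples, from
#'   [min_peak_distance_samples()].
#' @return A list of class `extrema_set`: `minima_idx`, `maxima_idx` (sample
#'   indices) and `prominence_threshold`.
#' @export
detect_extrema <- function(signal, min_distance = min_peak_distance_samples(signal_fs(signal))) {
  y <- signal$amplitude
  max1 <- find_peaks(y, min_distance)
  min1 <- find_peaks(-y, min_distance)
  if (length(max1) < 1L || length(min1) < 1L) abort("no breathing detected")
  # median trough-to-peak swing from pass 1: each maximum minus the closest
  # preceding minimum
  swings <- vapply(max1, function(i) {
    prev <- min1[min1 < i]
    if (!length(prev)) return(NA_real_)
    y[i] - y[max(prev)]
  }, numeric(1))
  swings <- swings[!is.na(swings)]
  if (!length(swings)) {
    swings <- vapply(min1, function(i) {
      nxt <- max1[max1 > i]
      if (!length(nxt)) return(NA_real_)
      y[min(nxt)] - y[i]
    }, numeric(1))
    swings <- swings[!is.na(swings)]
  }
  if (!length(swings)) abort("no breathing detected")
  thr <- 0.25 * median(swings)
  max2 <- find_peaks(y, min_distance, min_prominence = thr)
  min2 <- find_peaks(-y, min_distance, min_prominence = thr)
  if (length(max2) + length(min2) < 2L) abort("no breathing detected")
  structure(
    list(
      minima_idx = min2, maxima_idx = max2,
      minima_t = refine_extremum_time(signal$time_s, y, min2),
      maxima_t = refine_extremum_time(signal$time_s, y, max2),
      prominence_threshold = thr
    ),
    class = "extrema_set"
  )
}

#' Enforce min/max alternation
#'
#' Resolves runs where one minimum is followed by two maxima (or vice versa)
#' by keeping the more extreme of the duplicates: the higher maximum, the
#' lower minimum. Ties keep the earlier sample.
#'
#' @param extrema An `extrema_set` from [detect_extrema()].
#' @param signal The signal the indices refer to.
#' @return An `extrema_set` whose minima and maxima strictly interleave.
#' @export
correct_alternation <- function(extrema, signal) {
  y <- signal$amplitude
  idx <- c(extrema$minima_idx, extrema$maxima_idx)
  kind <- rep(c(-1L, 1L), c(length(extrema$minima_idx), length(extrema$maxima_idx)))
  ord <- order(idx)
  idx <- idx[ord]; kind <- kind[ord]
  keep_idx <- integer(); keep_kind <- integer()
  for (j in seq_along(idx)) {
    if (length(keep_kind) && kind[j] == keep_kind[length(keep_kind)]) {
      # same-sign run: keep the more extreme (strict > so ties keep earlier)
      prev <- keep_idx[length(keep_idx)]
      better <- if (kind[j] == 1L) y[idx[j]] > y[prev] else y[idx[j]] < y[prev]
      if (better) keep_idx[length(keep_idx)] <- idx[j]
    } else {
      keep_idx <- c(keep_idx, idx[j])
      keep_kind <- c(keep_kind, kind[j])
    }
  }
  min_keep <- keep_idx[keep_kind == -1L]
  max_keep <- keep_idx[keep_kind == 1L]
  all_min_t <- extrema$minima_t %||% signal$time_s[extrema$minima_idx]
  all_max_t <- extrema$maxima_t %||% signal$time_s[extrema$maxima_idx]
  structure(
    list(
      minima_idx = min_keep,
      maxima_idx = max_keep,
      minima_t = all_min_t[match(min_keep, extrema$minima_idx)],
      maxima_t = all_max_t[match(max_keep, extrema$maxima_idx)],
      prominence_threshold = extrema$prominence_threshold
    ),
    class = "extrema_set"
  )
}


# evaluate the piecewise-linear phase ramp defined by extremum times at
# arbitrary time points; times outside [first, last] extremum get bin 0
eval_phase_bins <- function(ext_t, ext_kind, t, method = "segment") {
  m <- length(ext_t)
  bin <- integer(length(t))
  if (method == "segment") {
    seg <- findInterval(t, ext_t) # t exactly at an extremum starts its segment
    seg[t >= ext_t[m]] <- m - 1L  # the final extremum closes the last segment
    ok <- seg >= 1L & t >= ext_t[1] & t <= ext_t[m]
    frac <- pmin(pmax((t[ok] - ext_t[seg[ok]]) /
                        (ext_t[seg[ok] + 1L] - ext_t[seg[ok]]), 0), 1)
    insp <- ext_kind[seg[ok]] == -1L
    bin[ok] <- ifelse(insp,
                      pmin(1L + floor(40 * frac), 40),
                      pmin(41L + floor(60 * frac), 100))
  } else {
    min_t <- ext_t[ext_kind == -1L]
    if (length(min_t) < 2L) abort("no complete breathing cycle in the trace.")
    nm <- length(min_t)
    seg <- findInterval(t, min_t)
    seg[t >= min_t[nm]] <- nm - 1L
    ok <- seg >= 1L & t >= min_t[1] & t <= min_t[nm]
    frac <- pmin(pmax((t[ok] - min_t[seg[ok]]) /
                        (min_t[seg[ok] + 1L] - min_t[seg[ok]]), 0), 1)
    bin[ok] <- pmin(1L + floor(100 * frac), 100)
  }
  as.integer(bin)
}

#' Assign respiratory phase bins
#'
#' Maps every sample between the first and last retained extremum to a bin in
#' 1..100. With the default `"segment"` method, samples between a minimum at
#' `t_m` and the following maximum at `t_M` (inspiration) get
#' `1 + floor(40 * (t - t_m) / (t_M - t_m))` clipped to 1-40, and samples
#' between a maximum and the following minimum (expiration) get
#' `41 + floor(60 * (t - t_M) / (t_m' - t_M))` clipped to 41-100; a sample
#' exactly at a maximum starts the expiration segment at bin 41. Segment
#' boundaries `t_m`, `t_M` are the sub-sample (parabolically interpolated)
#' extremum times, so coarse sampling does not shift the ramps. The
#' `"cycle"` method instead spreads all 100 bins linearly over each full
#' min-to-min cycle. Samples before the first or after the last extremum get
#' bin 0 and are rejected. A sample is accepted when its bin falls inside
#' `accept_range`.
#'
#' @param signal A `resp_signal`.
#' @param extrema Alternation-corrected `extrema_set`.
#' @param accept_range Length-2 inclusive bin range accepted for
#'   reconstruction; the default 41:100 is the 60% expiration acceptance.
#' @param method `"segment"` (default) or `"cycle"`; see above.
#' @return A tibble of class `resp_phase` with columns `time_s`, `amplitude`,
#'   `bin` (0 = unassigned) and `accepted`.
#' @export
assign_phase_bins <- function(signal, extrema, accept_range = c(41L, 100L),
                              method = c("segment", "cycle")) {
  method <- rlang::arg_match(method)
  ext_t <- c(extrema$minima_t %||% signal$time_s[extrema$minima_idx],
             extrema$maxima_t %||% signal$time_s[extrema$maxima_idx])
  ext_kind <- rep(c(-1L, 1L), c(length(extrema$minima_idx), length(extrema$maxima_idx)))
  ord <- order(ext_t)
  ext_t <- ext_t[ord]; ext_kind <- ext_kind[ord]
  m <- length(ext_t)
  if (m < 2L) abort("no complete breathing cycle in the trace.")
  bin <- eval_phase_bins(ext_t, ext_kind, signal$time_s, method)

  out <- tibble(
    time_s = signal$time_s, amplitude = signal$amplitude,
    bin = bin,
    accepted = bin >= accept_range[1] & bin <= accept_range[2]
  )
  class(out) <- c("resp_phase", class(out))
  attr(out, "fs") <- signal_fs(signal)
  attr(out, "extrema") <- list(t = ext_t, kind = ext_kind, method = method)
  attr(out, "n_bins") <- 100L
  attr(out, "accept_range") <- as.integer(accept_range)
  attr(out, "modality") <- attr(signal, "modality", exact = TRUE)
  attr(out, "subject_id") <- attr(signal, "subject_id", exact = TRUE)
  out
}

#' Run the full phase-binning chain
#'
#' Convenience wrapper: zero-median rescale, 1-s smoothing, two-pass extrema
#' detection with the 45 bpm minimal peak distance, alternation correction,
#' and phase-bin assignment with expiration acceptance.
#'
#' @param signal A raw `resp_signal`.
#' @param window_s Smoothing window (s).
#' @param max_rate_bpm Highest expected breathing rate (bpm).
#' @inheritParams assign_phase_bins
#' @return A `resp_phase` tibble; see [assign_phase_bins()].
#' @examples
#' latent <- gen_breathing_waveform(breathing_params(duration_s = 60))
#' pair <- gen_modality_pair(latent, seed = 1)
#' phase <- bin_phases(pair$camera)
#' mean(phase$accepted[phase$bin > 0])
#' @export
bin_phases <- function(signal, window_s = 1.0, max_rate_bpm = 45,
                       accept_range = c(41L, 100L),
                       method = c("segment", "cycle")) {
  sig <- smooth_signal(rescale_to_zero_median(signal), window_s)
  ext <- detect_extrema(sig, min_peak_distance_samples(signal_fs(sig), max_rate_bpm))
  ext <- correct_alternation(ext, sig)
  assign_phase_bins(sig, ext, accept_range = accept_range, method = method)
}

#' Label acquisition events with phase-bin acceptance
#'
#' Each acquisition event inherits the bin and acceptance of the
#' nearest-in-time signal sample; exact ties take the earlier sample. Events
#' outside the signal's time span are rejected with bin 0.
#'
#' @param phase A `resp_phase` tibble.
#' @param acq_times Numeric vector of acquisition event times (s).
#' @return A tibble with `acq_time_s`, `bin`, `accepted`.
#' @export
label_acquisition <- function(phase, acq_times) {
  if (!length(acq_times)) {
    return(tibble(acq_time_s = numeric(), bin = integer(), accepted = logical()))
  }
  t <- phase$time_s
  # nearest sample; on exact midpoint ties findInterval picks the earlier
  pos <- findInterval(acq_times, t)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(t))
  nearer_hi <- (acq_times - t[lo]) > (t[hi] - acq_times) # strict: ties earlier
  nearest <- ifelse(nearer_hi, hi, lo)
  inside <- acq_times >= t[1] & acq_times <= t[length(t)]
  tibble(
    acq_time_s = acq_times,
    bin = ifelse(inside, phase$bin[nearest], 0L),
    accepted = inside & phase$accepted[nearest]
  )
}
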