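# Shared fixture builders; everything is generated in code at test time.

# pure sinusoid trace: amplitude 1, given rate, no noise
sine_signal <- function(rate_bpm = 15, fs = 20, duration_s = 90) {
  t <- seq(0, duration_s, by = 1 / fs)
  resp_signal(t, sin(2 * pi * t * rate_bpm / 60), fs = fs)
}

# quick latent + sensor pair under clean-ish conditions
clean_pair <- function(seed = 1, duration_s = 90, rate_jitter = 0.05,
                       nav_lag_s = 0, noise_sd = 0) {
  latent <- gen_breathing_waveform(breathing_params(
    duration_s = duration_s, rate_jitter = rate_jitter, seed = seed
  ))
  gen_modality_pair(
    latent,
    cam_params = modality_params(noise_sd = noise_sd),
    nav_params = modality_params(noise_sd = noise_sd),
    nav_lag_s = nav_lag_s, seed = seed + 1000
  )
}

# build an extrema_set by hand from times on a signal's grid
manual_extrema <- function(signal, minima_t, maxima_t) {
  structure(
    list(
      minima_idx = match(minima_t, signal$time_s),
      maxima_idx = match(maxima_t, signal$time_s),
      minima_t = minima_t, maxima_t = maxima_t,
      prominence_threshold = 0
    ),
    class = "extrema_set"
  )
}

# exact logistic edge profile
logistic_profile <- function(nz = 30, b = 0, a = 100, z0 = 15, w = 2) {
  z <- seq_len(nz)
  b + a / (1 + exp(-(z - z0) / w))
}

# independent brute-force ordinal Krippendorff alpha: literal enumeration of
# pairable value pairs, no coincidence matrix
kripp_oracle <- function(ratings, levels = NULL) {
  m <- as.matrix(ratings[, setdiff(names(ratings), "item_id"), drop = FALSE])
  units <- apply(m, 1, function(r) r[!is.na(r)], simplify = FALSE)
  units <- units[vapply(units, length, 0L) >= 2]
  pooled <- unlist(units)
  levels <- sort(levels %||% unique(pooled))
  n_g <- vapply(levels, function(l) sum(pooled == l), 0)
  n_tot <- sum(n_g)
  d2 <- function(v1, v2) {
    if (v1 == v2) return(0)
    i1 <- which(levels == v1); i2 <- which(levels == v2)
    lo <- min(i1, i2); hi <- max(i1, i2)
    (sum(n_g[lo:hi]) - (n_g[lo] + n_g[hi]) / 2)^2
  }
  Do <- 0
  for (vals in units) {
    mu <- length(vals)
    for (i in seq_len(mu)) for (j in seq_len(mu)) {
      if (i != j) Do <- Do + d2(vals[i], vals[j]) / (mu - 1)
    }
  }
  De <- 0
  for (c1 in seq_along(levels)) for (c2 in seq_along(levels)) {
    De <- De + n_g[c1] * n_g[c2] * d2(levels[c1], levels[c2])
  }
  if (De == 0) return(1)
  1 - (n_tot - 1) * Do / De
}

`%||%` <- function(x, y) if (is.null(x)) y else x
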