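# Synthetic respiratory signals: a latent quasi-periodic breathing process
# sampled by two emulated sensors (in-bore camera at 20 Hz in arbitrary units,
# liver-lung navigator at 2 Hz in mm).

LATENT_FS <- 100 # Hz; latent process grid, well above both sensor rates

# run code with a private RNG stream, leaving the caller's stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Parameters of the synthetic breathing process
#'
#' Bundles the knobs of the latent breathing waveform and the per-sensor
#' corruption settings. Defaults describe quiet adult breathing: 15 breaths
#' per minute with mild cycle-to-cycle jitter and an inspiration fraction of
#' 0.4, i.e. a physiologic inspiration:expiration time ratio of 40:60.
#'
#' @param rate_bpm Mean breathing rate, breaths per minute; must lie in (5, 60).
#' @param rate_jitter Fractional SD of the cycle length (0 = strictly periodic).
#' @param insp_fraction Fraction of each cycle spent in inspiration, in (0, 1).
#' @param drift_amp Slow baseline drift amplitude (signal units).
#' @param drift_period_s Drift period in seconds.
#' @param noise_sd Additive Gaussian noise SD (signal units).
#' @param outlier_rate_hz Expected spike rate, events per second.
#' @param outlier_scale Spike magnitude as a multiple of the signal scale.
#' @param duration_s Trace length in seconds; must exceed 3 cycle lengths.
#' @param seed RNG seed.
#' @return A list of class `breathing_params`.
#' @examples
#' p <- breathing_params(rate_bpm = 12, duration_s = 120)
#' @export
breathing_params <- function(rate_bpm = 15, rate_jitter = 0.05,
                             insp_fraction = 0.4,
                             drift_amp = 0, drift_period_s = 60,
                             noise_sd = 0, outlier_rate_hz = 0,
                             outlier_scale = 5,
                             duration_s = 90, seed = 1L) {
  p <- list(
    rate_bpm = rate_bpm, rate_jitter = rate_jitter,
    insp_fraction = insp_fraction,
    drift_amp = drift_amp, drift_period_s = drift_period_s,
    noise_sd = noise_sd, outlier_rate_hz = outlier_rate_hz,
    outlier_scale = outlier_scale, duration_s = duration_s, seed = seed
  )
  if (!(p$rate_bpm > 5 && p$rate_bpm < 60)) {
    abort("`rate_bpm` must lie in (5, 60).")
  }
  if (!(p$insp_fraction > 0 && p$insp_fraction < 1)) {
    abort("`insp_fraction` must lie in (0, 1).")
  }
  for (f in c("rate_jitter", "drift_amp", "noise_sd", "outlier_rate_hz")) {
    if (p[[f]] < 0) abort(sprintf("`%s` must be >= 0.", f))
  }
  if (p$duration_s <= 3 * 60 / p$rate_bpm) {
    abort("`duration_s` must exceed 3 mean cycle lengths.")
  }
  structure(p, class = "breathing_params")
}

#' Generate the latent breathing waveform
#'
#' Produces a unit-amplitude quasi-periodic trace on a 100 Hz grid. Each cycle
#' runs trough (end-expiration, amplitude 0) to trough through one inspiratory
#' peak (amplitude 1) placed at `insp_fraction` of the cycle, as a
#' time-warped cosine `y = 0.5 - 0.5 cos(2 pi phi(t))`: the cycle phase `phi`
#' advances at a constant rate within a turnaround window around each
#' extremum and at a segment-specific constant rate in between. The constant
#' rate across each extremum makes the waveform locally symmetric about its
#' peaks and troughs, so a centred moving-average smoother of window up to
#' twice the turnaround half-width leaves the extremum positions unshifted --
#' which is what makes the downstream accepted-fraction of phase binning
#' reflect the true inspiration:expiration time split. Cycle lengths vary by
#' a fractional Gaussian jitter. Drift, noise and outliers are sensor
#' properties and are added later by [gen_modality_pair()], not here.
#'
#' @param params A [breathing_params()] object.
#' @return A `resp_signal` tibble (modality `"latent"`, fs = 100 Hz).
#' @examples
#' latent <- gen_breathing_waveform(breathing_params(duration_s = 60))
#' @export
gen_breathing_waveform <- function(params) {
  if (!inherits(params, "breathing_params")) {
    params <- do.call(breathing_params, as.list(params))
  }
  T0 <- 60 / params$rate_bpm
  with_seed(params$seed, {
    # draw cycle lengths until the trace covers the requested duration
    n_guess <- ceiling(params$duration_s / T0) + 10L
    lens <- T0 * pmax(0.25, 1 + params$rate_jitter * rnorm(n_guess))
    while (sum(lens) < params$duration_s + T0) {
      lens <- c(lens, T0 * pmax(0.25, 1 + params$rate_jitter * rnorm(10L)))
    }
    starts <- cumsum(c(0, lens))
    t <- seq(0, params$duration_s, by = 1 / LATENT_FS)
    cycle <- findInterval(t, starts, rightmost.closed = FALSE)
    tau <- t - starts[cycle] # time into the current cycle
    fi <- params$insp_fraction
    Tc <- lens[cycle]
    L1 <- fi * Tc            # inspiration duration
    L2 <- (1 - fi) * Tc      # expiration duration
    Lmin <- pmin(L1, L2)
    h <- pmin(0.65, 0.35 * Lmin)     # turnaround half-width (s); kept wider
                                     # than the 1-s smoother half-window so
                                     # the window sees a symmetric extremum
    s_cap <- 1.3 * 0.5 / Lmin        # constant phase rate across extrema
    m1 <- (0.5 - 2 * h * s_cap) / (L1 - 2 * h) # mid-inspiration phase rate
    m2 <- (0.5 - 2 * h * s_cap) / (L2 - 2 * h) # mid-expiration phase rate
    phi <- ifelse(
      tau < h, s_cap * tau,
      ifelse(
        tau < L1 - h, s_cap * h + m1 * (tau - h),
        ifelse(
          tau < L1 + h, 0.5 - s_cap * (L1 - tau),
          ifelse(
            tau < Tc - h, 0.5 + s_cap * h + m2 * (tau - L1 - h),
            1 - s_cap * (Tc - tau)
          )
        )
      )
    )
    y <- 0.5 - 0.5 * cos(2 * pi * phi)
    sig <- resp_signal(t, y, fs = LATENT_FS, modality = "latent")
    attr(sig, "cycle_starts") <- starts[starts <= params$duration_s]
    attr(sig, "insp_fraction") <- fi
    sig
  })
}

#' Per-sensor corruption settings
#'
#' @param noise_sd Additive Gaussian noise SD, as a fraction of the signal scale.
#' @param drift_amp Baseline drift amplitude, fraction of the signal scale.
#' @param drift_period_s Drift period in seconds.
#' @param outlier_rate_hz Expected single-sample spike rate, events/s.
#' @param outlier_scale Spike magnitude as a multiple of the signal scale.
#' @return A list of class `modality_params`.
#' @export
modality_params <- function(noise_sd = 0, drift_amp = 0, drift_period_s = 60,
                            outlier_rate_hz = 0, outlier_scale = 5) {
  structure(
    list(
      noise_sd = noise_sd, drift_amp = drift_amp,
      drift_period_s = drift_period_s,
      outlier_rate_hz = outlier_rate_hz, outlier_scale = outlier_scale
    ),
    class = "modality_params"
  )
}

# sample one sensor's view of the latent trace
sample_modality <- function(latent, fs, scale, mp, lag_s, modality, subject_id) {
  t_end <- max(latent$time_s)
  t <- seq(0, floor(t_end * fs) / fs, by = 1 / fs)
  # the sensor at time t reports the latent state at t - lag_s
  y <- approx(latent$time_s, latent$amplitude, xout = pmax(t - lag_s, 0),
              rule = 2)$y * scale
  if (mp$drift_amp > 0) {
    phase <- runif(1, 0, 2 * pi)
    y <- y + mp$drift_amp * scale * sin(2 * pi * t / mp$drift_period_s + phase)
  }
  if (mp$noise_sd > 0) y <- y + rnorm(length(y), sd = mp$noise_sd * scale)
  if (mp$outlier_rate_hz > 0) {
    n_spk <- rpois(1, mp$outlier_rate_hz * t_end)
    if (n_spk > 0) {
      idx <- sample.int(length(y), min(n_spk, length(y)))
      y[idx] <- y[idx] + mp$outlier_scale * scale * sample(c(-1, 1), length(idx), TRUE)
    }
  }
  resp_signal(t, y, fs = fs, modality = modality, subject_id = subject_id)
}

#' Emulate simultaneous camera and navigator recordings
#'
#' Samples one latent breathing trace with two sensor models: a camera-like
#' channel at 20 Hz in arbitrary units and a navigator-like channel at 2 Hz in
#' millimetres of liver displacement. Each channel gets independent drift,
#' noise and single-sample outlier spikes; the navigator can additionally lag
#' the camera by `nav_lag_s` seconds. In observed cohorts the camera amplitude
#' scale is fairly uniform across subjects while navigator amplitudes spread
#' roughly 3-fold, so `nav_scale_mm` is the knob to vary per subject.
#'
#' @param latent Latent trace from [gen_breathing_waveform()].
#' @param cam_scale Camera amplitude scale (a.u.); must be > 0.
#' @param nav_scale_mm Navigator amplitude scale (mm); must be > 0.
#' @param cam_params,nav_params [modality_params()] for each channel.
#' @param nav_lag_s Navigator time lag in seconds (positive = navigator lags).
#' @param cam_fs,nav_fs Sensor sampling rates in Hz.
#' @param seed RNG seed for sensor noise (independent of the latent seed).
#' @param subject_id Subject label stamped on both outputs.
#' @return A list with elements `camera` and `navigator`, both `resp_signal`.
#' @examples
#' latent <- gen_breathing_waveform(breathing_params(duration_s = 60))
#' pair <- gen_modality_pair(latent, nav_lag_s = 0.5, seed = 2)
#' @export
gen_modality_pair <- function(latent, cam_scale = 1, nav_scale_mm = 10,
                              cam_params = modality_params(),
                              nav_params = modality_params(),
                              nav_lag_s = 0, cam_fs = 20, nav_fs = 2,
                              seed = NULL, subject_id = "s01") {
  if (!is_resp_signal(latent)) abort("`latent` must be a resp_signal tibble.")
  if (cam_scale <= 0 || nav_scale_mm <= 0) abort("scales must be > 0.")
  if (abs(nav_lag_s) >= max(latent$time_s)) {
    abort("`nav_lag_s` exceeds the latent trace duration.")
  }
  with_seed(seed, {
    cam <- sample_modality(latent, cam_fs, cam_scale, cam_params,
                           lag_s = 0, modality = "camera", subject_id)
    nav <- sample_modality(latent, nav_fs, nav_scale_mm, nav_params,
                           lag_s = nav_lag_s, modality = "navigator", subject_id)
    list(camera = cam, navigator = nav)
  })
}
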