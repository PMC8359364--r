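#' Build a respiratory signal tibble
#'
#' A respiratory signal is an ordinary tibble with columns `time_s` (seconds,
#' strictly increasing) and `amplitude` (arbitrary units for camera traces,
#' millimetres for navigator traces), plus `fs`, `modality` and `subject_id`
#' attributes. Because it is a plain tibble, it survives dplyr verbs; all
#' functions that need the sampling rate fall back to inferring it from the
#' time stamps when the attribute has been dropped.
#'
#' @param time_s Numeric vector of sample times in seconds, strictly increasing.
#' @param amplitude Numeric vector of amplitudes, same length as `time_s`.
#' @param fs Nominal sampling rate in Hz. Defaults to the inverse median time
#'   step.
#' @param modality One of `"camera"`, `"navigator"`, `"latent"`.
#' @param subject_id Subject label.
#' @return A tibble of class `resp_signal` with columns `time_s`, `amplitude`.
#' @examples
#' s <- resp_signal(seq(0, 1, by = 0.05), sin(seq(0, 1, by = 0.05) * 2 * pi))
#' signal_fs(s)
#' @export
resp_signal <- function(time_s, amplitude, fs = NULL,
                        modality = c("camera", "navigator", "latent"),
                        subject_id = "s01") {
  if (length(time_s) != length(amplitude)) {
    abort("`time_s` and `amplitude` must have the same length.")
  }
  if (length(time_s) < 1L) abort("a respiratory signal needs at least one sample.")
  if (length(time_s) > 1L && any(diff(time_s) <= 0)) {
    abort("`time_s` must be strictly increasing.")
  }
  modality <- rlang::arg_match(modality)
  if (is.null(fs)) {
    fs <- if (length(time_s) > 1L) 1 / median(diff(time_s)) else NA_real_
  }
  out <- tibble(time_s = as.numeric(time_s), amplitude = as.numeric(amplitude))
  class(out) <- c("resp_signal", class(out))
  attr(out, "fs") <- fs
  attr(out, "modality") <- modality
  attr(out, "subject_id") <- subject_id
  out
}

#' Sampling rate of a signal or phase tibble
#'
#' Returns the `fs` attribute when present, otherwise infers the rate from the
#' median spacing of `time_s`.
#'
#' @param signal A data frame with a `time_s` column.
#' @return Sampling rate in Hz.
#' @export
signal_fs <- function(signal) {
  fs <- attr(signal, "fs", exact = TRUE)
  if (!is.null(fs) && is.finite(fs)) return(fs)
  t <- signal[["time_s"]]
  if (is.null(t) || length(t) < 2L) abort("cannot infer sampling rate from < 2 samples.")
  1 / median(diff(t))
}

# carry resp_signal attributes onto a modified copy
restamp_signal <- function(new, old) {
  class(new) <- unique(c("resp_signal", class(new)))
  for (a in c("fs", "modality", "subject_id")) {
    attr(new, a) <- attr(old, a, exact = TRUE)
  }
  new
}

#' @export
print.resp_signal <- function(x, ...) {
  fs <- attr(x, "fs", exact = TRUE)
  cat(sprintf(
    "<resp_signal> %s, subject %s, %d samples%s\n",
    attr(x, "modality", exact = TRUE) %||% "?",
    attr(x, "subject_id", exact = TRUE) %||% "?",
    nrow(x),
    if (!is.null(fs)) sprintf(", fs = %g Hz", fs) else ""
  ))
  NextMethod()
}

#' @rdname resp_signal
#' @param x Object to test.
#' @export
is_resp_signal <- function(x) {
  is.data.frame(x) && all(c("time_s", "amplitude") %in% names(x))
}
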