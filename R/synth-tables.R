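# Synthetic rater x item ordinal scores and subject x condition metric tables.

#' Generate an ordinal ratings table
#'
#' Emulates several raters scoring the same items on a k-point Likert scale
#' (the study used 4 points: unusable / fair / good / excellent).
#'
#' @param n_items Number of rated items.
#' @param n_raters Number of raters, >= 2.
#' @param k_levels Number of ordinal levels, >= 2.
#' @param agreement `"perfect"` (all raters identical), `"high"` (raters agree
#'   with the latent score 80% of the time, else miss by one level), or
#'   `"random"` (independent uniform scores).
#' @param seed RNG seed.
#' @return A tibble with `item_id` and one column per rater, scores in
#'   `1..k_levels`.
#' @examples
#' gen_ordinal_ratings(6, 3, 4, "high", seed = 1)
#' @export
gen_ordinal_ratings <- function(n_items, n_raters, k_levels = 4,
                                agreement = c("high", "perfect", "random"),
                                seed = 1L) {
  agreement <- rlang::arg_match(agreement)
  if (k_levels < 2) abort("`k_levels` must be >= 2.")
  if (n_raters < 2) abort("`n_raters` must be >= 2.")
  with_seed(seed, {
    scores <- switch(agreement,
      perfect = {
        latent <- sample.int(k_levels, n_items, replace = TRUE)
        matrix(rep(latent, n_raters), ncol = n_raters)
      },
      high = {
        latent <- sample.int(k_levels, n_items, replace = TRUE)
        m <- matrix(rep(latent, n_raters), ncol = n_raters)
        miss <- matrix(runif(n_items * n_raters) > 0.8, ncol = n_raters)
        step <- matrix(sample(c(-1L, 1L), n_items * n_raters, TRUE), ncol = n_raters)
        pmin(pmax(m + miss * step, 1L), k_levels)
      },
      random = matrix(sample.int(k_levels, n_items * n_raters, replace = TRUE),
                      ncol = n_raters)
    )
    colnames(scores) <- paste0("rater", seq_len(n_raters))
    dplyr::bind_cols(tibble(item_id = seq_len(n_items)), as_tibble(scores))
  })
}

#' Generate a subject x condition metric table
#'
#' Simulates one quality metric measured on every subject under the three
#' gating conditions CAM (camera-gated), NAV (navigator-gated) and NO
#' (ungated), with an additive subject random effect:
#' `value = subject_effect + condition_mean + residual`.
#'
#' @param n_subjects Number of subjects.
#' @param means Length-3 numeric vector of condition means `(cam, nav, no)`.
#' @param subject_sd SD of the subject random effect, >= 0.
#' @param residual_sd SD of the residual, >= 0.
#' @param seed RNG seed.
#' @return A tibble with columns `subject_id`, `cam`, `nav`, `no`.
#' @examples
#' gen_condition_table(8, means = c(10, 10, 8.2), seed = 4)
#' @export
gen_condition_table <- function(n_subjects, means = c(10, 10, 8.2),
                                subject_sd = 1, residual_sd = 0.5, seed = 1L) {
  if (length(means) != 3L) abort("`means` must have length 3 (cam, nav, no).")
  if (subject_sd < 0 || residual_sd < 0) abort("SDs must be >= 0.")
  with_seed(seed, {
    subj <- rnorm(n_subjects, sd = subject_sd)
    vals <- outer(subj, means, "+") +
      matrix(rnorm(n_subjects * 3, sd = residual_sd), ncol = 3)
    tibble(
      subject_id = sprintf("s%02d", seq_len(n_subjects)),
      cam = vals[, 1], nav = vals[, 2], no = vals[, 3]
    )
  })
}
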