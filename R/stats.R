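# Study-level statistics: one-way repeated-measures ANOVA in the multivariate
# (Wilks' lambda / Hotelling T^2) form, Bonferroni-corrected pairwise paired
# comparisons with adjusted confidence intervals, Krippendorff's alpha for
# ordinal ratings, Bland-Altman agreement, and a one-sided one-sample t test.

cond_matrix <- function(data, cols) {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("condition columns not found: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(data[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Repeated-measures ANOVA, multivariate (Wilks' lambda) form
#'
#' Tests whether a metric differs across k within-subject conditions using
#' the multivariate approach: form the k - 1 within-subject difference
#' variables, compute Hotelling's `T^2 = n * dbar' S^-1 dbar` on their mean
#' vector `dbar` and covariance `S`, and convert
#' `Lambda = 1 / (1 + T^2 / (n - 1))`,
#' `F = T^2 (n - k + 1) / ((n - 1)(k - 1))` on `(k - 1, n - k + 1)` degrees
#' of freedom. Partial eta squared is `1 - Lambda`. Complete cases only.
#'
#' @param data A data frame with one row per subject.
#' @param cols Names of the k condition columns (default the study's
#'   `c("cam", "nav", "no")`).
#' @return An object of class `rm_anova` with fields `wilks_lambda`, `F`,
#'   `df1`, `df2`, `p`, `partial_eta_sq`, `n`, `k`; supports [tidy()] and
#'   [glance()].
#' @examples
#' tab <- gen_condition_table(12, means = c(10, 10, 8), seed = 2)
#' rm_anova_wilks(tab)
#' @export
rm_anova_wilks <- function(data, cols = c("cam", "nav", "no")) {
  m <- cond_matrix(data, cols)
  n <- nrow(m); k <- ncol(m)
  if (n <= k - 1) abort("need more subjects than conditions minus one.")
  d <- m[, -k, drop = FALSE] - m[, k] # k - 1 difference variables
  dbar <- colMeans(d)
  S <- stats::cov(d)
  if (all(d == 0)) {
    # no within-subject differences at all: no condition effect by definition
    T2 <- 0
  } else {
    Sinv <- tryCatch(solve(S), error = function(e) {
      abort(paste(
        "covariance of within-subject differences is singular;",
        "the metric is degenerate across conditions."
      ))
    })
    T2 <- n * drop(t(dbar) %*% Sinv %*% dbar)
  }
  lambda <- 1 / (1 + T2 / (n - 1))
  df1 <- k - 1
  df2 <- n - k + 1
  Fstat <- T2 * df2 / ((n - 1) * df1)
  structure(
    list(
      wilks_lambda = lambda, F = Fstat, df1 = df1, df2 = df2,
      p = pf(Fstat, df1, df2, lower.tail = FALSE),
      partial_eta_sq = 1 - lambda, T2 = T2, n = n, k = k, cols = cols
    ),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA (multivariate): Wilks' lambda = %.3f, F(%d, %d) = %.3f, p = %.4g, partial eta^2 = %.3f (n = %d)\n",
    x$wilks_lambda, x$df1, x$df2, x$F, x$p, x$partial_eta_sq, x$n
  ))
  invisible(x)
}

#' @export
tidy.rm_anova <- function(x, ...) {
  tibble(
    term = "condition", wilks_lambda = x$wilks_lambda, statistic = x$F,
    df1 = x$df1, df2 = x$df2, p.value = x$p, partial_eta_sq = x$partial_eta_sq
  )
}

#' @export
glance.rm_anova <- function(x, ...) {
  tibble(wilks_lambda = x$wilks_lambda, statistic = x$F, p.value = x$p,
         partial_eta_sq = x$partial_eta_sq, n = x$n, k = x$k)
}

#' Bonferroni-corrected pairwise paired comparisons
#'
#' For every ordered pair of conditions (so each comparison also appears
#' sign-mirrored, as study tables print them): paired mean difference
#' `X - Y`, its standard error `sd(diff)/sqrt(n)`, the Bonferroni-adjusted
#' two-sided paired-t p-value `min(1, 3 p)`, and a Bonferroni-adjusted
#' confidence interval at level `1 - alpha / 3`.
#'
#' @inheritParams rm_anova_wilks
#' @param alpha Family significance level (default 0.05).
#' @return A tibble with one row per ordered pair: `x`, `y`, `mean_diff`,
#'   `se`, `p_bonf`, `ci_low`, `ci_high`.
#' @export
bonferroni_pairwise <- function(data, cols = c("cam", "nav", "no"), alpha = 0.05) {
  m <- cond_matrix(data, cols)
  n <- nrow(m)
  if (n < 2L) abort("need at least 2 subjects for pairwise comparisons.")
  n_comp <- choose(ncol(m), 2)
  pairs <- expand.grid(x = cols, y = cols, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$x != pairs$y, ]
  purrr::pmap_dfr(pairs, function(x, y) {
    d <- m[, x] - m[, y]
    md <- mean(d)
    se <- sd(d) / sqrt(n)
    if (se == 0) {
      p <- if (md == 0) 1 else 0
      ci <- c(md, md)
    } else {
      tstat <- md / se
      p <- min(1, n_comp * 2 * pt(abs(tstat), n - 1, lower.tail = FALSE))
      tcrit <- qt(1 - alpha / (2 * n_comp), n - 1)
      ci <- md + c(-1, 1) * tcrit * se
    }
    tibble(x = x, y = y, mean_diff = md, se = se, p_bonf = p,
           ci_low = ci[1], ci_high = ci[2])
  })
}

#' Krippendorff's alpha for ordinal ratings
#'
#' Chance-corrected inter-rater agreement from the coincidence matrix, with
#' the ordinal distance
#' `delta^2(c, k) = (sum_{g=c}^{k} n_g - (n_c + n_k) / 2)^2` where `n_g` are
#' the value marginals. Missing scores are allowed; items with fewer than two
#' ratings are dropped (the pairable-values rule). `alpha = 1` under perfect
#' agreement and about 0 for chance-level rating.
#'
#' @param ratings A data frame of one row per item, one column per rater
#'   (a leading `item_id` column is ignored); integer scores or `NA`.
#' @param levels Vector of possible ordinal levels; defaults to the sorted
#'   observed values.
#' @return An object of class `kripp_alpha` with `alpha`, `metric`,
#'   `n_raters`, `n_items`; supports [tidy()].
#' @examples
#' r <- gen_ordinal_ratings(30, 3, 4, "high", seed = 1)
#' krippendorff_alpha_ordinal(r)
#' @export
krippendorff_alpha_ordinal <- function(ratings, levels = NULL) {
  m <- as.matrix(ratings[, setdiff(names(ratings), "item_id"), drop = FALSE])
  storage.mode(m) <- "double"
  if (ncol(m) < 2L) abort("need at least 2 raters.")
  levels <- sort(levels %||% unique(stats::na.omit(as.vector(m))))
  L <- length(levels)
  # coincidence matrix: each ordered pair of scores within an item adds
  # 1 / (m_u - 1)
  o <- matrix(0, L, L, dimnames = list(levels, levels))
  for (u in seq_len(nrow(m))) {
    vals <- m[u, ]
    vals <- vals[!is.na(vals)]
    mu <- length(vals)
    if (mu < 2L) next
    ci <- match(vals, levels)
    for (i in seq_len(mu)) for (j in seq_len(mu)) {
      if (i != j) o[ci[i], ci[j]] <- o[ci[i], ci[j]] + 1 / (mu - 1)
    }
  }
  nc <- rowSums(o)
  n_tot <- sum(nc)
  if (n_tot <= 1) abort("no pairable values in the ratings table.")
  # ordinal squared distance between level ranks c <= k
  csum <- cumsum(nc)
  delta2 <- matrix(0, L, L)
  for (c in seq_len(L)) for (k in seq_len(L)) {
    if (c == k) next
    lo <- min(c, k); hi <- max(c, k)
    delta2[c, k] <- (sum(nc[lo:hi]) - (nc[lo] + nc[hi]) / 2)^2
  }
  Do <- sum(o * delta2)
  De <- sum(outer(nc, nc) * delta2) / (n_tot - 1)
  alpha <- if (De == 0) 1 else 1 - Do / De
  structure(
    list(alpha = alpha, metric = "ordinal",
         n_raters = ncol(m), n_items = nrow(m)),
    class = "kripp_alpha"
  )
}

#' @export
print.kripp_alpha <- function(x, ...) {
  cat(sprintf("Krippendorff's alpha (%s) = %.3f (%d raters, %d items)\n",
              x$metric, x$alpha, x$n_raters, x$n_items))
  invisible(x)
}

#' @export
tidy.kripp_alpha <- function(x, ...) {
  tibble(alpha = x$alpha, metric = x$metric,
         n_raters = x$n_raters, n_items = x$n_items)
}

#' Bland-Altman agreement between two paired measurements
#'
#' Bias (mean of the paired differences `x - y`) and 95% limits of agreement
#' `bias +/- 1.96 sd(diff)` using the sample SD.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return An object of class `bland_altman` with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n` and the per-pair `means`/`diffs`; supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' ba <- bland_altman(rnorm(20, 10), rnorm(20, 10))
#' glance(ba)
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have the same length.")
  if (length(x) < 2L) abort("need at least 2 pairs.")
  d <- x - y
  bias <- mean(d); s <- sd(d)
  structure(
    list(bias = bias, sd_diff = s,
         loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         n = length(d), means = (x + y) / 2, diffs = d),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias = %.4g, 95%% limits of agreement [%.4g, %.4g] (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(mean = x$means, diff = x$diffs)
}

#' @export
glance.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high, n = x$n)
}

#' One-sided one-sample mean test
#'
#' One-sample t test of `mean(values)` against `threshold`, one-sided. Used
#' e.g. to test that the cohort's phase cross-correlations exceed 0.5 (no
#' strong correlation) on average. A zero-variance sample is degenerate:
#' p is 0 or 1 by the sign of the mean difference, 0.5 when exactly equal.
#'
#' @param values Numeric vector, length >= 2.
#' @param threshold Null-hypothesis mean.
#' @param direction `"greater"` tests mean > threshold, `"less"` the reverse.
#' @return A one-row tibble `estimate`, `threshold`, `statistic`, `df`,
#'   `p.value`, `direction`.
#' @export
one_sided_mean_test <- function(values, threshold,
                                direction = c("greater", "less")) {
  direction <- rlang::arg_match(direction)
  if (length(values) < 2L) abort("need at least 2 values.")
  mdiff <- mean(values) - threshold
  if (sd(values) == 0) {
    p <- if (mdiff == 0) 0.5
         else if ((mdiff > 0) == (direction == "greater")) 0 else 1
    return(tibble(estimate = mean(values), threshold = threshold,
                  statistic = NA_real_, df = length(values) - 1,
                  p.value = p, direction = direction))
  }
  tt <- stats::t.test(values, mu = threshold, alternative = direction)
  tibble(estimate = unname(tt$estimate), threshold = threshold,
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p.value = tt$p.value, direction = direction)
}
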