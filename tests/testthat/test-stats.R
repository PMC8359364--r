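test_that("multivariate RM-ANOVA matches the anova.mlm Wilks oracle", {
  set.seed(51)
  tab <- gen_condition_table(5, means = c(10, 9.5, 8), subject_sd = 1,
                             residual_sd = 0.8, seed = 51)
  res <- rm_anova_wilks(tab)

  # independent oracle: intercept test on the difference variables via
  # R's multivariate linear model machinery
  D <- cbind(tab$cam - tab$no, tab$nav - tab$no)
  fit <- stats::lm(D ~ 1)
  oracle <- stats::anova(fit, test = "Wilks")
  expect_equal(res$wilks_lambda, oracle["(Intercept)", "Wilks"], tolerance = 1e-10)
  expect_equal(res$F, oracle["(Intercept)", "approx F"], tolerance = 1e-10)
  expect_equal(res$p, oracle["(Intercept)", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(c(res$df1, res$df2), c(2, 3)) # (k - 1, n - k + 1)
  expect_equal(res$partial_eta_sq, 1 - res$wilks_lambda)
})

test_that("RM-ANOVA agrees with the oracle over many random small tables", {
  set.seed(52)
  for (i in 1:100) {
    tab <- tibble::tibble(cam = rnorm(5), nav = rnorm(5), no = rnorm(5))
    res <- rm_anova_wilks(tab)
    D <- cbind(tab$cam - tab$no, tab$nav - tab$no)
    oracle <- stats::anova(stats::lm(D ~ 1), test = "Wilks")
    expect_equal(res$wilks_lambda, oracle["(Intercept)", "Wilks"],
                 tolerance = 1e-8)
    expect_equal(res$F, oracle["(Intercept)", "approx F"], tolerance = 1e-8)
  }
})

test_that("identical condition columns give no effect, and tiny n errors", {
  tab <- tibble::tibble(cam = c(1, 2, 3, 4), nav = c(1, 2, 3, 4),
                        no = c(1, 2, 3, 4))
  res <- rm_anova_wilks(tab)
  expect_equal(res$wilks_lambda, 1)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_equal(res$partial_eta_sq, 0)
  expect_error(rm_anova_wilks(tab[1:2, ]), "subjects")
  expect_error(rm_anova_wilks(tab, cols = c("cam", "xx", "no")), "not found")
})

test_that("type-I error of the RM-ANOVA sits at the nominal level", {
  set.seed(11)
  rej <- mean(replicate(400, {
    tab <- tibble::tibble(cam = rnorm(12, 10), nav = rnorm(12, 10),
                          no = rnorm(12, 10))
    rm_anova_wilks(tab)$p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("Bonferroni pairwise comparisons mirror in sign and cap at 1", {
  tab <- gen_condition_table(10, means = c(10, 10, 8.2), subject_sd = 1,
                             residual_sd = 0.5, seed = 61)
  pw <- bonferroni_pairwise(tab)
  expect_identical(nrow(pw), 6L)
  get <- function(x, y) pw[pw$x == x & pw$y == y, ]
  expect_equal(get("cam", "no")$mean_diff, -get("no", "cam")$mean_diff)
  expect_equal(get("cam", "no")$p_bonf, get("no", "cam")$p_bonf)
  expect_equal(get("cam", "no")$ci_low, -get("no", "cam")$ci_high)
  expect_true(all(pw$p_bonf <= 1))
  expect_true(all(pw$ci_low <= pw$mean_diff & pw$mean_diff <= pw$ci_high))

  # adjusted p is never below the raw paired-t p
  d <- tab$cam - tab$no
  raw <- stats::t.test(d)$p.value
  expect_gte(get("cam", "no")$p_bonf, raw)

  # identical columns: zero differences, p = 1
  same <- tibble::tibble(cam = 1:5, nav = 1:5, no = 1:5)
  pws <- bonferroni_pairwise(same)
  expect_true(all(pws$mean_diff == 0))
  expect_true(all(pws$p_bonf == 1))

  # zero-variance nonzero difference: certainty, CI collapses off zero
  sure <- tibble::tibble(cam = 1:5 + 2, nav = 1:5, no = 1:5)
  pwc <- bonferroni_pairwise(sure)
  row <- pwc[pwc$x == "cam" & pwc$y == "nav", ]
  expect_equal(row$p_bonf, 0)
  expect_true(row$ci_low > 0)
  expect_error(bonferroni_pairwise(same[1, ]), "2 subjects")
})

test_that("ordinal Krippendorff alpha equals brute-force pair enumeration", {
  # toy 3 raters x 6 items, 4-point scale, including a missing entry
  ratings <- tibble::tibble(
    item_id = 1:6,
    rater1 = c(1, 2, 3, 3, 2, 4),
    rater2 = c(1, 2, 3, 4, 2, 4),
    rater3 = c(NA, 2, 3, 3, 1, 4)
  )
  res <- krippendorff_alpha_ordinal(ratings, levels = 1:4)
  expect_equal(res$alpha, kripp_oracle(ratings, levels = 1:4), tolerance = 1e-12)

  set.seed(71)
  big <- tibble::tibble(
    item_id = 1:40,
    rater1 = sample(1:4, 40, TRUE),
    rater2 = sample(1:4, 40, TRUE),
    rater3 = sample(1:4, 40, TRUE)
  )
  expect_equal(krippendorff_alpha_ordinal(big)$alpha, kripp_oracle(big),
               tolerance = 1e-12)
})

test_that("alpha is 1 under perfect agreement and ~0 under chance", {
  perfect <- gen_ordinal_ratings(25, 4, 4, "perfect", seed = 2)
  expect_equal(krippendorff_alpha_ordinal(perfect)$alpha, 1.0)
  random <- gen_ordinal_ratings(500, 3, 4, "random", seed = 3)
  expect_lt(abs(krippendorff_alpha_ordinal(random)$alpha), 0.05)
})

test_that("alpha is invariant to order-preserving relabelling and rater order", {
  r <- gen_ordinal_ratings(60, 3, 4, "high", seed = 5)
  a0 <- krippendorff_alpha_ordinal(r, levels = 1:4)$alpha
  relab <- r
  for (cc in paste0("rater", 1:3)) relab[[cc]] <- c(10, 20, 30, 40)[r[[cc]]]
  expect_equal(krippendorff_alpha_ordinal(relab, levels = c(10, 20, 30, 40))$alpha,
               a0, tolerance = 1e-12)
  shuffled <- r[, c("item_id", "rater3", "rater1", "rater2")]
  expect_equal(krippendorff_alpha_ordinal(shuffled)$alpha, a0, tolerance = 1e-12)
})

test_that("alpha rejects unusable tables", {
  expect_error(krippendorff_alpha_ordinal(tibble::tibble(item_id = 1, rater1 = 1)),
               "raters")
  empty <- tibble::tibble(item_id = 1:3, rater1 = c(1, NA, NA),
                          rater2 = c(NA, 2, NA))
  expect_error(krippendorff_alpha_ordinal(empty), "pairable")
})

test_that("Bland-Altman bias and limits follow the plug-in formulas", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(glance(bland_altman(x, x)),
               tibble::tibble(bias = 0, sd_diff = 0, loa_low = 0, loa_high = 0,
                              n = 5L))
  ba2 <- bland_altman(x, x - 2)
  expect_equal(ba2$bias, 2)
  expect_equal(ba2$sd_diff, 0)

  set.seed(5)
  d <- rnorm(1e4, mean = 1, sd = 2)
  ba <- bland_altman(d, rep(0, 1e4))
  expect_equal(ba$bias, 1, tolerance = 0.05)
  expect_equal(ba$loa_high, 1 + 1.96 * 2, tolerance = 0.03)
  expect_equal(ba$loa_low, 1 - 1.96 * 2, tolerance = 0.05)
  expect_equal(ba$loa_high, ba$bias + 1.96 * ba$sd_diff)
  expect_error(bland_altman(1:3, 1:4), "length")
})

test_that("one-sided mean test behaves at the boundary and under certainty", {
  expect_equal(one_sided_mean_test(rep(0.5, 5), 0.5, "greater")$p.value, 0.5)
  set.seed(2)
  cs <- rnorm(32, mean = 0.93, sd = 0.09)
  expect_lt(one_sided_mean_test(cs, 0.5, "greater")$p.value, 0.01)
  pg <- one_sided_mean_test(cs, 0.9, "greater")$p.value
  pl <- one_sided_mean_test(cs, 0.9, "less")$p.value
  expect_equal(pg + pl, 1)
  expect_equal(one_sided_mean_test(rep(1, 4), 0.5, "greater")$p.value, 0)
  expect_equal(one_sided_mean_test(rep(0, 4), 0.5, "greater")$p.value, 1)
})

test_that("tidy and glance methods return one-row tibbles with the key fields", {
  tab <- gen_condition_table(8, seed = 9)
  res <- rm_anova_wilks(tab)
  td <- tidy(res)
  expect_identical(nrow(td), 1L)
  expect_true(all(c("wilks_lambda", "statistic", "p.value", "partial_eta_sq")
                  %in% names(td)))
  gl <- glance(res)
  expect_identical(gl$n, 8L)
  ka <- krippendorff_alpha_ordinal(gen_ordinal_ratings(10, 3, 4, "high", seed = 1))
  expect_identical(names(tidy(ka)), c("alpha", "metric", "n_raters", "n_items"))
})
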