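test_that("no-correlation test recovers exact linear structure", {
  x <- 1:10
  ut <- uncorrelated_test(x, 2 * x + 1)
  expect_equal(ut$r, 1)
  expect_lt(ut$p, 1e-12)
  expect_equal(uncorrelated_test(x, -x)$r, -1)
  expect_error(uncorrelated_test(rep(1, 5), 1:5), "zero variance")
  expect_error(uncorrelated_test(1:4, 1:5), "equal length")
  expect_error(uncorrelated_test(1:2, 2:3), "at least 3")
})

test_that("no-correlation p-value matches the t-transform closed form", {
  withr::with_seed(9, {
    x <- rnorm(25)
    y <- 0.5 * x + rnorm(25)
  })
  ut <- uncorrelated_test(x, y)
  tstat <- ut$r * sqrt((ut$n - 2) / (1 - ut$r^2))
  expect_equal(ut$p, 2 * stats::pt(-abs(tstat), ut$n - 2), tolerance = 1e-12)
})

test_that("gated regression recovers a noiseless published line exactly", {
  mf <- seq(15, 40, length.out = 20)
  # summary.lm warns on an exact fit; the warning is the expected behaviour here
  fit <- suppressWarnings(
    fit_task_group(mf, 2.364 * mf + 2.593, task = "hip_flexion", group = "A")
  )
  expect_true(fit$fitted)
  expect_equal(fit$slope, 2.364, tolerance = 1e-10)
  expect_equal(fit$intercept, 2.593, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("OLS self-consistency: r^2 identity, mean point, zero residual sum", {
  withr::with_seed(31, {
    mf <- rnorm(40, 26, 5.5)
    mm <- 2.364 * mf + 2.593 + rnorm(40, 0, 11.2)
  })
  fit <- fit_task_group(mf, mm)
  expect_equal(fit$r_squared, fit$pearson_r^2, tolerance = 1e-10)
  # fitted line passes through the mean point
  expect_equal(fit$slope * mean(mf) + fit$intercept, mean(mm), tolerance = 1e-10)
  residuals <- mm - (fit$slope * mf + fit$intercept)
  expect_lt(abs(sum(residuals)), 1e-8)
})

test_that("regression is withheld when the correlation gate does not reject", {
  withr::with_seed(77, {
    mf <- rnorm(44, 7.5, 1.8)
    mm <- rnorm(44, 18.5, 9.3) # independent of mf
  })
  fit <- fit_task_group(mf, mm, task = "knee_flexion", group = "C")
  expect_false(fit$fitted)
  expect_true(is.na(fit$slope) && is.na(fit$intercept))
  expect_error(fit_task_group(c(1, 2), c(2, 4)), "at least 3")
})

test_that("two-group interaction test equals the pooled slope-difference t test", {
  withr::with_seed(12, {
    d <- data.frame(
      group = rep(c("A", "B"), each = 30),
      mf = rnorm(60, 25, 5)
    )
    d$mm <- ifelse(d$group == "A", 2.4 * d$mf + 3, 1.8 * d$mf + 8) + rnorm(60, 0, 10)
  })
  rep_ <- ancova_for_task(d, alpha = 0.05, task = "check", exclude_unfitted = FALSE)
  # independent oracle: pooled-variance t test for equality of two slopes
  fa <- stats::lm(mm ~ mf, d[d$group == "A", ])
  fb <- stats::lm(mm ~ mf, d[d$group == "B", ])
  rss <- sum(stats::resid(fa)^2) + sum(stats::resid(fb)^2)
  s2 <- rss / (nrow(d) - 4)
  sxx_a <- sum((d$mf[d$group == "A"] - mean(d$mf[d$group == "A"]))^2)
  sxx_b <- sum((d$mf[d$group == "B"] - mean(d$mf[d$group == "B"]))^2)
  tstat <- (stats::coef(fa)[2] - stats::coef(fb)[2]) / sqrt(s2 * (1 / sxx_a + 1 / sxx_b))
  p_oracle <- 2 * stats::pt(-abs(tstat), nrow(d) - 4)
  expect_equal(rep_$p_interaction, unname(p_oracle), tolerance = 1e-8)
})

test_that("parallel groups with shifted intercepts are detected as different", {
  gen <- function(seed) {
    withr::with_seed(seed, {
      d <- data.frame(group = rep(c("A", "B", "C"), each = 40),
                      mf = rnorm(120, 26, 5.5))
      shift <- c(A = 0, B = 10, C = 20)[d$group]
      d$mm <- 2.364 * d$mf + 2.593 + shift + rnorm(120, 0, 11.2)
      d
    })
  }
  detected_ac <- parallel_kept <- logical(100)
  for (i in seq_len(100)) {
    rep_ <- ancova_for_task(gen(3000 + i), task = "hip_flexion")
    parallel_kept[i] <- rep_$parallel
    if (rep_$parallel) {
      ac <- rep_$pairwise[rep_$pairwise$contrast == "A - C", ]
      detected_ac[i] <- ac$p_adj < 0.05
    }
  }
  expect_gte(mean(parallel_kept), 0.85) # nominal 95% retention
  expect_gt(mean(detected_ac[parallel_kept]), 0.9) # 20 N·m apart, high power
})

test_that("non-parallel groups stop the ANCOVA after the interaction test", {
  withr::with_seed(55, {
    d <- data.frame(group = rep(c("A", "B", "C"), each = 40),
                    mf = rnorm(120, 8, 1.9))
    slope <- c(A = 12, B = 8, C = 4)[d$group]
    d$mm <- slope * d$mf + rnorm(120, 0, 3)
  })
  rep_ <- ancova_for_task(d, task = "knee_extension")
  expect_false(rep_$parallel)
  expect_null(rep_$p_common_slope)
  expect_null(rep_$pairwise)
})

test_that("groups without a significant correlation are excluded up front", {
  withr::with_seed(88, {
    d <- data.frame(group = rep(c("A", "B", "C"), each = 40),
                    mf = rnorm(120, 8, 2))
    d$mm <- ifelse(d$group == "C", rnorm(120, 20, 9),
                   4 * d$mf + rnorm(120, 0, 4))
  })
  rep_ <- ancova_for_task(d, task = "knee_flexion")
  expect_equal(rep_$groups_excluded, "C")
  expect_setequal(rep_$groups_included, c("A", "B"))
  # with only one eligible group, the ANCOVA must refuse
  expect_error(ancova_for_task(d[d$group %in% c("B", "C"), ], task = "knee_flexion"),
               "fewer than 2 eligible groups")
})

test_that("summary ratios use the ratio-of-means convention", {
  moments <- tibble::tibble(
    task = rep("hip_flexion", 4), group = "A",
    mf_nm = c(20, 30, 25, 29), mm_nm = c(50, 80, 60, 70)
  )
  s <- summarize_moments(moments)
  expect_equal(s$ratio_pct, 100 * mean(moments$mf_nm) / mean(moments$mm_nm))
  expect_false(isTRUE(all.equal(s$ratio_pct, mean(100 * moments$mf_nm / moments$mm_nm))))
})

test_that("full analysis runs end to end on simulated cohorts", {
  cohorts <- lapply(builtin_group_specs(), simulate_cohort, seed = 2024)
  res <- run_full_analysis(cohorts)
  expect_s3_class(res, "mmt_analysis")
  expect_equal(nrow(res$summary), 12)
  expect_equal(nrow(res$regressions), 12)
  expect_named(res$ancova, mmt_tasks())
  expect_equal(res$config$n_subjects, 130)
  # every ANCOVA that ran used only fitted groups
  for (task in mmt_tasks()) {
    a <- res$ancova[[task]]
    if (is.null(a$skipped) || !isTRUE(a$skipped)) {
      fitted_groups <- res$regressions$group[res$regressions$task == task &
                                              res$regressions$fitted]
      expect_true(all(a$groups_included %in% fitted_groups))
    }
  }
})

test_that("a group too small to regress is refused with a clear error", {
  s <- make_subject(id = "only")
  expect_error(run_full_analysis(s), "n >= 3")
})
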