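#' Published group-level reference statistics
#'
#' The normative study behind this package reports, for three age groups
#' (A: 20s-30s, n = 40; B: 40s-50s, n = 46; C: 60s-70s, n = 44) and four
#' lower-limb tasks, the group means and SDs of the theoretical Grade 3
#' moment \eqn{M_f} and the measured maximum moment \eqn{M_m}, the
#' mean-based ratio \eqn{M_f/M_m} in percent, and (where \eqn{M_f} and
#' \eqn{M_m} were correlated) the fitted regression line
#' \eqn{M_m = a M_f + b} with its coefficient of determination. Group C
#' knee flexion showed no correlation (p = 0.52) and has no regression
#' line; its `slope`, `intercept` and `r_squared` are `NA` and
#' `correlation_present` is `FALSE`.
#'
#' @return A tibble with one row per task x group: `task`, `group`,
#'   `mf_mean`, `mf_sd`, `mm_mean`, `mm_sd`, `ratio_pct`, `slope`,
#'   `intercept`, `r_squared`, `correlation_present`.
#' @export
#' @examples
#' reference_statistics()
reference_statistics <- function() {
  out <- tibble::tribble(
    ~task, ~group, ~mf_mean, ~mf_sd, ~mm_mean, ~mm_sd, ~ratio_pct, ~slope, ~intercept, ~r_squared,
    "hip_flexion",    "A", 25.9, 5.5, 63.7, 17.2, 40.7,  2.364,   2.593, 0.574,
    "hip_flexion",    "B", 26.9, 5.3, 61.1, 17.0, 44.0,  2.111,   4.185, 0.432,
    "hip_flexion",    "C", 25.2, 5.6, 52.7, 14.8, 47.8,  1.855,   5.988, 0.489,
    "hip_extension",  "A", 25.9, 5.5, 59.2, 16.5, 43.8,  2.072,   5.673, 0.480,
    "hip_extension",  "B", 26.9, 5.3, 52.9, 16.4, 50.9,  1.762,   5.470, 0.321,
    "hip_extension",  "C", 25.2, 5.6, 47.2, 12.4, 53.4,  1.326,  13.816, 0.352,
    "knee_flexion",   "A",  8.3, 1.9, 32.8, 18.1, 25.3,  6.482, -20.694, 0.452,
    "knee_flexion",   "B",  8.0, 2.2, 26.2, 17.5, 22.1,  3.939,  -5.254, 0.236,
    "knee_flexion",   "C",  7.5, 1.8, 18.5,  9.3, 40.5,     NA,      NA,    NA,
    "knee_extension", "A",  8.3, 1.9, 59.9, 29.0, 13.9, 11.758, -37.261, 0.575,
    "knee_extension", "B",  8.0, 2.2, 46.0, 27.2, 17.4,  8.088, -18.703, 0.412,
    "knee_extension", "C",  7.5, 1.8, 40.7, 19.7, 18.4,  4.046,  10.465, 0.141
  )
  out$correlation_present <- !is.na(out$slope)
  out
}

#' Published cohort anthropometrics
#'
#' Group sizes by sex and body-mass distributions of the normative cohort
#' (130 healthy Japanese adults).
#'
#' @return A tibble with one row per group: `group`, `n_male`, `n_female`,
#'   `age_mean`, `age_min`, `age_max`, `mass_mean`, `mass_sd` (kg).
#' @export
reference_anthropometrics <- function() {
  tibble::tribble(
    ~group, ~n_male, ~n_female, ~age_mean, ~age_min, ~age_max, ~mass_mean, ~mass_sd,
    "A", 22L, 18L, 28.3, 20, 39, 60.8,  9.2,
    "B", 21L, 25L, 49.8, 40, 59, 62.3, 10.2,
    "C", 22L, 22L, 69.6, 61, 79, 58.5,  9.7
  )
}

#' Built-in simulation specifications for the three age groups
#'
#' Bundles the published group statistics into one simulation spec per age
#' group, ready for [simulate_cohort()]. Each spec carries the sex counts
#' and body-mass distribution, the per-task \eqn{M_f}/\eqn{M_m} moments,
#' regression lines and target \eqn{R^2}, plus the artifact parameters of
#' the generator: the hip-knee \eqn{M_f} correlation (`mf_correlation`,
#' default 0.6, a shared body-size factor), the relative trial jitter
#' (`trial_jitter`, default 0.02) and the physical truncation bounds.
#'
#' @param mf_correlation Correlation between a subject's hip and knee
#'   \eqn{M_f} draws.
#' @param trial_jitter Half-range of the symmetric relative perturbation
#'   applied to the two emitted force trials (they always average back to
#'   the generating force exactly).
#' @return A named list of three `group_spec` objects (`A`, `B`, `C`).
#' @export
#' @examples
#' specs <- builtin_group_specs()
#' specs$A$n_male + specs$A$n_female # 40
builtin_group_specs <- function(mf_correlation = 0.6, trial_jitter = 0.02) {
  stats <- reference_statistics()
  anthro <- reference_anthropometrics()
  specs <- lapply(c(A = "A", B = "B", C = "C"), function(g) {
    a <- anthro[anthro$group == g, ]
    spec <- list(
      group = g,
      n_male = a$n_male,
      n_female = a$n_female,
      mass_mean = a$mass_mean,
      mass_sd = a$mass_sd,
      tasks = stats[stats$group == g,
                    c("task", "mf_mean", "mf_sd", "mm_mean", "mm_sd",
                      "slope", "intercept", "r_squared", "correlation_present")],
      mf_correlation = mf_correlation,
      trial_jitter = trial_jitter,
      mf_min = 3,        # N·m, positivity truncation for the M_f draws
      length_bounds = c(0.2, 0.7) # m, plausible segment lengths
    )
    class(spec) <- "group_spec"
    spec
  })
  specs
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf("Simulation spec, group %s: %d male + %d female, mass %.1f (%.1f) kg\n",
              x$group, x$n_male, x$n_female, x$mass_mean, x$mass_sd))
  print(x$tasks)
  invisible(x)
}
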