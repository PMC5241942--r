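#' Residual SD that yields a target population R-squared
#'
#' For the generating model \eqn{M_m = a M_f + b + \epsilon} with
#' \eqn{\epsilon \sim N(0, \sigma_\epsilon^2)} independent of \eqn{M_f},
#' the population coefficient of determination is
#' \eqn{R^2 = a^2\sigma_{M_f}^2 / (a^2\sigma_{M_f}^2 + \sigma_\epsilon^2)}.
#' Solving for the residual SD gives
#' \deqn{\sigma_\epsilon = |a|\,\sigma_{M_f}\sqrt{(1 - R^2)/R^2}.}
#' This calibrates the simulator's noise so a generated cohort reproduces a
#' published \eqn{R^2}, and implies a total \eqn{M_m} SD of
#' \eqn{|a|\sigma_{M_f}/\sqrt{R^2}} — an internal-consistency check against
#' the published \eqn{M_m} dispersion.
#'
#' @param slope Generating slope `a` (nonzero).
#' @param mf_sd Population SD of the covariate \eqn{M_f} in N·m (> 0).
#' @param r2 Target population R-squared, in (0, 1).
#' @return Residual SD in N·m.
#' @export
#' @examples
#' noise_sd_for_r2(2.364, 5.5, 0.574) # ~11.2 N·m
noise_sd_for_r2 <- function(slope, mf_sd, r2) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) || slope == 0) {
    stop("`slope` must be a single nonzero number", call. = FALSE)
  }
  check_positive(mf_sd, "mf_sd (N·m)")
  if (!is.numeric(r2) || length(r2) != 1L || !is.finite(r2) || r2 <= 0 || r2 >= 1) {
    stop("`r2` must lie strictly between 0 and 1, got ", r2, call. = FALSE)
  }
  abs(slope) * mf_sd * sqrt((1 - r2) / r2)
}

#' Simulate a raw-measurement cohort for one age group
#'
#' Generates a synthetic cohort whose *recomputed* moment statistics match a
#' group spec (see [builtin_group_specs()]). The generator works backwards
#' from the published moment distributions, because those are what the study
#' reports, whereas segment-length distributions are not:
#'
#' 1. Sex is assigned by the spec counts; body mass is drawn from the spec's
#'    normal distribution.
#' 2. The subject's hip and knee \eqn{M_f} are drawn from a bivariate normal
#'    with the spec means/SDs and correlation `mf_correlation`, truncated
#'    below at `mf_min`.
#' 3. Thigh and lower-leg lengths are back-solved from the \eqn{M_f} values
#'    through the gravitational moment formulas with the subject's sex
#'    constants; if either length falls outside `length_bounds` the whole
#'    subject is redrawn (bounded retries).
#' 4. Per task, a latent \eqn{M_m} is drawn from the spec regression line
#'    plus Gaussian noise with SD from [noise_sd_for_r2()]; for tasks with
#'    `correlation_present = FALSE` the latent \eqn{M_m} is drawn from an
#'    independent normal with the spec's \eqn{M_m} mean/SD.
#' 5. The sensor force is back-solved by inverting the maximum-moment
#'    formulas with distal-1/3 lever arms and truncated at zero, and two
#'    trial forces are emitted with a symmetric relative jitter so they
#'    average back to the generating force exactly.
#'
#' The emitted table contains raw measurements only; moments must be
#' recomputed downstream with [compute_moments()]. Regenerating with the
#' same seed reproduces the cohort exactly.
#'
#' @param spec A `group_spec`, e.g. one element of [builtin_group_specs()].
#' @param seed Integer seed (required; there is no default randomness).
#' @param max_retries Redraw budget per subject for the length bounds.
#' @return A list of class `simulated_cohort` with elements `subjects`
#'   (a subjects tibble accepted by [compute_moments()]) and `provenance`
#'   (seed, group, per-task noise SDs, truncation counters).
#' @export
#' @examples
#' cohort <- simulate_cohort(builtin_group_specs()$A, seed = 1)
#' nrow(cohort$subjects) # 40
simulate_cohort <- function(spec, seed, max_retries = 100L) {
  stopifnot(inherits(spec, "group_spec"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("an explicit integer `seed` is required", call. = FALSE)
  }
  tasks <- spec$tasks
  noise_sd <- vapply(seq_len(nrow(tasks)), function(j) {
    if (tasks$correlation_present[j]) {
      noise_sd_for_r2(tasks$slope[j], tasks$mf_sd[j], tasks$r_squared[j])
    } else {
      NA_real_
    }
  }, numeric(1))
  names(noise_sd) <- tasks$task

  n <- spec$n_male + spec$n_female
  sexes <- rep(c("male", "female"), c(spec$n_male, spec$n_female))
  # one hip and one knee M_f per subject (flexion/extension share them)
  hip <- tasks[tasks$task == "hip_flexion", ]
  knee <- tasks[tasks$task == "knee_flexion", ]
  mf_mu <- c(hip$mf_mean, knee$mf_mean)
  mf_sigma <- diag(c(hip$mf_sd, knee$mf_sd)^2)
  mf_sigma[1, 2] <- mf_sigma[2, 1] <-
    spec$mf_correlation * hip$mf_sd * knee$mf_sd

  truncated_force <- 0L
  redraws <- 0L

  subjects <- withr::with_seed(as.integer(seed), {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      sex <- sexes[i]
      const <- constants_for_sex(sex)
      ok <- FALSE
      L1 <- L2 <- NA_real_
      for (attempt in seq_len(max_retries)) {
        mass <- stats::rnorm(1, spec$mass_mean, spec$mass_sd)
        mf <- as.numeric(MASS::mvrnorm(1, mf_mu, mf_sigma))
        if (mass <= 0 || any(mf < spec$mf_min)) next
        L1 <- mf[1] / (mass * const$g * (const$k1 * const$K1 + const$k2))
        L2 <- mf[2] / (mass * const$k2 * const$g * const$K2)
        if (L1 >= spec$length_bounds[1] && L1 <= spec$length_bounds[2] &&
            L2 >= spec$length_bounds[1] && L2 <= spec$length_bounds[2]) {
          ok <- TRUE
          break
        }
        redraws <- redraws + 1L
      }
      if (!ok) {
        stop("could not draw a physically plausible subject after ",
             max_retries, " attempts (group ", spec$group, ", subject ", i,
             "; last lengths L1 = ", round(L1, 3), ", L2 = ", round(L2, 3), " m)",
             call. = FALSE)
      }
      l1 <- default_lever_arm(L1)
      l2 <- default_lever_arm(L2)
      row <- list(
        id = sprintf("%s%03d", spec$group, i), sex = sex,
        age_group = spec$group, mass_kg = mass,
        thigh_m = L1, lowerleg_m = L2, lever_hip_m = l1, lever_knee_m = l2
      )
      for (j in seq_len(nrow(tasks))) {
        task <- tasks$task[j]
        is_hip <- grepl("^hip", task)
        mf_task <- if (is_hip) mf[1] else mf[2]
        mm <- if (tasks$correlation_present[j]) {
          tasks$slope[j] * mf_task + tasks$intercept[j] +
            stats::rnorm(1, 0, noise_sd[j])
        } else {
          stats::rnorm(1, tasks$mm_mean[j], tasks$mm_sd[j])
        }
        f <- if (is_hip) (mm - mf_task) / l1 else mm / l2
        if (f < 0) {
          f <- 0
          truncated_force <- truncated_force + 1L
        }
        d <- stats::runif(1, 0, spec$trial_jitter)
        row[[paste0(task, "_trial1_N")]] <- f * (1 + d)
        row[[paste0(task, "_trial2_N")]] <- f * (1 - d)
      }
      rows[[i]] <- tibble::as_tibble(row)
    }
    dplyr::bind_rows(rows)
  })

  out <- list(
    subjects = subjects,
    provenance = list(
      seed = as.integer(seed),
      group = spec$group,
      n = n,
      noise_sd = noise_sd,
      mf_correlation = spec$mf_correlation,
      trial_jitter = spec$trial_jitter,
      redraws = redraws,
      truncated_forces = truncated_force,
      package_version = as.character(utils::packageVersion("mmtstrength"))
    )
  )
  class(out) <- "simulated_cohort"
  out
}

#' @export
print.simulated_cohort <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "Simulated cohort: group %s, n = %d (seed %d, %d force truncations, %d redraws)\n",
    p$group, p$n, p$seed, p$truncated_forces, p$redraws
  ))
  invisible(x)
}
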