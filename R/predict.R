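#' Built-in prediction model from the published regression table
#'
#' The eleven published age-group regression lines \eqn{M_m = a M_f + b}
#' as a prediction model. Knee flexion in group C has no line (no
#' \eqn{M_f}-\eqn{M_m} correlation in that group) and is marked unavailable:
#' predicting from it is an error, never a silent fallback to another group.
#'
#' @return A tibble of class `prediction_model` with columns `task`,
#'   `group`, `slope`, `intercept`, `available`, and a `provenance`
#'   attribute.
#' @export
#' @examples
#' m <- builtin_prediction_model()
#' m[m$task == "hip_flexion" & m$group == "A", ]
builtin_prediction_model <- function() {
  stats <- reference_statistics()
  out <- tibble::tibble(
    task = stats$task,
    group = stats$group,
    slope = stats$slope,
    intercept = stats$intercept,
    available = stats$correlation_present
  )
  attr(out, "provenance") <- "builtin_reference_table"
  class(out) <- c("prediction_model", class(out))
  out
}

#' Prediction model from freshly fitted regressions
#'
#' Builds a [predict_mm()]-compatible model from the `regressions` table of
#' a [run_full_analysis()] result; task x group cells whose no-correlation
#' gate did not reject are marked unavailable.
#'
#' @param regressions A regressions tibble as returned in
#'   `run_full_analysis()$regressions` (or by [fit_task_group()] rows).
#' @param run_id Provenance label stored on the model.
#' @return A `prediction_model` tibble.
#' @export
prediction_model_from_fit <- function(regressions, run_id = "fitted") {
  needed <- c("task", "group", "slope", "intercept", "fitted")
  stopifnot(all(needed %in% names(regressions)))
  out <- tibble::tibble(
    task = as.character(regressions$task),
    group = regressions$group,
    slope = regressions$slope,
    intercept = regressions$intercept,
    available = regressions$fitted
  )
  attr(out, "provenance") <- paste0("fitted:", run_id)
  class(out) <- c("prediction_model", class(out))
  out
}

#' Predict the maximum strength moment from M_f
#'
#' Evaluates the model line \eqn{M_m = a M_f + b} for one task and age
#' group.
#'
#' @param model A `prediction_model`.
#' @param task One of [mmt_tasks()].
#' @param group Age group `"A"`, `"B"` or `"C"`.
#' @param mf Theoretical Grade 3 moment in N·m (> 0). Vectorised.
#' @return Predicted maximum moment(s) in N·m.
#' @export
#' @examples
#' predict_mm(builtin_prediction_model(), "hip_flexion", "A", 25.5) # ~62.9
predict_mm <- function(model, task, group, mf) {
  stopifnot(inherits(model, "prediction_model"))
  if (!task %in% mmt_tasks()) {
    stop("unknown task: ", task, call. = FALSE)
  }
  row <- model[model$task == task & model$group == group, ]
  if (nrow(row) != 1L) {
    stop("model has no entry for task ", task, ", group ", group, call. = FALSE)
  }
  if (!row$available) {
    stop("no regression line exists for task ", task, " in group ", group,
         " (no significant M_f-M_m correlation); prediction is not possible",
         call. = FALSE)
  }
  check_positive(mf, "mf (N·m)")
  row$slope * mf + row$intercept
}

#' Clinical prediction from anthropometrics
#'
#' The full clinical path: from body mass and segment lengths, compute the
#' hip and knee \eqn{M_f} with the sex-specific constants, then substitute
#' into the age-group regression lines for every available task. Tasks
#' without a line in the model (knee flexion for the eldest group in the
#' built-in model) are reported as unavailable rather than dropped.
#'
#' By default the \eqn{M_f} values are rounded to `digits` decimals before
#' substitution — the clinical convention in which the practitioner reads
#' the reported one-decimal \eqn{M_f} off the moment calculation and feeds
#' it into the formula. Set `round_mf = FALSE` to substitute the
#' full-precision \eqn{M_f} instead.
#'
#' Predictions for groups B and C carry an attribute `note` warning that the
#' published coefficients of determination are low for those groups, so the
#' prediction is reliable for young adults only.
#'
#' @param model A `prediction_model`.
#' @param sex `"male"` or `"female"`.
#' @param group Age group `"A"`, `"B"` or `"C"` (see [age_to_group()]).
#' @param mass_kg Body mass in kg (> 0).
#' @param thigh_m Thigh length in m (> 0).
#' @param lowerleg_m Lower-leg length in m (> 0).
#' @param round_mf Round \eqn{M_f} to `digits` decimals before substitution.
#' @param digits Reporting precision in decimals (default 1, N·m).
#' @return A tibble with one row per task: `task`, `group`, `mf_nm`
#'   (full precision), `mf_display`, `available`, `mm_pred`, `mm_display`.
#' @export
#' @examples
#' predict_from_anthropometrics(builtin_prediction_model(),
#'                              "male", "A", 65.0, 0.35, 0.40)
predict_from_anthropometrics <- function(model, sex, group, mass_kg, thigh_m,
                                         lowerleg_m, round_mf = TRUE,
                                         digits = 1L) {
  stopifnot(inherits(model, "prediction_model"))
  if (!group %in% c("A", "B", "C")) {
    stop("unknown age group: ", group, call. = FALSE)
  }
  const <- constants_for_sex(sex)
  mfh <- mf_hip(mass_kg, thigh_m, const)
  mfk <- mf_knee(mass_kg, lowerleg_m, const)

  out <- purrr::map_dfr(mmt_tasks(), function(task) {
    mf_full <- if (grepl("^hip", task)) mfh else mfk
    mf_used <- if (round_mf) round(mf_full, digits) else mf_full
    row <- model[model$task == task & model$group == group, ]
    available <- nrow(row) == 1L && isTRUE(row$available)
    pred <- if (available) predict_mm(model, task, group, mf_used) else NA_real_
    tibble::tibble(
      task = task, group = group,
      mf_nm = mf_full, mf_display = round(mf_full, digits),
      available = available,
      mm_pred = pred, mm_display = round(pred, digits)
    )
  })
  if (group %in% c("B", "C")) {
    attr(out, "note") <- paste0(
      "group ", group, " coefficients of determination are low; ",
      "predictions are reliable for young adults (group A) only"
    )
  }
  out
}
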