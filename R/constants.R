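#' Experimental tasks covered by the moment model
#'
#' The four lower-limb isometric tasks: hip flexion (seated), hip extension
#' (prone), knee flexion and knee extension (both seated, 90 degrees of hip
#' and knee flexion).
#'
#' @return Character vector of the four task identifiers, in canonical order.
#' @export
#' @examples
#' mmt_tasks()
mmt_tasks <- function() {
  c("hip_flexion", "hip_extension", "knee_flexion", "knee_extension")
}

#' Sex-specific anthropometric segment parameters
#'
#' Returns the segment-parameter set used by the gravitational moment model:
#' `k1`, the thigh mass as a fraction of body mass; `K1`, the thigh
#' centre-of-gravity position as a fraction of thigh length from the hip;
#' `k2`, the combined lower-leg-plus-foot mass fraction; `K2`, the combined
#' lower-leg-plus-foot centre-of-gravity distance ratio from the knee; and
#' `g`, the gravitational acceleration (9.8 m/s^2).
#'
#' The mass fractions are sex-specific (men: k1 = 0.1, k2 = 0.0725;
#' women: k1 = 0.1115, k2 = 0.0685); the centre-of-gravity ratios
#' (K1 = 0.42, K2 = 0.51) are shared. There is no default sex: the
#' constants differ between sexes and an unknown value is an error, never
#' a silent fallback.
#'
#' @param sex `"male"` or `"female"`.
#' @return A list of class `anthropometric_constants` with fields
#'   `sex`, `k1`, `K1`, `k2`, `K2`, `g`.
#' @export
#' @examples
#' constants_for_sex("male")$k1 # 0.1
#' constants_for_sex("female")$k2 # 0.0685
constants_for_sex <- function(sex) {
  if (!is.character(sex) || length(sex) != 1L || !sex %in% c("male", "female")) {
    stop("`sex` must be \"male\" or \"female\", got: ",
         paste(deparse(sex), collapse = ""), call. = FALSE)
  }
  out <- list(
    sex = sex,
    k1 = if (sex == "male") 0.1 else 0.1115,
    K1 = 0.42,
    k2 = if (sex == "male") 0.0725 else 0.0685,
    K2 = 0.51,
    g  = 9.8
  )
  class(out) <- "anthropometric_constants"
  out
}

#' @export
print.anthropometric_constants <- function(x, ...) {
  cat(sprintf(
    "Anthropometric constants (%s): k1 = %.4f, K1 = %.2f, k2 = %.4f, K2 = %.2f, g = %.1f m/s^2\n",
    x$sex, x$k1, x$K1, x$k2, x$K2, x$g
  ))
  invisible(x)
}

#' Map an age in years to its analysis age group
#'
#' Group A covers ages 20-39, group B 40-59 and group C 60-79. Ages outside
#' 20-79 are outside the validity domain of the built-in regression
#' coefficients and are rejected.
#'
#' @param age Age in whole years.
#' @return `"A"`, `"B"` or `"C"`.
#' @export
#' @examples
#' age_to_group(28) # "A"
#' age_to_group(69) # "C"
age_to_group <- function(age) {
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age)) {
    stop("`age` must be a single finite number", call. = FALSE)
  }
  if (age < 20 || age > 79) {
    stop("age ", age, " is outside the 20-79 year validity domain of the model",
         call. = FALSE)
  }
  if (age < 40) "A" else if (age < 60) "B" else "C"
}
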