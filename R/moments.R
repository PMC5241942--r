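#' Theoretical Grade 3 hip moment
#'
#' Gravitational moment about the hip of the flexed thigh plus the hanging
#' lower leg and foot, i.e. the static muscular moment a subject must produce
#' to hold the limb against gravity alone (MMT Grade 3):
#' \deqn{M_f = m \, g \, L_1 (k_1 K_1 + k_2)}
#' The thigh contributes its weight `k1 * m * g` acting at `K1 * L1`; the
#' lower leg and foot hang vertically from the knee, so their weight
#' `k2 * m * g` acts at the full thigh length `L1`.
#'
#' @param m Body mass in kg (> 0). Vectorised.
#' @param L1 Thigh length in m, greater trochanter to knee-joint space (> 0).
#' @param constants An `anthropometric_constants` object from
#'   [constants_for_sex()].
#' @return Moment in N·m.
#' @export
#' @examples
#' mf_hip(65, 0.35, constants_for_sex("male")) # ~25.53 N·m
mf_hip <- function(m, L1, constants) {
  stopifnot(inherits(constants, "anthropometric_constants"))
  check_positive(m, "m (body mass, kg)")
  check_positive(L1, "L1 (thigh length, m)")
  m * constants$g * L1 * (constants$k1 * constants$K1 + constants$k2)
}

#' Theoretical Grade 3 knee moment
#'
#' Gravitational moment about the knee of the horizontally extended lower leg
#' and foot:
#' \deqn{M_f = m \, k_2 \, g \, K_2 \, L_2}
#'
#' @param m Body mass in kg (> 0). Vectorised.
#' @param L2 Lower-leg length in m, knee-joint space to lateral malleolus (> 0).
#' @inheritParams mf_hip
#' @return Moment in N·m.
#' @export
#' @examples
#' mf_knee(65, 0.40, constants_for_sex("male")) # ~9.42 N·m
mf_knee <- function(m, L2, constants) {
  stopifnot(inherits(constants, "anthropometric_constants"))
  check_positive(m, "m (body mass, kg)")
  check_positive(L2, "L2 (lower-leg length, m)")
  m * constants$k2 * constants$g * constants$K2 * L2
}

#' Maximum strength moment for hip tasks
#'
#' For the hip tasks the dynamometer resists the limb in the test position,
#' so the muscle works against gravity *and* the sensor; the maximum moment is
#' the gravitational term plus the sensor force times its lever arm:
#' \deqn{M_m = M_f + F \, \ell_1}
#'
#' @param mf Theoretical Grade 3 hip moment in N·m (>= 0).
#' @param F Resisting force in N (>= 0; the sensor reports a magnitude).
#' @param l1 Lever arm in m, greater trochanter to sensor site (> 0).
#' @return Moment in N·m, always >= `mf`.
#' @export
mm_hip <- function(mf, F, l1) {
  check_nonnegative(mf, "mf (N·m)")
  check_nonnegative(F, "F (force, N)")
  check_positive(l1, "l1 (lever arm, m)")
  mf + F * l1
}

#' Maximum strength moment for knee tasks
#'
#' For the knee tasks (seated, lower leg vertical at rest) the gravitational
#' moment at the measurement position is taken as zero and the maximum moment
#' is the sensor force times its lever arm:
#' \deqn{M_m = F \, \ell_2}
#'
#' @param F Resisting force in N (>= 0).
#' @param l2 Lever arm in m, knee-joint space to sensor site (> 0).
#' @return Moment in N·m; zero exactly when `F` is zero.
#' @export
mm_knee <- function(F, l2) {
  check_nonnegative(F, "F (force, N)")
  check_positive(l2, "l2 (lever arm, m)")
  F * l2
}

#' Default lever arm for the distal-1/3 sensor convention
#'
#' The sensor pad is placed at the distal one-third of the segment, i.e. at
#' two thirds of the segment length from the proximal joint landmark.
#'
#' @param segment_length Segment length in m (> 0). Vectorised.
#' @return Lever arm in m, `2/3 * segment_length`.
#' @export
#' @examples
#' default_lever_arm(0.35) # 0.2333...
default_lever_arm <- function(segment_length) {
  check_positive(segment_length, "segment_length (m)")
  2 / 3 * segment_length
}

#' Compute per-task moments for a table of subjects
#'
#' For every subject and every task, averages the two force trials, then
#' applies the hip or knee moment formulas. Hip flexion and hip extension
#' share one hip \eqn{M_f}; knee flexion and knee extension share one knee
#' \eqn{M_f}. Lever arms come from the subject columns `lever_hip_m` /
#' `lever_knee_m` (defaulting, at read time, to the distal-1/3 convention).
#'
#' @param subjects A subjects tibble as produced by [read_subjects()] or
#'   [simulate_cohort()]; see [validate_subjects()] for the required columns.
#' @return A tibble with one row per subject x task: `subject_id`, `task`,
#'   `force_n` (mean of the two trials), `mf_nm`, `mm_nm` at full precision.
#' @export
#' @examples
#' s <- tibble::tibble(
#'   id = "s1", sex = "male", age_group = "A", mass_kg = 65,
#'   thigh_m = 0.35, lowerleg_m = 0.40,
#'   lever_hip_m = default_lever_arm(0.35),
#'   lever_knee_m = default_lever_arm(0.40),
#'   hip_flexion_trial1_N = 158, hip_flexion_trial2_N = 162,
#'   hip_extension_trial1_N = 140, hip_extension_trial2_N = 140,
#'   knee_flexion_trial1_N = 90, knee_flexion_trial2_N = 90,
#'   knee_extension_trial1_N = 240, knee_extension_trial2_N = 240
#' )
#' compute_moments(s)
compute_moments <- function(subjects) {
  validate_subjects(subjects)
  rows <- purrr::map(seq_len(nrow(subjects)), function(i) {
    subj <- subjects[i, ]
    const <- constants_for_sex(subj$sex)
    mfh <- mf_hip(subj$mass_kg, subj$thigh_m, const)
    mfk <- mf_knee(subj$mass_kg, subj$lowerleg_m, const)
    purrr::map(mmt_tasks(), function(task) {
      t1 <- subj[[paste0(task, "_trial1_N")]]
      t2 <- subj[[paste0(task, "_trial2_N")]]
      if (is.na(t1) || is.na(t2)) {
        stop("subject ", subj$id, ", task ", task,
             ": both force trials are required", call. = FALSE)
      }
      f <- (t1 + t2) / 2
      hip <- grepl("^hip", task)
      tibble::tibble(
        subject_id = subj$id,
        task = task,
        force_n = f,
        mf_nm = if (hip) mfh else mfk,
        mm_nm = if (hip) mm_hip(mfh, f, subj$lever_hip_m) else mm_knee(f, subj$lever_knee_m)
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  out$task <- factor(out$task, levels = mmt_tasks())
  out
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(what, " must be finite and strictly positive", call. = FALSE)
  }
  invisible(x)
}

check_nonnegative <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(what, " must be finite and non-negative", call. = FALSE)
  }
  invisible(x)
}

#' Validate a subjects table
#'
#' Checks the column contract and the physical invariants: positive mass and
#' segment lengths, lever arms in `(0, segment length]`, non-negative forces,
#' known sex and age-group codes. All violations are collected and reported
#' together with their row numbers.
#'
#' @param subjects A data frame of subjects.
#' @return The (unchanged) subjects tibble, invisibly.
#' @export
validate_subjects <- function(subjects) {
  force_cols <- as.vector(outer(mmt_tasks(), c("_trial1_N", "_trial2_N"), paste0))
  needed <- c("id", "sex", "age_group", "mass_kg", "thigh_m", "lowerleg_m",
              "lever_hip_m", "lever_knee_m", force_cols)
  missing_cols <- setdiff(needed, names(subjects))
  if (length(missing_cols) > 0) {
    stop("subjects table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx) > 0) {
      problems <<- c(problems, paste0("row ", idx, ": ", msg))
    }
  }
  bad(!subjects$sex %in% c("male", "female"), "sex must be \"male\" or \"female\"")
  bad(!subjects$age_group %in% c("A", "B", "C"), "age_group must be A, B or C")
  bad(!is.finite(subjects$mass_kg) | subjects$mass_kg <= 0, "mass_kg must be > 0")
  bad(!is.finite(subjects$thigh_m) | subjects$thigh_m <= 0, "thigh_m must be > 0")
  bad(!is.finite(subjects$lowerleg_m) | subjects$lowerleg_m <= 0, "lowerleg_m must be > 0")
  bad(!is.finite(subjects$lever_hip_m) | subjects$lever_hip_m <= 0 |
        subjects$lever_hip_m > subjects$thigh_m,
      "lever_hip_m must be in (0, thigh_m]")
  bad(!is.finite(subjects$lever_knee_m) | subjects$lever_knee_m <= 0 |
        subjects$lever_knee_m > subjects$lowerleg_m,
      "lever_knee_m must be in (0, lowerleg_m]")
  # trial completeness (NA) is diagnosed per subject and task at moment
  # computation, where the offender can be named; here only sign/finiteness
  for (col in force_cols) {
    bad(!is.na(subjects[[col]]) & (is.nan(subjects[[col]]) |
          is.infinite(subjects[[col]]) | subjects[[col]] < 0),
        paste0(col, " must be >= 0"))
  }
  if (length(problems) > 0) {
    stop("invalid subjects table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(tibble::as_tibble(subjects))
}
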