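#' Read a subjects table from CSV
#'
#' The dialect is fixed: comma-separated, "." decimal point, UTF-8, header
#' required. Expected columns: `id`, `sex`, `age_group`, `mass_kg`,
#' `thigh_m`, `lowerleg_m`, optional `lever_hip_m` / `lever_knee_m`, and
#' `<task>_trial1_N` / `<task>_trial2_N` for the four tasks. Missing lever
#' columns are filled with the distal-1/3 convention (2/3 of the segment
#' length) and a message is emitted. All row-level invariant violations are
#' collected and reported with their row numbers.
#'
#' @param path Path to a CSV file.
#' @param quiet Suppress the lever-arm default message.
#' @return A validated subjects tibble.
#' @export
read_subjects <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    stop("subjects file not found: ", path, call. = FALSE)
  }
  subjects <- readr::read_csv(path, show_col_types = FALSE,
                              locale = readr::locale(decimal_mark = "."))
  force_cols <- as.vector(outer(mmt_tasks(), c("_trial1_N", "_trial2_N"), paste0))
  needed <- c("id", "sex", "age_group", "mass_kg", "thigh_m", "lowerleg_m",
              force_cols)
  missing_cols <- setdiff(needed, names(subjects))
  if (length(missing_cols) > 0) {
    stop(path, ": missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- c("mass_kg", "thigh_m", "lowerleg_m",
                    intersect(c("lever_hip_m", "lever_knee_m"), names(subjects)),
                    force_cols)
  non_numeric <- numeric_cols[!vapply(subjects[numeric_cols], is.numeric, logical(1))]
  if (length(non_numeric) > 0) {
    stop(path, ": non-numeric values in columns: ",
         paste(non_numeric, collapse = ", "), call. = FALSE)
  }
  if (!"lever_hip_m" %in% names(subjects)) {
    subjects$lever_hip_m <- default_lever_arm(subjects$thigh_m)
    if (!quiet) message("lever_hip_m not supplied; using distal-1/3 default (2/3 of thigh length)")
  }
  if (!"lever_knee_m" %in% names(subjects)) {
    subjects$lever_knee_m <- default_lever_arm(subjects$lowerleg_m)
    if (!quiet) message("lever_knee_m not supplied; using distal-1/3 default (2/3 of lower-leg length)")
  }
  subjects$id <- as.character(subjects$id)
  validate_subjects(subjects)
  tibble::as_tibble(subjects)
}

#' Write a subjects table to CSV
#'
#' @param subjects A subjects tibble or a `simulated_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  if (inherits(subjects, "simulated_cohort")) subjects <- subjects$subjects
  validate_subjects(subjects)
  readr::write_csv(subjects, path)
  invisible(path)
}

#' Write per-task moments to CSV
#'
#' Full-precision `mf_nm` / `mm_nm` plus one-decimal display columns
#' matching the reporting convention of the normative tables.
#'
#' @param moments Output of [compute_moments()].
#' @param path Output path.
#' @param digits Display rounding in decimals.
#' @return `path`, invisibly.
#' @export
write_moments <- function(moments, path, digits = 1L) {
  out <- moments
  out$mf_display <- round(out$mf_nm, digits)
  out$mm_display <- round(out$mm_nm, digits)
  readr::write_csv(out, path)
  invisible(path)
}

report_as_list <- function(report) {
  stopifnot(inherits(report, "mmt_analysis"))
  list(
    schema = "mmtstrength/report/v1",
    config = report$config,
    summary = as.data.frame(report$summary),
    regressions = as.data.frame(report$regressions),
    ancova = lapply(report$ancova, function(a) {
      if (!is.null(a$skipped) && isTRUE(a$skipped)) {
        list(task = a$task, skipped = TRUE, reason = a$reason)
      } else {
        list(
          task = a$task,
          skipped = FALSE,
          groups_included = a$groups_included,
          groups_excluded = a$groups_excluded,
          n = a$n,
          p_interaction = a$p_interaction,
          parallel = a$parallel,
          p_common_slope = a$p_common_slope,
          pairwise = if (is.null(a$pairwise)) NULL else as.data.frame(a$pairwise)
        )
      }
    })
  )
}

#' Serialise an analysis report
#'
#' `json` writes the full report (deterministic field order, full numeric
#' precision); `csv` writes the regression table with the summary columns
#' joined in; `text` writes a human-readable pair of tables mirroring the
#' normative summary/regression layout, with an em-dash for task x group
#' cells without a regression line.
#'
#' @param report An `mmt_analysis` from [run_full_analysis()].
#' @param path Output path.
#' @param format `"json"`, `"csv"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv", "text")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("output directory does not exist: ", dir, call. = FALSE)
  }
  if (format == "json") {
    jsonlite::write_json(report_as_list(report), path,
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  } else if (format == "csv") {
    tbl <- dplyr::left_join(
      dplyr::mutate(report$regressions, task = as.character(.data$task)),
      dplyr::mutate(report$summary, task = as.character(.data$task)),
      by = c("task", "group", "n")
    )
    readr::write_csv(tbl, path)
  } else {
    writeLines(format_report_text(report), path, useBytes = TRUE)
  }
  invisible(path)
}

#' Format an analysis report as aligned text tables
#'
#' @param report An `mmt_analysis`.
#' @return A character vector of lines.
#' @export
format_report_text <- function(report) {
  stopifnot(inherits(report, "mmt_analysis"))
  dash <- "—"
  s <- report$summary
  lines <- c(
    "Moment summary (mean (SD), N·m; ratio = 100 * mean Mf / mean Mm)",
    sprintf("%-15s %-5s %3s %14s %14s %8s", "task", "group", "n",
            "Mf", "Mm", "Mf/Mm %"))
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf(
      "%-15s %-5s %3d %14s %14s %8.1f",
      as.character(s$task[i]), s$group[i], s$n[i],
      sprintf("%.1f (%.1f)", s$mf_mean[i], s$mf_sd[i]),
      sprintf("%.1f (%.1f)", s$mm_mean[i], s$mm_sd[i]),
      s$ratio_pct[i]))
  }
  r <- report$regressions
  lines <- c(lines, "",
             "Regression of Mm on Mf per task and group",
             sprintf("%-15s %-5s %28s %10s %8s", "task", "group",
                     "formula", "p", "R^2"))
  for (i in seq_len(nrow(r))) {
    if (r$fitted[i]) {
      formula <- sprintf("Mm = %.3f Mf %s %.3f", r$slope[i],
                         ifelse(r$intercept[i] < 0, "-", "+"),
                         abs(r$intercept[i]))
      lines <- c(lines, sprintf("%-15s %-5s %28s %10.3g %8.3f",
                                as.character(r$task[i]), r$group[i], formula,
                                r$p_regression[i], r$r_squared[i]))
    } else {
      lines <- c(lines, sprintf("%-15s %-5s %28s %10s %8s",
                                as.character(r$task[i]), r$group[i],
                                dash, dash, dash))
    }
  }
  lines <- c(lines, "", "ANCOVA per task (covariate Mf)")
  for (a in report$ancova) {
    if (!is.null(a$skipped) && isTRUE(a$skipped)) {
      lines <- c(lines, sprintf("%-15s skipped: %s", a$task, a$reason))
    } else {
      lines <- c(lines, sprintf(
        "%-15s groups %s: interaction p = %.3f (%s)",
        a$task, paste(a$groups_included, collapse = ","), a$p_interaction,
        if (a$parallel) "parallel" else "not parallel"))
      if (a$parallel) {
        lines <- c(lines, sprintf("%-15s common slope p = %.3g", "", a$p_common_slope))
        for (i in seq_len(nrow(a$pairwise))) {
          lines <- c(lines, sprintf("%-15s %s: diff %.2f N·m, adj. p = %.3f", "",
                                    a$pairwise$contrast[i], a$pairwise$estimate[i],
                                    a$pairwise$p_adj[i]))
        }
      }
    }
  }
  lines
}
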