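#' Test for no correlation between M_f and M_m
#'
#' Two-sided Pearson test of zero correlation, via the exact t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom
#' (delegated to [stats::cor.test()]).
#'
#' @param mf,mm Numeric vectors of equal length (>= 3), both with nonzero
#'   variance.
#' @return A list with `r` (Pearson correlation), `p` (two-sided p-value)
#'   and `n`.
#' @export
uncorrelated_test <- function(mf, mm) {
  if (length(mf) != length(mm)) {
    stop("`mf` and `mm` must have equal length", call. = FALSE)
  }
  if (length(mf) < 3) {
    stop("at least 3 paired observations are required, got ", length(mf),
         call. = FALSE)
  }
  if (any(!is.finite(mf)) || any(!is.finite(mm))) {
    stop("`mf` and `mm` must be finite", call. = FALSE)
  }
  if (stats::sd(mf) == 0 || stats::sd(mm) == 0) {
    stop("correlation is undefined: zero variance in mf or mm", call. = FALSE)
  }
  ct <- stats::cor.test(mf, mm, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(mf))
}

#' Regression of M_m on M_f for one task and group
#'
#' Mirrors the study's two-step protocol: first the no-correlation test;
#' only if it rejects at `alpha` is the ordinary least-squares line
#' \eqn{M_m = a M_f + b} fitted. When the correlation is not significant the
#' result is flagged `fitted = FALSE` and carries no line — the situation of
#' knee flexion in the eldest group.
#'
#' @inheritParams uncorrelated_test
#' @param alpha Significance level for the no-correlation gate.
#' @param task,group Optional labels carried into the result.
#' @return A one-row tibble: `task`, `group`, `n`, `pearson_r`,
#'   `p_uncorrelated`, `fitted`, `slope`, `intercept`, `r_squared`,
#'   `p_regression` (slope/intercept/r-squared are `NA` when not fitted).
#' @export
fit_task_group <- function(mf, mm, alpha = 0.05,
                           task = NA_character_, group = NA_character_) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  ut <- uncorrelated_test(mf, mm)
  if (ut$p < alpha) {
    fit <- stats::lm(mm ~ mf)
    sm <- summary(fit)
    tibble::tibble(
      task = task, group = group, n = ut$n,
      pearson_r = ut$r, p_uncorrelated = ut$p, fitted = TRUE,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = sm$r.squared,
      p_regression = unname(sm$coefficients["mf", "Pr(>|t|)"])
    )
  } else {
    tibble::tibble(
      task = task, group = group, n = ut$n,
      pearson_r = ut$r, p_uncorrelated = ut$p, fitted = FALSE,
      slope = NA_real_, intercept = NA_real_,
      r_squared = NA_real_, p_regression = NA_real_
    )
  }
}

#' Analysis of covariance of M_m across age groups for one task
#'
#' Three-step ANCOVA with \eqn{M_f} as the covariate:
#'
#' 1. *Parallelism*: F test of the `mf:group` interaction in
#'    `mm ~ mf * group`. If the interaction is significant the group
#'    regression lines are not parallel and the analysis stops — adjusted
#'    group means are not comparable.
#' 2. *Common slope*: in the additive model `mm ~ mf + group`, Type II F
#'    test that the shared slope is nonzero.
#' 3. *Adjusted group comparisons*: pairwise differences of
#'    covariate-adjusted group means (estimated marginal means at the grand
#'    mean of \eqn{M_f}), Bonferroni-adjusted.
#'
#' Groups without a fitted regression for the task (no significant
#' \eqn{M_f}-\eqn{M_m} correlation) are excluded before the ANCOVA, so e.g.
#' a knee-flexion analysis may compare only the two younger groups.
#'
#' @param data A data frame with columns `group`, `mf`, `mm` for one task.
#' @param alpha Significance level.
#' @param task Optional task label carried into the report.
#' @param exclude_unfitted If `TRUE` (default), drop groups whose
#'   no-correlation test does not reject before running the ANCOVA.
#' @param adjust Multiplicity adjustment for the pairwise comparisons
#'   (passed to emmeans; default `"bonferroni"`).
#' @return A list of class `ancova_report`: `task`, `groups_included`,
#'   `groups_excluded`, `n`, `p_interaction`, `parallel`, and — when
#'   parallelism is not rejected — `p_common_slope` and `pairwise`
#'   (tibble: `contrast`, `estimate`, `p_adj`).
#' @export
ancova_for_task <- function(data, alpha = 0.05, task = NA_character_,
                            exclude_unfitted = TRUE, adjust = "bonferroni") {
  stopifnot(all(c("group", "mf", "mm") %in% names(data)))
  data <- data[stats::complete.cases(data[, c("group", "mf", "mm")]), ]

  excluded <- character(0)
  if (exclude_unfitted) {
    for (g in unique(data$group)) {
      gd <- data[data$group == g, ]
      if (nrow(gd) < 3 || !fit_task_group(gd$mf, gd$mm, alpha)$fitted) {
        excluded <- c(excluded, g)
      }
    }
    data <- data[!data$group %in% excluded, ]
  }
  groups <- sort(unique(data$group))
  if (length(groups) < 2) {
    stop("ANCOVA for task ", task, ": fewer than 2 eligible groups ",
         "(excluded: ", paste(excluded, collapse = ", "), ")", call. = FALSE)
  }
  counts <- table(data$group)
  if (any(counts < 3)) {
    stop("ANCOVA for task ", task, ": every included group needs >= 3 subjects",
         call. = FALSE)
  }
  data$group <- factor(data$group, levels = groups)

  full <- stats::lm(mm ~ mf * group, data = data)
  additive <- stats::lm(mm ~ mf + group, data = data)
  p_int <- stats::anova(additive, full)[2, "Pr(>F)"]

  report <- list(
    task = task,
    groups_included = groups,
    groups_excluded = excluded,
    n = nrow(data),
    alpha = alpha,
    p_interaction = p_int,
    parallel = p_int >= alpha,
    p_common_slope = NULL,
    pairwise = NULL
  )
  if (report$parallel) {
    aov2 <- car::Anova(additive, type = 2)
    report$p_common_slope <- aov2["mf", "Pr(>F)"]
    emm <- emmeans::emmeans(additive, "group")
    prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                           adjust = adjust))
    report$pairwise <- tibble::tibble(
      contrast = as.character(prs$contrast),
      estimate = prs$estimate,
      p_adj = prs$p.value
    )
  }
  class(report) <- "ancova_report"
  report
}

#' @export
print.ancova_report <- function(x, ...) {
  cat(sprintf("ANCOVA, task %s (groups %s; n = %d)\n", x$task,
              paste(x$groups_included, collapse = ", "), x$n))
  if (length(x$groups_excluded) > 0) {
    cat("  excluded (no M_f-M_m correlation):",
        paste(x$groups_excluded, collapse = ", "), "\n")
  }
  cat(sprintf("  parallelism: p = %.3f -> %s\n", x$p_interaction,
              if (x$parallel) "slopes parallel, adjusted comparisons follow"
              else "slopes differ, analysis stops"))
  if (x$parallel) {
    cat(sprintf("  common slope nonzero: p = %.3g\n", x$p_common_slope))
    for (i in seq_len(nrow(x$pairwise))) {
      cat(sprintf("  %s: diff = %.2f N·m, adj. p = %.3f\n",
                  x$pairwise$contrast[i], x$pairwise$estimate[i],
                  x$pairwise$p_adj[i]))
    }
  }
  invisible(x)
}

#' Per task x group moment summaries
#'
#' Means and SDs of \eqn{M_f} and \eqn{M_m} plus the mean-based strength
#' ratio \eqn{100 \cdot \bar{M_f} / \bar{M_m}} (percent) — the convention
#' under which e.g. group means 25.9 / 63.7 N·m give 40.7%.
#'
#' @param moments Output of [compute_moments()] with an added `group` column.
#' @return A tibble: `task`, `group`, `n`, `mf_mean`, `mf_sd`, `mm_mean`,
#'   `mm_sd`, `ratio_pct`.
#' @export
summarize_moments <- function(moments) {
  stopifnot(all(c("task", "group", "mf_nm", "mm_nm") %in% names(moments)))
  moments |>
    dplyr::group_by(.data$task, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mf_mean = mean(.data$mf_nm), mf_sd = stats::sd(.data$mf_nm),
      mm_mean = mean(.data$mm_nm), mm_sd = stats::sd(.data$mm_nm),
      ratio_pct = 100 * mean(.data$mf_nm) / mean(.data$mm_nm),
      .groups = "drop"
    )
}

#' Full analysis: summaries, regressions and ANCOVAs
#'
#' Runs the complete analysis over one or more age-group cohorts of raw
#' subject measurements: recomputes all moments, produces the task x group
#' summary table, fits the gated regression for every task x group, and runs
#' the per-task ANCOVA over the groups with a fitted line (tasks with fewer
#' than two eligible groups are skipped with a note).
#'
#' @param subjects A subjects tibble (possibly several groups, distinguished
#'   by `age_group`), or a list of subjects tibbles / `simulated_cohort`s.
#' @param alpha Significance level used throughout.
#' @return A list of class `mmt_analysis`: `summary`, `regressions`,
#'   `ancova` (named list per task, entries either an `ancova_report` or a
#'   skip note), `config` (alpha, seed-free, package version).
#' @export
#' @examples
#' cohorts <- lapply(builtin_group_specs(), simulate_cohort, seed = 7)
#' res <- run_full_analysis(cohorts)
#' res$summary
run_full_analysis <- function(subjects, alpha = 0.05) {
  if (inherits(subjects, "simulated_cohort")) {
    subjects <- subjects$subjects
  } else if (is.list(subjects) && !is.data.frame(subjects)) {
    subjects <- dplyr::bind_rows(lapply(subjects, function(x) {
      if (inherits(x, "simulated_cohort")) x$subjects else x
    }))
  }
  validate_subjects(subjects)

  moments <- compute_moments(subjects) |>
    dplyr::left_join(
      dplyr::select(subjects, subject_id = "id", group = "age_group"),
      by = "subject_id"
    )
  summary_tbl <- summarize_moments(moments)

  cells <- moments |> dplyr::group_by(.data$task, .data$group) |> dplyr::group_split()
  regressions <- dplyr::bind_rows(lapply(cells, function(cell) {
    task <- as.character(cell$task[1])
    group <- cell$group[1]
    if (nrow(cell) < 3) {
      stop("task ", task, ", group ", group,
           ": regression requires n >= 3, got ", nrow(cell), call. = FALSE)
    }
    fit_task_group(cell$mf_nm, cell$mm_nm, alpha, task = task, group = group)
  }))

  ancova <- lapply(stats::setNames(nm = mmt_tasks()), function(task) {
    td <- moments[moments$task == task, c("group", "mf_nm", "mm_nm")]
    names(td) <- c("group", "mf", "mm")
    eligible <- regressions$fitted[regressions$task == task]
    if (sum(eligible) < 2) {
      list(task = task, skipped = TRUE,
           reason = "fewer than 2 groups with a fitted regression")
    } else {
      ancova_for_task(td, alpha = alpha, task = task)
    }
  })

  out <- list(
    summary = summary_tbl,
    regressions = regressions,
    ancova = ancova,
    config = list(
      alpha = alpha,
      n_subjects = nrow(subjects),
      groups = sort(unique(subjects$age_group)),
      package_version = as.character(utils::packageVersion("mmtstrength"))
    )
  )
  class(out) <- "mmt_analysis"
  out
}

#' @export
print.mmt_analysis <- function(x, ...) {
  cat("Strength-moment analysis:", x$config$n_subjects, "subjects, groups",
      paste(x$config$groups, collapse = ", "),
      sprintf("(alpha = %.2f)\n\n", x$config$alpha))
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}
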