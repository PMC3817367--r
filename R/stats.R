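# Group-level statistics: two-sample t-tests on graph metrics, behavioral
# switch-cost summaries, mixed-design ANOVA on reaction times, and Pearson
# structure-function correlations. Test engines are the base R ones
# (stats::t.test, stats::cor.test, stats::aov); this module fixes the
# conventions (pooled variance by default, two-sided p-values, no
# multiplicity correction) and the tabular result shapes.

#' Two-sample t-test
#'
#' Pooled-variance by default (df = n1 + n2 - 2), Welch optional.
#'
#' @param a,b Numeric sample vectors (each of length >= 2).
#' @param variant `"pooled"` or `"welch"`.
#' @return A one-row tibble: `t`, `df`, `p`, `mean_a`, `mean_b`, `se_a`,
#'   `se_b`, `variant`.
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) {
    stop("Each sample needs at least 2 observations.", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop("Both samples are constant; the t statistic is undefined ",
         "(or infinite for unequal means).", call. = FALSE)
  }
  res <- stats::t.test(a, b, var.equal = variant == "pooled")
  tibble::tibble(
    t = unname(res$statistic),
    df = unname(res$parameter),
    p = res$p.value,
    mean_a = mean(a), mean_b = mean(b),
    se_a = stats::sd(a) / sqrt(length(a)),
    se_b = stats::sd(b) / sqrt(length(b)),
    variant = variant
  )
}

#' Pearson correlation
#'
#' Product-moment correlation with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y Numeric vectors of equal length (>= 3), both non-constant.
#' @return A one-row tibble: `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length.",
                                   call. = FALSE)
  if (length(x) < 3L) stop("At least 3 pairs are required.", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Correlation is undefined for constant input.", call. = FALSE)
  }
  res <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(res$estimate), p = res$p.value, n = length(x))
}

#' Switch cost of one behavioral table
#'
#' Mean reaction time of switch trials minus mean reaction time of repeat
#' trials in the switch block, over correct trials only.
#'
#' @param behavior A `behavioral_table`.
#' @return Scalar switch cost in ms.
#' @export
switch_cost <- function(behavior) {
  sw <- dplyr::filter(behavior, .data$block == "switch", .data$correct,
                      !is.na(.data$trial_type))
  m <- dplyr::summarise(dplyr::group_by(sw, .data$trial_type),
                        rt = mean(.data$rt_ms))
  if (!all(c("switch", "repeat") %in% m$trial_type)) {
    stop("Switch block must contain correct trials of both types.",
         call. = FALSE)
  }
  m$rt[m$trial_type == "switch"] - m$rt[m$trial_type == "repeat"]
}

#' Switch-block accuracy rate
#'
#' Proportion of correct responses among switch-block trials; the behavioral
#' score used for the median-split classification.
#'
#' @param behavior A `behavioral_table`.
#' @return Scalar in `[0, 1]`.
#' @export
switch_accuracy <- function(behavior) {
  sw <- dplyr::filter(behavior, .data$block == "switch")
  if (nrow(sw) == 0L) stop("No switch block found.", call. = FALSE)
  mean(sw$correct)
}

#' 2 x 2 mixed-design ANOVA
#'
#' One between-subject factor (group) and one within-subject factor with two
#' levels (e.g. switch vs repeat, or global vs local), fitted by the standard
#' sums-of-squares decomposition via `stats::aov` with a subject error
#' stratum. Returns the three effects: group (between), condition (within),
#' and their interaction.
#'
#' @param data Long tibble with columns `subject`, `group`, `condition`,
#'   `value`: one row per subject x condition cell (condition means).
#' @return A tibble with columns `effect`, `df1`, `df2`, `F`, `p`.
#' @export
mixed_anova_2x2 <- function(data) {
  required <- c("subject", "group", "condition", "value")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0L) {
    stop("`data` is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(data$group)) != 2L ||
      length(unique(data$condition)) != 2L) {
    stop("Exactly two groups and two conditions are required.",
         call. = FALSE)
  }
  counts <- table(data$subject, data$condition)
  if (any(counts != 1L)) {
    stop("Every subject needs exactly one value per condition.",
         call. = FALSE)
  }
  d <- data.frame(subject = factor(data$subject),
                  group = factor(data$group),
                  condition = factor(data$condition),
                  value = data$value)
  fit <- stats::aov(value ~ group * condition + Error(subject), data = d)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: subject"]][[1]])
  within <- as.data.frame(s[["Error: Within"]][[1]])
  pick <- function(tab, name) {
    row <- trimws(rownames(tab)) == name
    c(df1 = tab$Df[row], F = tab$`F value`[row], p = tab$`Pr(>F)`[row],
      df2 = tab$Df[trimws(rownames(tab)) == "Residuals"])
  }
  g <- pick(between, "group")
  cnd <- pick(within, "condition")
  gc <- pick(within, "group:condition")
  tibble::tibble(
    effect = c("group", "condition", "group:condition"),
    df1 = unname(c(g["df1"], cnd["df1"], gc["df1"])),
    df2 = unname(c(g["df2"], cnd["df2"], gc["df2"])),
    F = unname(c(g["F"], cnd["F"], gc["F"])),
    p = unname(c(g["p"], cnd["p"], gc["p"]))
  )
}

#' Per-subject condition means of switch-block reaction times
#'
#' Correct trials only; one row per subject x trial type, ready for
#' [mixed_anova_2x2()].
#'
#' @param cohort A `cohort`.
#' @param factor `"switch"` (switch vs repeat trial types) or `"cue"`
#'   (global vs local, pure blocks).
#' @return Long tibble with columns `subject`, `group`, `condition`, `value`.
#' @export
rt_condition_means <- function(cohort, factor = c("switch", "cue")) {
  factor <- match.arg(factor)
  purrr::pmap_dfr(cohort$subjects[, c("subject_id", "group", "behavior")],
                  function(subject_id, group, behavior) {
    if (factor == "switch") {
      rows <- dplyr::filter(behavior, .data$block == "switch", .data$correct,
                            !is.na(.data$trial_type))
      rows <- dplyr::rename(rows, condition = "trial_type")
    } else {
      rows <- dplyr::filter(behavior, .data$block %in% c("pure_global",
                                                         "pure_local"),
                            .data$correct)
      rows <- dplyr::rename(rows, condition = "cue")
    }
    out <- dplyr::summarise(dplyr::group_by(rows, .data$condition),
                            value = mean(.data$rt_ms))
    dplyr::mutate(out, subject = subject_id, group = group,
                  .before = 1)
  })
}

#' Structure-function association across subjects
#'
#' At the `global` level, correlates subjects' structural and functional
#' network summaries per metric, within each group separately. At the
#' `nodal` level, correlates nodal degree across subjects per node (all
#' subjects pooled), one row per ROI.
#'
#' @param structural,functional Long metric tibbles with columns
#'   `subject_id`, `group`, `node`, and metric columns (`degree`, `strength`,
#'   `local_efficiency`, `betweenness`), as produced by [cohort_metrics()].
#' @param level `"global"` or `"nodal"`.
#' @return A tibble of correlation rows (`r`, `p`, `n`) keyed by metric and
#'   group (global) or node (nodal).
#' @export
crossmodal_association <- function(structural, functional,
                                   level = c("global", "nodal")) {
  level <- match.arg(level)
  if (!setequal(unique(structural$subject_id), unique(functional$subject_id))) {
    stop("Structural and functional tables must cover the same subjects.",
         call. = FALSE)
  }
  metrics <- c("degree", "strength", "local_efficiency", "betweenness")
  if (level == "global") {
    s_g <- dplyr::summarise(
      dplyr::group_by(structural, .data$subject_id, .data$group),
      dplyr::across(dplyr::all_of(metrics), mean), .groups = "drop")
    f_g <- dplyr::summarise(
      dplyr::group_by(functional, .data$subject_id, .data$group),
      dplyr::across(dplyr::all_of(metrics), mean), .groups = "drop")
    joined <- dplyr::inner_join(s_g, f_g, by = c("subject_id", "group"),
                                suffix = c("_struct", "_func"))
    purrr::map_dfr(metrics, function(m) {
      purrr::map_dfr(split(joined, joined$group), function(gd) {
        res <- tryCatch(
          pearson_r(gd[[paste0(m, "_struct")]], gd[[paste0(m, "_func")]]),
          error = function(e) tibble::tibble(r = NA_real_, p = NA_real_,
                                             n = nrow(gd)))
        dplyr::mutate(res, metric = m, group = gd$group[1], .before = 1)
      })
    })
  } else {
    joined <- dplyr::inner_join(
      structural[, c("subject_id", "node", "degree")],
      functional[, c("subject_id", "node", "degree")],
      by = c("subject_id", "node"), suffix = c("_struct", "_func"))
    purrr::map_dfr(split(joined, joined$node), function(nd) {
      res <- tryCatch(pearson_r(nd$degree_struct, nd$degree_func),
                      error = function(e) tibble::tibble(
                        r = NA_real_, p = NA_real_, n = nrow(nd)))
      dplyr::mutate(res, node = nd$node[1], .before = 1)
    })
  }
}
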