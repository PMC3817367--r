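# Local-Global Task (LGT) behavioral generator: two pure blocks of 24 trials
# and one switch block of 49 trials in which the cued dimension alternates
# every other trial (local, local, global, global, ...). Reaction times are
# drawn per condition from truncated normals; correctness is Bernoulli.

#' The Local-Global Task trial schedule
#'
#' Deterministic trial layout: 24 `pure_global` trials, 24 `pure_local`
#' trials, and 49 `switch` trials. In the switch block the cued dimension
#' alternates every other trial (pairs: local, local, global, global, ...),
#' so each pair opens with a cue change. The first trial after a cue change is
#' labeled `switch`, the second of each pair `repeat`; the first trial of the
#' block follows no previous cue and is labeled `NA` (excluded from both
#' categories). Pure-block trials carry `NA` trial type.
#'
#' @return A tibble with columns `block`, `trial_index`, `cue`, `trial_type`.
#' @export
lgt_schedule <- function() {
  pure <- function(block, cue, n) {
    tibble::tibble(block = block, trial_index = seq_len(n), cue = cue,
                   trial_type = NA_character_)
  }
  n_switch <- 49L
  # pairs of cues: local, local, global, global, ...
  cue <- rep(rep(c("local", "global"), each = 2L),
             length.out = n_switch)
  trial_type <- c(NA_character_,
                  ifelse(cue[-1L] != cue[-n_switch], "switch", "repeat"))
  dplyr::bind_rows(
    pure("pure_global", "global", 24L),
    pure("pure_local", "local", 24L),
    tibble::tibble(block = "switch", trial_index = seq_len(n_switch),
                   cue = cue, trial_type = trial_type)
  )
}

#' Default reaction-time parameters, per group and condition
#'
#' Means and SDs (ms) of the per-condition normal RT distributions. Pure-block
#' trials use the cue condition (global faster than local, same in both
#' groups); switch-block trials use the trial type, with the patient group
#' given a larger switch cost (676 vs 641 ms) than controls (610 vs 600 ms).
#'
#' @return A tibble with columns `group`, `condition`, `mean_ms`, `sd_ms`.
#' @export
default_rt_params <- function() {
  tibble::tribble(
    ~group,    ~condition, ~mean_ms, ~sd_ms,
    "patient", "global",        597,    130,
    "patient", "local",         634,    130,
    "patient", "switch",        676,    152,
    "patient", "repeat",        641,    132,
    "control", "global",        597,    130,
    "control", "local",         634,    130,
    "control", "switch",        610,    120,
    "control", "repeat",        600,    120
  )
}

#' Default per-group probability of a correct response
#'
#' @return A tibble with columns `group`, `p_correct`; the patient group is
#'   planted less accurate than controls.
#' @export
default_accuracy_params <- function() {
  tibble::tibble(group = c("patient", "control"),
                 p_correct = c(0.88, 0.95))
}

#' Simulate one subject's Local-Global Task table
#'
#' Emits the full LGT schedule (see [lgt_schedule()]) with reaction times
#' drawn per condition from the group's normal distribution (truncated at 0
#' by rejection) and correctness drawn Bernoulli with the group's success
#' probability. The switch block's first trial has no trial type and draws
#' its RT from the switch-trial distribution.
#'
#' @param group `"patient"` or `"control"`.
#' @param config A [cohort_config()] list (uses `rt_params` and
#'   `accuracy_params`).
#' @param seed Integer seed.
#' @return A `behavioral_table` tibble with columns `block`, `trial_index`,
#'   `cue`, `trial_type`, `rt_ms`, `correct`.
#' @export
simulate_behavior <- function(group, config = cohort_config(), seed = 1) {
  if (!group %in% c("patient", "control")) {
    stop("`group` must be \"patient\" or \"control\".", call. = FALSE)
  }
  rt <- dplyr::filter(config$rt_params, .data$group == !!group)
  acc <- dplyr::filter(config$accuracy_params, .data$group == !!group)
  if (nrow(rt) == 0L || nrow(acc) == 0L) {
    stop("No RT/accuracy parameters for group \"", group, "\".", call. = FALSE)
  }
  if (any(rt$mean_ms <= 0) || any(rt$sd_ms < 0)) {
    stop("RT means must be positive and SDs non-negative.", call. = FALSE)
  }
  sched <- lgt_schedule()
  cond <- ifelse(sched$block == "switch",
                 dplyr::coalesce(sched$trial_type, "switch"),
                 sched$cue)
  idx <- match(cond, rt$condition)
  if (anyNA(idx)) {
    stop("RT parameters missing condition(s): ",
         paste(unique(cond[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  withr_seed(seed)
  rt_ms <- truncated_normal(length(cond), rt$mean_ms[idx], rt$sd_ms[idx])
  correct <- stats::runif(length(cond)) < acc$p_correct[[1L]]
  out <- dplyr::mutate(sched, rt_ms = rt_ms, correct = correct)
  class(out) <- c("behavioral_table", class(out))
  out
}

# Normal truncated at zero via rejection; degenerate sd = 0 returns the mean.
truncated_normal <- function(n, mean, sd, max_tries = 100L) {
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(max_tries)) {
    bad <- x <= 0
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
  }
  x[x <= 0] <- .Machine$double.eps
  x
}

#' Read / write a behavioral table
#'
#' TSV with columns `block`, `trial_index`, `cue`, `trial_type`, `rt_ms`,
#' `correct`.
#'
#' @param path File path.
#' @export
read_behavior <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          block = "c", trial_index = "i", cue = "c",
                          trial_type = "c", rt_ms = "d", correct = "l"))
  class(df) <- c("behavioral_table", class(df))
  df
}

#' @rdname read_behavior
#' @param behavior A `behavioral_table`.
#' @export
write_behavior <- function(behavior, path) {
  readr::write_tsv(behavior, path)
  invisible(path)
}
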