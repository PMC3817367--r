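# End-to-end orchestration: simulate (or load) a cohort, build the four
# networks per subject, compute metrics, group statistics, hubs, and the
# discriminant models, writing every table to a run directory.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()].
#' @param tracking A [tracking_params()].
#' @param ridge Ridge for [partial_correlation_matrix()] (default 0).
#' @param negativity_mode `"zero_negatives"` or `"absolute"` for
#'   [weight_functional()].
#' @param binarize_threshold Magnitude threshold for [binarize()]
#'   (default 0, the strict non-zero rule).
#' @param structural_normalization `"raw"` or `"total_fraction"` for
#'   [normalize_structural()].
#' @param verbose Log stage boundaries with timing (default TRUE).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            tracking = tracking_params(),
                            ridge = 0,
                            negativity_mode = c("zero_negatives", "absolute"),
                            binarize_threshold = 0,
                            structural_normalization = c("raw",
                                                         "total_fraction"),
                            verbose = TRUE) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(tracking, "tracking_params"),
            ridge >= 0, binarize_threshold >= 0)
  structure(list(cohort = cohort,
                 tracking = tracking,
                 ridge = ridge,
                 negativity_mode = match.arg(negativity_mode),
                 binarize_threshold = binarize_threshold,
                 structural_normalization =
                   match.arg(structural_normalization),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
}

#' Build the four networks of one subject
#'
#' Weighted functional (non-negative partial correlations), binary
#' functional, weighted structural (streamline counts, optionally
#' normalized), binary structural.
#'
#' @param timeseries A `timeseries_panel`.
#' @param tensor A `tensor_volume` or `NULL` (structural networks skipped).
#' @param atlas An `roi_atlas`.
#' @param config A [pipeline_config()].
#' @return Named list of `connectivity_matrix` objects: `func_signed`,
#'   `func_weighted`, `func_binary`, and (with a tensor) `struct_weighted`,
#'   `struct_binary`.
#' @export
subject_networks <- function(timeseries, tensor, atlas,
                             config = pipeline_config()) {
  signed <- partial_correlation_matrix(timeseries, ridge = config$ridge)
  fw <- weight_functional(signed, mode = config$negativity_mode)
  fb <- binarize(fw, threshold = config$binarize_threshold)
  nets <- list(func_signed = signed, func_weighted = fw, func_binary = fb)
  if (!is.null(tensor)) {
    streamlines <- track_streamlines(tensor, config$tracking)
    sw <- count_matrix(streamlines, atlas)
    sw <- normalize_structural(sw, mode = config$structural_normalization)
    nets$struct_weighted <- sw
    nets$struct_binary <- binarize(sw)
  }
  nets
}

#' Per-subject networks for a whole cohort
#'
#' @param cohort A `cohort`.
#' @param config A [pipeline_config()].
#' @return Tibble with `subject_id`, `group`, and one list-column per
#'   network kind.
#' @export
cohort_networks <- function(cohort, config = pipeline_config()) {
  rows <- purrr::pmap(cohort$subjects[, c("subject_id", "group",
                                          "timeseries", "tensor")],
                      function(subject_id, group, timeseries, tensor) {
    nets <- subject_networks(timeseries, tensor, cohort$atlas, config)
    c(list(subject_id = subject_id, group = group), lapply(nets, list))
  })
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

#' Long table of nodal metrics for a set of networks
#'
#' @param networks Output of [cohort_networks()].
#' @param which Name of the network column to score (e.g.
#'   `"func_weighted"`).
#' @return Long tibble: `subject_id`, `group`, `node`, `degree`, `strength`,
#'   `local_efficiency`, `betweenness`.
#' @export
cohort_metrics <- function(networks, which = "func_weighted") {
  stopifnot(which %in% names(networks))
  purrr::pmap_dfr(networks[, c("subject_id", "group", which)],
                  function(subject_id, group, ...) {
    m <- list(...)[[1]]
    dplyr::mutate(nodal_metrics(m), subject_id = subject_id, group = group,
                  .before = 1)
  })
}

#' Table-2-style group comparison of network summaries
#'
#' Per metric, the per-subject network summary (mean over nodes) is compared
#' between groups with a two-sample t-test (patients as sample `a`, controls
#' as sample `b`, pooled variance).
#'
#' @param metrics Long metric tibble from [cohort_metrics()].
#' @param modality Label recorded in the output.
#' @return Tibble: `modality`, `metric`, group means/SEs, `t`, `df`, `p`.
#' @export
group_metric_tests <- function(metrics, modality) {
  metric_names <- c("degree", "strength", "local_efficiency", "betweenness")
  summaries <- dplyr::summarise(
    dplyr::group_by(metrics, .data$subject_id, .data$group),
    dplyr::across(dplyr::all_of(metric_names), mean), .groups = "drop")
  purrr::map_dfr(metric_names, function(m) {
    a <- summaries[[m]][summaries$group == "patient"]
    b <- summaries[[m]][summaries$group == "control"]
    # a metric can be degenerate (zero variance in both groups, e.g. degree
    # on identical topologies); report the means with an NA test
    res <- tryCatch(two_sample_t(a, b), error = function(e) {
      tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_,
                     mean_a = mean(a), mean_b = mean(b),
                     se_a = stats::sd(a) / sqrt(length(a)),
                     se_b = stats::sd(b) / sqrt(length(b)))
    })
    tibble::tibble(modality = modality, metric = m,
                   mean_patient = res$mean_a, se_patient = res$se_a,
                   mean_control = res$mean_b, se_control = res$se_b,
                   t = res$t, df = res$df, p = res$p)
  })
}

#' Run the full pipeline
#'
#' Simulates the cohort, builds the four networks per subject, computes
#' nodal metrics, the group statistics (metric t-tests per modality,
#' behavioral switch-cost/accuracy t-tests, mixed ANOVAs on reaction times,
#' structure-function correlations), the per-group hub reports, and the
#' three discriminant models; writes every table plus a JSON run manifest to
#' `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param atlas An `roi_atlas`.
#' @return Invisibly, a list with all in-memory results (`cohort`,
#'   `networks`, `metrics`, `stats`, `hubs`, `classification`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         atlas = make_roi_atlas()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  v <- config$verbose
  t0 <- Sys.time()

  stage_log(v, "simulate: building cohort (seed %s)", config$cohort$seed)
  cohort <- make_cohort(config$cohort, atlas)
  write_cohort(cohort, file.path(out_dir, "cohort"))

  stage_log(v, "networks: %d subjects", nrow(cohort$subjects))
  networks <- cohort_networks(cohort, config)
  net_dir <- file.path(out_dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  net_kinds <- intersect(c("func_weighted", "func_binary",
                           "struct_weighted", "struct_binary"),
                         names(networks))
  for (i in seq_len(nrow(networks))) {
    for (kind in net_kinds) {
      write_matrix_tsv(networks[[kind]][[i]],
                       file.path(net_dir, paste0(networks$subject_id[i], "_",
                                                 kind, ".tsv")))
    }
  }

  stage_log(v, "metrics: %s", paste(net_kinds, collapse = ", "))
  metric_sets <- lapply(stats::setNames(net_kinds, net_kinds),
                        function(k) cohort_metrics(networks, k))
  metrics_long <- dplyr::bind_rows(metric_sets, .id = "network")
  readr::write_tsv(metrics_long, file.path(out_dir, "nodal_metrics.tsv"))

  stage_log(v, "stats: group tests, ANOVA, cross-modal correlations")
  has_struct <- "struct_weighted" %in% net_kinds
  metric_tests <- dplyr::bind_rows(
    group_metric_tests(metric_sets$func_weighted, "functional"),
    if (has_struct) group_metric_tests(metric_sets$struct_weighted,
                                       "structural"))
  readr::write_tsv(metric_tests, file.path(out_dir, "group_metric_tests.tsv"))

  behavior_summary <- purrr::pmap_dfr(
    cohort$subjects[, c("subject_id", "group", "behavior")],
    function(subject_id, group, behavior) {
      tibble::tibble(subject_id = subject_id, group = group,
                     switch_cost_ms = switch_cost(behavior),
                     switch_accuracy = switch_accuracy(behavior))
    })
  readr::write_tsv(behavior_summary, file.path(out_dir,
                                               "behavior_summary.tsv"))
  behavioral_tests <- dplyr::bind_rows(
    dplyr::mutate(two_sample_t(
      behavior_summary$switch_cost_ms[behavior_summary$group == "patient"],
      behavior_summary$switch_cost_ms[behavior_summary$group == "control"]),
      measure = "switch_cost", .before = 1),
    dplyr::mutate(two_sample_t(
      behavior_summary$switch_accuracy[behavior_summary$group == "patient"],
      behavior_summary$switch_accuracy[behavior_summary$group == "control"]),
      measure = "switch_accuracy", .before = 1))
  readr::write_tsv(behavioral_tests, file.path(out_dir,
                                               "behavioral_tests.tsv"))

  anova_results <- dplyr::bind_rows(
    dplyr::mutate(mixed_anova_2x2(rt_condition_means(cohort, "switch")),
                  factor = "switch", .before = 1),
    dplyr::mutate(mixed_anova_2x2(rt_condition_means(cohort, "cue")),
                  factor = "cue", .before = 1))
  readr::write_tsv(anova_results, file.path(out_dir, "rt_anova.tsv"))

  crossmodal <- NULL
  hubs <- NULL
  if (has_struct) {
    crossmodal <- list(
      global = crossmodal_association(metric_sets$struct_weighted,
                                      metric_sets$func_weighted, "global"),
      nodal = crossmodal_association(metric_sets$struct_weighted,
                                     metric_sets$func_weighted, "nodal"))
    readr::write_tsv(crossmodal$global,
                     file.path(out_dir, "crossmodal_global.tsv"))
    readr::write_tsv(crossmodal$nodal,
                     file.path(out_dir, "crossmodal_nodal.tsv"))
  }

  hub_input <- dplyr::bind_rows(metric_sets, .id = "network")
  hub_input <- dplyr::filter(hub_input,
                             .data$network %in% c("func_weighted",
                                                  "struct_weighted"))
  hubs <- purrr::map_dfr(split(hub_input,
                               list(hub_input$network, hub_input$group)),
                         function(d) {
    rep <- identify_hubs(dplyr::rename(d, betweenness = "betweenness"))
    dplyr::mutate(rep, network = d$network[1], group = d$group[1],
                  threshold = attr(rep, "threshold"), .before = 1)
  })
  readr::write_tsv(hubs, file.path(out_dir, "hub_report.tsv"))

  stage_log(v, "classify: median-split discriminant models")
  classification <- NULL
  if (has_struct) {
    degrees <- dplyr::inner_join(
      dplyr::summarise(dplyr::group_by(metric_sets$struct_weighted,
                                       .data$subject_id),
                       structural_degree = mean(.data$degree)),
      dplyr::summarise(dplyr::group_by(metric_sets$func_weighted,
                                       .data$subject_id),
                       functional_degree = mean(.data$degree)),
      by = "subject_id")
    scores <- dplyr::select(behavior_summary, "subject_id",
                            score = "switch_accuracy")
    classification <- run_model_suite(degrees, scores)
    readr::write_tsv(classification,
                     file.path(out_dir, "classification_reports.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("switchnet")),
    seed = config$cohort$seed,
    n_subjects = nrow(cohort$subjects),
    n_nodes = nrow(cohort$atlas),
    networks_per_subject = length(net_kinds),
    config = serialize_config(config),
    outputs = list.files(out_dir, recursive = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log(v, "done in %.1f s",
            as.numeric(difftime(Sys.time(), t0, units = "secs")))

  invisible(list(cohort = cohort, networks = networks,
                 metrics = metrics_long, metric_tests = metric_tests,
                 behavioral_tests = behavioral_tests,
                 anova = anova_results, crossmodal = crossmodal,
                 hubs = hubs, classification = classification,
                 manifest = manifest))
}

serialize_config <- function(config) {
  list(
    cohort = list(
      n_patients = config$cohort$n_patients,
      n_controls = config$cohort$n_controls,
      n_timepoints = config$cohort$n_timepoints,
      coupling_gain_patients = config$cohort$coupling_gain_patients,
      simulate_tensors = config$cohort$simulate_tensors,
      voxel_mm = config$cohort$voxel_mm,
      seed = config$cohort$seed,
      bundles = lapply(config$cohort$bundle_list, as.character)
    ),
    tracking = unclass(config$tracking),
    ridge = config$ridge,
    negativity_mode = config$negativity_mode,
    binarize_threshold = config$binarize_threshold,
    structural_normalization = config$structural_normalization
  )
}

#' Validate pipeline input files
#'
#' Structural checks on a set of files: atlas TSV schema, connectivity-matrix
#' TSV symmetry and zero diagonal, behavioral TSV schema, tensor NIfTI
#' dimensionality. Problems are reported, not raised.
#'
#' @param paths Character vector of file paths; the check applied to each is
#'   inferred from its name (`atlas`, `behavior`, `tensor`/`.nii`, else
#'   matrix TSV).
#' @param atlas Optional `roi_atlas` for node-count checks on matrices.
#' @return Tibble with columns `file`, `check`, `pass`, `detail`.
#' @export
validate_inputs <- function(paths, atlas = NULL) {
  purrr::map_dfr(paths, function(p) {
    check <- if (grepl("atlas", basename(p))) "atlas_schema"
    else if (grepl("behavior", basename(p))) "behavior_schema"
    else if (grepl("\\.nii(\\.gz)?$", p)) "tensor_nifti"
    else "matrix_tsv"
    res <- tryCatch({
      if (check == "atlas_schema") {
        read_atlas(p)
        list(TRUE, "ok")
      } else if (check == "behavior_schema") {
        b <- read_behavior(p)
        need <- c("block", "trial_index", "cue", "trial_type", "rt_ms",
                  "correct")
        miss <- setdiff(need, names(b))
        if (length(miss) > 0L) {
          list(FALSE, paste("missing column(s):",
                            paste(miss, collapse = ", ")))
        } else list(TRUE, "ok")
      } else if (check == "tensor_nifti") {
        read_tensor_nifti(p)
        list(TRUE, "ok")
      } else {
        df <- readr::read_tsv(p, show_col_types = FALSE)
        m <- as.matrix(df[, -1, drop = FALSE])
        rownames(m) <- df[[1]]
        asym <- which(abs(m - t(m)) > 1e-8, arr.ind = TRUE)
        if (nrow(asym) > 0L) {
          list(FALSE, paste0("asymmetric at (", asym[1, 1], ",",
                             asym[1, 2], ")"))
        } else if (any(diag(m) != 0)) {
          list(FALSE, "non-zero diagonal")
        } else if (!is.null(atlas) && nrow(m) != nrow(atlas)) {
          list(FALSE, sprintf("expected %d nodes, found %d", nrow(atlas),
                              nrow(m)))
        } else list(TRUE, "ok")
      }
    }, error = function(e) list(FALSE, conditionMessage(e)))
    tibble::tibble(file = p, check = check, pass = res[[1]],
                   detail = res[[2]])
  })
}
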