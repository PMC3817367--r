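# Synthetic cohort assembly: per-subject time-series panels, tensor phantoms
# and behavioral tables with ground truth, under a single master seed.

#' Default planted fiber bundles
#'
#' Seven ROI pairs of the switching motor atlas that receive planted
#' white-matter bundles in the synthetic tensor phantoms. They form a
#' connected medial-frontal/prefrontal circuit (including a
#' pre-SMA/ACC/DLPFC triangle) plus a parietal link, so structural local
#' efficiency and betweenness are non-degenerate on the planted topology.
#'
#' @return List of length-2 character vectors of ROI names.
#' @export
default_bundles <- function() {
  list(c("pre_SMA", "ACC"),
       c("ACC", "DLPFC_R"),
       c("DLPFC_R", "pre_SMA"),
       c("pre_SMA", "PMd_L"),
       c("PMd_L", "SMA_proper"),
       c("DLPFC_R", "Insula_R"),
       c("Precuneus_R", "SPL_R"))
}

#' Cohort configuration
#'
#' Parameters of the synthetic cohort generator. Defaults reproduce the study
#' conditions the pipeline targets: 17 patients and 16 controls, a planted
#' multiplicative increase (gain 1.5) of the patients' off-diagonal precision
#' entries (hence higher functional coupling), six planted fiber bundles, and
#' Local-Global Task reaction-time/accuracy distributions with a larger
#' switch cost and lower accuracy in the patient group.
#'
#' @param n_patients,n_controls Group sizes (defaults 17 and 16).
#' @param n_timepoints Timepoints per functional panel (default 200).
#' @param coupling_gain_patients Off-diagonal precision multiplier for the
#'   patient group (default 1.5; > 0).
#' @param precision Control-group precision matrix (default
#'   [default_precision()]).
#' @param bundle_list Planted bundles: list of ROI name (or index) pairs.
#' @param rt_params Reaction-time distribution table (see
#'   [default_rt_params()]).
#' @param accuracy_params Per-group success probabilities (see
#'   [default_accuracy_params()]).
#' @param simulate_tensors Whether to build a tensor phantom per subject
#'   (default TRUE).
#' @param voxel_mm Phantom voxel size, mm (default 2).
#' @param bundle_keep_prob Per-subject probability that each planted bundle
#'   is present (default 0.85). Identical in both groups, so structural
#'   topology varies across subjects without a group effect; each subject's
#'   own planted adjacency is recorded with its record.
#' @param tube_radius_range Per-subject bundle radius, drawn uniformly from
#'   this mm range (default `c(3, 5)`).
#' @param seed Master seed; per-subject seeds are derived deterministically
#'   from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 17, n_controls = 16,
                          n_timepoints = 200, coupling_gain_patients = 1.5,
                          precision = default_precision(),
                          bundle_list = default_bundles(),
                          rt_params = default_rt_params(),
                          accuracy_params = default_accuracy_params(),
                          simulate_tensors = TRUE, voxel_mm = 2,
                          bundle_keep_prob = 0.85,
                          tube_radius_range = c(3, 5),
                          seed = 1) {
  stopifnot(n_patients >= 0, n_controls >= 0, n_patients + n_controls > 0,
            n_timepoints > 0, coupling_gain_patients > 0, voxel_mm > 0,
            bundle_keep_prob >= 0, bundle_keep_prob <= 1,
            length(tube_radius_range) == 2L, all(tube_radius_range > 0))
  if (any(accuracy_params$p_correct < 0) ||
      any(accuracy_params$p_correct > 1)) {
    stop("Accuracy probabilities must lie in [0, 1].", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 n_timepoints = as.integer(n_timepoints),
                 coupling_gain_patients = coupling_gain_patients,
                 precision = precision,
                 bundle_list = bundle_list,
                 rt_params = rt_params,
                 accuracy_params = accuracy_params,
                 simulate_tensors = isTRUE(simulate_tensors),
                 voxel_mm = voxel_mm,
                 bundle_keep_prob = bundle_keep_prob,
                 tube_radius_range = tube_radius_range,
                 seed = seed),
            class = "cohort_config")
}

resolve_bundles <- function(bundle_list, atlas) {
  lapply(bundle_list, function(b) {
    if (is.character(b)) {
      idx <- match(b, atlas$name)
      if (anyNA(idx)) {
        stop("Unknown ROI name(s) in bundle: ",
             paste(b[is.na(idx)], collapse = ", "), call. = FALSE)
      }
      idx
    } else {
      as.integer(b)
    }
  })
}

#' Generate a complete synthetic cohort
#'
#' Builds `n_patients + n_controls` subject records. Every subject draws a
#' time-series panel from the group precision matrix (patients: control
#' precision with off-diagonal entries scaled by `coupling_gain_patients`,
#' re-projected to positive definite), a Local-Global Task table, and -
#' optionally - a tensor phantom with the configured planted bundles.
#' Per-subject seeds are derived deterministically from the master seed, so
#' an identical configuration reproduces the cohort exactly.
#'
#' @param config A [cohort_config()].
#' @param atlas An `roi_atlas` (default [make_roi_atlas()]).
#' @return A `cohort` list with elements `subjects` (tibble with list-columns
#'   `timeseries`, `behavior`, `tensor`), `atlas`, `config`, and
#'   `ground_truth` (group precision matrices, their partial correlations,
#'   and the planted structural adjacency).
#' @export
make_cohort <- function(config = cohort_config(), atlas = make_roi_atlas()) {
  stopifnot(inherits(config, "cohort_config"))
  n_nodes <- nrow(atlas)
  stopifnot(nrow(config$precision) == n_nodes)
  prec <- list(control = config$precision,
               patient = patient_precision(config$precision,
                                           config$coupling_gain_patients))
  bundles <- resolve_bundles(config$bundle_list, atlas)
  grid <- phantom_grid(atlas, voxel_mm = config$voxel_mm)

  groups <- c(rep("patient", config$n_patients),
              rep("control", config$n_controls))
  n <- length(groups)
  subject_id <- sprintf("%s_%02d", ifelse(groups == "patient", "pat", "con"),
                        c(seq_len(config$n_patients),
                          seq_len(config$n_controls)))
  records <- purrr::map(seq_len(n), function(i) {
    s <- derive_seed(config$seed, i)
    panel <- simulate_timeseries_panel(atlas, prec[[groups[i]]],
                                       config$n_timepoints, seed = s)
    behavior <- simulate_behavior(groups[i], config, seed = s + 1)
    tensor <- NULL
    adjacency <- NULL
    if (config$simulate_tensors) {
      # anatomical variability: per-subject bundle presence and radius,
      # identical in distribution across groups
      withr_seed(s + 3)
      keep <- stats::runif(length(bundles)) < config$bundle_keep_prob
      radius <- stats::runif(1, config$tube_radius_range[1],
                             config$tube_radius_range[2])
      ph <- simulate_tensor_phantom(atlas, bundles[keep], grid,
                                    seed = s + 2,
                                    tube_radius_mm = radius)
      tensor <- ph$volume
      adjacency <- ph$adjacency
    }
    list(seed = s, timeseries = panel, behavior = behavior, tensor = tensor,
         adjacency = adjacency)
  })
  subjects <- tibble::tibble(
    subject_id = subject_id,
    group = groups,
    seed = purrr::map_dbl(records, "seed"),
    timeseries = purrr::map(records, "timeseries"),
    behavior = purrr::map(records, "behavior"),
    tensor = purrr::map(records, "tensor"),
    adjacency = purrr::map(records, "adjacency")
  )
  planted_adjacency <- matrix(0, n_nodes, n_nodes,
                              dimnames = list(atlas$name, atlas$name))
  for (b in bundles) {
    planted_adjacency[b[1], b[2]] <- 1
    planted_adjacency[b[2], b[1]] <- 1
  }
  structure(list(subjects = subjects,
                 atlas = atlas,
                 config = config,
                 ground_truth = list(
                   precision = prec,
                   partial = lapply(prec, precision_to_partial),
                   adjacency = planted_adjacency)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$subjects), " subjects (",
      sum(x$subjects$group == "patient"), " patient, ",
      sum(x$subjects$group == "control"), " control), ",
      nrow(x$atlas), " nodes\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes the atlas TSV, one time-series TSV and one behavioral TSV per
#' subject (plus a tensor NIfTI when present), and a JSON manifest listing
#' per-subject file paths, group, and seed.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  entries <- purrr::pmap(cohort$subjects, function(subject_id, group, seed,
                                                  timeseries, behavior,
                                                  tensor, ...) {
    ts_path <- file.path(dir, paste0(subject_id, "_timeseries.tsv"))
    readr::write_tsv(tibble::as_tibble(unclass(timeseries)), ts_path)
    beh_path <- file.path(dir, paste0(subject_id, "_behavior.tsv"))
    write_behavior(behavior, beh_path)
    entry <- list(subject_id = subject_id, group = group, seed = seed,
                  timeseries = basename(ts_path),
                  behavior = basename(beh_path))
    if (!is.null(tensor)) {
      tv_path <- file.path(dir, paste0(subject_id, "_tensor.nii.gz"))
      write_tensor_nifti(tensor, tv_path)
      entry$tensor <- basename(tv_path)
    }
    entry
  })
  manifest <- list(atlas = "atlas.tsv",
                   seed = cohort$config$seed,
                   n_subjects = nrow(cohort$subjects),
                   subjects = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
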