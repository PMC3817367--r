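# ROI atlas: node identity and order for every matrix in the pipeline.

# Fixture coordinates for the 22-node switching motor network. The node names
# and their count define the network; the coordinates shipped here are
# plausible MNI-space locations for each label, provided so that spatial
# stages (sphere extraction, phantoms, tractography) are runnable. They are a
# synthetic fixture, not published activation peaks; supply your own atlas
# table for real data.
.switching_motor_rois <- tibble::tribble(
  ~name,              ~x_mm, ~y_mm, ~z_mm,
  "pre_SMA",              0,    10,    52,
  "SMA_proper",          -2,    -8,    56,
  "ACC",                  2,    22,    36,
  "DLPFC_L",            -40,    34,    30,
  "DLPFC_R",             42,    34,    30,
  "IFG_BA44_L",         -52,    12,    14,
  "IFG_BA44_R",          54,    12,    14,
  "GP_L",               -18,    -2,    -2,
  "GP_R",                18,    -2,    -2,
  "Putamen_L",          -26,     2,     0,
  "Putamen_R",           26,     2,     0,
  "STN_L",              -10,   -14,    -6,
  "STN_R",               10,   -14,    -6,
  "Cerebellum_VI_L",    -26,   -60,   -26,
  "Cerebellum_VI_R",     28,   -60,   -26,
  "Precuneus_R",         10,   -62,    48,
  "PMd_L",              -28,    -8,    54,
  "PMv_L",              -52,     4,    34,
  "Insula_L",           -36,    16,     2,
  "Insula_R",            38,    16,     2,
  "SPL_R",               30,   -56,    58,
  "IPL_R",               44,   -44,    46
)

#' Build the 22-node switching motor network atlas
#'
#' Returns the ordered table of spherical regions of interest (ROIs) that
#' defines node identity and node order for every connectivity matrix in the
#' pipeline: pre-SMA, SMA-proper, anterior cingulate, bilateral DLPFC,
#' bilateral inferior frontal cortex (BA44), bilateral globus pallidus,
#' putamen and subthalamic region, bilateral cerebellar lobule VI, right
#' precuneus, left dorsal and ventral premotor cortex, bilateral insula, and
#' right superior and inferior parietal lobules.
#'
#' Node names and order are the contract; the shipped coordinates are a
#' documented synthetic fixture (plausible MNI locations), and any
#' user-supplied atlas read with [read_atlas()] can replace them.
#'
#' @param radius_mm Sphere radius in mm placed around each ROI center
#'   (default 10).
#' @return A tibble of class `roi_atlas` with columns `name`, `x_mm`, `y_mm`,
#'   `z_mm`, `radius_mm`; exactly 22 rows in fixed order.
#' @examples
#' atlas <- make_roi_atlas()
#' nrow(atlas)
#' @export
make_roi_atlas <- function(radius_mm = 10) {
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || !is.finite(radius_mm) ||
      radius_mm <= 0) {
    stop("`radius_mm` must be a single positive number.", call. = FALSE)
  }
  new_roi_atlas(dplyr::mutate(.switching_motor_rois, radius_mm = radius_mm))
}

new_roi_atlas <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("name", "x_mm", "y_mm", "z_mm", "radius_mm")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("Atlas is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$name)) {
    stop("Atlas ROI names must be unique.", call. = FALSE)
  }
  if (any(!is.finite(df$radius_mm)) || any(df$radius_mm <= 0)) {
    stop("Atlas radii must all be positive.", call. = FALSE)
  }
  class(df) <- c("roi_atlas", class(df))
  df
}

#' Read / write an ROI atlas table
#'
#' The on-disk format is a TSV with header
#' `name<TAB>x_mm<TAB>y_mm<TAB>z_mm<TAB>radius_mm`.
#'
#' @param path File path.
#' @return `read_atlas()` returns a `roi_atlas` tibble; `write_atlas()`
#'   returns `path` invisibly.
#' @export
read_atlas <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  new_roi_atlas(df)
}

#' @rdname read_atlas
#' @param atlas An `roi_atlas` tibble.
#' @export
write_atlas <- function(atlas, path) {
  readr::write_tsv(atlas, path)
  invisible(path)
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat("<roi_atlas> ", nrow(x), " spherical ROIs\n", sep = "")
  NextMethod()
}

atlas_centers <- function(atlas) {
  as.matrix(atlas[, c("x_mm", "y_mm", "z_mm")])
}
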