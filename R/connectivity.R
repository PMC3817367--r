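# Connectivity matrices: symmetric node x node matrices tagged with modality
# (functional | structural) and weighting (signed | weighted | binary), zero
# diagonal, ROI names on both margins.

#' Construct a connectivity matrix
#'
#' @param values Symmetric numeric node x node matrix; the diagonal is
#'   forced to zero (self-connections are excluded from all analyses).
#' @param modality `"functional"` or `"structural"`.
#' @param weighting `"signed"`, `"weighted"` or `"binary"`.
#' @param node_order Character vector of ROI names (defaults to existing
#'   dimnames).
#' @return A `connectivity_matrix` (numeric matrix with metadata attributes).
#' @export
connectivity_matrix <- function(values, modality, weighting,
                                node_order = rownames(values)) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  modality <- match.arg(modality, c("functional", "structural"))
  weighting <- match.arg(weighting, c("signed", "weighted", "binary"))
  check_symmetric(values, "values")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (is.null(node_order)) {
    node_order <- paste0("node_", seq_len(nrow(values)))
  }
  stopifnot(length(node_order) == nrow(values))
  dimnames(values) <- list(node_order, node_order)
  if (weighting == "binary" && !all(values %in% c(0, 1))) {
    stop("Binary matrices may contain only 0 and 1.", call. = FALSE)
  }
  if (weighting == "weighted" && any(values < 0)) {
    stop("Weighted matrices must be non-negative; use weighting = \"signed\" ",
         "for raw partial correlations.", call. = FALSE)
  }
  structure(values, modality = modality, weighting = weighting,
            node_order = node_order,
            class = c("connectivity_matrix", "matrix", "array"))
}

matrix_modality <- function(m) attr(m, "modality")
matrix_weighting <- function(m) attr(m, "weighting")

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", nrow(x), " x ", ncol(x), " ",
      matrix_modality(x), "/", matrix_weighting(x), "\n", sep = "")
  print(unclass_matrix(x), ...)
  invisible(x)
}

unclass_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x), dimnames = dimnames(x))
  x
}

#' Long (edge-list) view of a connectivity matrix
#'
#' @param x A `connectivity_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per unordered node pair: `from`, `to`,
#'   `weight`, `modality`, `weighting`.
#' @export
as_tibble.connectivity_matrix <- function(x, ...) {
  n <- nrow(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    from = rownames(x)[idx[, 1]],
    to = colnames(x)[idx[, 2]],
    weight = x[idx],
    modality = matrix_modality(x),
    weighting = matrix_weighting(x)
  )
}

#' Read / write a connectivity matrix as TSV
#'
#' TSV with ROI names as header row and first column; modality and weighting
#' are carried in the file name by convention and must be supplied on read.
#'
#' @param path File path.
#' @param modality,weighting Tags for the matrix being read.
#' @export
read_matrix_tsv <- function(path, modality, weighting) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  nodes <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- nodes
  connectivity_matrix(m, modality, weighting, node_order = nodes)
}

#' @rdname read_matrix_tsv
#' @param matrix A `connectivity_matrix`.
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- tibble::as_tibble(unclass_matrix(matrix), rownames = "node")
  readr::write_tsv(df, path)
  invisible(path)
}
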