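# Nodal graph metrics on connectivity matrices. Weighted metrics map edge
# weight w to length 1/w (Brain Connectivity Toolbox convention); binary
# matrices reduce to unit lengths. Shortest paths and betweenness are
# delegated to igraph (Dijkstra / Brandes); local efficiency composes them
# on neighbor-induced subgraphs.

as_graph <- function(m) {
  v <- unclass_matrix(m)
  if (any(v < 0)) {
    stop("Graph metrics require non-negative weights.", call. = FALSE)
  }
  g <- igraph::graph_from_adjacency_matrix(v, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}

edge_lengths <- function(g) 1 / igraph::E(g)$weight

#' Nodal degree
#'
#' Number of links (non-zero entries) at each node; for a weighted matrix
#' this equals the degree of its binarized version.
#'
#' @param matrix A `connectivity_matrix` (or plain symmetric matrix).
#' @return Named numeric vector, one value per node.
#' @export
nodal_degree <- function(matrix) {
  v <- unclass_matrix(as_cm(matrix))
  rowSums(v != 0)
}

#' Nodal strength
#'
#' Sum of edge weights at each node; equals degree on binary matrices.
#'
#' @inheritParams nodal_degree
#' @return Named numeric vector.
#' @export
nodal_strength <- function(matrix) {
  v <- unclass_matrix(as_cm(matrix))
  if (any(v < 0)) stop("Strength requires non-negative weights.",
                       call. = FALSE)
  rowSums(v)
}

#' All-pairs shortest path lengths
#'
#' Edge lengths are 1/weight (1 for binary edges); unreachable pairs are
#' `Inf`, the diagonal is 0.
#'
#' @inheritParams nodal_degree
#' @return Symmetric node x node matrix of path lengths.
#' @export
shortest_path_lengths <- function(matrix) {
  m <- as_cm(matrix)
  g <- as_graph(m)
  d <- igraph::distances(g, weights = edge_lengths(g), algorithm = "dijkstra")
  d
}

#' Nodal local efficiency
#'
#' For node v, the global efficiency (mean of 1/length over ordered pairs,
#' 0 for unreachable pairs) of the subgraph induced by v's neighbors with v
#' removed; nodes with fewer than two neighbors score 0. Weighted inputs use
#' 1/weight edge lengths inside the neighborhood subgraph.
#'
#' @inheritParams nodal_degree
#' @return Named numeric vector.
#' @export
local_efficiency <- function(matrix) {
  m <- as_cm(matrix)
  v <- unclass_matrix(m)
  n <- nrow(v)
  out <- stats::setNames(numeric(n), rownames(v))
  for (node in seq_len(n)) {
    nb <- which(v[node, ] != 0)
    if (length(nb) < 2L) next
    sub <- v[nb, nb, drop = FALSE]
    d <- shortest_path_lengths(connectivity_matrix(
      sub, matrix_modality(m), matrix_weighting(m),
      node_order = rownames(v)[nb]))
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    out[node] <- sum(inv) / (length(nb) * (length(nb) - 1L))
  }
  out
}

#' Global efficiency of a whole matrix
#'
#' Mean of 1/shortest-path-length over ordered node pairs (0 for unreachable
#' pairs).
#'
#' @inheritParams nodal_degree
#' @return Scalar.
#' @export
global_efficiency <- function(matrix) {
  d <- shortest_path_lengths(matrix)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(d)
  sum(inv) / (n * (n - 1L))
}

#' Nodal betweenness centrality
#'
#' Sum over unordered source-target pairs of the fraction of shortest paths
#' passing through the node (Brandes' algorithm with 1/weight lengths,
#' exact tie counting, unnormalized).
#'
#' @inheritParams nodal_degree
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(matrix) {
  m <- as_cm(matrix)
  g <- as_graph(m)
  b <- igraph::betweenness(g, directed = FALSE, weights = edge_lengths(g))
  stats::setNames(as.numeric(b), rownames(m))
}

#' Network-level summary of a nodal metric
#'
#' Arithmetic mean over nodes, the single per-subject value used in group
#' comparisons.
#'
#' @param nodal Non-empty numeric vector of nodal values.
#' @return Scalar mean.
#' @export
network_summary <- function(nodal) {
  if (length(nodal) == 0L) stop("Empty metric vector.", call. = FALSE)
  mean(nodal)
}

#' All nodal metrics of one network
#'
#' @param matrix A `connectivity_matrix`.
#' @return A tibble with columns `node`, `degree`, `strength`,
#'   `local_efficiency`, `betweenness`.
#' @export
nodal_metrics <- function(matrix) {
  m <- as_cm(matrix)
  tibble::tibble(
    node = attr(m, "node_order"),
    degree = as.numeric(nodal_degree(m)),
    strength = as.numeric(nodal_strength(m)),
    local_efficiency = as.numeric(local_efficiency(m)),
    betweenness = as.numeric(betweenness_centrality(m))
  )
}

#' Identify hubs by the 2-SD betweenness rule
#'
#' Averages nodal betweenness across subjects, then flags as hubs the nodes
#' whose mean betweenness exceeds the across-node mean by more than two
#' across-node standard deviations (n-1 denominator, strict inequality).
#'
#' @param per_subject_betweenness Subject x node numeric matrix (or a tibble
#'   with columns `subject_id`, `node`, `betweenness` in long form).
#' @return A `hub_report` tibble with columns `node`, `mean_betweenness`,
#'   `is_hub`; the threshold is stored in the `threshold` attribute.
#' @export
identify_hubs <- function(per_subject_betweenness) {
  b <- per_subject_betweenness
  if (is.data.frame(b)) {
    b <- long_to_wide_betweenness(b)
  }
  stopifnot(is.matrix(b))
  if (ncol(b) < 2L) stop("At least two nodes are required.", call. = FALSE)
  if (nrow(b) < 2L) stop("At least two subjects are required.", call. = FALSE)
  node_mean <- colMeans(b)
  thr <- mean(node_mean) + 2 * stats::sd(node_mean)
  nodes <- colnames(b)
  if (is.null(nodes)) nodes <- paste0("node_", seq_along(node_mean))
  out <- tibble::tibble(node = nodes,
                        mean_betweenness = as.numeric(node_mean),
                        is_hub = unname(node_mean > thr))
  attr(out, "threshold") <- thr
  class(out) <- c("hub_report", class(out))
  out
}

long_to_wide_betweenness <- function(df) {
  stopifnot(all(c("subject_id", "node", "betweenness") %in% names(df)))
  wide <- tidyr::pivot_wider(df[, c("subject_id", "node", "betweenness")],
                             names_from = "node",
                             values_from = "betweenness")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$subject_id
  m
}

# accept plain symmetric matrices anywhere a connectivity matrix is expected
as_cm <- function(matrix) {
  if (inherits(matrix, "connectivity_matrix")) return(matrix)
  stopifnot(is.matrix(matrix))
  weighting <- if (all(matrix %in% c(0, 1))) "binary" else "weighted"
  connectivity_matrix(matrix, "functional", weighting)
}
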