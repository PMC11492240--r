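# Shortest-path analysis of residue networks: all-pairs Dijkstra, per-residue
# average path length, normalisation, and the peak-to-mean ratio used to flag
# poorly connected candidate mutation sites.

#' All-pairs shortest path lengths (Dijkstra)
#'
#' @param network A [resnet()]; all finite edge costs must be positive.
#' @return A `path_matrix`: `N x N` matrix of shortest-path costs in the cost
#'   units of the source network, `Inf` where no path exists, zero diagonal.
#'   Entry `(i, j)` is the cost of the cheapest path *from* `i` *to* `j`.
#' @export
all_pairs_shortest_paths <- function(network) {
  stopifnot(inherits(network, "resnet"))
  costs <- network$costs
  if (any(costs[is.finite(costs)] <= 0)) {
    stop_validation("shortest paths require positive edge costs")
  }
  adj <- costs
  adj[!is.finite(adj)] <- 0              # igraph: 0 = no edge
  g <- igraph::graph_from_adjacency_matrix(
    adj, mode = if (network$directed) "directed" else "undirected",
    weighted = TRUE, diag = FALSE
  )
  d <- igraph::distances(g, mode = "out", algorithm = "dijkstra")
  dimnames(d) <- list(network$node_labels, network$node_labels)
  structure(d, class = c("path_matrix", "matrix", "array"),
            directed = network$directed, semantics = network$semantics)
}

#' Per-residue average shortest-path length profile
#'
#' For residue `j` the profile value is the mean over all other residues `i`
#' of the shortest-path length from `i` to `j` (the column average; for
#' undirected networks rows and columns agree). The lower the value, the
#' better connected the residue — well-connected residues reach the rest of
#' the structure cheaply, and perturbations there are expected to be more
#' disruptive. Unreachable pairs are excluded from the mean and counted.
#'
#' @param paths A `path_matrix` from [all_pairs_shortest_paths()].
#' @param direction `"in"` (column average, default) or `"out"` (row average),
#'   meaningful only for directed networks.
#' @param max_unreachable_frac Error if more than this fraction of ordered
#'   off-diagonal pairs is unreachable; dense residue networks are connected,
#'   so widespread unreachability signals a degenerate input.
#' @return A `residue_profile` tibble with columns `index` (0-based ordinal),
#'   `label`, `value`, `unreachable_count`; residues unreachable from every
#'   other residue get `Inf` with a warning.
#' @export
average_shortest_path_profile <- function(paths, direction = c("in", "out"),
                                          max_unreachable_frac = 0.1) {
  stopifnot(inherits(paths, "path_matrix"))
  direction <- match.arg(direction)
  d <- unclass(paths)
  n <- nrow(d)
  if (direction == "out") d <- t(d)
  diag(d) <- NA                          # self-distances excluded from the mean
  unreachable <- apply(d, 2, function(col) sum(is.infinite(col)))
  total_unreachable <- sum(unreachable)
  if (n > 1L && total_unreachable > max_unreachable_frac * n * (n - 1L)) {
    stop_validation(sprintf(
      "%d of %d residue pairs are unreachable (> %.0f%%): network too disconnected for a path profile",
      total_unreachable, n * (n - 1L), 100 * max_unreachable_frac))
  }
  vals <- apply(d, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) == 0L) Inf else mean(col)
  })
  if (any(is.infinite(vals))) {
    warn(sprintf("%d residue(s) unreachable from all others; profile value Inf",
                 sum(is.infinite(vals))))
  }
  out <- tibble(
    index = seq_len(n) - 1L,
    label = colnames(paths) %||% as.character(seq_len(n)),
    value = unname(vals),
    unreachable_count = unname(as.integer(unreachable))
  )
  attr(out, "normalized") <- FALSE
  attr(out, "semantics") <- attr(paths, "semantics")
  attr(out, "direction") <- direction
  class(out) <- c("residue_profile", class(out))
  out
}

#' Normalise a residue profile
#'
#' Profiles from different network types carry different cost units; to be
#' comparable they are normalised. The `mean` method divides by the mean of
#' the finite values (so the normalised profile has mean 1 and the
#' peak-to-mean ratio is unchanged); `minmax` maps the finite values onto
#' `[0, 1]`.
#'
#' @param profile A `residue_profile`.
#' @param method `"mean"` or `"minmax"`.
#' @return The profile with an added `normalized_value` column and attributes
#'   `normalized = TRUE`, `norm_method`.
#' @export
normalize_profile <- function(profile, method = c("mean", "minmax")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "residue_profile"))
  v <- profile$value
  fin <- v[is.finite(v)]
  if (length(fin) == 0L) stop_validation("profile has no finite values to normalise")
  if (method == "mean") {
    if (mean(fin) == 0) stop_validation("profile mean is zero; cannot mean-normalise")
    nv <- v / mean(fin)
  } else {
    if (max(fin) == min(fin)) {
      stop_validation("degenerate profile spread: min-max normalisation undefined")
    }
    nv <- (v - min(fin)) / (max(fin) - min(fin))
  }
  profile$normalized_value <- nv
  attr(profile, "normalized") <- TRUE
  attr(profile, "norm_method") <- method
  profile
}

#' Peak-to-mean ratio of a residue's average path length
#'
#' The profile value of one residue divided by the mean over all residues
#' (finite values). Ratios well above 1 flag residues whose connectivity
#' stands out from the protein average — in the energy network this is the
#' signature of candidate mutation sites; ratios below 1 mark well-connected
#' residues such as catalytic ones. Invariant to uniform edge-cost scaling and
#' to mean normalisation.
#'
#' @param profile A `residue_profile`.
#' @param residue_label Residue label (string) or 0-based ordinal.
#' @return Dimensionless scalar.
#' @export
peak_to_average_ratio <- function(profile, residue_label) {
  stopifnot(inherits(profile, "residue_profile"))
  if (is.numeric(residue_label)) {
    hit <- which(profile$index == as.integer(residue_label))
  } else {
    hit <- which(profile$label == as.character(residue_label))
  }
  if (length(hit) == 0L) {
    stop_validation(sprintf("no residue with label '%s' in profile", residue_label))
  }
  fin <- profile$value[is.finite(profile$value)]
  profile$value[hit[1L]] / mean(fin)
}
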