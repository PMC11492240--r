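# broom-style tidiers: every result container tidies to a long tibble so the
# outputs drop straight into dplyr/ggplot2 workflows.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a pair energy matrix into a long pair table
#'
#' @param x A [pair_energy_matrix()].
#' @param keep_zero Keep non-interacting (zero) pairs.
#' @param ... Unused.
#' @return Tibble with columns `res_a`, `res_b` (labels, upper triangle) and
#'   `mean_abs_energy_kcal_mol`.
#' @method tidy pair_energy_matrix
#' @export
tidy.pair_energy_matrix <- function(x, keep_zero = FALSE, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  out <- tibble(
    res_a = rownames(m)[idx[, 1]],
    res_b = colnames(m)[idx[, 2]],
    mean_abs_energy_kcal_mol = m[idx]
  )
  if (!keep_zero) out <- dplyr::filter(out, .data$mean_abs_energy_kcal_mol > 0)
  out
}

#' One-row summary of a pair energy matrix
#' @param x A [pair_energy_matrix()].
#' @param ... Unused.
#' @return Tibble with residue count, interacting pair count, frame count and
#'   the mean absolute interaction energy over interacting pairs.
#' @method glance pair_energy_matrix
#' @export
glance.pair_energy_matrix <- function(x, ...) {
  up <- x[upper.tri(x)]
  tibble(
    n_residues = nrow(x),
    n_pairs = sum(up > 0),
    n_frames = attr(x, "n_frames"),
    mean_abs_energy_kcal_mol = mean_abs_interaction_energy(x)
  )
}

#' Tidy a residue network into an edge list
#' @param x A [resnet()].
#' @param ... Unused.
#' @return Tibble with `source_label`, `target_label`, `cost` (undirected
#'   edges listed once, `source` the lower ordinal).
#' @method tidy resnet
#' @export
tidy.resnet <- function(x, ...) {
  sel <- if (x$directed) is.finite(x$costs) else is.finite(x$costs) & upper.tri(x$costs)
  idx <- which(sel, arr.ind = TRUE)
  tibble(
    source_label = x$node_labels[idx[, 1]],
    target_label = x$node_labels[idx[, 2]],
    cost = x$costs[idx]
  )
}

#' One-row summary of a residue network
#' @param x A [resnet()].
#' @param ... Unused.
#' @return Tibble with node/edge counts, directedness, semantics.
#' @method glance resnet
#' @export
glance.resnet <- function(x, ...) {
  ne <- sum(is.finite(x$costs))
  tibble(
    n_nodes = x$n_nodes,
    n_edges = if (x$directed) ne else ne %/% 2L,
    directed = x$directed,
    semantics = x$semantics
  )
}

#' Tidy a shortest-path matrix into a long table
#' @param x A `path_matrix`.
#' @param ... Unused.
#' @return Tibble with `from`, `to`, `path_length` for all ordered pairs.
#' @method tidy path_matrix
#' @export
tidy.path_matrix <- function(x, ...) {
  m <- unclass(x)
  idx <- which(row(m) != col(m), arr.ind = TRUE)
  tibble(
    from = rownames(m)[idx[, 1]],
    to = colnames(m)[idx[, 2]],
    path_length = m[idx]
  )
}

#' One-row summary of a residue profile
#' @param x A `residue_profile`.
#' @param ... Unused.
#' @return Tibble with residue count, profile mean/min/max over finite
#'   values, the best-connected residue label, and network semantics.
#' @method glance residue_profile
#' @export
glance.residue_profile <- function(x, ...) {
  fin <- x$value[is.finite(x$value)]
  tibble(
    n_residues = nrow(x),
    mean_path_length = mean(fin),
    min_path_length = min(fin),
    max_path_length = max(fin),
    best_connected = x$label[which.min(x$value)],
    semantics = attr(x, "semantics") %||% NA_character_
  )
}

#' One-row summary of an aligned profile comparison
#' @param x An `aligned_comparison`.
#' @param ... Unused.
#' @return Tibble with aligned column count, pair count, and the mean
#'   absolute normalised difference over the aligned pairs.
#' @method glance aligned_comparison
#' @export
glance.aligned_comparison <- function(x, ...) {
  tibble(
    n_columns = nrow(x),
    n_pairs = sum(!is.na(x$diff)),
    mean_abs_difference = attr(x, "mean_abs_difference")
  )
}
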