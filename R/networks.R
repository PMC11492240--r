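# Residue network builders. A network is an N x N edge-cost matrix (Inf where
# no edge, no self edges) plus residue labels, a directedness flag, and a
# semantics tag recording what the costs mean:
#   binary         - unit costs on centre-of-mass contacts
#   com_distance   - averaged centre-of-mass distance (Angstrom)
#   inv_connectivity - inverse atom-contact connectivity (directed)
#   inv_energy     - inverse mean |E| (mol/kcal)

#' Construct a residue network
#'
#' Low-level constructor; the `build_*` functions are the usual entry points.
#'
#' @param costs `N x N` numeric matrix of edge costs; `Inf` (or `NA`) marks an
#'   absent edge. Finite costs must be positive (shortest-path semantics).
#' @param labels Residue labels (defaults to the matrix dimnames).
#' @param directed Logical; undirected networks must have symmetric costs.
#' @param semantics One of `"binary"`, `"com_distance"`, `"inv_connectivity"`,
#'   `"inv_energy"`, `"synthetic"`.
#' @return A `resnet` object.
#' @export
resnet <- function(costs, labels = NULL,
                   directed = FALSE,
                   semantics = c("binary", "com_distance", "inv_connectivity",
                                 "inv_energy", "synthetic")) {
  semantics <- match.arg(semantics)
  costs <- as.matrix(costs)
  if (nrow(costs) != ncol(costs)) stop_validation("cost matrix must be square")
  costs[is.na(costs)] <- Inf
  diag(costs) <- Inf                     # no self-edges
  if (any(costs[is.finite(costs)] <= 0)) {
    stop_validation("finite edge costs must be positive")
  }
  if (!directed && !identical(costs, t(costs))) {
    stop_validation("undirected network requires a symmetric cost matrix")
  }
  if (is.null(labels)) labels <- rownames(costs) %||% as.character(seq_len(nrow(costs)))
  dimnames(costs) <- list(labels, labels)
  structure(list(n_nodes = nrow(costs), node_labels = labels, costs = costs,
                 directed = directed, semantics = semantics),
            class = "resnet")
}

#' @export
print.resnet <- function(x, ...) {
  ne <- sum(is.finite(x$costs))
  if (!x$directed) ne <- ne / 2
  cat(sprintf("<resnet> %d nodes, %d %s edges, semantics '%s'\n",
              x$n_nodes, ne, if (x$directed) "directed" else "undirected", x$semantics))
  invisible(x)
}

#' Centre-of-mass residue contact network
#'
#' The mass-weighted centre of mass of every residue is computed in each
#' frame; pair distances are averaged over frames and thresholded: pairs with
#' an averaged distance at or below `cutoff` (boundary inclusive) get an edge,
#' with cost 1 in `binary` mode or the averaged distance itself in `weighted`
#' mode.
#'
#' @param topology A [topology()] (masses required).
#' @param trajectory A trajectory over that topology.
#' @param cutoff Centre-of-mass distance threshold, Angstrom.
#' @param mode `"binary"` or `"weighted"`.
#' @return An undirected [resnet()].
#' @export
build_residue_com_network <- function(topology, trajectory, cutoff = 8,
                                      mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  nres <- n_residues(topology)
  nf <- n_frames(trajectory)
  acc <- matrix(0, nres, nres)
  rr <- topology$res_rows
  mass <- topology$atoms$mass
  for (f in seq_len(nf)) {
    xyz <- trajectory$coords[, , f]
    com <- t(vapply(rr, function(rows) {
      w <- mass[rows]
      colSums(xyz[rows, , drop = FALSE] * w) / sum(w)
    }, numeric(3)))
    acc <- acc + as.matrix(stats::dist(com))
  }
  avg <- acc / nf
  costs <- matrix(Inf, nres, nres)
  edge <- avg <= cutoff
  costs[edge] <- if (mode == "binary") 1 else avg[edge]
  resnet(costs, labels = topology$residues$label, directed = FALSE,
         semantics = if (mode == "binary") "binary" else "com_distance")
}

#' Directed atom-contact residue network
#'
#' Built from a single snapshot (conventionally the final one). For residues
#' A (I atoms) and B (J atoms), `c` counts atom pairs strictly closer than
#' `atom_cutoff`; the connectivity A -> B is `c / I` (normalised by the source
#' residue's atom count) and B -> A is `c / J`, so the network is directed
#' whenever I != J. Edge costs are the inverse connectivities, so better
#' connected pairs are cheaper to traverse; `c = 0` means no edge.
#'
#' @param topology A [topology()].
#' @param frame A `frame` or coordinate matrix (use [get_frame()] for the
#'   final snapshot of a trajectory).
#' @param atom_cutoff Contact distance threshold, Angstrom (strict `<`).
#' @return A directed [resnet()].
#' @export
build_atom_contact_network <- function(topology, frame, atom_cutoff = 3.5) {
  xyz <- frame_coords(frame)
  nres <- n_residues(topology)
  rr <- topology$res_rows
  dall <- as.matrix(stats::dist(xyz))
  costs <- matrix(Inf, nres, nres)
  nat <- vapply(rr, length, 1L)
  for (a in seq_len(nres - 1L)) {
    for (b in (a + 1L):nres) {
      cc <- sum(dall[rr[[a]], rr[[b]]] < atom_cutoff)
      if (cc > 0L) {
        costs[a, b] <- nat[a] / cc       # 1 / (c / I)
        costs[b, a] <- nat[b] / cc       # 1 / (c / J)
      }
    }
  }
  resnet(costs, labels = topology$residues$label, directed = TRUE,
         semantics = "inv_connectivity")
}

#' Interaction-energy residue network
#'
#' Each residue pair with trajectory-mean absolute interaction energy above
#' `min_energy` gets an undirected edge of cost `1 / mean|E|`, so strongly
#' interacting residues are close in the network regardless of whether the
#' interaction is attractive or repulsive. No geometric threshold enters:
#' distance participates only through the physics of the energy itself.
#'
#' @param matrix A [pair_energy_matrix()].
#' @param min_energy Edges below this mean |E| (kcal/mol) are dropped; the
#'   small default suppresses numerically-zero interactions whose inverse
#'   would be float noise.
#' @return An undirected [resnet()].
#' @export
build_energy_network <- function(matrix, min_energy = 1e-8) {
  m <- unclass(as.matrix(matrix))
  costs <- ifelse(m > min_energy, 1 / m, Inf)
  resnet(costs, labels = rownames(m), directed = FALSE, semantics = "inv_energy")
}
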