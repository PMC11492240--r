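#' Assemble a molecular topology
#'
#' A topology bundles the per-atom force-field information (partial charge,
#' Lennard-Jones well depth and half minimum-energy distance, mass) with the
#' residue grouping and the covalent bond graph. The bond graph is used to
#' classify nonbonded exclusions: atom pairs separated by one bond (1-2) or two
#' bonds (1-3) are excluded from nonbonded sums, pairs separated by three bonds
#' (1-4) receive special treatment (optional Lennard-Jones overrides, scalable
#' electrostatics).
#'
#' @param atoms Data frame with columns `atom_id` (integer, unique), `name`,
#'   `type`, `residue_key`, `charge` (elementary charges), `lj_eps` (kcal/mol,
#'   well depth, non-negative), `lj_rmin_half` (Angstrom), `mass` (amu, > 0).
#'   Optional columns `lj_eps14`, `lj_rmin_half14` hold 1-4 overrides.
#' @param residues Data frame with columns `index` (0-based, contiguous),
#'   `key`, `label` (author residue number as a string, preserved verbatim),
#'   `name` (three-letter code), `chain`.
#' @param bonds Data frame with integer columns `i`, `j` holding bonded
#'   `atom_id` pairs. May have zero rows.
#' @return A `topology` object.
#' @export
topology <- function(atoms, residues, bonds = NULL) {
  atoms <- as_tibble(atoms)
  residues <- as_tibble(residues)
  if (is.null(bonds)) bonds <- tibble(i = integer(), j = integer())
  bonds <- as_tibble(bonds)

  if (nrow(residues) < 1L) stop_validation("topology needs at least one residue")
  if (anyDuplicated(atoms$atom_id)) stop_validation("atom_id values must be unique")
  if (!all(residues$index == seq_len(nrow(residues)) - 1L)) {
    stop_validation("residue ordinals must be contiguous 0..N-1 in file order")
  }
  if (!all(atoms$residue_key %in% residues$key)) {
    stop_validation("every atom must belong to a known residue")
  }
  if (any(!is.na(atoms$lj_eps) & atoms$lj_eps < 0)) {
    stop_validation("lj_eps must be non-negative (well depth)")
  }
  if (any(!is.na(atoms$mass) & atoms$mass <= 0)) stop_validation("atom masses must be positive")
  if (nrow(bonds) > 0L) {
    known <- c(bonds$i, bonds$j) %in% atoms$atom_id
    if (!all(known)) stop_validation("bond endpoints must be known atom ids")
  }
  if (!"lj_eps14" %in% names(atoms)) atoms$lj_eps14 <- NA_real_
  if (!"lj_rmin_half14" %in% names(atoms)) atoms$lj_rmin_half14 <- NA_real_

  # row index of each atom_id, and atom rows per residue, precomputed once
  row_of <- setNames(seq_len(nrow(atoms)), as.character(atoms$atom_id))
  res_rows <- lapply(residues$key, function(k) unname(which(atoms$residue_key == k)))
  if (any(vapply(res_rows, length, 1L) == 0L)) {
    stop_validation("every residue must contain at least one atom")
  }

  structure(
    list(
      atoms = atoms, residues = residues, bonds = bonds,
      exclusions = bond_path_classes(atoms$atom_id, bonds),
      res_rows = res_rows, row_of = row_of
    ),
    class = "topology"
  )
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf(
    "<topology> %d residues, %d atoms, %d bonds, %d excluded/special pairs\n",
    nrow(x$residues), nrow(x$atoms), nrow(x$bonds), nrow(x$exclusions)
  ))
  invisible(x)
}

#' Number of residues in a topology
#' @param topology A [topology()] object.
#' @return Integer residue count.
#' @export
n_residues <- function(topology) nrow(topology$residues)

# Classify atom pairs by shortest bond-path length: 1 -> 1-2, 2 -> 1-3,
# 3 -> 1-4. Breadth-first search to depth 3 from every atom; pairs further
# apart get full nonbonded treatment and are not listed.
bond_path_classes <- function(atom_ids, bonds) {
  n <- length(atom_ids)
  if (nrow(bonds) == 0L || n == 0L) {
    return(tibble(i = integer(), j = integer(), class = integer()))
  }
  idx <- setNames(seq_len(n), as.character(atom_ids))
  bi <- idx[as.character(bonds$i)]
  bj <- idx[as.character(bonds$j)]
  adj <- vector("list", n)
  for (k in seq_along(bi)) {
    adj[[bi[k]]] <- c(adj[[bi[k]]], bj[k])
    adj[[bj[k]]] <- c(adj[[bj[k]]], bi[k])
  }
  out_i <- integer(0); out_j <- integer(0); out_c <- integer(0)
  for (s in seq_len(n)) {
    dist <- rep.int(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    for (d in 1:3) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[!is.na(nxt) & is.na(dist[nxt])]
      if (length(nxt) == 0L) break
      dist[nxt] <- d
      frontier <- nxt
    }
    reach <- which(!is.na(dist) & dist > 0L & seq_len(n) > s)
    out_i <- c(out_i, rep.int(s, length(reach)))
    out_j <- c(out_j, reach)
    out_c <- c(out_c, dist[reach])
  }
  tibble(
    i = atom_ids[out_i], j = atom_ids[out_j], class = out_c
  )
}

# lookup residue ordinal from a 0-based index or a label string
resolve_residue <- function(topology, res) {
  rs <- topology$residues
  if (is.numeric(res)) {
    if (!res %in% rs$index) stop_validation(sprintf("no residue with ordinal %s", res))
    return(as.integer(res))
  }
  hit <- which(rs$label == as.character(res))
  if (length(hit) == 0L) {
    stop_validation(sprintf("no residue with label '%s'", res))
  }
  rs$index[hit[1L]]
}

# standard 3- to 1-letter amino acid code table
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", HSD = "H", HSE = "H", HSP = "H",
  ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' Extract the one-letter amino-acid sequence of a topology
#'
#' Residues are emitted in ordinal order; any residue name outside the twenty
#' standard amino acids (plus CHARMM histidine variants) maps to `"X"` unless
#' an explicit mapping is supplied, so that modified residues never acquire a
#' silent chemical identity.
#'
#' @param topology A [topology()] object.
#' @param modified A named character vector of opt-in extra mappings, e.g.
#'   `c(MSE = "M")` to treat selenomethionine as methionine.
#' @return A single string of length-`N` one-letter codes.
#' @export
extract_sequence <- function(topology, modified = NULL) {
  tab <- AA_THREE_TO_ONE
  if (!is.null(modified)) tab[names(modified)] <- unname(modified)
  codes <- tab[toupper(topology$residues$name)]
  codes[is.na(codes)] <- "X"
  paste(codes, collapse = "")
}
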