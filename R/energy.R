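# Pairwise residue nonbonded interaction energies.
#
# The interaction between two residues is the sum over their atom pairs of a
# 12-6 Lennard-Jones term and a Coulomb term, in kcal/mol with distances in
# Angstrom and charges in elementary charges. The van der Waals term is taken
# smoothly to zero between switch_on and cutoff with the CHARMM switching
# polynomial; electrostatics use a selectable cutoff scheme (shifted by
# default) because a per-pair decomposition of a lattice sum does not exist.
# Atom pairs within one or two bonds of each other are excluded; pairs three
# bonds apart (1-4) take optional Lennard-Jones overrides and a scalable
# Coulomb factor.

#' Nonbonded evaluation parameters
#'
#' @param cutoff Nonbonded cutoff, Angstrom. Both terms are identically zero
#'   at and beyond it.
#' @param switch_on Distance where van der Waals switching begins, Angstrom
#'   (must be below `cutoff`).
#' @param coulomb_const Coulomb constant in kcal * Angstrom / (mol * e^2);
#'   the CHARMM/NAMD value 332.0636 collapses the vacuum-permittivity prefactor
#'   into these units.
#' @param dielectric Relative dielectric constant.
#' @param elec_scheme Electrostatic cutoff scheme: `"shifted"` multiplies by
#'   `(1 - (r/cutoff)^2)^2`, `"switched"` applies the same switching polynomial
#'   as van der Waals, `"truncated"` cuts abruptly.
#' @param scale14_elec Scaling of 1-4 electrostatics (1.0 per CHARMM36).
#' @return A `nb_params` list.
#' @export
nb_params <- function(cutoff = 12, switch_on = 10, coulomb_const = 332.0636,
                      dielectric = 1, elec_scheme = c("shifted", "switched", "truncated"),
                      scale14_elec = 1) {
  elec_scheme <- match.arg(elec_scheme)
  if (!(switch_on > 0 && switch_on < cutoff)) {
    stop_validation("need 0 < switch_on < cutoff")
  }
  if (coulomb_const <= 0) stop_validation("coulomb_const must be positive")
  structure(
    list(cutoff = cutoff, switch_on = switch_on, coulomb_const = coulomb_const,
         dielectric = dielectric, elec_scheme = elec_scheme,
         scale14_elec = scale14_elec),
    class = "nb_params"
  )
}

#' CHARMM van der Waals switching factor
#'
#' `1` at or below `switch_on`, `0` at or beyond `cutoff`, and in between the
#' polynomial `(rc^2 - r^2)^2 (rc^2 + 2 r^2 - 3 ron^2) / (rc^2 - ron^2)^3`,
#' which is C1-continuous at both ends.
#'
#' @param r Distance(s), Angstrom.
#' @param params [nb_params()].
#' @return Dimensionless factor(s) in `[0, 1]`.
#' @export
vdw_switch_factor <- function(r, params = nb_params()) {
  rc2 <- params$cutoff^2
  ron2 <- params$switch_on^2
  r2 <- r^2
  s <- (rc2 - r2)^2 * (rc2 + 2 * r2 - 3 * ron2) / (rc2 - ron2)^3
  out <- ifelse(r <= params$switch_on, 1, ifelse(r >= params$cutoff, 0, s))
  out
}

#' Lennard-Jones pair energy with switching
#'
#' `eps_ij * ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)` times the van der Waals
#' switching factor: the minimum is `-eps_ij` at `r = rmin_ij`, the zero
#' crossing at `rmin_ij * 2^(-1/6)`, and the value is exactly zero from the
#' cutoff outward.
#'
#' @param eps_ij Pair well depth, kcal/mol (combined as the geometric mean of
#'   the atomic well depths).
#' @param rmin_ij Pair minimum-energy distance, Angstrom (sum of atomic
#'   `rmin/2` values).
#' @param r Distance(s), Angstrom, > 0.
#' @param params [nb_params()].
#' @return Energy, kcal/mol.
#' @export
lj_pair_energy <- function(eps_ij, rmin_ij, r, params = nb_params()) {
  if (any(r <= 0)) stop_validation("Lennard-Jones energy is singular at r <= 0")
  sr6 <- (rmin_ij / r)^6
  e <- eps_ij * (sr6^2 - 2 * sr6) * vdw_switch_factor(r, params)
  ifelse(r >= params$cutoff, 0, e)
}

#' Coulomb pair energy under a cutoff scheme
#'
#' `coulomb_const * qi * qj / (dielectric * r)` modified by the configured
#' cutoff scheme and exactly zero at and beyond the cutoff.
#'
#' @param qi,qj Partial charges, elementary charges.
#' @param r Distance(s), Angstrom, > 0.
#' @param params [nb_params()].
#' @return Energy, kcal/mol.
#' @export
elec_pair_energy <- function(qi, qj, r, params = nb_params()) {
  if (any(r <= 0)) stop_validation("Coulomb energy is singular at r <= 0")
  base <- params$coulomb_const * qi * qj / (params$dielectric * r)
  mod <- switch(params$elec_scheme,
    shifted = (1 - (r / params$cutoff)^2)^2,
    switched = vdw_switch_factor(r, params),
    truncated = 1
  )
  ifelse(r >= params$cutoff, 0, base * mod)
}

# Precompute everything about a residue pair that does not depend on the
# frame: atom row indices, combined LJ parameters, charge products, and the
# exclusion / 1-4 masks. pair_energy_matrix reuses one context across frames.
pair_context <- function(topology, ia, ib, params) {
  at <- topology$atoms
  rows_a <- topology$res_rows[[ia + 1L]]
  rows_b <- topology$res_rows[[ib + 1L]]
  need <- c(rows_a, rows_b)
  if (any(is.na(at$charge[need])) || any(is.na(at$lj_eps[need])) ||
      any(is.na(at$lj_rmin_half[need]))) {
    stop_validation(sprintf(
      "missing charge or Lennard-Jones parameters for residue pair (%s, %s); load a parameterised topology",
      topology$residues$label[ia + 1L], topology$residues$label[ib + 1L]))
  }
  na <- length(rows_a); nb <- length(rows_b)
  A <- rep(rows_a, times = nb)           # column-major order of the na x nb grid
  B <- rep(rows_b, each = na)

  cls <- rep.int(0L, length(A))
  ex <- topology$exclusions
  if (nrow(ex) > 0L) {
    id_a <- at$atom_id[A]; id_b <- at$atom_id[B]
    keys <- paste(pmin(id_a, id_b), pmax(id_a, id_b))
    exk <- paste(pmin(ex$i, ex$j), pmax(ex$i, ex$j))
    hit <- match(keys, exk)
    cls[!is.na(hit)] <- ex$class[hit[!is.na(hit)]]
  }
  keep <- cls >= 3L | cls == 0L          # drop 1-2 and 1-3 pairs entirely
  A <- A[keep]; B <- B[keep]; is14 <- cls[keep] == 3L

  eps_a <- at$lj_eps[A]; eps_b <- at$lj_eps[B]
  rmh_a <- at$lj_rmin_half[A]; rmh_b <- at$lj_rmin_half[B]
  if (any(is14)) {
    # per-atom 1-4 overrides where present, regular parameters otherwise
    eps_a[is14] <- ifelse(is.na(at$lj_eps14[A[is14]]), eps_a[is14], at$lj_eps14[A[is14]])
    eps_b[is14] <- ifelse(is.na(at$lj_eps14[B[is14]]), eps_b[is14], at$lj_eps14[B[is14]])
    rmh_a[is14] <- ifelse(is.na(at$lj_rmin_half14[A[is14]]), rmh_a[is14], at$lj_rmin_half14[A[is14]])
    rmh_b[is14] <- ifelse(is.na(at$lj_rmin_half14[B[is14]]), rmh_b[is14], at$lj_rmin_half14[B[is14]])
  }
  list(
    A = A, B = B,
    eps_ij = sqrt(eps_a * eps_b),
    rmin_ij = rmh_a + rmh_b,
    qq = at$charge[A] * at$charge[B] * ifelse(is14, params$scale14_elec, 1)
  )
}

eval_pair_context <- function(ctx, xyz, params) {
  if (length(ctx$A) == 0L) return(0)
  d <- xyz[ctx$A, , drop = FALSE] - xyz[ctx$B, , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  if (any(r == 0)) stop_validation("coincident atoms: pair distance of zero")
  within <- r < params$cutoff
  if (!any(within)) return(0)
  r <- r[within]
  sr6 <- (ctx$rmin_ij[within] / r)^6
  lj <- ctx$eps_ij[within] * (sr6^2 - 2 * sr6) * vdw_switch_factor(r, params)
  el <- params$coulomb_const * ctx$qq[within] / (params$dielectric * r)
  el <- el * switch(params$elec_scheme,
    shifted = (1 - (r / params$cutoff)^2)^2,
    switched = vdw_switch_factor(r, params),
    truncated = 1
  )
  sum(lj + el)
}

#' Nonbonded interaction energy between two residues in one frame
#'
#' Sums Lennard-Jones and Coulomb terms over all atom pairs between the two
#' residues, skipping 1-2/1-3 excluded pairs and applying 1-4 special
#' parameters; symmetric in its residue arguments.
#'
#' @param topology A parameterised [topology()].
#' @param frame A `frame` or `n x 3` coordinate matrix, Angstrom.
#' @param res_a,res_b Residue ordinals (0-based) or labels; must differ.
#' @param params [nb_params()].
#' @return Energy in kcal/mol (signed).
#' @export
residue_pair_energy <- function(topology, frame, res_a, res_b, params = nb_params()) {
  ia <- resolve_residue(topology, res_a)
  ib <- resolve_residue(topology, res_b)
  if (ia == ib) stop_validation("res_a and res_b must be different residues")
  ctx <- pair_context(topology, ia, ib, params)
  eval_pair_context(ctx, frame_coords(frame), params)
}

#' Residue pairs that can contribute nonbonded energy
#'
#' Prefilter used before the full energy evaluation: a pair is a candidate if
#' its minimum atom-atom distance comes within `cutoff + margin` in at least
#' one retained frame. The margin makes the filter superset-safe — it changes
#' cost, never results.
#'
#' @param topology A [topology()].
#' @param trajectory A trajectory over that topology.
#' @param params [nb_params()].
#' @param margin Safety margin added to the cutoff, Angstrom.
#' @return Tibble with 0-based ordinal columns `res_i < res_j`.
#' @export
candidate_pairs <- function(topology, trajectory, params = nb_params(), margin = 2) {
  nres <- n_residues(topology)
  if (nres < 2L) return(tibble(res_i = integer(), res_j = integer()))
  lim <- params$cutoff + margin
  ok <- matrix(FALSE, nres, nres)
  rr <- topology$res_rows
  for (f in seq_len(n_frames(trajectory))) {
    xyz <- trajectory$coords[, , f]
    dall <- as.matrix(stats::dist(xyz))
    for (a in seq_len(nres - 1L)) {
      for (b in (a + 1L):nres) {
        if (!ok[a, b] && min(dall[rr[[a]], rr[[b]]]) <= lim) ok[a, b] <- TRUE
      }
    }
  }
  idx <- which(ok, arr.ind = TRUE)
  tibble(res_i = as.integer(idx[, 1] - 1L), res_j = as.integer(idx[, 2] - 1L)) |>
    arrange(.data$res_i, .data$res_j)
}

#' Trajectory-mean absolute residue-residue interaction energy matrix
#'
#' For every candidate residue pair, evaluates the nonbonded interaction
#' energy in each retained frame and stores the mean of the absolute values:
#' only the strength of an interaction enters the network, not whether it is
#' attractive or repulsive. Pairs outside the candidate set are zero.
#'
#' @inheritParams candidate_pairs
#' @return A `pair_energy_matrix`: symmetric `N x N` matrix (kcal/mol) with
#'   zero diagonal, residue labels as dimnames, and attributes `n_frames` and
#'   `params`.
#' @export
pair_energy_matrix <- function(topology, trajectory, params = nb_params()) {
  nres <- n_residues(topology)
  cand <- candidate_pairs(topology, trajectory, params)
  nf <- n_frames(trajectory)
  vals <- matrix(0, nres, nres,
                 dimnames = list(topology$residues$label, topology$residues$label))
  if (nrow(cand) > 0L) {
    ctxs <- purrr::map2(cand$res_i, cand$res_j,
                        ~ pair_context(topology, .x, .y, params))
    acc <- numeric(nrow(cand))
    for (f in seq_len(nf)) {
      xyz <- trajectory$coords[, , f]
      acc <- acc + abs(vapply(ctxs, eval_pair_context, numeric(1),
                              xyz = xyz, params = params))
    }
    m <- acc / nf
    vals[cbind(cand$res_i + 1L, cand$res_j + 1L)] <- m
    vals[cbind(cand$res_j + 1L, cand$res_i + 1L)] <- m
  }
  new_pair_energy_matrix(vals, n_frames = nf, params = params)
}

new_pair_energy_matrix <- function(values, n_frames, params) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop_validation("pair energy matrix must be square")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_validation("pair energy matrix entries must be finite and >= 0")
  }
  if (any(diag(values) != 0)) stop_validation("pair energy matrix diagonal must be zero")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-12))) {
    stop_validation("pair energy matrix must be symmetric")
  }
  structure(values, class = c("pair_energy_matrix", "matrix", "array"),
            n_frames = as.integer(n_frames), params = params)
}

#' @export
print.pair_energy_matrix <- function(x, ...) {
  nz <- sum(x[upper.tri(x)] > 0)
  cat(sprintf("<pair_energy_matrix> %d residues, %d interacting pairs, mean |E| over %d frame(s)\n",
              nrow(x), nz, attr(x, "n_frames")))
  cat(sprintf("  mean nonzero |E| = %.4g kcal/mol\n",
              if (nz > 0) mean(x[upper.tri(x)][x[upper.tri(x)] > 0]) else 0))
  invisible(x)
}

#' Mean absolute interaction energy over interacting pairs
#'
#' The headline per-system scalar: the average of the nonzero entries of the
#' mean-|E| matrix, i.e. the average absolute residue-residue interaction
#' energy over pairs that interact at all.
#'
#' @param matrix A [pair_energy_matrix()].
#' @return Scalar kcal/mol.
#' @export
mean_abs_interaction_energy <- function(matrix) {
  up <- matrix[upper.tri(matrix)]
  up <- up[up > 0]
  if (length(up) == 0L) return(0)
  mean(up)
}
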