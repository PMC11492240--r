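# Independent reference implementations used to cross-check the package.
# Deliberately naive and written against the definitions, not the package
# internals: a double-loop energy sum with its own exclusion search, a
# Floyd-Warshall all-pairs solver, and an exhaustive recursive enumeration of
# global alignments.

# shortest bond-path length between two atoms (breadth-first, unlimited depth)
bond_separation <- function(bonds, id_a, id_b, atom_ids) {
  if (nrow(bonds) == 0L) return(Inf)
  adj <- lapply(atom_ids, function(a) {
    c(bonds$j[bonds$i == a], bonds$i[bonds$j == a])
  })
  names(adj) <- as.character(atom_ids)
  seen <- setNames(rep(FALSE, length(atom_ids)), as.character(atom_ids))
  frontier <- id_a
  seen[as.character(id_a)] <- TRUE
  d <- 0L
  while (length(frontier) > 0L) {
    if (id_b %in% frontier) return(d)
    d <- d + 1L
    nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nxt <- nxt[!seen[as.character(nxt)]]
    seen[as.character(nxt)] <- TRUE
    frontier <- nxt
  }
  Inf
}

# naive double-loop residue pair energy, formulas written out longhand
naive_residue_pair_energy <- function(topo, xyz, res_a, res_b, params = reinet::nb_params()) {
  at <- topo$atoms
  rows_a <- which(at$residue_key == topo$residues$key[res_a + 1])
  rows_b <- which(at$residue_key == topo$residues$key[res_b + 1])
  total <- 0
  for (p in rows_a) {
    for (q in rows_b) {
      sep <- bond_separation(topo$bonds, at$atom_id[p], at$atom_id[q], at$atom_id)
      if (sep <= 2) next
      r <- sqrt(sum((xyz[p, ] - xyz[q, ])^2))
      if (r >= params$cutoff) next
      if (sep == 3) {
        eps_p <- if (!is.na(at$lj_eps14[p])) at$lj_eps14[p] else at$lj_eps[p]
        eps_q <- if (!is.na(at$lj_eps14[q])) at$lj_eps14[q] else at$lj_eps[q]
        rmh_p <- if (!is.na(at$lj_rmin_half14[p])) at$lj_rmin_half14[p] else at$lj_rmin_half[p]
        rmh_q <- if (!is.na(at$lj_rmin_half14[q])) at$lj_rmin_half14[q] else at$lj_rmin_half[q]
        qfac <- params$scale14_elec
      } else {
        eps_p <- at$lj_eps[p]; eps_q <- at$lj_eps[q]
        rmh_p <- at$lj_rmin_half[p]; rmh_q <- at$lj_rmin_half[q]
        qfac <- 1
      }
      eps <- sqrt(eps_p * eps_q)
      rmin <- rmh_p + rmh_q
      rc <- params$cutoff; ron <- params$switch_on
      sw <- if (r <= ron) 1 else if (r >= rc) 0 else
        (rc^2 - r^2)^2 * (rc^2 + 2 * r^2 - 3 * ron^2) / (rc^2 - ron^2)^3
      lj <- eps * ((rmin / r)^12 - 2 * (rmin / r)^6) * sw
      el <- params$coulomb_const * qfac * at$charge[p] * at$charge[q] /
        (params$dielectric * r)
      if (params$elec_scheme == "shifted") {
        el <- el * (1 - (r / rc)^2)^2
      } else if (params$elec_scheme == "switched") {
        el <- el * sw
      }
      total <- total + lj + el
    }
  }
  total
}

# Floyd-Warshall all-pairs shortest paths from a resnet cost matrix
floyd_warshall <- function(net) {
  d <- net$costs
  diag(d) <- 0
  n <- nrow(d)
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

# exhaustive recursion over all global alignments (no memoisation): best
# achievable score under linear gap penalties
enumerate_best_alignment_score <- function(a, b, score_fun, gap) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) best <- max(best, rec(i - 1L, j - 1L) + score_fun(a[i], b[j]))
    if (i > 0L) best <- max(best, rec(i - 1L, j) - gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) - gap)
    best
  }
  rec(length(a), length(b))
}

# small in-memory test topology: n_res residues in a row, explicit parameters
make_line_topology <- function(charges, eps, rmin_half, res_of, bonds = NULL,
                               coords = NULL) {
  n_at <- length(charges)
  n_res <- max(res_of)
  atoms <- tibble::tibble(
    atom_id = seq_len(n_at),
    name = sprintf("A%d", seq_len(n_at)),
    type = sprintf("T%d", seq_len(n_at)),
    residue_key = sprintf("R:%d", res_of),
    charge = charges, lj_eps = eps, lj_rmin_half = rmin_half,
    mass = rep(12, n_at)
  )
  residues <- tibble::tibble(
    index = seq_len(n_res) - 1L,
    key = sprintf("R:%d", seq_len(n_res)),
    label = as.character(seq_len(n_res)),
    name = "TOY", chain = "R"
  )
  reinet::topology(atoms, residues, bonds)
}

# hand-built residue profile for comparison tests
fake_profile <- function(values, labels = as.character(seq_along(values)),
                         semantics = "inv_energy") {
  out <- tibble::tibble(
    index = seq_along(values) - 1L, label = labels, value = values,
    unreachable_count = 0L
  )
  attr(out, "normalized") <- FALSE
  attr(out, "semantics") <- semantics
  class(out) <- c("residue_profile", class(out))
  out
}
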