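# Synthetic-system generator. Produces toy topologies, parameter tables and
# trajectories in the same formats the production readers consume, with a
# sidecar of exact per-frame pair energies from an intentionally naive
# brute-force oracle, so every pipeline stage can be checked against known
# ground truth without any external data. Fixture "residues" are simplified
# few-atom bodies; no physical dynamics is claimed — trajectory noise is
# isotropic per-atom Gaussian jitter.

#' Specification of a synthetic system
#'
#' @param n_residues Number of residues.
#' @param atoms_per_residue Length-2 integer range; each residue draws its
#'   atom count uniformly from it.
#' @param charge_scheme `"uniform"` draws atomic charges from
#'   `U(-charge_max, charge_max)`; `"neutral"` additionally shifts each
#'   residue to zero net charge.
#' @param charge_max Charge magnitude bound, elementary charges.
#' @param eps_range,rmin_half_range Lennard-Jones parameter ranges (kcal/mol,
#'   Angstrom) for the atom-type pool.
#' @param n_types Size of the atom-type pool.
#' @param geometry `"linear-chain"` (residues along x, spacing `spacing`),
#'   `"globule"` (residue centres in a sphere), or `"two-body"` (two residues
#'   at separation `spacing`).
#' @param spacing Residue spacing / separation, Angstrom.
#' @param jitter_sd Per-atom, per-frame isotropic Gaussian displacement,
#'   Angstrom (0 gives identical frames).
#' @param n_frames Number of trajectory frames.
#' @param seed Integer; fully determines the output.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues = 5, atoms_per_residue = c(2L, 8L),
                         charge_scheme = c("uniform", "neutral"),
                         charge_max = 0.5,
                         eps_range = c(0.05, 0.2), rmin_half_range = c(1.2, 2.0),
                         n_types = 6L,
                         geometry = c("linear-chain", "globule", "two-body"),
                         spacing = 5, jitter_sd = 0.1, n_frames = 3L,
                         seed = 1L) {
  geometry <- match.arg(geometry)
  charge_scheme <- match.arg(charge_scheme)
  if (geometry == "two-body") n_residues <- 2L
  stopifnot(n_residues >= 1L, n_frames >= 1L, jitter_sd >= 0,
            atoms_per_residue[1] >= 1L, atoms_per_residue[2] >= atoms_per_residue[1])
  structure(
    list(n_residues = as.integer(n_residues),
         atoms_per_residue = as.integer(atoms_per_residue),
         charge_scheme = charge_scheme, charge_max = charge_max,
         eps_range = eps_range, rmin_half_range = rmin_half_range,
         n_types = as.integer(n_types), geometry = geometry, spacing = spacing,
         jitter_sd = jitter_sd, n_frames = as.integer(n_frames),
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Generate a synthetic system with exact energy ground truth
#'
#' Builds a topology (random charges and Lennard-Jones types from the spec's
#' pool, atoms chained by bonds within each residue and across consecutive
#' residues in chain geometries) and a jittered trajectory, optionally writes
#' PDB + PSF + parameter table + XYZ trajectory + a JSON sidecar holding the
#' brute-force per-frame pair energies, and returns everything in memory.
#' Geometries where two atoms land closer than 0.5 Angstrom are rejected and
#' redrawn from the same seeded stream (bounded retries), so outputs remain a
#' pure function of the seed.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory; when given, `system.pdb`, `system.psf`,
#'   `system.prm`, `traj.xyz` and `sidecar.json` are written there.
#' @param params [nb_params()] used for the sidecar oracle energies.
#' @return List with `topology`, `trajectory`, `sidecar` (long tibble of
#'   per-frame pair energies plus the mean-|E| matrix), and `paths` (file
#'   paths, when `dir` was given).
#' @export
make_toy_system <- function(spec = fixture_spec(), dir = NULL,
                            params = nb_params()) {
  set.seed(spec$seed)
  sys <- NULL
  for (try in 1:20) {
    cand <- generate_system_draw(spec)
    if (cand$min_dist >= 0.5) { sys <- cand; break }
  }
  if (is.null(sys)) {
    stop_validation("could not generate non-overlapping geometry in 20 attempts; increase spacing")
  }
  topo <- sys$topology
  traj <- new_trajectory(topo, sys$coords)
  sidecar <- oracle_sidecar(topo, traj, params)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      pdb = file.path(dir, "system.pdb"),
      psf = file.path(dir, "system.psf"),
      prm = file.path(dir, "system.prm"),
      traj = file.path(dir, "traj.xyz"),
      sidecar = file.path(dir, "sidecar.json")
    )
    write_profile_structure(new_frame(sys$coords[, , 1]), topo,
                            rep(0, n_residues(topo)), paths$pdb)
    write_psf(topo, paths$psf)
    write_nb_param_table(sys$type_table, paths$prm)
    write_xyz_frames(sys$coords, topo$atoms$name, paths$traj)
    jsonlite::write_json(
      list(per_frame = sidecar$per_frame, mean_abs = sidecar$mean_abs,
           params = unclass(params), seed = spec$seed),
      paths$sidecar, digits = NA, auto_unbox = TRUE
    )
  }
  list(topology = topo, trajectory = traj, sidecar = sidecar, paths = paths)
}

generate_system_draw <- function(spec) {
  n_res <- spec$n_residues
  nat <- sample(seq(spec$atoms_per_residue[1], spec$atoms_per_residue[2]),
                n_res, replace = TRUE)
  n_at <- sum(nat)

  type_table <- tibble(
    type = sprintf("T%d", seq_len(spec$n_types)),
    eps = runif(spec$n_types, spec$eps_range[1], spec$eps_range[2]),
    rmin_half = runif(spec$n_types, spec$rmin_half_range[1], spec$rmin_half_range[2]),
    eps14 = NA_real_, rmin_half14 = NA_real_
  )
  # give one type a 1-4 override so the special-pair path is exercised
  type_table$eps14[1] <- type_table$eps[1] / 2
  type_table$rmin_half14[1] <- type_table$rmin_half[1]

  res_of <- rep(seq_len(n_res), times = nat)
  charge <- runif(n_at, -spec$charge_max, spec$charge_max)
  if (spec$charge_scheme == "neutral") {
    for (r in seq_len(n_res)) {
      idx <- which(res_of == r)
      charge[idx] <- charge[idx] - mean(charge[idx])
    }
  }
  ttype <- sample(type_table$type, n_at, replace = TRUE)

  centers <- switch(spec$geometry,
    "linear-chain" = cbind((seq_len(n_res) - 1L) * spec$spacing, 0, 0),
    "two-body" = rbind(c(0, 0, 0), c(spec$spacing, 0, 0)),
    "globule" = {
      # sequential placement with a minimum centre separation keeps the
      # atom-overlap rejection rate low while staying seed-deterministic
      R <- max(spec$spacing, 2.5 * n_res^(1 / 3) * 1.6)
      m <- matrix(NA_real_, n_res, 3)
      for (r in seq_len(n_res)) {
        for (attempt in 1:200) {
          cand <- runif(3, -R, R)
          if (r == 1L) break
          sep <- sqrt(rowSums((m[seq_len(r - 1L), , drop = FALSE] -
                                 matrix(cand, r - 1L, 3, byrow = TRUE))^2))
          if (min(sep) >= 3.5) break
        }
        m[r, ] <- cand
      }
      m
    }
  )
  # atoms placed sequentially with rejection against all earlier atoms, so
  # overlapping geometries are rare on the first draw
  coords0 <- matrix(NA_real_, n_at, 3)
  for (k in seq_len(n_at)) {
    for (attempt in 1:200) {
      cand <- centers[res_of[k], ] + runif(3, -1.2, 1.2)
      if (k == 1L) break
      sep <- sqrt(rowSums((coords0[seq_len(k - 1L), , drop = FALSE] -
                             matrix(cand, k - 1L, 3, byrow = TRUE))^2))
      if (min(sep) >= 0.8) break
    }
    coords0[k, ] <- cand
  }

  trow <- match(ttype, type_table$type)
  atoms <- tibble(
    atom_id = seq_len(n_at),
    name = sprintf("A%d", seq_len(n_at)),
    type = ttype,
    residue_key = sprintf("S:%d", res_of),
    charge = charge,
    lj_eps = type_table$eps[trow],
    lj_rmin_half = type_table$rmin_half[trow],
    lj_eps14 = type_table$eps14[trow],
    lj_rmin_half14 = type_table$rmin_half14[trow],
    mass = runif(n_at, 1, 16)
  )
  residues <- tibble(
    index = seq_len(n_res) - 1L,
    key = sprintf("S:%d", seq_len(n_res)),
    label = as.character(seq_len(n_res)),
    name = "TOY",
    chain = "S"
  )
  # chain bonds within each residue; chain geometries also bond consecutive
  # residues so inter-residue exclusions are exercised
  bond_i <- integer(0); bond_j <- integer(0)
  first_of <- cumsum(c(1L, nat))[seq_len(n_res)]
  for (r in seq_len(n_res)) {
    idx <- first_of[r]:(first_of[r] + nat[r] - 1L)
    if (length(idx) > 1L) {
      bond_i <- c(bond_i, idx[-length(idx)]); bond_j <- c(bond_j, idx[-1])
    }
  }
  if (spec$geometry == "linear-chain" && n_res > 1L) {
    last_of <- first_of + nat - 1L
    bond_i <- c(bond_i, last_of[-n_res]); bond_j <- c(bond_j, first_of[-1])
  }
  topo <- topology(atoms, residues, tibble(i = bond_i, j = bond_j))

  coords <- array(rep(coords0, spec$n_frames), dim = c(n_at, 3L, spec$n_frames))
  if (spec$jitter_sd > 0) {
    coords <- coords + array(rnorm(length(coords), 0, spec$jitter_sd), dim = dim(coords))
  }
  min_dist <- min(vapply(seq_len(spec$n_frames),
                         function(f) min(stats::dist(coords[, , f])), numeric(1)))
  list(topology = topo, coords = coords, type_table = type_table, min_dist = min_dist)
}

# ---- brute-force oracle ----

#' Brute-force residue pair energies (naive reference)
#'
#' Deliberately naive double loop over every atom pair of every residue pair
#' in every frame, with its own inline energy formulas and its own bond-graph
#' breadth-first search for exclusion classification. It shares no code with
#' the vectorised energy module and serves as the ground truth written into
#' fixture sidecars.
#'
#' @param topology,trajectory,params As in [pair_energy_matrix()].
#' @return List: `per_frame` tibble (`frame`, `res_i`, `res_j`, `energy`) and
#'   `mean_abs` matrix.
#' @export
oracle_pair_energies <- function(topology, trajectory, params = nb_params()) {
  at <- topology$atoms
  n_res <- n_residues(topology)
  nf <- n_frames(trajectory)

  # own exclusion classification: repeated relaxation over the bond list
  n_at <- nrow(at)
  id2row <- setNames(seq_len(n_at), as.character(at$atom_id))
  D <- matrix(Inf, n_at, n_at); diag(D) <- 0
  if (nrow(topology$bonds) > 0L) {
    bi <- id2row[as.character(topology$bonds$i)]
    bj <- id2row[as.character(topology$bonds$j)]
    for (k in seq_along(bi)) { D[bi[k], bj[k]] <- 1; D[bj[k], bi[k]] <- 1 }
    for (rep in 1:3) {
      for (k in seq_along(bi)) {
        D <- pmin(D, outer(D[, bi[k]], D[bj[k], ] + 1, "+"))
        D <- pmin(D, outer(D[, bj[k]], D[bi[k], ] + 1, "+"))
      }
    }
  }

  rows <- list(); nrow_out <- 0L
  mean_abs <- matrix(0, n_res, n_res,
                     dimnames = list(topology$residues$label, topology$residues$label))
  for (f in seq_len(nf)) {
    xyz <- trajectory$coords[, , f]
    for (a in seq_len(n_res - 1L)) {
      for (b in (a + 1L):n_res) {
        e <- 0
        for (p in topology$res_rows[[a]]) {
          for (q in topology$res_rows[[b]]) {
            nb_sep <- D[p, q]
            if (nb_sep <= 2) next                      # 1-2 / 1-3 excluded
            r <- sqrt(sum((xyz[p, ] - xyz[q, ])^2))
            if (r >= params$cutoff) next
            if (nb_sep == 3) {                          # 1-4 special treatment
              ep <- if (is.na(at$lj_eps14[p])) at$lj_eps[p] else at$lj_eps14[p]
              eq <- if (is.na(at$lj_eps14[q])) at$lj_eps[q] else at$lj_eps14[q]
              rp <- if (is.na(at$lj_rmin_half14[p])) at$lj_rmin_half[p] else at$lj_rmin_half14[p]
              rq <- if (is.na(at$lj_rmin_half14[q])) at$lj_rmin_half[q] else at$lj_rmin_half14[q]
              qscale <- params$scale14_elec
            } else {
              ep <- at$lj_eps[p]; eq <- at$lj_eps[q]
              rp <- at$lj_rmin_half[p]; rq <- at$lj_rmin_half[q]
              qscale <- 1
            }
            eps <- sqrt(ep * eq); rmin <- rp + rq
            rc2 <- params$cutoff^2; ron2 <- params$switch_on^2
            sw <- if (r <= params$switch_on) 1 else
              (rc2 - r^2)^2 * (rc2 + 2 * r^2 - 3 * ron2) / (rc2 - ron2)^3
            lj <- eps * ((rmin / r)^12 - 2 * (rmin / r)^6) * sw
            el <- params$coulomb_const * qscale * at$charge[p] * at$charge[q] /
              (params$dielectric * r)
            el <- el * switch(params$elec_scheme,
              shifted = (1 - (r / params$cutoff)^2)^2,
              switched = sw, truncated = 1)
            e <- e + lj + el
          }
        }
        nrow_out <- nrow_out + 1L
        rows[[nrow_out]] <- list(frame = f - 1L, res_i = a - 1L, res_j = b - 1L,
                                 energy = e)
        mean_abs[a, b] <- mean_abs[a, b] + abs(e) / nf
        mean_abs[b, a] <- mean_abs[a, b]
      }
    }
  }
  list(per_frame = dplyr::bind_rows(rows), mean_abs = mean_abs)
}

oracle_sidecar <- oracle_pair_energies

# ---- random graphs ----

#' Seeded random weighted graph
#'
#' Test harness for the shortest-path analysis: every (ordered, if directed)
#' node pair receives an edge with probability `edge_prob`, with cost drawn
#' uniformly from `cost_range`.
#'
#' @param n_nodes Number of nodes.
#' @param edge_prob Edge probability in `[0, 1]`.
#' @param cost_range Positive cost range.
#' @param seed Integer seed; regeneration is exact.
#' @param directed Directed graph flag.
#' @return A [resnet()] with `synthetic` semantics.
#' @export
make_random_graph <- function(n_nodes, edge_prob, cost_range = c(0.5, 2),
                              seed = 1L, directed = FALSE) {
  stopifnot(n_nodes >= 1, edge_prob >= 0, edge_prob <= 1, cost_range[1] > 0)
  set.seed(seed)
  costs <- matrix(Inf, n_nodes, n_nodes)
  if (directed) {
    sel <- which(matrix(TRUE, n_nodes, n_nodes) & !diag(TRUE, n_nodes))
    on <- sel[runif(length(sel)) < edge_prob]
    costs[on] <- runif(length(on), cost_range[1], cost_range[2])
  } else {
    up <- which(upper.tri(costs))
    on <- up[runif(length(up)) < edge_prob]
    costs[on] <- runif(length(on), cost_range[1], cost_range[2])
    costs[lower.tri(costs)] <- t(costs)[lower.tri(costs)]
  }
  resnet(costs, labels = as.character(seq_len(n_nodes)), directed = directed,
         semantics = "synthetic")
}

# ---- hub systems ----

#' Synthetic system with designated strongly-interacting hub residues
#'
#' Emulates the situation where a few residues (like a catalytic triad)
#' interact much more strongly with the rest of the structure than typical
#' residues do. Non-hub residues sit on a sphere, hubs near its centre within
#' the nonbonded cutoff of everyone. Hub atoms carry zero Lennard-Jones well
#' depth, so hub pair energies are exactly linear in the hub charge scale; the
#' scale is solved from one cheap matrix evaluation such that every hub pair's
#' mean |E| is at least `hub_strength_factor` times the median non-hub pair
#' energy. With a large factor the hubs attain the minimal average
#' shortest-path values in the energy network; with factor 1 no ordering is
#' guaranteed (negative control).
#'
#' @param n_residues Total residues (including hubs).
#' @param hub_strength_factor Required ratio of hub pair mean |E| to the
#'   median non-hub pair mean |E|.
#' @param n_hubs Number of hub residues.
#' @param seed Integer seed.
#' @param n_frames,jitter_sd Trajectory shape (as in [fixture_spec()]).
#' @param params [nb_params()].
#' @return List: `topology`, `trajectory`, `hub_index` (0-based ordinals).
#' @export
make_hub_system <- function(n_residues = 20, hub_strength_factor = 10,
                            n_hubs = 1L, seed = 1L, n_frames = 3L,
                            jitter_sd = 0.05, params = nb_params()) {
  stopifnot(n_residues >= n_hubs + 2L, hub_strength_factor > 0)
  set.seed(seed)
  n_other <- n_residues - n_hubs
  # Fibonacci sphere for the non-hub residues, hubs clustered at the centre
  R <- 6
  k <- seq_len(n_other)
  phi <- acos(1 - 2 * (k - 0.5) / n_other)
  theta <- pi * (1 + sqrt(5)) * k
  centers_other <- R * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  centers_hub <- matrix(rnorm(3L * n_hubs, 0, 0.4), ncol = 3)
  centers <- rbind(centers_hub, centers_other)
  hub_index <- seq_len(n_hubs) - 1L

  n_at_per <- 2L
  n_at <- n_residues * n_at_per
  res_of <- rep(seq_len(n_residues), each = n_at_per)
  offs <- matrix(rnorm(3L * n_at, 0, 0.3), ncol = 3)
  coords0 <- centers[res_of, , drop = FALSE] + offs

  is_hub_atom <- res_of <= n_hubs
  base_q <- rep(c(0.1, -0.1), n_residues)        # small dipoles everywhere
  atoms <- tibble(
    atom_id = seq_len(n_at),
    name = sprintf("A%d", seq_len(n_at)),
    type = ifelse(is_hub_atom, "HUB", "TOY"),
    residue_key = sprintf("S:%d", res_of),
    charge = base_q,
    lj_eps = ifelse(is_hub_atom, 0, 0.05),
    lj_rmin_half = 1.2,
    mass = 12
  )
  residues <- tibble(
    index = seq_len(n_residues) - 1L,
    key = sprintf("S:%d", seq_len(n_residues)),
    label = as.character(seq_len(n_residues)),
    name = "TOY", chain = "S"
  )
  # jitter must be identical across the two builds below: draw it once
  jitter_draw <- if (jitter_sd > 0) rnorm(n_at * 3L * n_frames, 0, jitter_sd) else NULL
  build <- function(at) {
    topo <- topology(at, residues)
    coords <- array(rep(coords0, n_frames), dim = c(n_at, 3L, n_frames))
    if (!is.null(jitter_draw)) {
      coords <- coords + array(jitter_draw, dim = dim(coords))
    }
    list(topology = topo, trajectory = new_trajectory(topo, coords))
  }

  probe <- build(atoms)
  pem <- pair_energy_matrix(probe$topology, probe$trajectory, params)
  hub_rows <- hub_index + 1L
  hub_vals <- as.numeric(pem[hub_rows, -hub_rows, drop = FALSE])
  other <- unclass(pem)[-hub_rows, -hub_rows, drop = FALSE]
  other_vals <- other[upper.tri(other)]
  med_other <- median(other_vals[other_vals > 0])
  if (!is.finite(med_other) || med_other <= 0 || min(hub_vals) <= 0) {
    stop_validation("degenerate hub geometry; change the seed")
  }
  # hub pair energies are purely electrostatic and linear in the hub charges
  scale <- hub_strength_factor * med_other / min(hub_vals) * 1.05
  atoms$charge[is_hub_atom] <- atoms$charge[is_hub_atom] * scale

  final <- build(atoms)
  c(final, list(hub_index = hub_index))
}

# ---- PSF / parameter writers (fixture side of the round trip) ----

write_psf <- function(topology, path) {
  at <- topology$atoms
  rs <- topology$residues
  ridx <- match(at$residue_key, rs$key)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("PSF", "", sprintf("%8d !NTITLE", 1L),
               " REMARKS synthetic toy system", ""), con)
  writeLines(sprintf("%8d !NATOM", nrow(at)), con)
  writeLines(sprintf("%8d %-4s %-4s %-4s %-4s %-4s %10.6f %13.4f %11d",
                     at$atom_id, substr(rs$chain[ridx], 1, 4), rs$label[ridx],
                     substr(rs$name[ridx], 1, 4), at$name, at$type,
                     at$charge, at$mass, 0L), con)
  writeLines("", con)
  nb <- nrow(topology$bonds)
  writeLines(sprintf("%8d !NBOND: bonds", nb), con)
  if (nb > 0L) {
    flat <- as.integer(t(as.matrix(topology$bonds[, c("i", "j")])))
    idx <- split(flat, ceiling(seq_along(flat) / 8))
    writeLines(vapply(idx, function(v) paste(sprintf("%8d", v), collapse = ""), ""), con)
  }
  writeLines("", con)
  invisible(path)
}

write_nb_param_table <- function(type_table, path) {
  has14 <- !is.na(type_table$eps14)
  lines <- ifelse(
    has14,
    sprintf("%-6s %.10f %.10f %.10f %.10f", type_table$type, type_table$eps,
            type_table$rmin_half, type_table$eps14, type_table$rmin_half14),
    sprintf("%-6s %.10f %.10f", type_table$type, type_table$eps, type_table$rmin_half)
  )
  writeLines(c("# type eps rmin_half [eps14 rmin_half14]", lines), path)
  invisible(path)
}
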