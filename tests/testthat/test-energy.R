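# Nonbonded energy terms: analytic values of the Lennard-Jones form, the
# switching polynomial and the shifted Coulomb factor; continuity at the
# scheme boundaries; agreement of the vectorised residue-pair sum with the
# naive double-loop reference.

test_that("Lennard-Jones term hits its analytic landmarks", {
  p <- nb_params()
  expect_identical(lj_pair_energy(0.1, 3.0, 3.0, p), -0.1)
  expect_equal(lj_pair_energy(0.1, 3.0, 3.0 * 2^(-1 / 6), p), 0, tolerance = 1e-14)
  # hand evaluation: 0.1 * ((3/4)^12 - 2 (3/4)^6), switch factor 1 at 4 A
  expect_equal(lj_pair_energy(0.1, 3.0, 4.0, p),
               0.1 * ((3 / 4)^12 - 2 * (3 / 4)^6), tolerance = 1e-14)
  expect_equal(lj_pair_energy(0.1, 3.0, 4.0, p), -0.0324280679, tolerance = 1e-8)
  expect_identical(lj_pair_energy(0.1, 3.0, 12.0, p), 0)
  expect_identical(lj_pair_energy(0.1, 3.0, 14.2, p), 0)
  expect_error(lj_pair_energy(0.1, 3.0, 0, p), class = "reinet_validation_error")
})

test_that("switching factor matches the CHARMM polynomial", {
  p <- nb_params()
  expect_identical(vdw_switch_factor(9, p), 1)
  expect_identical(vdw_switch_factor(10, p), 1)
  expect_identical(vdw_switch_factor(12, p), 0)
  # integer-arithmetic hand value at 11 A: 23^2 * 86 / 44^3
  expect_equal(vdw_switch_factor(11, p), 529 * 86 / 85184, tolerance = 1e-12)
  expect_equal(vdw_switch_factor(11, p), 0.5341, tolerance = 1e-4)
})

test_that("energy terms are continuous at switch-on and cutoff", {
  p <- nb_params()
  h <- 1e-7
  for (r0 in c(p$switch_on, p$cutoff)) {
    below <- lj_pair_energy(0.1, 3.0, r0 - h, p)
    above <- lj_pair_energy(0.1, 3.0, r0 + h, p)
    expect_lt(abs(below - above), 1e-9)
  }
  expect_lt(abs(elec_pair_energy(0.3, -0.4, p$cutoff - h, p) -
                elec_pair_energy(0.3, -0.4, p$cutoff + h, p)), 1e-9)
})

test_that("Coulomb term obeys charge, cutoff and scheme rules", {
  p <- nb_params()
  expect_identical(elec_pair_energy(0, 1, 5, p), 0)
  expect_identical(elec_pair_energy(1, 1, 13, p), 0)
  expect_identical(elec_pair_energy(1, 1, 12, p), 0)
  # shifted scheme hand value at 10 A
  expect_equal(elec_pair_energy(1, 1, 10, p),
               332.0636 / 10 * (1 - (10 / 12)^2)^2, tolerance = 1e-12)
  expect_equal(elec_pair_energy(1, 1, 10, p), 3.100, tolerance = 1e-3)
  pt <- nb_params(elec_scheme = "truncated")
  expect_equal(elec_pair_energy(1, 1, 10, pt), 33.20636, tolerance = 1e-10)
  ps <- nb_params(elec_scheme = "switched")
  expect_equal(elec_pair_energy(1, 1, 11, ps),
               332.0636 / 11 * 529 * 86 / 85184, tolerance = 1e-10)
  expect_error(elec_pair_energy(1, 1, 0, p), class = "reinet_validation_error")
})

test_that("residue pair energy equals the naive double-loop reference", {
  # printed-parameter fixture: 3 + 2 atoms, no bonds
  topo <- make_line_topology(
    charges = c(0.21, -0.13, 0.05, -0.3, 0.18),
    eps = c(0.05, 0.12, 0.2, 0.09, 0.15),
    rmin_half = c(1.3, 1.7, 2.0, 1.5, 1.4),
    res_of = c(1, 1, 1, 2, 2)
  )
  set.seed(1)
  xyz <- rbind(matrix(rnorm(9, 0, 1), 3), matrix(rnorm(6, 5, 1), 2))
  for (scheme in c("shifted", "switched", "truncated")) {
    p <- nb_params(elec_scheme = scheme)
    got <- residue_pair_energy(topo, xyz, 0, 1, p)
    expect_equal(got, naive_residue_pair_energy(topo, xyz, 0, 1, p),
                 tolerance = 1e-12)
  }
  # symmetric in the residue arguments
  expect_equal(residue_pair_energy(topo, xyz, 0, 1),
               residue_pair_energy(topo, xyz, 1, 0))
  expect_error(residue_pair_energy(topo, xyz, 0, 0),
               class = "reinet_validation_error")
})

test_that("bonded adjacent residues honour the exclusion lists", {
  # chain spanning the residue boundary: atom3-atom4 bonded, so (3,4) is 1-2,
  # (2,4) and (3,5) are 1-3, (1,4) and (2,5) are 1-4
  topo <- make_line_topology(
    charges = c(0.2, -0.1, 0.3, -0.25, 0.15),
    eps = rep(0.1, 5), rmin_half = rep(1.5, 5),
    res_of = c(1, 1, 1, 2, 2),
    bonds = tibble::tibble(i = 1:4, j = 2:5)
  )
  xyz <- cbind(seq(0, 6, length.out = 5), 0, 0)
  p <- nb_params()
  expect_equal(residue_pair_energy(topo, xyz, 0, 1, p),
               naive_residue_pair_energy(topo, xyz, 0, 1, p), tolerance = 1e-12)
  # excluding pairs changes the answer relative to an exclusion-free topology
  topo_free <- make_line_topology(
    charges = topo$atoms$charge, eps = topo$atoms$lj_eps,
    rmin_half = topo$atoms$lj_rmin_half, res_of = c(1, 1, 1, 2, 2)
  )
  expect_false(isTRUE(all.equal(residue_pair_energy(topo, xyz, 0, 1, p),
                                residue_pair_energy(topo_free, xyz, 0, 1, p))))
})

test_that("1-4 pairs use override parameters and the electrostatic scale", {
  topo <- make_line_topology(
    charges = c(0.4, -0.4), eps = c(0.2, 0.2), rmin_half = c(1.6, 1.6),
    res_of = c(1, 2),
    bonds = NULL
  )
  # force the two atoms three bonds apart through two ghost atoms
  at <- topo$atoms
  at <- dplyr::bind_rows(at, tibble::tibble(
    atom_id = 3:4, name = c("G1", "G2"), type = c("G", "G"),
    residue_key = c("R:1", "R:2"), charge = 0, lj_eps = 0.01,
    lj_rmin_half = 1.0, mass = 1
  ))
  at$lj_eps14 <- c(0.05, 0.05, NA, NA)
  at$lj_rmin_half14 <- c(1.2, 1.2, NA, NA)
  topo14 <- topology(at, topo$residues,
                     tibble::tibble(i = c(1, 3, 4), j = c(3, 4, 2)))
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(1.5, 1, 0), c(2.5, -1, 0))
  p <- nb_params(scale14_elec = 0.5)
  expect_equal(residue_pair_energy(topo14, xyz, 0, 1, p),
               naive_residue_pair_energy(topo14, xyz, 0, 1, p), tolerance = 1e-12)
  # overrides actually matter: wiping them changes the energy
  at2 <- at; at2$lj_eps14 <- NA_real_; at2$lj_rmin_half14 <- NA_real_
  topo_plain <- topology(at2, topo$residues,
                         tibble::tibble(i = c(1, 3, 4), j = c(3, 4, 2)))
  expect_false(isTRUE(all.equal(residue_pair_energy(topo14, xyz, 0, 1, p),
                                residue_pair_energy(topo_plain, xyz, 0, 1, p))))
})

test_that("candidate pair prefilter matches a brute-force distance filter", {
  # three collinear single-atom residues at 0, 5, 50 A
  topo <- make_line_topology(rep(0.1, 3), rep(0.1, 3), rep(1.5, 3), res_of = 1:3)
  coords <- array(cbind(c(0, 5, 50), 0, 0), dim = c(3, 3, 1))
  traj <- reinet:::new_trajectory(topo, coords)
  cand <- candidate_pairs(topo, traj)
  expect_equal(nrow(cand), 1L)
  expect_equal(c(cand$res_i, cand$res_j), c(0L, 1L))

  # far-apart residues yield an empty candidate set
  coords_far <- array(cbind(c(0, 40, 80), 0, 0), dim = c(3, 3, 1))
  cand0 <- candidate_pairs(topo, reinet:::new_trajectory(topo, coords_far))
  expect_equal(nrow(cand0), 0L)

  # random system: candidates = pairs within cutoff + margin in any frame
  sys <- make_toy_system(fixture_spec(n_residues = 6, geometry = "globule",
                                      spacing = 9, seed = 21, n_frames = 2))
  p <- nb_params()
  cand <- candidate_pairs(sys$topology, sys$trajectory, p)
  got <- sprintf("%d-%d", cand$res_i, cand$res_j)
  want <- character(0)
  rr <- sys$topology$res_rows
  for (a in 1:5) for (b in (a + 1):6) {
    mind <- Inf
    for (f in 1:2) {
      xa <- sys$trajectory$coords[rr[[a]], , f, drop = FALSE]
      xb <- sys$trajectory$coords[rr[[b]], , f, drop = FALSE]
      for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
        mind <- min(mind, sqrt(sum((xa[i, , ] - xb[j, , ])^2)))
      }
    }
    if (mind <= p$cutoff + 2) want <- c(want, sprintf("%d-%d", a - 1L, b - 1L))
  }
  expect_setequal(got, want)
})

test_that("pair energy matrix is the mean of per-frame absolute energies", {
  sys <- make_toy_system(fixture_spec(n_residues = 5, seed = 13, n_frames = 5,
                                      jitter_sd = 0.3))
  pem <- pair_energy_matrix(sys$topology, sys$trajectory)
  # exact match with the package's naive oracle on the same in-memory system
  expect_lt(max(abs(unclass(pem) - sys$sidecar$mean_abs)), 1e-10)
  # and with the test suite's own reference
  p <- nb_params()
  for (pair in list(c(0, 1), c(1, 3), c(0, 4))) {
    es <- vapply(seq_len(n_frames(sys$trajectory)), function(f) {
      naive_residue_pair_energy(sys$topology, sys$trajectory$coords[, , f],
                                pair[1], pair[2], p)
    }, numeric(1))
    expect_equal(pem[pair[1] + 1, pair[2] + 1], mean(abs(es)), tolerance = 1e-10)
  }
  # structural invariants
  expect_true(isSymmetric(unclass(pem)))
  expect_true(all(diag(pem) == 0))
  expect_true(all(pem >= 0))
})

test_that("absolute values are taken per frame, not after averaging", {
  # two frames with opposite-sign energies of the same magnitude
  topo <- make_line_topology(c(0.2, -0.2), c(0, 0), c(1.5, 1.5), res_of = 1:2)
  coords <- array(0, dim = c(2, 3, 2))
  coords[2, 1, 1] <- 5    # attractive arrangement
  coords[2, 1, 2] <- 5
  topo2 <- make_line_topology(c(0.2, 0.2), c(0, 0), c(1.5, 1.5), res_of = 1:2)
  e_att <- residue_pair_energy(topo, coords[, , 1], 0, 1)
  e_rep <- residue_pair_energy(topo2, coords[, , 1], 0, 1)
  expect_equal(e_att, -e_rep)
  # emulate sign flip across frames by charge flip: |+E| and |-E| average to |E|
  pem1 <- pair_energy_matrix(topo, reinet:::new_trajectory(topo, coords))
  expect_equal(pem1[1, 2], abs(e_att), tolerance = 1e-12)
})

test_that("jitter-free multi-frame mean equals the single-frame energy", {
  sys <- make_toy_system(fixture_spec(n_residues = 3, seed = 4, jitter_sd = 0,
                                      n_frames = 3))
  expect_equal(sys$trajectory$coords[, , 1], sys$trajectory$coords[, , 3])
  pem <- pair_energy_matrix(sys$topology, sys$trajectory)
  e01 <- residue_pair_energy(sys$topology, sys$trajectory$coords[, , 1], 0, 1)
  expect_equal(pem[1, 2], abs(e01), tolerance = 1e-12)
})
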