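# Network builders: threshold boundaries, atom-contact normalisation and
# directedness, energy-cost inversion and sign independence.

# two single-atom residues a given centre distance apart, one frame
two_body_traj <- function(d, masses = c(12, 12)) {
  topo <- make_line_topology(c(0, 0), c(0.1, 0.1), c(1.5, 1.5), res_of = 1:2)
  topo$atoms$mass <- masses
  coords <- array(0, dim = c(2, 3, 1))
  coords[2, 1, 1] <- d
  list(topology = topo, trajectory = reinet:::new_trajectory(topo, coords))
}

test_that("centre-of-mass network boundary is inclusive at the cutoff", {
  for (case in list(list(d = 7.9, edge = TRUE), list(d = 8.0, edge = TRUE),
                    list(d = 8.1, edge = FALSE))) {
    tb <- two_body_traj(case$d)
    nb <- build_residue_com_network(tb$topology, tb$trajectory, mode = "binary")
    nw <- build_residue_com_network(tb$topology, tb$trajectory, mode = "weighted")
    if (case$edge) {
      expect_equal(nb$costs[1, 2], 1)
      expect_equal(nw$costs[1, 2], case$d, tolerance = 1e-12)
    } else {
      expect_false(is.finite(nb$costs[1, 2]))
      expect_false(is.finite(nw$costs[1, 2]))
    }
  }
})

test_that("centre of mass is mass-weighted and averaged over frames", {
  # residue 1: atoms at x = 0 (mass 1) and x = 2 (mass 3) -> COM at 1.5
  topo <- make_line_topology(rep(0, 3), rep(0.1, 3), rep(1.5, 3),
                             res_of = c(1, 1, 2))
  topo$atoms$mass <- c(1, 3, 12)
  coords <- array(0, dim = c(3, 3, 2))
  coords[, 1, 1] <- c(0, 2, 9.4)
  coords[, 1, 2] <- c(0, 2, 9.6)   # frame-averaged COM distance: 8.0 exactly
  traj <- reinet:::new_trajectory(topo, coords)
  nw <- build_residue_com_network(topo, traj, mode = "weighted")
  expect_equal(nw$costs[1, 2], 8.0, tolerance = 1e-12)
  expect_false(nw$directed)
  expect_equal(nw$semantics, "com_distance")
})

test_that("atom-contact costs divide the count by the source residue's atoms", {
  # residue A: 5 atoms, residue B: 4 atoms, exactly 2 cross pairs under 3.5 A
  topo <- make_line_topology(rep(0, 9), rep(0.1, 9), rep(1.5, 9),
                             res_of = c(rep(1, 5), rep(2, 4)))
  xyz <- rbind(
    c(0, 0, 0), c(0, 2, 0), c(0, 4, 0), c(0, 6, 0), c(0, 8, 0),     # A
    c(3, 0, 0), c(3, 2, 0), c(30, 0, 0), c(30, 2, 0)                # B
  )
  # contacts: A1-B1 (3.0), A1-B2 (~3.6? no: dist((0,0),(3,2))=3.606 >3.5),
  # A2-B2 (3.0): exactly A1-B1, A2-B2, plus A2-B1 (3.606, out) -> c = 2
  net <- build_atom_contact_network(topo, xyz)
  expect_true(net$directed)
  expect_equal(net$costs[1, 2], 5 / 2)
  expect_equal(net$costs[2, 1], 4 / 2)
  # both directions recover the same raw count c
  expect_equal(5 / net$costs[1, 2], 4 / net$costs[2, 1])
})

test_that("atom-contact boundary is strict and zero contacts mean no edge", {
  topo <- make_line_topology(rep(0, 2), rep(0.1, 2), rep(1.5, 2), res_of = 1:2)
  at_3.5 <- rbind(c(0, 0, 0), c(3.5, 0, 0))
  net <- build_atom_contact_network(topo, at_3.5)
  expect_false(is.finite(net$costs[1, 2]))
  expect_false(is.finite(net$costs[2, 1]))
  just_in <- rbind(c(0, 0, 0), c(3.499, 0, 0))
  net2 <- build_atom_contact_network(topo, just_in)
  expect_equal(net2$costs[1, 2], 1)
  # equal atom counts give symmetric costs whatever c is
  expect_equal(net2$costs[1, 2], net2$costs[2, 1])
})

test_that("energy network inverts mean |E| and drops empty pairs", {
  m <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m[1, 2] <- m[2, 1] <- 0.5
  m[2, 3] <- m[3, 2] <- 4
  pem <- reinet:::new_pair_energy_matrix(m, n_frames = 1L, params = nb_params())
  net <- build_energy_network(pem)
  expect_equal(net$costs[1, 2], 2.0)
  expect_equal(net$costs[2, 3], 0.25)
  expect_false(is.finite(net$costs[1, 3]))
  expect_false(net$directed)
  expect_equal(net$semantics, "inv_energy")
})

test_that("attractive and repulsive interactions of equal strength get equal cost", {
  # same geometry, charges flipped on one residue: +E vs -E, same |E|
  topo_att <- make_line_topology(c(0.3, -0.3), c(0, 0), c(1.5, 1.5), res_of = 1:2)
  topo_rep <- make_line_topology(c(0.3, 0.3), c(0, 0), c(1.5, 1.5), res_of = 1:2)
  coords <- array(0, dim = c(2, 3, 1)); coords[2, 1, 1] <- 6
  pem_att <- pair_energy_matrix(topo_att, reinet:::new_trajectory(topo_att, coords))
  pem_rep <- pair_energy_matrix(topo_rep, reinet:::new_trajectory(topo_rep, coords))
  e_att <- residue_pair_energy(topo_att, coords[, , 1], 0, 1)
  e_rep <- residue_pair_energy(topo_rep, coords[, , 1], 0, 1)
  expect_lt(e_att, 0)
  expect_gt(e_rep, 0)
  net_att <- build_energy_network(pem_att)
  net_rep <- build_energy_network(pem_rep)
  expect_equal(net_att$costs[1, 2], net_rep$costs[1, 2], tolerance = 1e-14)
})

test_that("network construction rejects nonpositive costs and asymmetric undirected input", {
  expect_error(resnet(matrix(c(Inf, -1, -1, Inf), 2), semantics = "synthetic"),
               class = "reinet_validation_error")
  m <- matrix(c(Inf, 1, 2, Inf), 2)
  expect_error(resnet(m, directed = FALSE, semantics = "synthetic"),
               class = "reinet_validation_error")
  expect_silent(resnet(m, directed = TRUE, semantics = "synthetic"))
})

test_that("strengthening one pair never lengthens any shortest path", {
  set.seed(99)
  for (rep in 1:5) {
    sys <- make_toy_system(fixture_spec(n_residues = 5, seed = 100 + rep,
                                        geometry = "globule", spacing = 6))
    pem <- pair_energy_matrix(sys$topology, sys$trajectory)
    d0 <- all_pairs_shortest_paths(build_energy_network(pem))
    m <- unclass(pem)
    nz <- which(m > 0 & upper.tri(m), arr.ind = TRUE)
    pick <- nz[sample(nrow(nz), 1), ]
    m[pick[1], pick[2]] <- m[pick[1], pick[2]] * 5
    m[pick[2], pick[1]] <- m[pick[1], pick[2]]
    pem2 <- reinet:::new_pair_energy_matrix(m, attr(pem, "n_frames"), nb_params())
    d1 <- all_pairs_shortest_paths(build_energy_network(pem2))
    expect_true(all(unclass(d1) <= unclass(d0) + 1e-12))
  }
})
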