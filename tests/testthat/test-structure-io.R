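# Readers/writers: fixture round trips, exclusion classification, sequence
# extraction, B-factor annotated output.

test_that("generated PSF/parameter/XYZ files round-trip to the same system", {
  sys <- make_toy_system(fixture_spec(n_residues = 4, seed = 11, n_frames = 3),
                         dir = file.path(tempdir(), "rt1"))
  topo2 <- read_topology(sys$paths$psf, sys$paths$prm)
  traj2 <- read_trajectory(topo2, sys$paths$traj)

  expect_equal(nrow(topo2$atoms), nrow(sys$topology$atoms))
  expect_equal(topo2$residues$label, sys$topology$residues$label)
  expect_equal(topo2$atoms$charge, sys$topology$atoms$charge, tolerance = 1e-5)
  expect_equal(topo2$atoms$lj_eps, sys$topology$atoms$lj_eps, tolerance = 1e-9)
  expect_equal(topo2$atoms$mass, sys$topology$atoms$mass, tolerance = 1e-3)
  expect_equal(dim(traj2$coords), dim(sys$trajectory$coords))
  expect_equal(traj2$coords, sys$trajectory$coords, tolerance = 1e-5)
  # bonds and therefore exclusion classes survive the round trip exactly
  expect_equal(topo2$exclusions, sys$topology$exclusions)
})

test_that("PDB written by the generator reads back with labels preserved", {
  sys <- make_toy_system(fixture_spec(n_residues = 3, seed = 2),
                         dir = file.path(tempdir(), "rt2"))
  st <- read_structure(sys$paths$pdb)
  expect_equal(n_residues(st$topology), 3L)
  expect_equal(st$topology$residues$label, c("1", "2", "3"))
  # charges unknown from a bare PDB
  expect_true(all(is.na(st$topology$atoms$charge)))
  expect_equal(st$frame$coords, sys$trajectory$coords[, , 1], tolerance = 2e-3)
})

test_that("a file with only HETATM water is an empty-input error", {
  p <- file.path(tempdir(), "water.pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00",
    "HETATM    2  H1  HOH A   1       0.960   0.000   0.000  1.00  0.00",
    "END"), p)
  expect_error(read_structure(p), class = "reinet_validation_error")
})

test_that("exclusion classes on a linear 4-atom chain are 1-2/1-3/1-4", {
  topo <- make_line_topology(
    charges = rep(0, 4), eps = rep(0.1, 4), rmin_half = rep(1.5, 4),
    res_of = c(1, 1, 2, 2),
    bonds = tibble::tibble(i = 1:3, j = 2:4)
  )
  ex <- dplyr::arrange(topo$exclusions, i, j)
  expect_equal(ex$class[ex$i == 1 & ex$j == 2], 1L)
  expect_equal(ex$class[ex$i == 2 & ex$j == 3], 1L)
  expect_equal(ex$class[ex$i == 3 & ex$j == 4], 1L)
  expect_equal(ex$class[ex$i == 1 & ex$j == 3], 2L)
  expect_equal(ex$class[ex$i == 2 & ex$j == 4], 2L)
  expect_equal(ex$class[ex$i == 1 & ex$j == 4], 3L)
  expect_equal(nrow(ex), 6L)
})

test_that("exclusion builder agrees with breadth-first bond search on random graphs", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    nb <- sample(3:(n + 2), 1)
    bonds <- unique(tibble::tibble(
      i = sample(n, nb, replace = TRUE), j = sample(n, nb, replace = TRUE)
    ))
    bonds <- bonds[bonds$i != bonds$j, ]
    if (nrow(bonds) == 0) next
    topo <- make_line_topology(rep(0, n), rep(0.1, n), rep(1.5, n),
                               res_of = rep(1, n), bonds = bonds)
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        sep <- bond_separation(bonds, a, b, 1:n)
        row <- topo$exclusions[topo$exclusions$i == a & topo$exclusions$j == b, ]
        if (is.finite(sep) && sep <= 3) {
          expect_equal(row$class, as.integer(sep))
        } else {
          expect_equal(nrow(row), 0L)
        }
      }
    }
  }
})

test_that("unknown atom type in the PSF is a lookup error naming the type", {
  sys <- make_toy_system(fixture_spec(n_residues = 2, seed = 5),
                         dir = file.path(tempdir(), "rt3"))
  psf <- readLines(sys$paths$psf)
  k <- grep("!NATOM", psf) + 1L
  psf[k] <- sub(" T\\d ", " XX ", psf[k])
  bad <- file.path(tempdir(), "bad.psf")
  writeLines(psf, bad)
  expect_error(read_topology(bad, sys$paths$prm), "XX",
               class = "reinet_validation_error")
})

test_that("trajectory stride keeps every stride-th frame in file order", {
  sys <- make_toy_system(fixture_spec(n_residues = 2, seed = 8, n_frames = 10),
                         dir = file.path(tempdir(), "rt4"))
  topo <- sys$topology
  t1 <- read_trajectory(topo, sys$paths$traj, stride = 1)
  t3 <- read_trajectory(topo, sys$paths$traj, stride = 3)
  expect_equal(n_frames(t1), 10L)
  expect_equal(n_frames(t3), 4L)
  expect_equal(t3$frame_index, c(0L, 3L, 6L, 9L))
  expect_equal(t3$coords[, , 2], t1$coords[, , 4])
})

test_that("atom-count mismatch between trajectory and topology is a shape error", {
  sys5 <- make_toy_system(fixture_spec(n_residues = 2, atoms_per_residue = c(3, 3), seed = 1),
                          dir = file.path(tempdir(), "rt5"))
  topo_bigger <- make_line_topology(rep(0, 7), rep(0.1, 7), rep(1.5, 7),
                                    res_of = c(1, 1, 1, 2, 2, 2, 2))
  expect_error(read_trajectory(topo_bigger, sys5$paths$traj),
               class = "reinet_validation_error")
})

test_that("sequence extraction maps standard residues and flags the rest as X", {
  at <- tibble::tibble(
    atom_id = 1:3, name = "CA", type = NA_character_,
    residue_key = c("A:1", "A:2", "A:3"),
    charge = NA_real_, lj_eps = NA_real_, lj_rmin_half = NA_real_, mass = 12
  )
  rs <- tibble::tibble(index = 0:2, key = c("A:1", "A:2", "A:3"),
                       label = c("1", "2", "3"),
                       name = c("ALA", "GLY", "SER"), chain = "A")
  expect_equal(extract_sequence(topology(at, rs)), "AGS")
  rs$name <- c("ALA", "MSE", "SER")
  topo <- topology(at, rs)
  expect_equal(extract_sequence(topo), "AXS")
  expect_equal(extract_sequence(topo, modified = c(MSE = "M")), "AMS")
  expect_equal(nchar(extract_sequence(topo)), n_residues(topo))
})

test_that("profile values land in the B-factor column per residue", {
  sys <- make_toy_system(fixture_spec(n_residues = 2, seed = 3, jitter_sd = 0),
                         dir = file.path(tempdir(), "rt6"))
  out <- file.path(tempdir(), "prof.pdb")
  write_profile_structure(get_frame(sys$trajectory), sys$topology, c(0.5, 2.5), out)
  pdb <- bio3d::read.pdb(out, verbose = FALSE)
  ridx <- match(sys$topology$atoms$residue_key, sys$topology$residues$key)
  expect_equal(pdb$atom$b, c(0.5, 2.5)[ridx])

  expect_warning(
    write_profile_structure(get_frame(sys$trajectory), sys$topology, c(Inf, 1), out),
    "999.99"
  )
  pdb <- bio3d::read.pdb(out, verbose = FALSE)
  expect_equal(unique(pdb$atom$b[ridx == 1]), 999.99)
})
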