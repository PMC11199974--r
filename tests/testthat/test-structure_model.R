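test_that("multi-model PDB files become one frame per MODEL, in nm", {
  m1 <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 3.00, 2.00, 1.00, "C"),
          pdb_atom_line(2, "CB", "ALA", "A", 1, 4.00, 2.00, 1.00, "C"),
          pdb_atom_line(3, "O",  "ALA", "A", 1, 5.00, 2.00, 1.00, "O"))
  m2 <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 3.10, 2.00, 1.00, "C"),
          pdb_atom_line(2, "CB", "ALA", "A", 1, 4.10, 2.00, 1.00, "C"),
          pdb_atom_line(3, "O",  "ALA", "A", 1, 5.10, 2.00, 1.00, "O"))
  tr <- read_structure(write_fixture_pdb(list(m1, m2)))
  expect_equal(n_frames(tr), 2L)
  expect_equal(nrow(tr$topology), 3L)
  # Angstrom -> nm on read
  expect_equal(tr$coords[1, 1, 1], 0.300)
  expect_equal(tr$coords[2, 1, 1], 0.310)

  # no MODEL records: single-frame convention
  tr1 <- read_structure(write_fixture_pdb(list(m1)))
  expect_equal(n_frames(tr1), 1L)
})

test_that("malformed coordinates and inconsistent models are rejected", {
  bad <- pdb_atom_line(1, "CA", "ALA", "A", 1, 3, 2, 1, "C")
  substr(bad, 32, 38) <- "abcdefg"
  f <- write_fixture_pdb(list(bad))
  expect_error(read_structure(f), "line 1")

  m1 <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 3, 2, 1, "C"))
  m2 <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 3, 2, 1, "C"),
          pdb_atom_line(2, "CB", "ALA", "A", 1, 4, 2, 1, "C"))
  expect_error(read_structure(write_fixture_pdb(list(m1, m2))),
               "inconsistent atom count")
})

test_that("trajectories round-trip through PDB to coordinate precision", {
  sim <- generate_two_state_trajectory(n_frames = 5L, seed = 3L)
  f <- tempfile(fileext = ".pdb")
  write_structure(sim$trajectory, f)
  back <- read_structure(f)
  expect_identical(back$topology$name, sim$trajectory$topology$name)
  expect_identical(back$topology$residue_name,
                   sim$trajectory$topology$residue_name)
  # PDB stores 3 decimals in Angstrom = 1e-4 nm
  expect_lt(max(abs(back$coords - sim$trajectory$coords)), 1e-4 + 1e-12)
})

test_that("aromatic ring detection follows side-chain chemistry, not coordinates", {
  tr <- aromatic_fixture_trajectory()
  rings <- detect_aromatic_rings(tr)
  kinds <- vapply(rings, `[[`, character(1), "ring_kind")
  res <- vapply(rings, function(r) residue_key_string(r$residue_key), character(1))
  # Trp: one six-membered + one five-membered; Phe: one six-membered; Ala: none
  expect_setequal(res[kinds == "six_membered"], c("A:28:TRP", "A:23:PHE"))
  expect_equal(res[kinds == "five_membered"], "A:28:TRP")
  sizes <- vapply(rings, function(r) length(r$member_atom_indices), integer(1))
  expect_setequal(sizes[res == "A:28:TRP"], c(6L, 5L))
  expect_false(any(grepl("ALA", res)))

  # selection by residue name and by chain-qualified id agree
  expect_length(detect_aromatic_rings(tr, "PHE"), 1L)
  expect_length(detect_aromatic_rings(tr, "A:23"), 1L)

  # topology-only: scrambling coordinates changes nothing
  tr2 <- tr
  tr2$coords[] <- rnorm(length(tr2$coords))
  expect_identical(detect_aromatic_rings(tr2), rings)
})

test_that("an aromatic residue missing a ring atom is reported by name", {
  lines <- aromatic_fixture_lines()
  lines <- lines[!grepl(" CZ2", lines)]
  tr <- read_structure(write_fixture_pdb(list(lines)))
  expect_error(detect_aromatic_rings(tr), "A:28.*TRP.*CZ2")
})

test_that("C-H donor inference keeps carbon-bound hydrogens only", {
  tr <- aromatic_fixture_trajectory()
  donors <- infer_ch_donors(tr)
  # H1 (1.09 A from C1, 2.1 A from O5) is a donor; hydroxyl HO3 is not
  expect_length(donors, 1L)
  expect_equal(tr$topology$name[donors[[1]]$hydrogen_index], "H1")
  expect_equal(tr$topology$name[donors[[1]]$carbon_index], "C1")
  expect_equal(donors[[1]]$residue_key$residue_name, "NAG")

  # residue not on the whitelist contributes nothing
  expect_length(infer_ch_donors(tr, glycan_residue_names = "XYZ"), 0L)

  # donor count never exceeds hydrogen count
  n_h <- sum(tr$topology$element == "H" & tr$topology$residue_name == "NAG")
  expect_lte(length(donors), n_h)
})

test_that("a glycan residue without hydrogens is an error, not a silent zero", {
  lines <- aromatic_fixture_lines()
  lines <- lines[!(grepl("NAG", lines) & grepl("^H", substr(lines, 13, 16)))]
  tr <- read_structure(write_fixture_pdb(list(lines)))
  expect_error(infer_ch_donors(tr), "no hydrogen")
})

test_that("ring centers are unweighted means, equivariant under rigid motion", {
  tr <- aromatic_fixture_trajectory()
  ring <- detect_aromatic_rings(tr, "PHE")[[1]]
  fc <- frame_coords(tr, 1)
  # regular hexagon centred at (1, 0, 0) nm
  expect_equal(ring_center(ring, fc), c(1, 0, 0), tolerance = 1e-12)

  set.seed(99)
  for (k in 1:5) {
    R <- random_rotation(); t <- rnorm(3)
    moved <- apply_rigid(fc, R, t)
    expect_lt(sqrt(sum((ring_center(ring, moved) -
                          (as.vector(R %*% ring_center(ring, fc)) + t))^2)),
              1e-12)
  }

  # degenerate ring with coincident atoms
  fc2 <- fc
  fc2[ring$member_atom_indices, ] <- rep(c(0.5, 0.6, 0.7), each = 6)
  expect_equal(ring_center(ring, fc2), c(0.5, 0.6, 0.7))
})
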