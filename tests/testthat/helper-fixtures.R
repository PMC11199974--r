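# Fixture builders: tiny PDB files and coordinate sets constructed in code.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element, record = "ATOM") {
  # fixed-column PDB ATOM/HETATM line; coordinates in Angstrom
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resname, chain, resno, x, y, z, 1, 0, element)
}

write_fixture_pdb <- function(models, path = tempfile(fileext = ".pdb")) {
  # models: list of character vectors (atom lines); >1 model gets MODEL blocks
  lines <- if (length(models) == 1L) {
    c(models[[1L]], "END")
  } else {
    unlist(lapply(seq_along(models), function(i) {
      c(sprintf("MODEL %8d", i), models[[i]], "ENDMDL")
    }))
  }
  writeLines(c(lines, "END"), path)
  path
}

# A Trp + Phe + Ala topology with plausible (not physical) coordinates,
# plus a NAG bearing ring C-H, hydroxyl O-H and an O5 decoy.
aromatic_fixture_lines <- function() {
  trp_ring6 <- c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
  trp_ring5 <- c("CG", "CD1", "NE1")  # CE2/CD2 shared with the 6-ring
  i <- 0
  lines <- character(0)
  add <- function(name, resname, chain, resno, x, y, z, el, rec = "ATOM") {
    i <<- i + 1
    lines <<- c(lines, pdb_atom_line(i, name, resname, chain, resno,
                                     x, y, z, el, rec))
  }
  ang <- 2 * pi * (0:5) / 6
  for (k in 1:6) add(trp_ring6[k], "TRP", "A", 28,
                     1.4 * cos(ang[k]), 1.4 * sin(ang[k]), 0, "C")
  add("CG",  "TRP", "A", 28, -1.4, 1.2, 0.3, "C")
  add("CD1", "TRP", "A", 28, -2.1, 0.3, 0.5, "C")
  add("NE1", "TRP", "A", 28, -1.6, -0.9, 0.4, "N")
  for (k in 1:6) add(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")[k], "PHE", "A", 23,
                     10 + 1.4 * cos(ang[k]), 1.4 * sin(ang[k]), 0, "C")
  add("CB", "ALA", "A", 5, 20, 0, 0, "C")
  # NAG: H1 bonded to C1 (1.09 A), O5 decoy 2.1 A from H1; hydroxyl H3-O3
  add("C1", "NAG", "G", 1, 0, 0, 3.0, "C", "HETATM")
  add("H1", "NAG", "G", 1, 0, 0, 1.91, "H", "HETATM")
  add("O5", "NAG", "G", 1, 0, 2.0, 3.6, "O", "HETATM")
  add("O3", "NAG", "G", 1, 4, 0, 3.0, "O", "HETATM")
  add("HO3", "NAG", "G", 1, 4, 0, 2.03, "H", "HETATM")
  lines
}

aromatic_fixture_trajectory <- function() {
  read_structure(write_fixture_pdb(list(aromatic_fixture_lines())))
}

# random rigid-body transform
random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3))) |> (\(Q) if (det(Q) < 0) -Q else Q)()
}

apply_rigid <- function(coords_mat, R, t) {
  sweep(coords_mat %*% t(R), 2, -t)
}

# independent brute-force coordination number: plain double loop
brute_coordination <- function(frame_coords, rings, donors, params) {
  total <- 0
  for (ring in rings) {
    ctr <- colMeans(frame_coords[ring$member_atom_indices, , drop = FALSE])
    for (d in donors) {
      h <- frame_coords[d$hydrogen_index, ]
      r <- sqrt(sum((h - ctr)^2))
      x <- r / params$r0
      val <- if (abs(r - params$r0) < 1e-12) params$n / params$m
             else (1 - x^params$n) / (1 - x^params$m)
      total <- total + val
    }
  }
  total
}

# five-protein filter example: A passes everything, B fails p, C fails FC,
# D lacks two replicates with >= 2 peptides, E passes
worked_example <- function() {
  stats <- data.frame(
    accession = c("A", "B", "C", "D", "E"),
    fold_change = c(10, 6, 4, 8, 20),
    log2_fc = log2(c(10, 6, 4, 8, 20)),
    p_value = c(0.001, 0.02, 0.001, 0.005, 1e-5),
    degenerate = FALSE, stringsAsFactors = FALSE)
  pep <- rbind(c(3, 3, 2), c(3, 3, 3), c(3, 3, 3), c(2, 1, 1), c(2, 2, 0))
  tab <- quant_table(stats$accession, matrix(10, 5, 3), matrix(1, 5, 3), pep)
  list(stats = stats, tab = tab)
}
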