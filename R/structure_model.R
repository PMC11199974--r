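#' @importFrom stats setNames
NULL

# Ring atom definitions for the aromatic side chains. Trp contributes two
# rings: the six-membered benzene ring and the five-membered pyrrole ring.
.RING_DEFS <- list(
  TRP = list(
    list(kind = "six_membered",  atoms = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
    list(kind = "five_membered", atoms = c("CG", "CD1", "NE1", "CE2", "CD2"))
  ),
  PHE = list(list(kind = "six_membered", atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))),
  TYR = list(list(kind = "six_membered", atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))),
  HIS = list(list(kind = "five_membered", atoms = c("CG", "ND1", "CD1", "CE1", "NE2")))
)

#' Default glycan residue whitelist
#'
#' Three-letter PDB residue codes treated as glycan residues when inferring
#' C-H donors. Covers the common pyranose units of N-glycans (GlcNAc,
#' fucose, mannose, galactose, glucose).
#'
#' @export
default_glycan_residues <- function() {
  c("NAG", "FUC", "BMA", "MAN", "GAL", "NDG", "GLC")
}

.guess_element <- function(name) {
  # strip digits/primes; leading digit (e.g. "1HB1") implies hydrogen naming
  vapply(name, function(nm) {
    if (grepl("^[0-9]", nm)) return("H")
    stripped <- gsub("[0-9']", "", nm)
    if (nchar(stripped) == 0L) return("")
    toupper(substr(stripped, 1L, 1L))
  }, character(1), USE.NAMES = FALSE)
}

.residue_key <- function(chain_id, residue_number, insertion_code, residue_name) {
  list(chain_id = chain_id, residue_number = as.integer(residue_number),
       insertion_code = insertion_code, residue_name = residue_name)
}

#' Format a residue key as "chain:number[insert]:name"
#'
#' @param key residue key list with chain_id, residue_number, insertion_code,
#'   residue_name
#' @return single character string
#' @export
residue_key_string <- function(key) {
  paste0(key$chain_id, ":", key$residue_number,
         ifelse(nzchar(key$insertion_code), key$insertion_code, ""),
         ":", key$residue_name)
}

.topology_residue_id <- function(topology) {
  paste0(topology$chain_id, ":", topology$residue_number,
         ifelse(nzchar(topology$insertion_code), topology$insertion_code, ""))
}

# Pre-validate a PDB file: coordinate fields must parse, and MODEL blocks
# (when present) must all hold the same number of atom records.
.validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  for (i in which(is_atom)) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (anyNA(coords)) {
      stop(sprintf("PDB parse error at line %d: non-numeric coordinate field", i),
           call. = FALSE)
    }
  }
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1L) {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) != length(model_starts)) {
      stop("PDB topology error: unbalanced MODEL/ENDMDL records", call. = FALSE)
    }
    counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, model_ends)
    if (length(unique(counts)) != 1L) {
      stop(sprintf("PDB topology error: inconsistent atom count across models (%s)",
                   paste(unique(counts), collapse = ", ")), call. = FALSE)
    }
  }
  invisible(length(model_starts))
}

#' Read a (multi-model) PDB file into a trajectory
#'
#' Each MODEL block becomes one frame; a file without MODEL records yields a
#' single-frame trajectory. Coordinates are converted from Angstrom to nm on
#' read (all internal lengths are nm). Alternate locations other than blank
#' or 'A' are dropped.
#'
#' @param path path to a PDB file
#' @param time_step_ns time between frames in ns, or NA if unknown
#' @return object of class `glyco_trajectory` with elements `topology`
#'   (data.frame of atom records), `coords` (frames x atoms x 3 array, nm),
#'   and `time_step_ns`
#' @export
read_structure <- function(path, time_step_ns = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_lines(lines)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  alt <- atom$alt
  keep <- is.na(alt) | alt == "" | alt == "A"
  atom <- atom[keep, , drop = FALSE]

  elesy <- atom$elesy
  elesy[is.na(elesy)] <- ""
  need <- !nzchar(elesy)
  elesy[need] <- .guess_element(atom$elety[need])

  topology <- data.frame(
    serial = as.integer(atom$eleno),
    name = atom$elety,
    element = elesy,
    residue_name = atom$resid,
    chain_id = ifelse(is.na(atom$chain), "", atom$chain),
    residue_number = as.integer(atom$resno),
    insertion_code = ifelse(is.na(atom$insert), "", atom$insert),
    alt_loc = ifelse(is.na(atom$alt), "", atom$alt),
    stringsAsFactors = FALSE
  )

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  # subset xyz columns to kept atoms, convert A -> nm
  xyz_idx <- bio3d::atom2xyz(which(keep))
  xyz <- xyz[, xyz_idx, drop = FALSE] * 0.1
  n_frames <- nrow(xyz)
  n_atoms <- nrow(topology)
  coords <- array(NA_real_, dim = c(n_frames, n_atoms, 3L))
  for (f in seq_len(n_frames)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates in ", path, call. = FALSE)

  structure(list(topology = topology, coords = coords,
                 time_step_ns = time_step_ns),
            class = "glyco_trajectory")
}

#' Write a trajectory to a multi-model PDB file
#'
#' Inverse of [read_structure()]: coordinates are converted back from nm to
#' Angstrom. Multi-frame trajectories are written as MODEL/ENDMDL blocks.
#'
#' @param trajectory a `glyco_trajectory`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_structure <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "glyco_trajectory"))
  top <- trajectory$topology
  n_frames <- dim(trajectory$coords)[1]
  xyz <- matrix(NA_real_, nrow = n_frames, ncol = nrow(top) * 3L)
  for (f in seq_len(n_frames)) {
    xyz[f, ] <- as.vector(t(trajectory$coords[f, , , drop = TRUE])) * 10
  }
  if (n_frames == 1L) xyz <- xyz[1, ]
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = top$residue_number, resid = top$residue_name,
                   eleno = top$serial, elety = top$name,
                   chain = ifelse(nzchar(top$chain_id), top$chain_id, " "),
                   insert = ifelse(nzchar(top$insertion_code), top$insertion_code, ""),
                   elesy = top$element)
  invisible(path)
}

#' Number of frames in a trajectory
#' @param trajectory a `glyco_trajectory`
#' @return integer frame count
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[1]

#' Detect aromatic side-chain rings
#'
#' Trp yields two rings (six-membered benzene and five-membered pyrrole);
#' Phe and Tyr yield one six-membered ring each. Residues without an
#' aromatic side chain contribute no rings. Detection uses topology (atom
#' names) only, never coordinates. His rings are excluded unless
#' `include_histidine = TRUE`.
#'
#' @param trajectory a `glyco_trajectory`
#' @param residue_selection either a character vector of residue names
#'   (e.g. `c("TRP","PHE")`) or of chain-qualified residue ids
#'   (`"A:28"`); NULL selects all residues
#' @param include_histidine also detect His imidazole rings
#' @return list of rings, each a list with `residue_key`, `ring_kind`,
#'   `member_atom_indices`
#' @export
detect_aromatic_rings <- function(trajectory, residue_selection = NULL,
                                  include_histidine = FALSE) {
  top <- trajectory$topology
  res_id <- .topology_residue_id(top)
  res_tab <- unique(data.frame(id = res_id, name = top$residue_name,
                               chain = top$chain_id, number = top$residue_number,
                               insert = top$insertion_code,
                               stringsAsFactors = FALSE))
  if (!is.null(residue_selection)) {
    by_name <- res_tab$name %in% residue_selection
    by_id <- res_tab$id %in% residue_selection
    if (!any(by_name | by_id)) {
      stop("residue selection matches nothing in topology", call. = FALSE)
    }
    res_tab <- res_tab[by_name | by_id, , drop = FALSE]
  }
  defs <- .RING_DEFS
  if (!include_histidine) defs$HIS <- NULL

  rings <- list()
  for (i in seq_len(nrow(res_tab))) {
    rname <- res_tab$name[i]
    if (is.null(defs[[rname]])) next
    in_res <- which(res_id == res_tab$id[i] & top$residue_name == rname)
    for (def in defs[[rname]]) {
      idx <- vapply(def$atoms, function(a) {
        hit <- in_res[top$name[in_res] == a]
        if (length(hit) == 0L) {
          stop(sprintf("incomplete ring: residue %s:%s%s (%s) is missing atom %s",
                       res_tab$chain[i], res_tab$number[i], res_tab$insert[i],
                       rname, a), call. = FALSE)
        }
        hit[1L]
      }, integer(1))
      rings[[length(rings) + 1L]] <- list(
        residue_key = .residue_key(res_tab$chain[i], res_tab$number[i],
                                   res_tab$insert[i], rname),
        ring_kind = def$kind,
        member_atom_indices = unname(idx)
      )
    }
  }
  rings
}

#' Infer glycan C-H donor groups
#'
#' Every hydrogen in a whitelisted glycan residue whose nearest heavy atom
#' (within the same residue, frame 1 coordinates) is a carbon within
#' `bond_cutoff_nm` becomes a donor; hydroxyl/amide hydrogens (nearest heavy
#' atom O or N) are excluded. Ties are broken by smaller distance, then
#' lower atom serial.
#'
#' @param trajectory a `glyco_trajectory`
#' @param glycan_residue_names 3-letter codes treated as glycan residues
#' @param bond_cutoff_nm maximum C-H bond length in nm
#' @return list of donors, each a list with `carbon_index`,
#'   `hydrogen_index`, `residue_key`
#' @export
infer_ch_donors <- function(trajectory,
                            glycan_residue_names = default_glycan_residues(),
                            bond_cutoff_nm = 0.13) {
  top <- trajectory$topology
  pos <- trajectory$coords[1, , , drop = TRUE]
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3L)
  res_id <- .topology_residue_id(top)
  glyc_rows <- which(top$residue_name %in% glycan_residue_names)
  donors <- list()
  for (rid in unique(res_id[glyc_rows])) {
    in_res <- which(res_id == rid & top$residue_name %in% glycan_residue_names)
    h_idx <- in_res[top$element[in_res] == "H"]
    heavy_idx <- in_res[top$element[in_res] != "H"]
    if (length(h_idx) == 0L) {
      stop(sprintf("glycan residue %s (%s) has no hydrogen atoms; the CH-pi statistic requires explicit hydrogens",
                   rid, top$residue_name[in_res[1]]), call. = FALSE)
    }
    for (h in h_idx) {
      d <- sqrt(rowSums((pos[heavy_idx, , drop = FALSE] -
                           matrix(pos[h, ], nrow = length(heavy_idx),
                                  ncol = 3L, byrow = TRUE))^2))
      ord <- order(d, top$serial[heavy_idx])
      nearest <- heavy_idx[ord[1L]]
      if (top$element[nearest] == "C" && d[ord[1L]] <= bond_cutoff_nm) {
        donors[[length(donors) + 1L]] <- list(
          carbon_index = nearest, hydrogen_index = h,
          residue_key = .residue_key(top$chain_id[h], top$residue_number[h],
                                     top$insertion_code[h], top$residue_name[h])
        )
      }
    }
  }
  donors
}

#' Geometric center of an aromatic ring in one frame
#'
#' Unweighted mean of the ring member-atom positions.
#'
#' @param ring a ring from [detect_aromatic_rings()]
#' @param frame_coords atoms x 3 matrix of positions (nm) for one frame
#' @return length-3 numeric vector (nm)
#' @export
ring_center <- function(ring, frame_coords) {
  p <- frame_coords[ring$member_atom_indices, , drop = FALSE]
  if (!all(is.finite(p))) stop("non-finite ring member coordinates", call. = FALSE)
  colMeans(p)
}

#' Extract one frame's coordinate matrix
#' @param trajectory a `glyco_trajectory`
#' @param i frame index (1-based)
#' @return atoms x 3 matrix (nm)
#' @export
frame_coords <- function(trajectory, i) {
  m <- trajectory$coords[i, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = 3L)
  m
}

#' Summarize detected rings and donors as a JSON-ready list
#'
#' @param trajectory a `glyco_trajectory`
#' @param ... passed to [detect_aromatic_rings()] and [infer_ch_donors()]
#' @return list with `n_atoms`, `n_frames`, `rings`, `donors`
#' @export
topology_summary <- function(trajectory, ...) {
  rings <- detect_aromatic_rings(trajectory)
  donors <- tryCatch(infer_ch_donors(trajectory), error = function(e) list())
  list(
    n_atoms = nrow(trajectory$topology),
    n_frames = n_frames(trajectory),
    rings = lapply(rings, function(r) list(
      residue = residue_key_string(r$residue_key),
      kind = r$ring_kind, n_members = length(r$member_atom_indices))),
    donors = lapply(donors, function(d) list(
      residue = residue_key_string(d$residue_key),
      carbon = trajectory$topology$name[d$carbon_index],
      hydrogen = trajectory$topology$name[d$hydrogen_index]))
  )
}
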