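#' Heavy-atom contact test for one residue pair in one frame
#'
#' A pair is in contact when the minimum distance between their heavy
#' (non-hydrogen) atoms is at or below the cutoff.
#'
#' @param frame_coords atoms x 3 matrix (nm)
#' @param idx_a,idx_b topology indices of heavy atoms of the two residues
#' @param cutoff_nm contact cutoff in nm
#' @return logical
#' @export
residue_pair_in_contact <- function(frame_coords, idx_a, idx_b, cutoff_nm = 0.45) {
  stopifnot(length(idx_a) > 0L, length(idx_b) > 0L)
  .min_pair_distance(frame_coords, idx_a, idx_b) <= cutoff_nm
}

.min_pair_distance <- function(frame_coords, idx_a, idx_b) {
  a <- frame_coords[idx_a, , drop = FALSE]
  b <- frame_coords[idx_b, , drop = FALSE]
  # squared cross-distance matrix via the expansion |a-b|^2 = |a|^2+|b|^2-2ab
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

#' Residue-glycan interaction-frequency network
#'
#' For every (protein residue, glycan residue) pair that is in heavy-atom
#' contact in at least one frame, reports the fraction of frames in contact
#' (the quantity edge thickness is proportional to in interaction diagrams)
#' and the mean over frames of the minimum heavy-atom distance.
#'
#' @param trajectory a `glyco_trajectory`
#' @param protein_residue_names residue names counted as protein side
#' @param glycan_residue_names residue names counted as glycan side
#' @param cutoff_nm heavy-atom contact cutoff in nm (default 0.45)
#' @return object of class `interaction_network`: `edges` data.frame
#'   (protein_residue, glycan_residue, frequency, mean_min_distance_nm) and
#'   `frame_count`
#' @export
interaction_frequencies <- function(trajectory,
                                    protein_residue_names = NULL,
                                    glycan_residue_names = default_glycan_residues(),
                                    cutoff_nm = 0.45) {
  top <- trajectory$topology
  res_id <- .topology_residue_id(top)
  heavy <- top$element != "H"
  is_glyc <- top$residue_name %in% glycan_residue_names
  if (is.null(protein_residue_names)) {
    is_prot <- !is_glyc
  } else {
    is_prot <- top$residue_name %in% protein_residue_names
  }
  prot_res <- unique(res_id[is_prot & heavy])
  glyc_res <- unique(res_id[is_glyc & heavy])
  if (length(prot_res) == 0L || length(glyc_res) == 0L) {
    stop("empty protein or glycan residue selection", call. = FALSE)
  }
  prot_idx <- lapply(prot_res, function(r) which(res_id == r & is_prot & heavy))
  glyc_idx <- lapply(glyc_res, function(r) which(res_id == r & is_glyc & heavy))
  label <- function(rid) {
    row <- match(rid, res_id)
    paste0(rid, ":", top$residue_name[row])
  }

  nf <- n_frames(trajectory)
  np <- length(prot_res); ng <- length(glyc_res)
  contact_count <- matrix(0L, np, ng)
  min_dist_sum <- matrix(0, np, ng)
  for (f in seq_len(nf)) {
    fc <- frame_coords(trajectory, f)
    for (i in seq_len(np)) {
      for (j in seq_len(ng)) {
        d <- .min_pair_distance(fc, prot_idx[[i]], glyc_idx[[j]])
        min_dist_sum[i, j] <- min_dist_sum[i, j] + d
        if (d <= cutoff_nm) contact_count[i, j] <- contact_count[i, j] + 1L
      }
    }
  }
  keep <- which(contact_count > 0L, arr.ind = TRUE)
  edges <- data.frame(
    protein_residue = vapply(prot_res[keep[, 1]], label, character(1)),
    glycan_residue = vapply(glyc_res[keep[, 2]], label, character(1)),
    frequency = contact_count[keep] / nf,
    mean_min_distance_nm = min_dist_sum[keep] / nf,
    stringsAsFactors = FALSE
  )
  edges <- edges[order(-edges$frequency, edges$protein_residue,
                       edges$glycan_residue), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, frame_count = nf),
            class = "interaction_network")
}

#' Export an interaction network as an edge-list CSV
#'
#' Rows are sorted by descending frequency, ties broken by residue keys;
#' frequency and mean minimum distance are written with 4 decimals so that
#' re-export of a re-imported file is byte-identical.
#'
#' @param network an `interaction_network`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
export_network <- function(network, path) {
  e <- network$edges
  out <- data.frame(
    protein_residue = e$protein_residue,
    glycan_residue = e$glycan_residue,
    frequency = sprintf("%.4f", e$frequency),
    mean_min_distance_nm = sprintf("%.4f", e$mean_min_distance_nm),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an edge-list CSV written by [export_network()]
#'
#' @param path CSV path
#' @param frame_count frame count to attach (not stored in the CSV)
#' @return an `interaction_network`
#' @export
import_network <- function(path, frame_count = NA_integer_) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(frequency = "numeric",
                                      mean_min_distance_nm = "numeric"))
  structure(list(edges = e, frame_count = frame_count),
            class = "interaction_network")
}
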