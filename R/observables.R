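# Ensemble-level stability observables: protein-ligand hydrogen-bond
# time series and occupancy, and representative-frame selection from a
# per-frame energy table.

# protein-ligand hydrogen bonds of one frame (either direction)
frame_ligand_hbonds <- function(ensemble, f, table, d_max, angle_max,
                                angle_def) {
  hb <- find_hbonds(frame_structure(ensemble, f), table,
                    d_max = d_max, angle_max = angle_max,
                    angle_def = angle_def)
  hb[xor(hb$donor_het, hb$acceptor_het), , drop = FALSE]
}

#' Per-frame count of protein-ligand hydrogen bonds
#'
#' Counts, in every frame, the hydrogen bonds with one partner in the
#' protein and one in a ligand (HETATM) group, under the geometric
#' criterion of [find_hbonds()].
#'
#' @param ensemble An `ensemble` whose topology contains a ligand.
#' @param d_max,angle_max,angle_def Hydrogen-bond criterion, see
#'   [find_hbonds()].
#' @return Integer vector of length `n_frames(ensemble)`.
#' @export
hbond_count_series <- function(ensemble, d_max = 3.5, angle_max = 30,
                               angle_def = "HDA") {
  stopifnot(inherits(ensemble, "ensemble"))
  if (!any(ensemble$topology$atoms$het))
    stop("ensemble topology has no ligand group")
  table <- donor_acceptor_table(ensemble$topology)
  vapply(seq_len(n_frames(ensemble)), function(f)
    nrow(frame_ligand_hbonds(ensemble, f, table, d_max, angle_max, angle_def)),
    integer(1))
}

#' Hydrogen-bond occupancy of protein residues towards a ligand
#'
#' For each protein residue, the fraction of frames in which it forms at
#' least one hydrogen bond with a ligand group: the fraction of time the
#' residue participates in ligand recognition.
#'
#' @inheritParams hbond_count_series
#' @return An `occupancy_report`: data.frame with columns `resindex`,
#'   `label` and `occupancy` (in \[0, 1\]), plus attributes `n_frames` and
#'   `partner` (ligand residue names).
#' @export
hbond_occupancy <- function(ensemble, d_max = 3.5, angle_max = 30,
                            angle_def = "HDA") {
  stopifnot(inherits(ensemble, "ensemble"))
  if (!any(ensemble$topology$atoms$het))
    stop("ensemble topology has no ligand group")
  table <- donor_acceptor_table(ensemble$topology)
  rt <- residue_table(ensemble$topology)
  nf <- n_frames(ensemble)
  hits <- matrix(0, nrow(rt), nf)
  for (f in seq_len(nf)) {
    hb <- frame_ligand_hbonds(ensemble, f, table, d_max, angle_max, angle_def)
    if (!nrow(hb)) next
    res <- ifelse(hb$donor_het, hb$acceptor_res, hb$donor_res)
    hits[unique(res[!is.na(res)]), f] <- 1
  }
  out <- data.frame(resindex = rt$resindex, label = rt$label,
                    occupancy = rowMeans(hits))
  attr(out, "n_frames") <- nf
  attr(out, "partner") <- unique(ensemble$topology$atoms$resname[
    ensemble$topology$atoms$het])
  class(out) <- c("occupancy_report", "data.frame")
  out
}

#' Select a representative low-energy frame from an ensemble
#'
#' The representative structure is the frame of minimal energy (ties go
#' to the lowest frame index). The backbone RMSD of every frame to that
#' minimal-energy frame is reported, together with the 20 lowest-energy
#' frame indices and their pairwise backbone RMSD matrix for inspection;
#' the selection itself is always the energy minimum.
#'
#' @param ensemble An `ensemble`.
#' @param energies Numeric vector of per-frame energies (opaque input
#'   scalars, one per frame).
#' @param top_n Size of the reported low-energy set (default 20; truncated
#'   when the ensemble is shorter).
#' @return A `representative_selection`: list with `frame_index`, `energy`,
#'   `rmsd_to_min` (per-frame, Angstrom), `top_set` (frame indices sorted
#'   by ascending energy) and `top_rmsd` (pairwise RMSD matrix of the top
#'   set).
#' @export
select_representative <- function(ensemble, energies, top_n = 20) {
  stopifnot(inherits(ensemble, "ensemble"))
  nf <- n_frames(ensemble)
  if (length(energies) != nf)
    stop("energies length (", length(energies), ") does not match frame count (",
         nf, ")")
  best <- which.min(energies)           # ties: lowest index
  bb <- backbone_indices(ensemble$topology)
  ref <- frame_coords(ensemble, best)
  rmsd_to_min <- vapply(seq_len(nf), function(f)
    superpose(frame_coords(ensemble, f), ref, bb)$rmsd, numeric(1))
  top_set <- order(energies, seq_len(nf))[seq_len(min(top_n, nf))]
  k <- length(top_set)
  top_rmsd <- matrix(0, k, k, dimnames = list(top_set, top_set))
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      ci <- frame_coords(ensemble, top_set[i])
      for (j in (i + 1):k) {
        r <- superpose(frame_coords(ensemble, top_set[j]), ci, bb)$rmsd
        top_rmsd[i, j] <- top_rmsd[j, i] <- r
      }
    }
  }
  out <- list(frame_index = best, energy = energies[best],
              rmsd_to_min = rmsd_to_min, top_set = top_set,
              top_rmsd = top_rmsd)
  class(out) <- "representative_selection"
  out
}

#' @export
print.representative_selection <- function(x, ...) {
  cat(sprintf("representative frame %d (energy %.4g); top set of %d frames\n",
              x$frame_index, x$energy, length(x$top_set)))
  invisible(x)
}
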