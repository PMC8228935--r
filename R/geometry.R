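# Geometric kernels implemented from their definitions: Kabsch
# superposition, RMSD/RMSF, Shrake-Rupley solvent accessibility and
# geometric hydrogen-bond detection. All coordinates are in Angstrom;
# SASA is reported in nm^2.

as_coord_matrix <- function(x) {
  if (inherits(x, "structure3d")) return(coords(x))
  if (is.matrix(x) && ncol(x) == 3) return(x)
  stop("expected a structure3d or an N x 3 coordinate matrix")
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the rotation and translation minimising the RMSD between the
#' selected atoms of `mobile` and `reference`. The returned transform maps
#' mobile coordinates as `x %*% rotation + translation`; the rotation is a
#' proper rotation (det = +1).
#'
#' @param mobile,reference `structure3d` objects or N x 3 matrices with
#'   matching atom counts.
#' @param selection Integer atom indices used for the fit (default: all).
#' @return A `superposition`: list with `rotation` (3 x 3), `translation`
#'   (length 3) and `rmsd` (Angstrom, over the selection after fitting).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  M <- as_coord_matrix(mobile)
  R0 <- as_coord_matrix(reference)
  if (nrow(M) != nrow(R0)) stop("mobile and reference atom counts differ")
  if (is.null(selection)) selection <- seq_len(nrow(M))
  if (length(selection) < 3) stop("degenerate geometry: need >= 3 fit atoms")
  Pm <- M[selection, , drop = FALSE]
  Pr <- R0[selection, , drop = FALSE]
  cm <- colMeans(Pm); cr <- colMeans(Pr)
  Am <- sweep(Pm, 2, cm); Ar <- sweep(Pr, 2, cr)
  sv <- svd(Am)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate geometry: fit selection is collinear")
  C <- crossprod(Am, Ar)            # 3 x 3
  dec <- svd(C)
  d <- sign(det(dec$u %*% t(dec$v)))
  Rot <- dec$u %*% diag(c(1, 1, d)) %*% t(dec$v)
  fitted <- Am %*% Rot
  rmsd <- sqrt(mean(rowSums((fitted - Ar)^2)))
  out <- list(rotation = Rot, translation = cr - as.vector(cm %*% Rot),
              rmsd = rmsd)
  class(out) <- "superposition"
  out
}

#' Apply a superposition transform to coordinates
#' @param x `structure3d` or N x 3 matrix.
#' @param sp A `superposition` from [superpose()].
#' @return Transformed coordinates in the same form as the input matrix.
#' @export
apply_superposition <- function(x, sp) {
  stopifnot(inherits(sp, "superposition"))
  M <- as_coord_matrix(x)
  out <- sweep(M %*% sp$rotation, 2, sp$translation, "+")
  if (inherits(x, "structure3d")) {
    coords(x) <- out
    return(x)
  }
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

#' Frame-wise RMSD of an ensemble against a reference
#'
#' Each frame is rigid-body fitted to the reference on the selection
#' before the RMSD is evaluated over that same selection, mirroring the
#' usual trajectory-deviation measure against an equilibrated structure.
#'
#' @param ensemble An `ensemble`.
#' @param reference Reference coordinates (`structure3d` or matrix);
#'   default: the first frame.
#' @param selection Atom indices (default: backbone N, CA, C, O).
#' @return Numeric vector of per-frame RMSD values (Angstrom).
#' @export
rmsd_series <- function(ensemble, reference = NULL, selection = NULL) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (is.null(selection)) selection <- backbone_indices(ensemble$topology)
  if (!length(selection)) stop("empty atom selection")
  ref <- if (is.null(reference)) frame_coords(ensemble, 1)
         else as_coord_matrix(reference)
  vapply(seq_len(n_frames(ensemble)), function(f) {
    superpose(frame_coords(ensemble, f), ref, selection)$rmsd
  }, numeric(1))
}

# Fit every frame of an ensemble: first onto frame 1 over `selection`,
# then once more onto the resulting mean structure. Returns the list of
# fitted frame matrices and their mean.
fit_frames <- function(ensemble, selection) {
  nf <- n_frames(ensemble)
  frames <- lapply(seq_len(nf), function(f) frame_coords(ensemble, f))
  ref <- frames[[1]]
  pass <- function(frs, refc) lapply(frs, function(fr)
    apply_superposition(fr, superpose(fr, refc, selection)))
  fitted <- pass(frames, ref)
  mean1 <- Reduce(`+`, fitted) / nf
  fitted <- pass(fitted, mean1)
  list(frames = fitted, mean = Reduce(`+`, fitted) / nf)
}

#' Root mean square fluctuation per atom
#'
#' Frames are superposed onto the ensemble mean structure (one fit-to-mean
#' iteration after an initial fit to frame 1), then
#' `RMSF_i = sqrt(mean_t |r_i(t) - rbar_i|^2)` is evaluated for each
#' selected atom.
#'
#' @param ensemble An `ensemble` with at least 2 frames.
#' @param selection Atom indices (default: C-alpha atoms).
#' @return Numeric vector of per-atom RMSF values (Angstrom), one entry
#'   per selected atom in selection order.
#' @export
rmsf <- function(ensemble, selection = NULL) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (n_frames(ensemble) < 2) stop("RMSF needs at least 2 frames")
  if (is.null(selection)) selection <- ca_indices(ensemble$topology)
  if (!length(selection)) stop("empty atom selection")
  ft <- fit_frames(ensemble, selection)
  nf <- length(ft$frames)
  acc <- matrix(0, length(selection), 1)
  for (f in seq_len(nf)) {
    d <- ft$frames[[f]][selection, , drop = FALSE] -
      ft$mean[selection, , drop = FALSE]
    acc <- acc + rowSums(d^2)
  }
  sqrt(as.vector(acc) / nf)
}

# fixed van der Waals radii (Angstrom); unknown elements are hard errors
vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# deterministic quasi-uniform points on the unit sphere (Fibonacci spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Places `n_points` quasi-uniform test points on each atom's augmented
#' sphere (van der Waals radius + probe radius); a point is accessible if
#' it lies outside every other atom's augmented sphere. The accessible
#' fraction times the sphere area gives the per-atom SASA. Hydrogens are
#' excluded by default, matching common practice for heavy-atom SASA.
#'
#' @param structure A `structure3d`.
#' @param probe_radius Probe sphere radius in Angstrom (default 1.4, water).
#' @param n_points Test points per atom (default 960).
#' @param include_hydrogens If TRUE, hydrogens get a 1.20 Angstrom radius
#'   and participate.
#' @return List with `total` (nm^2), `per_residue` (named numeric, nm^2,
#'   protein residues in canonical order), `per_atom` (nm^2, one entry per
#'   included atom) and `atom_index` (their row indices).
#' @export
sasa <- function(structure, probe_radius = 1.4, n_points = 960,
                 include_hydrogens = FALSE) {
  stopifnot(inherits(structure, "structure3d"))
  a <- structure$atoms
  keep <- if (include_hydrogens) seq_len(nrow(a)) else which(a$element != "H")
  elems <- a$element[keep]
  unknown <- setdiff(unique(elems), names(vdw_radii))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  xyz <- coords(structure)[keep, , drop = FALSE]
  rad <- vdw_radii[elems] + probe_radius
  pts <- sphere_points(n_points)
  n <- length(keep)
  area <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    # neighbours whose augmented sphere can cover any of atom i's points
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad + rad[i])^2 & seq_len(n) != i)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dj2 >= rad[j]^2
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(free) / n_points
  }
  area_nm2 <- area / 100
  ri <- a$resindex[keep]
  per_res <- if (any(!is.na(ri))) {
    rt <- residue_table(structure)
    v <- vapply(rt$resindex, function(k) sum(area_nm2[!is.na(ri) & ri == k]),
                numeric(1))
    stats::setNames(v, rt$label)
  } else numeric(0)
  list(total = sum(area_nm2), per_residue = per_res,
       per_atom = area_nm2, atom_index = keep)
}

#' Detect hydrogen bonds by geometric criteria
#'
#' A donor-acceptor pair is reported when the donor-acceptor distance is
#' at most `d_max` and the deviation from linearity is at most
#' `angle_max`. The deviation is measured at the donor by default (the
#' hydrogen-donor-acceptor angle, `angle_def = "HDA"`); with
#' `angle_def = "DHA"` it is measured at the hydrogen as 180 degrees minus
#' the donor-hydrogen-acceptor angle. Pairs within one residue are
#' excluded by default.
#'
#' @param structure A `structure3d` carrying the frame coordinates.
#' @param table A `da_table` from [donor_acceptor_table()]; computed from
#'   `structure` when omitted.
#' @param d_max Donor-acceptor distance cutoff in Angstrom (default 3.5).
#' @param angle_max Deviation-angle cutoff in degrees (default 30).
#' @param angle_def Where the deviation is measured: `"HDA"` or `"DHA"`.
#' @param exclude_same_residue Drop intra-residue pairs (default TRUE).
#' @return data.frame with one row per bond: atom row indices `donor`,
#'   `hydrogen`, `acceptor`; `donor_res`/`acceptor_res` (canonical residue
#'   index, NA for ligand atoms); `donor_het`/`acceptor_het`; `distance`
#'   (Angstrom) and `angle` (deviation, degrees).
#' @export
find_hbonds <- function(structure, table = NULL, d_max = 3.5, angle_max = 30,
                        angle_def = c("HDA", "DHA"),
                        exclude_same_residue = TRUE) {
  stopifnot(inherits(structure, "structure3d"))
  angle_def <- match.arg(angle_def)
  if (is.null(table)) table <- donor_acceptor_table(structure)
  empty <- data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), donor_res = integer(),
                      acceptor_res = integer(), donor_het = logical(),
                      acceptor_het = logical(), distance = numeric(),
                      angle = numeric())
  if (!nrow(table$donors) || !length(table$acceptors)) return(empty)
  a <- structure$atoms
  xyz <- coords(structure)
  grp <- paste(a$chain, a$resno, a$insert, a$resname, a$het)
  out <- vector("list", nrow(table$donors))
  for (k in seq_len(nrow(table$donors))) {
    D <- table$donors$heavy[k]; H <- table$donors$hydrogen[k]
    acc <- setdiff(table$acceptors, D)
    if (exclude_same_residue) acc <- acc[grp[acc] != grp[D]]
    if (!length(acc)) next
    dv <- sweep(xyz[acc, , drop = FALSE], 2, xyz[D, ])
    dist <- sqrt(rowSums(dv^2))
    # cutoffs are inclusive; the epsilon guards exact-boundary geometries
    # against floating-point round-off
    sel <- which(dist <= d_max + 1e-9 & dist > 1e-6)
    if (!length(sel)) next
    hv <- xyz[H, ] - xyz[D, ]
    hn <- sqrt(sum(hv^2))
    if (angle_def == "HDA") {
      cosang <- (dv[sel, , drop = FALSE] %*% hv) / (dist[sel] * hn)
      dev <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    } else {
      ha <- sweep(xyz[acc[sel], , drop = FALSE], 2, xyz[H, ])
      hd <- xyz[D, ] - xyz[H, ]
      cosang <- (ha %*% hd) / (sqrt(rowSums(ha^2)) * sqrt(sum(hd^2)))
      dev <- 180 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    }
    ok <- which(dev <= angle_max + 1e-9)
    if (!length(ok)) next
    acc_ok <- acc[sel][ok]
    out[[k]] <- data.frame(donor = D, hydrogen = H, acceptor = acc_ok,
                           donor_res = a$resindex[D],
                           acceptor_res = a$resindex[acc_ok],
                           donor_het = a$het[D], acceptor_het = a$het[acc_ok],
                           distance = dist[sel][ok], angle = as.vector(dev)[ok])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  # canonical row order, independent of input atom ordering
  res <- res[order(res$donor_res, res$acceptor_res, res$distance), ]
  rownames(res) <- NULL
  res
}
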