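#' @keywords internal
"_PACKAGE"

# Atom table columns used throughout the package:
#   eleno   atom serial
#   name    PDB atom name (e.g. "CA", "OD1")
#   resname three-letter residue name
#   chain   chain identifier
#   resno   author residue number
#   insert  insertion code ("" if none); sorts after the base number
#   element element symbol, never empty
#   x, y, z coordinates in Angstrom
#   occ     occupancy
#   het     TRUE for HETATM records (ligands)
#   resindex 1-based index into the canonical protein residue order
#            (NA for HETATM atoms); all per-residue vectors use this order

#' Construct a structure object from an atom table
#'
#' Low-level constructor shared by the PDB reader and the synthetic
#' generator. Protein residues are ordered by (chain, author number,
#' insertion code) and indexed 1..K; HETATM groups are kept separately
#' as ligands and never enter the residue indexing.
#'
#' @param atoms data.frame with columns `eleno`, `name`, `resname`, `chain`,
#'   `resno`, `insert`, `element`, `x`, `y`, `z`, `occ`, `het`.
#' @return An object of class `structure3d`.
#' @keywords internal
new_structure3d <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("eleno", "name", "resname", "chain", "resno", "insert",
            "element", "x", "y", "z", "occ", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$element))) stop("empty element symbols in atom table")

  prot <- !atoms$het
  # canonical residue order: chain, author number, insertion code
  key <- paste(atoms$chain, formatC(atoms$resno, width = 8, flag = "0"),
               atoms$insert, sep = "|")
  atoms$resindex <- NA_integer_
  if (any(prot)) {
    ukey <- sort(unique(key[prot]))
    atoms$resindex[prot] <- match(key[prot], ukey)
    ord <- order(atoms$resindex, seq_len(nrow(atoms)), na.last = TRUE)
    atoms <- atoms[ord, , drop = FALSE]
  }
  rownames(atoms) <- NULL
  x <- list(atoms = atoms)
  class(x) <- "structure3d"
  x
}

#' Number of protein residues in a structure
#' @param x A `structure3d` object.
#' @return Integer count of protein residues.
#' @export
n_residues <- function(x) {
  stopifnot(inherits(x, "structure3d"))
  idx <- x$atoms$resindex
  if (all(is.na(idx))) 0L else max(idx, na.rm = TRUE)
}

#' Atom coordinates as an N x 3 matrix
#' @param x A `structure3d` object.
#' @return Numeric matrix with one row per atom, columns x/y/z (Angstrom).
#' @export
coords <- function(x) {
  stopifnot(inherits(x, "structure3d"))
  as.matrix(x$atoms[, c("x", "y", "z")])
}

`coords<-` <- function(x, value) {
  stopifnot(inherits(x, "structure3d"), nrow(value) == nrow(x$atoms))
  x$atoms$x <- value[, 1]; x$atoms$y <- value[, 2]; x$atoms$z <- value[, 3]
  x
}

#' Per-residue summary table of a structure
#'
#' One row per protein residue in canonical order, with the residue label
#' used in reports ("A12"-style one-letter code plus author number).
#'
#' @param x A `structure3d` object.
#' @return data.frame with columns `resindex`, `resname`, `chain`, `resno`,
#'   `insert`, `label`, `has_ca`.
#' @export
residue_table <- function(x) {
  stopifnot(inherits(x, "structure3d"))
  a <- x$atoms[!x$atoms$het & !is.na(x$atoms$resindex), , drop = FALSE]
  if (!nrow(a)) {
    return(data.frame(resindex = integer(), resname = character(),
                      chain = character(), resno = integer(),
                      insert = character(), label = character(),
                      has_ca = logical(), stringsAsFactors = FALSE))
  }
  first <- !duplicated(a$resindex)
  r <- a[first, c("resindex", "resname", "chain", "resno", "insert")]
  has_ca <- vapply(r$resindex, function(i)
    any(a$resindex == i & a$name == "CA" & a$element != "H"), logical(1))
  r$label <- paste0(aa321(r$resname), r$resno, ifelse(nzchar(r$insert), r$insert, ""))
  r$has_ca <- has_ca
  rownames(r) <- NULL
  r
}

#' Ligand (HETATM) groups of a structure
#' @param x A `structure3d` object.
#' @return Named list of atom tables, one per (resname, chain, resno) group.
#' @export
ligand_groups <- function(x) {
  stopifnot(inherits(x, "structure3d"))
  h <- x$atoms[x$atoms$het, , drop = FALSE]
  if (!nrow(h)) return(list())
  key <- paste(h$resname, h$chain, h$resno, sep = "_")
  split(h, factor(key, levels = unique(key)))
}

# three-letter to one-letter amino-acid codes; unknown names map to "X"
aa321 <- function(resname) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  out <- tab[toupper(resname)]
  out[is.na(out)] <- "X"
  unname(out)
}

# row indices of atoms matching a name within protein residues
atom_select <- function(x, names = NULL, heavy_only = FALSE, protein_only = TRUE) {
  a <- x$atoms
  sel <- rep(TRUE, nrow(a))
  if (protein_only) sel <- sel & !a$het
  if (!is.null(names)) sel <- sel & a$name %in% names
  if (heavy_only) sel <- sel & a$element != "H"
  which(sel)
}

#' Indices of backbone atoms (N, CA, C, O)
#' @param x A `structure3d` object.
#' @return Integer atom row indices.
#' @export
backbone_indices <- function(x) atom_select(x, c("N", "CA", "C", "O"), heavy_only = TRUE)

#' Indices of C-alpha atoms in canonical residue order
#' @param x A `structure3d` object.
#' @return Integer atom row indices, one per residue that has a C-alpha.
#' @export
ca_indices <- function(x) {
  i <- atom_select(x, "CA", heavy_only = TRUE)
  i[order(x$atoms$resindex[i])]
}

#' @export
print.structure3d <- function(x, ...) {
  nlig <- length(ligand_groups(x))
  cat("structure3d: ", n_residues(x), " residues, ",
      sum(!x$atoms$het), " protein atoms",
      if (nlig) paste0(", ", nlig, " ligand group(s)") else "", "\n", sep = "")
  invisible(x)
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble: ", nrow(x$xyz), " frames x ", ncol(x$xyz) / 3, " atoms (",
      n_residues(x$topology), " residues)\n", sep = "")
  invisible(x)
}

# Ensemble container: topology (structure3d), xyz (n_frames x 3*n_atoms,
# bio3d layout x1 y1 z1 x2 ...), times in ps (strictly increasing)
new_ensemble <- function(topology, xyz, times = NULL) {
  stopifnot(inherits(topology, "structure3d"), is.matrix(xyz))
  if (ncol(xyz) != 3L * nrow(topology$atoms))
    stop("frame width does not match topology atom count")
  if (is.null(times)) times <- (seq_len(nrow(xyz)) - 1) * 100
  if (length(times) != nrow(xyz)) stop("times length must equal frame count")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  x <- list(topology = topology, xyz = xyz, times = as.numeric(times))
  class(x) <- "ensemble"
  x
}

#' Number of frames in an ensemble
#' @param x An `ensemble` object.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "ensemble"))
  nrow(x$xyz)
}

# frame f as an N x 3 coordinate matrix
frame_coords <- function(ens, f) {
  matrix(ens$xyz[f, ], ncol = 3, byrow = TRUE)
}

# structure3d with coordinates replaced by frame f
frame_structure <- function(ens, f) {
  s <- ens$topology
  coords(s) <- frame_coords(ens, f)
  s
}
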