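# PDB reading is delegated to bio3d; this module normalises its output to
# the package's canonical atom table (altloc resolution, residue ordering,
# element fallback) and provides plain-text writers for structures,
# multi-model ensembles and xvg-style energy tables.

bio3d_to_atoms <- function(atom_df) {
  alt <- atom_df$alt
  alt[is.na(alt)] <- ""
  ins <- atom_df$insert
  ins[is.na(ins)] <- ""
  occ <- atom_df$o
  occ[is.na(occ)] <- 1
  elem <- atom_df$elesy
  elem[is.na(elem) | !nzchar(elem)] <- NA
  # fall back to the first letter of the atom name when the element column
  # is absent (legacy PDB files)
  fb <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", atom_df$elety))
  fb <- toupper(substr(fb, 1, 1))
  elem <- ifelse(is.na(elem), fb, toupper(elem))

  atoms <- data.frame(eleno = atom_df$eleno, name = atom_df$elety,
                      resname = atom_df$resid, chain = atom_df$chain,
                      resno = atom_df$resno, insert = ins, element = elem,
                      x = atom_df$x, y = atom_df$y, z = atom_df$z,
                      occ = occ, het = atom_df$type == "HETATM",
                      alt = alt, stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "

  # altloc: keep the highest-occupancy variant of each alternate atom;
  # ties prefer altloc "A", then alphabetical
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, atoms$het)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
    if (length(i) == 1) return(i)
    o <- atoms$occ[i]
    best <- i[o == max(o)]
    if (length(best) > 1) {
      pa <- best[atoms$alt[best] == "A"]
      best <- if (length(pa)) pa[1] else best[order(atoms$alt[best])][1]
    }
    best
  }), use.names = FALSE)
  atoms <- atoms[sort(keep), setdiff(names(atoms), "alt"), drop = FALSE]
  atoms
}

#' Read a protein structure from a PDB file
#'
#' Residues are ordered by (chain, author number, insertion code) and
#' indexed 1..K; this canonical order is used by every per-residue vector
#' downstream. Alternate locations keep the highest-occupancy copy (ties
#' prefer altloc "A"); hydrogens are retained when present; HETATM records
#' become ligand groups. Waters and ions are excluded.
#'
#' @param path Path to a PDB file.
#' @param keep_solvent If TRUE, water/ion HETATM groups are retained.
#' @return A `structure3d`.
#' @export
read_structure <- function(path, keep_solvent = FALSE) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  atoms <- bio3d_to_atoms(pdb$atom)
  if (!keep_solvent)
    atoms <- atoms[!(atoms$het & atoms$resname %in%
                       c("HOH", "WAT", "SOL", "NA", "CL", "K", "MG", "ZN", "CA")), ,
                   drop = FALSE]
  if (!nrow(atoms)) stop("empty structure: no atom records in '", path, "'")
  new_structure3d(atoms)
}

#' Read a conformational ensemble from a multi-model PDB file
#'
#' The topology is taken from the first MODEL; frames follow MODEL order.
#' All models must have the same atom count. Frame times default to a
#' 100 ps stride starting at 0, matching a typical trajectory sampling
#' interval; pass `dt` to change the stride.
#'
#' @param path Path to a PDB file with one or more MODEL blocks.
#' @param dt Time between frames in ps (default 100).
#' @return An `ensemble`.
#' @export
read_ensemble <- function(path, dt = 100) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  # verify per-model atom counts before handing to the parser
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_id <- cumsum(rec == "MODEL ")
  if (max(model_id) > 1) {
    counts <- table(model_id[is_atom & model_id > 0])
    if (length(unique(as.integer(counts))) > 1)
      stop("format error: models differ in atom count")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  atoms <- bio3d_to_atoms(pdb$atom)
  topo <- new_structure3d(atoms)
  # reorder frame columns to match the canonical atom order of the topology
  perm <- match(topo$atoms$eleno, atoms$eleno)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  col_perm <- as.vector(rbind(3 * perm - 2, 3 * perm - 1, 3 * perm))
  xyz <- xyz[, col_perm, drop = FALSE]
  new_ensemble(topo, xyz, times = (seq_len(nrow(xyz)) - 1) * dt)
}

pdb_atom_line <- function(rec, eleno, name, resname, chain, resno, insert,
                          xyz, occ, element) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, eleno %% 100000L, nm, "", resname, chain, resno %% 10000L,
          ifelse(nzchar(insert), insert, " "),
          xyz[1], xyz[2], xyz[3], occ, 0, element)
}

structure_lines <- function(x, xyz = NULL) {
  a <- x$atoms
  if (is.null(xyz)) xyz <- coords(x)
  out <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    out[i] <- pdb_atom_line(if (a$het[i]) "HETATM" else "ATOM",
                            i, a$name[i], a$resname[i], a$chain[i],
                            a$resno[i], a$insert[i], xyz[i, ], a$occ[i],
                            a$element[i])
  }
  out
}

#' Write a structure or ensemble to a PDB file
#'
#' Structures produce a single-model file; ensembles produce a multi-model
#' file (MODEL/ENDMDL). Output is deterministic: identical objects give
#' byte-identical files.
#'
#' @param x A `structure3d` or `ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) UseMethod("write_pdb")

#' @export
write_pdb.structure3d <- function(x, path) {
  writeLines(c(structure_lines(x), "TER", "END"), path)
  invisible(path)
}

#' @export
write_pdb.ensemble <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(x))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(structure_lines(x$topology, frame_coords(x, f)), con)
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a two-column per-frame energy table
#'
#' Whitespace-separated text with time (ps) in the first column and an
#' energy scalar in the second; lines starting with `#` or `@` (xvg-style
#' headers) are ignored. Energies are treated as opaque input scalars.
#'
#' @param path Path to the table.
#' @return data.frame with columns `time` and `energy`.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty energy table '", path, "'")
  vals <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  m <- do.call(rbind, vals)
  if (ncol(m) < 2) stop("energy table needs two columns")
  data.frame(time = m[, 1], energy = m[, 2])
}

#' Write a two-column energy table
#' @param time Numeric vector of frame times (ps).
#' @param energy Numeric vector of per-frame energies.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(time, energy, path) {
  stopifnot(length(time) == length(energy))
  writeLines(c("# frame_time_ps  energy",
               sprintf("%.4f %.6f", time, energy)), path)
  invisible(path)
}

#' Assign hydrogen-bond donors and acceptors
#'
#' Donors are N/O heavy atoms with at least one hydrogen within 1.25
#' Angstrom (covalent attachment inferred by distance; no CONECT records
#' needed), one (heavy, hydrogen) pair per attached hydrogen. Acceptors
#' are all N and O heavy atoms. Structures without hydrogens yield an
#' empty donor list with a warning.
#'
#' @param structure A `structure3d`.
#' @param include_ligand If TRUE (default) HETATM atoms participate.
#' @return A `da_table`: list with `donors` (data.frame of atom row indices
#'   `heavy`, `hydrogen`) and `acceptors` (integer atom row indices).
#' @export
donor_acceptor_table <- function(structure, include_ligand = TRUE) {
  stopifnot(inherits(structure, "structure3d"))
  a <- structure$atoms
  pool <- if (include_ligand) rep(TRUE, nrow(a)) else !a$het
  xyz <- coords(structure)
  hy <- which(pool & a$element == "H")
  no <- which(pool & a$element %in% c("N", "O"))
  donors <- data.frame(heavy = integer(), hydrogen = integer())
  if (!length(hy)) {
    warning("structure has no hydrogens: donor list is empty")
  } else if (length(no)) {
    for (h in hy) {
      d2 <- (xyz[no, 1] - xyz[h, 1])^2 + (xyz[no, 2] - xyz[h, 2])^2 +
        (xyz[no, 3] - xyz[h, 3])^2
      j <- which(d2 <= 1.25^2)
      if (length(j)) {
        j <- j[which.min(d2[j])]
        donors <- rbind(donors, data.frame(heavy = no[j], hydrogen = h))
      }
    }
  }
  out <- list(donors = donors, acceptors = no)
  class(out) <- "da_table"
  out
}
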