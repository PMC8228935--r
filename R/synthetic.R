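# Synthetic structures and ensembles with planted, analytically known
# properties. Ensembles use correlated Gaussian residue displacements, for
# which RMSF, covariance PCA and cross-correlation all have closed-form
# expectations, so every downstream stage can be tested without real
# trajectories.

#' Specification for a synthetic structure/ensemble
#'
#' Collects and validates all knobs of the synthetic generator. The same
#' spec (including `seed`) always reproduces bit-identical output.
#'
#' @param n_residues Number of protein residues (>= 1).
#' @param geometry One of `"ideal_helix"`, `"extended_chain"`, `"two_domain"`.
#'   The two-domain form is two helical halves separated by 40 Angstrom.
#' @param ca_spacing Consecutive C-alpha spacing in Angstrom for extended
#'   chains (default 3.8, the trans peptide value).
#' @param seed Integer random seed; all randomness in [make_ensemble()] is
#'   drawn from an isolated RNG stream seeded with this value.
#' @param n_frames Number of ensemble frames.
#' @param blocks Partition of residue indices `1..n_residues` into blocks
#'   (list of integer vectors, disjoint and covering). Default: one block.
#' @param rho_within Displacement correlation between residues in the same
#'   block, in \[-1, 1\].
#' @param rho_between Displacement correlation across blocks, in \[-1, 1\].
#' @param sigma Per-coordinate fluctuation scale in Angstrom (> 0 unless the
#'   ensemble is meant to be static, where 0 is allowed).
#' @param terminal_gly If TRUE the last residue is glycine (no C-beta).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues,
                           geometry = c("ideal_helix", "extended_chain", "two_domain"),
                           ca_spacing = 3.8,
                           seed = 1L,
                           n_frames = 100L,
                           blocks = NULL,
                           rho_within = 0,
                           rho_between = 0,
                           sigma = 0.5,
                           terminal_gly = FALSE) {
  geometry <- match.arg(geometry)
  if (!is.numeric(n_residues) || length(n_residues) != 1 || n_residues < 1 ||
      n_residues != round(n_residues))
    stop("invalid spec: n_residues must be a positive integer")
  n_residues <- as.integer(n_residues)
  if (ca_spacing <= 0) stop("invalid spec: ca_spacing must be positive")
  if (abs(rho_within) > 1 || abs(rho_between) > 1)
    stop("invalid spec: correlations must lie in [-1, 1]")
  if (sigma < 0) stop("invalid spec: sigma must be non-negative")
  if (n_frames < 1) stop("invalid spec: n_frames must be >= 1")
  if (is.null(blocks)) blocks <- list(seq_len(n_residues))
  all_idx <- sort(unlist(blocks))
  if (!identical(as.integer(all_idx), seq_len(n_residues)))
    stop("invalid spec: blocks must partition 1..n_residues disjointly")
  out <- list(n_residues = n_residues, geometry = geometry,
              ca_spacing = ca_spacing, seed = as.integer(seed),
              n_frames = as.integer(n_frames), blocks = lapply(blocks, as.integer),
              rho_within = rho_within, rho_between = rho_between,
              sigma = sigma, terminal_gly = isTRUE(terminal_gly))
  class(out) <- "synthetic_spec"
  out
}

# C-alpha trace for each geometry kind. Helix parameters: radius 2.3 A,
# rise 1.5 A and 100 degrees per residue (canonical alpha helix), which
# puts CA(i)-CA(i+3) near 5 A, inside the 7 A contact cutoff.
ca_trace <- function(spec) {
  n <- spec$n_residues
  helix <- function(idx, origin = c(0, 0, 0)) {
    th <- (idx - 1) * 100 * pi / 180
    cbind(2.3 * cos(th) + origin[1], 2.3 * sin(th) + origin[2],
          (idx - 1) * 1.5 + origin[3])
  }
  switch(spec$geometry,
    extended_chain = {
      # zigzag of a beta-strand-like extended chain; the y alternation
      # keeps the trace non-collinear while consecutive C-alpha spacing
      # stays exactly ca_spacing
      amp <- 0.25
      dx <- sqrt(spec$ca_spacing^2 - (2 * amp)^2)
      cbind((seq_len(n) - 1) * dx, amp * (-1)^(seq_len(n)), 0)
    },
    ideal_helix = helix(seq_len(n)),
    two_domain = {
      n1 <- ceiling(n / 2)
      rbind(helix(seq_len(n1)),
            if (n > n1) helix(seq_len(n - n1), origin = c(40, 0, 0)))
    })
}

#' Generate a synthetic poly-alanine structure
#'
#' Builds a backbone (N, CA, C, O plus amide hydrogen) with C-beta
#' side-chain atoms on a chosen C-alpha trace. Atoms are placed in a local
#' frame derived from the chain tangent at each residue, at bond lengths
#' close to ideal values; the construction is deterministic.
#'
#' @param spec A [synthetic_spec()].
#' @return A `structure3d`, chain "A", residues numbered from 1.
#' @export
#' @examples
#' s <- make_structure(synthetic_spec(5, "extended_chain"))
#' n_residues(s)
make_structure <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ca <- ca_trace(spec)
  n <- spec$n_residues
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    # local frame: tangent along the chain, two orthogonal normals
    tvec <- if (n == 1) c(1, 0, 0)
            else if (i == 1) ca[2, ] - ca[1, ]
            else if (i == n) ca[n, ] - ca[n - 1, ]
            else ca[i + 1, ] - ca[i - 1, ]
    tvec <- tvec / sqrt(sum(tvec^2))
    up <- if (abs(tvec[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- c(tvec[2] * up[3] - tvec[3] * up[2],
           tvec[3] * up[1] - tvec[1] * up[3],
           tvec[1] * up[2] - tvec[2] * up[1])
    u <- u / sqrt(sum(u^2))
    v <- c(tvec[2] * u[3] - tvec[3] * u[2],
           tvec[3] * u[1] - tvec[1] * u[3],
           tvec[1] * u[2] - tvec[2] * u[1])
    p <- ca[i, ]
    gly <- spec$terminal_gly && i == n
    resname <- if (gly) "GLY" else "ALA"
    atom <- function(name, element, xyz)
      data.frame(eleno = 0L, name = name, resname = resname, chain = "A",
                 resno = i, insert = "", element = element,
                 x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, het = FALSE,
                 stringsAsFactors = FALSE)
    Npos <- p - 0.75 * tvec + 1.25 * u
    res <- list(atom("N", "N", Npos),
                atom("H", "H", Npos + 1.0 * u),
                atom("CA", "C", p),
                atom("C", "C", p + 0.75 * tvec + 1.25 * v),
                atom("O", "O", p + 0.75 * tvec + 2.48 * v))
    if (!gly) res <- c(res, list(atom("CB", "C", p - 1.0 * u - 1.15 * v)))
    rows[[i]] <- do.call(rbind, res)
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  new_structure3d(atoms)
}

#' Generate a synthetic ensemble with planted displacement correlations
#'
#' Frames are the reference coordinates plus zero-mean Gaussian
#' displacements with per-coordinate standard deviation `sigma`. One
#' displacement vector is drawn per residue and applied rigidly to all of
#' its atoms, so the residue-level correlation structure is exact by
#' construction: `rho_within` inside each block of `spec$blocks`,
#' `rho_between` across blocks, independently on x, y and z. Frame 1 is
#' the unperturbed reference. Ligand (HETATM) atoms are carried along
#' unperturbed.
#'
#' @param spec A [synthetic_spec()]; its residue count must match `reference`.
#' @param reference A `structure3d`, typically from [make_structure()].
#' @return An `ensemble` with `spec$n_frames` frames sampled every 100 ps.
#' @export
make_ensemble <- function(spec, reference) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(reference, "structure3d"))
  n <- spec$n_residues
  if (n_residues(reference) != n)
    stop("reference residue count does not match spec")

  # residue-residue correlation matrix and its factor
  block_id <- integer(n)
  for (b in seq_along(spec$blocks)) block_id[spec$blocks[[b]]] <- b
  R <- matrix(spec$rho_between, n, n)
  same <- outer(block_id, block_id, "==")
  R[same] <- spec$rho_within
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("invalid spec: requested correlations give a non positive ",
         "semi-definite matrix")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n)

  xyz0 <- as.vector(t(coords(reference)))
  nf <- spec$n_frames
  xyz <- matrix(xyz0, nrow = nf, ncol = length(xyz0), byrow = TRUE)
  ridx <- reference$atoms$resindex

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  if (nf > 1 && spec$sigma > 0) {
    for (f in 2:nf) {
      disp <- spec$sigma * (L %*% matrix(stats::rnorm(3 * n), n, 3))  # n x 3
      for (k in 1:3) {
        dk <- ifelse(is.na(ridx), 0, disp[ifelse(is.na(ridx), 1L, ridx), k])
        xyz[f, seq(k, by = 3, length.out = length(ridx))] <-
          xyz[f, seq(k, by = 3, length.out = length(ridx))] + dk
      }
    }
  }
  new_ensemble(reference, xyz, times = (seq_len(nf) - 1) * 100)
}

#' Plant an exact hydrogen-bond geometry between two residues
#'
#' Inserts a donor oxygen (named OD1, with hydrogen HD1) on the donor
#' residue and an acceptor oxygen (OE1) on the acceptor residue such that
#' the donor-acceptor distance equals `distance` and the deviation angle
#' at the donor (hydrogen-donor-acceptor) equals `angle` exactly, up to
#' coordinate round-off. The donor sits 3 Angstrom from the donor C-alpha
#' along the direction towards the acceptor residue.
#'
#' @param structure A `structure3d`.
#' @param donor_res,acceptor_res Residue indices (canonical order).
#' @param distance Donor-acceptor distance in Angstrom (> 0).
#' @param angle Deviation angle in degrees, in \[0, 180).
#' @return The structure with three atoms appended.
#' @export
plant_hbond <- function(structure, donor_res, acceptor_res, distance, angle) {
  stopifnot(inherits(structure, "structure3d"))
  if (distance <= 0) stop("invalid spec: distance must be positive")
  if (angle < 0 || angle >= 180)
    stop("invalid spec: angle must lie in [0, 180) degrees")
  rt <- residue_table(structure)
  if (!all(c(donor_res, acceptor_res) %in% rt$resindex))
    stop("donor or acceptor residue not present")
  a <- structure$atoms
  ca_of <- function(ri) {
    j <- which(a$resindex == ri & a$name == "CA")[1]
    c(a$x[j], a$y[j], a$z[j])
  }
  ca_d <- ca_of(donor_res); ca_a <- ca_of(acceptor_res)
  u <- ca_a - ca_d
  nu <- sqrt(sum(u^2))
  u <- if (nu < 1e-9) c(1, 0, 0) else u / nu
  # perpendicular to u, used to open the deviation angle
  w <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  perp <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
  perp <- perp / sqrt(sum(perp^2))
  D <- ca_d + 3.0 * u
  A <- D + distance * u
  th <- angle * pi / 180
  H <- D + 1.0 * (cos(th) * u + sin(th) * perp)

  res_row <- function(ri, name, element, xyz) {
    j <- which(a$resindex == ri)[1]
    data.frame(eleno = 0L, name = name, resname = a$resname[j],
               chain = a$chain[j], resno = a$resno[j], insert = a$insert[j],
               element = element, x = xyz[1], y = xyz[2], z = xyz[3],
               occ = 1, het = FALSE, stringsAsFactors = FALSE)
  }
  add <- rbind(res_row(donor_res, "OD1", "O", D),
               res_row(donor_res, "HD1", "H", H),
               res_row(acceptor_res, "OE1", "O", A))
  atoms <- rbind(a[, setdiff(names(a), "resindex")],
                 add)
  atoms$eleno <- seq_len(nrow(atoms))
  new_structure3d(atoms)
}

#' Add a small ligand forming an exact hydrogen bond to one residue
#'
#' Appends a two-atom HETATM group (a carbon and an acceptor oxygen) placed
#' so that the oxygen accepts a hydrogen bond from the backbone amide donor
#' of `residue`: the N-O distance equals `distance` and the H-N-O deviation
#' angle equals `angle`.
#'
#' @param structure A `structure3d` whose residue has backbone N and H atoms.
#' @param residue Residue index donating the hydrogen bond.
#' @param distance Donor-acceptor (N-O) distance in Angstrom.
#' @param angle Deviation angle at the donor in degrees.
#' @param resname Ligand residue name (default "LIG").
#' @return The structure with the ligand group appended.
#' @export
add_ligand <- function(structure, residue, distance = 2.9, angle = 10,
                       resname = "LIG") {
  stopifnot(inherits(structure, "structure3d"))
  if (angle < 0 || angle >= 180) stop("invalid spec: angle out of range")
  a <- structure$atoms
  jn <- which(a$resindex == residue & a$name == "N")[1]
  jh <- which(a$resindex == residue & a$name == "H")[1]
  if (is.na(jn) || is.na(jh)) stop("residue lacks backbone N-H donor")
  N <- c(a$x[jn], a$y[jn], a$z[jn])
  H <- c(a$x[jh], a$y[jh], a$z[jh])
  u <- (H - N) / sqrt(sum((H - N)^2))   # donor->hydrogen direction
  w <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  perp <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
  perp <- perp / sqrt(sum(perp^2))
  th <- angle * pi / 180
  O <- N + distance * (cos(th) * u + sin(th) * perp)
  C <- O + 1.4 * perp
  lig <- data.frame(eleno = 0L, name = c("C1", "O1"), resname = resname,
                    chain = "A", resno = 901L, insert = "",
                    element = c("C", "O"),
                    x = c(C[1], O[1]), y = c(C[2], O[2]), z = c(C[3], O[3]),
                    occ = 1, het = TRUE, stringsAsFactors = FALSE)
  atoms <- rbind(a[, setdiff(names(a), "resindex")], lig)
  atoms$eleno <- seq_len(nrow(atoms))
  new_structure3d(atoms)
}

#' Make a planted ligand hydrogen bond intermittent across frames
#'
#' Displaces all HETATM atoms by `shift` in every frame not listed in
#' `frames_on`, so a planted protein-ligand hydrogen bond is present in
#' exactly the requested fraction of frames.
#'
#' @param ensemble An `ensemble` whose topology contains a ligand.
#' @param frames_on Integer frame indices (1-based) where the bond persists.
#' @param shift Displacement vector in Angstrom (default 20 along x, far
#'   outside any hydrogen-bond cutoff).
#' @return The modified ensemble.
#' @export
set_ligand_frames <- function(ensemble, frames_on, shift = c(20, 0, 0)) {
  stopifnot(inherits(ensemble, "ensemble"))
  het <- which(ensemble$topology$atoms$het)
  if (!length(het)) stop("ensemble topology has no ligand")
  off <- setdiff(seq_len(n_frames(ensemble)), frames_on)
  for (f in off) {
    for (k in 1:3)
      ensemble$xyz[f, 3 * (het - 1) + k] <- ensemble$xyz[f, 3 * (het - 1) + k] + shift[k]
  }
  ensemble
}
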