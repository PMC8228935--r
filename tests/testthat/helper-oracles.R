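# Independent oracles used to validate the package implementations.
# These deliberately use different algorithms from the package code:
# Floyd-Warshall for distances, explicit bounded DFS enumeration of all
# shortest paths for betweenness, and direct grid/simplex minimisation
# over rotations for superposition.

random_graph <- function(K, p, seed) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(i = pairs[keep, 1], j = pairs[keep, 2])
}

graph_obj <- function(K, edges) list(K = K, edges = edges)

# all-pairs hop distances by Floyd-Warshall
oracle_distances <- function(K, edges) {
  D <- matrix(Inf, K, K)
  diag(D) <- 0
  for (k in seq_len(nrow(edges))) {
    D[edges$i[k], edges$j[k]] <- 1
    D[edges$j[k], edges$i[k]] <- 1
  }
  for (m in seq_len(K)) for (a in seq_len(K)) for (b in seq_len(K))
    if (D[a, m] + D[m, b] < D[a, b]) D[a, b] <- D[a, m] + D[m, b]
  D
}

# exhaustive enumeration of every shortest path between every pair,
# counting paths and interior-node occurrences
oracle_centralities <- function(K, edges) {
  D <- oracle_distances(K, edges)
  adj <- lapply(seq_len(K), function(v)
    c(edges$j[edges$i == v], edges$i[edges$j == v]))
  through <- numeric(K)   # sum over pairs of sigma_ab(r)/sigma_ab
  pair_through <- function(a, b) {
    target <- D[a, b]
    n_paths <- 0
    interior <- numeric(K)
    walk <- function(v, len, visited) {
      if (v == b) {
        n_paths <<- n_paths + 1
        mid <- setdiff(visited, c(a, b))
        if (length(mid)) interior[mid] <<- interior[mid] + 1
        return(invisible())
      }
      for (w in adj[[v]])
        if (!(w %in% visited) && len + 1 + D[w, b] == target)
          walk(w, len + 1, c(visited, w))
    }
    walk(a, 0, a)
    list(n = n_paths, interior = interior)
  }
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    if (!is.finite(D[a, b])) next
    pt <- pair_through(a, b)
    through <- through + pt$interior / pt$n
  }
  cb <- 2 / ((K - 1) * (K - 2)) * through
  cc <- vapply(seq_len(K), function(r) {
    d <- D[r, -r]
    reach <- d[is.finite(d)]
    if (!length(reach)) return(0)
    (length(reach) / (K - 1)) * length(reach) / sum(reach)
  }, numeric(1))
  list(C_B = cb, C_C = cc, D = D)
}

# direct minimisation of RMSD over rotations: coarse Euler-angle grid
# followed by Nelder-Mead refinement; translations handled by centring
oracle_min_rmsd <- function(mobile, reference) {
  Am <- sweep(mobile, 2, colMeans(mobile))
  Ar <- sweep(reference, 2, colMeans(reference))
  rot <- function(a) {
    ca <- cos(a); sa <- sin(a)
    Rz <- matrix(c(ca[1], sa[1], 0, -sa[1], ca[1], 0, 0, 0, 1), 3)
    Ry <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3)
    Rx <- matrix(c(1, 0, 0, 0, ca[3], sa[3], 0, -sa[3], ca[3]), 3)
    Rz %*% Ry %*% Rx
  }
  f <- function(a) sqrt(mean(rowSums((Am %*% rot(a) - Ar)^2)))
  grid <- as.matrix(expand.grid(a1 = seq(0, 2 * pi, by = pi / 12),
                                a2 = seq(0, pi, by = pi / 12),
                                a3 = seq(0, 2 * pi, by = pi / 12)))
  vals <- apply(grid, 1, f)
  best <- grid[which.min(vals), ]
  stats::optim(best, f, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}

# brute-force residue interaction network: recompute the two centres per
# residue directly from the atom table and scan all residue pairs
oracle_rin_edges <- function(structure, cutoff) {
  a <- structure$atoms
  rt <- residue_table(structure)
  backbone <- c("N", "CA", "C", "O", "OXT")
  centers <- lapply(rt$resindex, function(ri) {
    rows <- which(a$resindex == ri & a$element != "H")
    ca <- rows[a$name[rows] == "CA"][1]
    cav <- c(a$x[ca], a$y[ca], a$z[ca])
    side <- rows[!(a$name[rows] %in% backbone)]
    cand <- if (length(side)) side else rows
    d <- sqrt(colSums((rbind(a$x[cand], a$y[cand], a$z[cand]) - cav)^2))
    far <- cand[order(-d, a$name[cand])][1]
    rbind(cav, c(a$x[far], a$y[far], a$z[far]))
  })
  out <- list()
  K <- nrow(rt)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    dmin <- min(sqrt(rowSums((centers[[i]][c(1, 1, 2, 2), ] -
                                centers[[j]][c(1, 2, 1, 2), ])^2)))
    if (dmin < cutoff) out[[length(out) + 1]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer()))
  as.data.frame(do.call(rbind, out)) |> stats::setNames(c("i", "j"))
}

# measured geometry of a planted hydrogen bond, read back from coordinates
readback_hbond <- function(structure, donor_res, acceptor_res) {
  a <- structure$atoms
  D <- which(a$resindex == donor_res & a$name == "OD1")
  H <- which(a$resindex == donor_res & a$name == "HD1")
  A <- which(a$resindex == acceptor_res & a$name == "OE1")
  dvec <- c(a$x[A] - a$x[D], a$y[A] - a$y[D], a$z[A] - a$z[D])
  hvec <- c(a$x[H] - a$x[D], a$y[H] - a$y[D], a$z[H] - a$z[D])
  list(distance = sqrt(sum(dvec^2)),
       angle = acos(sum(dvec * hvec) /
                      sqrt(sum(dvec^2) * sum(hvec^2))) * 180 / pi)
}

# analytic SASA of two identical spheres of augmented radius R at centre
# distance d: each sphere loses a cap of height h = R - d/2
two_sphere_area <- function(r_vdw, probe, d) {
  R <- r_vdw + probe
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

make_test_structure <- function(n = 10, geometry = "ideal_helix", ...) {
  make_structure(synthetic_spec(n, geometry, ...))
}

# minimal hand-built structure: residues given as a list of atom
# data.frames rows (name, element, x, y, z)
hand_structure <- function(residues, resname = "ALA") {
  rows <- list()
  for (r in seq_along(residues)) {
    df <- residues[[r]]
    rows[[r]] <- data.frame(eleno = 0L, name = df$name, resname = resname,
                            chain = "A", resno = r, insert = "",
                            element = df$element, x = df$x, y = df$y,
                            z = df$z, occ = 1, het = FALSE,
                            stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  allomap:::new_structure3d(atoms)
}
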