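# Coarse-grained residue interaction network: two centres per residue
# (the C-alpha and the side-chain heavy atom furthest from it), a contact
# when any centre pair of two residues lies closer than the cutoff, and
# inter-residue hydrogen-bond counts stored as edge weights.

#' Coarse-grained centres of each residue
#'
#' Every residue is reduced to two centres: its C-alpha (backbone centre)
#' and the side-chain heavy atom furthest from the C-alpha (side-chain
#' centre), so backbone-backbone, backbone-side chain and side
#' chain-side chain contacts are all covered. Residues without side-chain
#' heavy atoms (glycine) fall back to the furthest heavy atom of the whole
#' residue; a residue whose only heavy atom is the C-alpha uses it for
#' both centres. Distance ties are broken by atom-name order.
#'
#' @param structure A `structure3d`; every residue must have a C-alpha.
#' @return data.frame with one row per residue: `resindex`, `label`,
#'   `ca_x/y/z`, `far_x/y/z`, `far_atom` (PDB atom name) and `far_dist`
#'   (Angstrom from the C-alpha).
#' @export
coarse_grain <- function(structure) {
  stopifnot(inherits(structure, "structure3d"))
  a <- structure$atoms
  rt <- residue_table(structure)
  if (any(!rt$has_ca))
    stop("missing C-alpha in residue(s): ",
         paste(rt$label[!rt$has_ca], collapse = ", "))
  backbone <- c("N", "CA", "C", "O", "OXT")
  out <- vector("list", nrow(rt))
  for (k in seq_len(nrow(rt))) {
    ri <- rt$resindex[k]
    rows <- which(a$resindex == ri & a$element != "H")
    ca_row <- rows[a$name[rows] == "CA"][1]
    ca <- c(a$x[ca_row], a$y[ca_row], a$z[ca_row])
    side <- rows[!(a$name[rows] %in% backbone)]
    cand <- if (length(side)) side else rows
    d <- sqrt((a$x[cand] - ca[1])^2 + (a$y[cand] - ca[2])^2 +
                (a$z[cand] - ca[3])^2)
    best <- cand[order(-d, a$name[cand])][1]
    out[[k]] <- data.frame(resindex = ri, label = rt$label[k],
                           ca_x = ca[1], ca_y = ca[2], ca_z = ca[3],
                           far_x = a$x[best], far_y = a$y[best],
                           far_z = a$z[best], far_atom = a$name[best],
                           far_dist = max(d[cand == best][1],
                                          sqrt(sum((c(a$x[best], a$y[best],
                                                      a$z[best]) - ca)^2))))
  }
  do.call(rbind, out)
}

#' Build the weighted residue interaction network of a structure
#'
#' Residues are nodes; an edge joins residues i and j (i != j) when the
#' minimum distance over their 2 x 2 coarse-grained centre pairs is
#' strictly below `cutoff`. The number of hydrogen bonds between the two
#' residues is stored as the edge weight; path-based centralities use hop
#' counts, not these weights (the centrality definitions count edges), so
#' the weights are reported for inspection only. Sequence-adjacent
#' residues are included as contacts unless `exclude_neighbours` is
#' raised.
#'
#' @param structure A `structure3d`.
#' @param cutoff Contact distance cutoff in Angstrom (default 7; the
#'   contact test is strict `<`).
#' @param hbonds Optional hydrogen-bond table from [find_hbonds()]; when
#'   omitted it is computed from the structure.
#' @param exclude_neighbours Exclude pairs with sequence separation
#'   `|i - j| <=` this value (default 0: no exclusion).
#' @return A `rin` object: list with `nodes` (residue table), `edges`
#'   (data.frame `i`, `j`, `distance`, `hbonds` with `i < j`), `cutoff`
#'   and `K` (node count).
#' @export
build_network <- function(structure, cutoff = 7, hbonds = NULL,
                          exclude_neighbours = 0) {
  cg <- coarse_grain(structure)
  K <- nrow(cg)
  centers <- rbind(as.matrix(cg[, c("ca_x", "ca_y", "ca_z")]),
                   as.matrix(cg[, c("far_x", "far_y", "far_z")]))
  owner <- rep(cg$resindex, 2)
  D <- as.matrix(stats::dist(centers))
  if (is.null(hbonds)) {
    # without hydrogens there are no detectable donors: weights stay 0
    hbonds <- if (any(structure$atoms$element == "H")) find_hbonds(structure)
              else data.frame(donor_res = integer(), acceptor_res = integer())
  }
  hb_count <- function(i, j) {
    if (!nrow(hbonds)) return(0L)
    sum((hbonds$donor_res == i & hbonds$acceptor_res == j) |
          (hbonds$donor_res == j & hbonds$acceptor_res == i), na.rm = TRUE)
  }
  edges <- list()
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      if (j - i <= exclude_neighbours) next
      ri <- cg$resindex[i]; rj <- cg$resindex[j]
      dmin <- min(D[owner == ri, owner == rj])
      if (dmin < cutoff)
        edges[[length(edges) + 1]] <-
          data.frame(i = ri, j = rj, distance = dmin, hbonds = hb_count(ri, rj))
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(i = integer(), j = integer(),
                           distance = numeric(), hbonds = integer())
  rt <- residue_table(structure)
  out <- list(nodes = rt, edges = edges, cutoff = cutoff, K = K)
  class(out) <- "rin"
  out
}

#' @export
print.rin <- function(x, ...) {
  cat("residue interaction network:", x$K, "nodes,", nrow(x$edges),
      "edges (cutoff", x$cutoff, "A)\n")
  invisible(x)
}

#' @export
plot.rin <- function(x, ...) {
  cb <- betweenness_centrality(x)
  graphics::plot(seq_len(x$K), cb, type = "h", xlab = "residue index",
                 ylab = expression(C[B]), ...)
  graphics::abline(h = 0.05, lty = 3)
  invisible(x)
}

#' Write a residue interaction network as edge-list and node TSV files
#'
#' @param network A `rin` object.
#' @param edge_path,node_path Output paths; either may be NULL to skip.
#' @param hash Optional provenance string written as a leading `#` comment.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, edge_path, node_path = NULL, hash = NULL) {
  stopifnot(inherits(network, "rin"))
  lab <- network$nodes$label[match(network$edges$i, network$nodes$resindex)]
  labj <- network$nodes$label[match(network$edges$j, network$nodes$resindex)]
  ed <- data.frame(res_i = lab, res_j = labj,
                   min_center_distance = sprintf("%.4f", network$edges$distance),
                   hbond_weight = network$edges$hbonds)
  emit <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(hash)) writeLines(paste0("# config=", hash), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  emit(ed, edge_path)
  if (!is.null(node_path))
    emit(network$nodes[, c("resindex", "label", "chain", "resno")], node_path)
  invisible(c(edge_path, node_path))
}
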