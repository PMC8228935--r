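# Dynamical cross-correlation of C-alpha displacements and community
# analysis of the resulting weighted graph. Edge weights are
# -log|c_ij| (small weight = strong coupling) and act as distances in the
# edge-betweenness removal; modularity is evaluated with |c_ij| as the
# coupling strength on the original graph.

#' Dynamical cross-correlation matrix of C-alpha displacements
#'
#' After superposing all frames onto the ensemble mean structure, the
#' normalised covariance of per-residue displacement vectors is
#' `c_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)`. Values near +1
#' mark residues moving in concert, near -1 in opposition. Residues with
#' zero fluctuation get zero off-diagonal entries with a warning; the
#' diagonal is exactly 1.
#'
#' @param ensemble An `ensemble` with at least 2 frames and a C-alpha per
#'   residue.
#' @param fit If TRUE (default) frames are least-squares superposed onto
#'   the ensemble mean structure first, as required for raw trajectories.
#'   For ensembles generated in a common reference frame set `fit = FALSE`
#'   to measure displacements about the mean directly: the fitted rigid
#'   transform subtracts each frame's net displacement and thereby couples
#'   otherwise independent collective motions, which distorts planted
#'   correlations.
#' @return A `corr_matrix`: K x K symmetric matrix with residue labels as
#'   dimnames.
#' @export
cross_correlation <- function(ensemble, fit = TRUE) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (n_frames(ensemble) < 2) stop("cross-correlation needs >= 2 frames")
  ca <- ca_indices(ensemble$topology)
  K <- length(ca)
  if (K < 2) stop("need at least 2 C-alpha atoms")
  frames <- if (fit) fit_frames(ensemble, ca)$frames
            else lapply(seq_len(n_frames(ensemble)),
                        function(f) frame_coords(ensemble, f))
  nf <- length(frames)
  # displacement matrix: frames x (K * 3)
  X <- t(vapply(frames, function(fr) as.vector(t(fr[ca, , drop = FALSE])),
                numeric(3 * K)))
  X <- sweep(X, 2, colMeans(X))
  # inner products summed over x,y,z per residue pair
  S <- matrix(0, K, K)
  for (k in 1:3) {
    Xk <- X[, seq(k, by = 3, length.out = K), drop = FALSE]
    S <- S + crossprod(Xk)
  }
  v <- diag(S)
  zero <- v <= 0
  if (any(zero)) {
    warning("zero-fluctuation residue(s): ",
            paste(which(zero), collapse = ", "))
    v[zero] <- 1
  }
  C <- S / sqrt(outer(v, v))
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  C <- (C + t(C)) / 2
  C[C > 1] <- 1
  C[C < -1] <- -1
  lab <- residue_table(ensemble$topology)$label
  dimnames(C) <- list(lab, lab)
  class(C) <- c("corr_matrix", class(C))
  C
}

#' @export
print.corr_matrix <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("cross-correlation matrix: %d residues, mean |c| %.3f, range [%.3f, %.3f]\n",
              nrow(x), mean(abs(off)), min(off), max(off)))
  invisible(x)
}

#' Threshold a correlation matrix into a weighted graph
#'
#' Residue pairs with `|c_ij| >= cutoff` (inclusive) become edges. Each
#' edge carries `weight = -log(|c_ij|)`, a distance-like quantity that is
#' 0 for perfect coupling, and `strength = |c_ij|` used for modularity.
#'
#' @param matrix A `corr_matrix` (or plain symmetric matrix in \[-1, 1\]).
#' @param cutoff Correlation-magnitude cutoff, strictly inside (0, 1).
#' @return A `corr_graph`: list with `K`, `edges` (data.frame `i`, `j`,
#'   `weight`, `strength`, `c`) and `cutoff`.
#' @export
build_correlation_network <- function(matrix, cutoff = 0.5) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie strictly in (0, 1)")
  K <- nrow(matrix)
  idx <- which(upper.tri(matrix) & abs(matrix) >= cutoff, arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      weight = -log(pmin(1, abs(matrix[idx]))),
                      strength = abs(matrix[idx]),
                      c = as.numeric(matrix[idx]))
  if (nrow(edges)) edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  out <- list(K = K, edges = edges, cutoff = cutoff,
              labels = rownames(matrix))
  class(out) <- "corr_graph"
  out
}

#' @export
print.corr_graph <- function(x, ...) {
  cat("correlation network:", x$K, "nodes,", nrow(x$edges),
      "edges (|c| >=", x$cutoff, ")\n")
  invisible(x)
}

# connected components of an edge subset; returns membership vector
graph_components <- function(K, edges) {
  edges$i <- as.integer(edges$i)
  edges$j <- as.integer(edges$j)
  comp <- seq_len(K)
  find <- function(v) {
    while (comp[v] != v) { comp[v] <<- comp[comp[v]]; v <- comp[v] }
    v
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- find(edges$i[k]); b <- find(edges$j[k])
    if (a != b) comp[a] <- b
  }
  roots <- vapply(seq_len(K), find, integer(1))
  match(roots, unique(roots))
}

# weighted Newman-Girvan modularity of a membership vector against the
# strengths of the full graph
modularity_q <- function(K, edges, membership, strength = NULL) {
  if (!nrow(edges)) return(0)
  w <- if (is.null(strength)) rep(1, nrow(edges)) else strength
  m <- sum(w)
  k_node <- numeric(K)
  for (e in seq_len(nrow(edges))) {
    k_node[edges$i[e]] <- k_node[edges$i[e]] + w[e]
    k_node[edges$j[e]] <- k_node[edges$j[e]] + w[e]
  }
  inside <- membership[edges$i] == membership[edges$j]
  e_cc <- sum(w[inside]) / m
  a_c <- vapply(split(k_node, membership), sum, numeric(1)) / (2 * m)
  e_cc - sum(a_c^2)
}

# weighted edge betweenness via Brandes/Dijkstra; weights are distances
edge_betweenness <- function(K, edges) {
  ne <- nrow(edges)
  eb <- numeric(ne)
  if (!ne) return(eb)
  # adjacency: for each node, matrix of (neighbour, weight, edge id)
  adj <- vector("list", K)
  for (v in seq_len(K)) adj[[v]] <- list(nb = integer(0), w = numeric(0), id = integer(0))
  for (e in seq_len(ne)) {
    i <- edges$i[e]; j <- edges$j[e]; w <- edges$weight[e]
    adj[[i]]$nb <- c(adj[[i]]$nb, j); adj[[i]]$w <- c(adj[[i]]$w, w)
    adj[[i]]$id <- c(adj[[i]]$id, e)
    adj[[j]]$nb <- c(adj[[j]]$nb, i); adj[[j]]$w <- c(adj[[j]]$w, w)
    adj[[j]]$id <- c(adj[[j]]$id, e)
  }
  for (s in seq_len(K)) {
    dist <- rep(Inf, K); dist[s] <- 0
    sigma <- numeric(K); sigma[s] <- 1
    pred_v <- vector("list", K)   # predecessor nodes
    pred_e <- vector("list", K)   # corresponding edge ids
    done <- logical(K)
    order_settled <- integer(0)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (!length(cand)) break
      v <- cand[which.min(dist[cand])]
      done[v] <- TRUE
      order_settled <- c(order_settled, v)
      a <- adj[[v]]
      for (t in seq_along(a$nb)) {
        w <- a$nb[t]
        nd <- dist[v] + a$w[t]
        if (nd < dist[w] - 1e-12) {
          dist[w] <- nd
          sigma[w] <- sigma[v]
          pred_v[[w]] <- v
          pred_e[[w]] <- a$id[t]
        } else if (abs(nd - dist[w]) <= 1e-12 && !done[w]) {
          sigma[w] <- sigma[w] + sigma[v]
          pred_v[[w]] <- c(pred_v[[w]], v)
          pred_e[[w]] <- c(pred_e[[w]], a$id[t])
        }
      }
    }
    delta <- numeric(K)
    for (w in rev(order_settled)) {
      pv <- pred_v[[w]]
      if (is.null(pv)) next
      contr <- sigma[pv] / sigma[w] * (1 + delta[w])
      for (t in seq_along(pv)) {
        delta[pv[t]] <- delta[pv[t]] + contr[t]
        eb[pred_e[[w]][t]] <- eb[pred_e[[w]][t]] + contr[t]
      }
    }
  }
  eb / 2
}

#' Community detection by edge-betweenness removal (Girvan-Newman)
#'
#' Repeatedly removes the edge of highest weighted edge betweenness
#' (weights act as path distances), tracking the component partition at
#' every split of the dendrogram; the returned partition is the cut that
#' maximises weighted modularity Q on the original graph. An empty graph
#' yields the singleton partition with Q = 0.
#'
#' @param graph A `corr_graph` (or compatible list with `K` and `edges`;
#'   missing `weight`/`strength` columns default to 1).
#' @return A `community_partition`: list with `membership` (community id
#'   per node), `n_communities`, `modularity` and `labels`.
#' @export
detect_communities <- function(graph) {
  K <- graph$K
  edges <- graph$edges
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  if (is.null(edges$strength)) edges$strength <- rep(1, nrow(edges))
  if (!nrow(edges)) {
    out <- list(membership = seq_len(K), n_communities = K, modularity = 0,
                labels = graph$labels)
    class(out) <- "community_partition"
    return(out)
  }
  best_mem <- graph_components(K, edges)
  best_q <- modularity_q(K, edges, best_mem, edges$strength)
  active <- rep(TRUE, nrow(edges))
  ncomp <- max(best_mem)
  while (any(active)) {
    sub <- edges[active, , drop = FALSE]
    eb <- edge_betweenness(K, sub)
    # deterministic tie-break: first maximal edge in canonical order
    drop <- which(active)[which.max(eb)]
    active[drop] <- FALSE
    mem <- graph_components(K, edges[active, , drop = FALSE])
    if (max(mem) > ncomp) {
      ncomp <- max(mem)
      q <- modularity_q(K, edges, mem, edges$strength)
      if (q > best_q + 1e-12) {
        best_q <- q
        best_mem <- mem
      }
    }
  }
  out <- list(membership = best_mem, n_communities = max(best_mem),
              modularity = best_q, labels = graph$labels)
  class(out) <- "community_partition"
  out
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community partition: %d communities, Q = %.4f\n",
              x$n_communities, x$modularity))
  invisible(x)
}

#' Collapse a partition into a community-level network
#'
#' Nodes are communities, sized by their residue counts; an edge joins
#' two communities with the summed weight of all graph edges crossing
#' between them (and the summed coupling strength alongside).
#'
#' @param partition A `community_partition`.
#' @param graph The graph the partition was computed on.
#' @return List with `communities` (data.frame `id`, `size`) and `edges`
#'   (data.frame `a`, `b`, `weight`, `strength`, `n_links`).
#' @export
community_network <- function(partition, graph) {
  stopifnot(inherits(partition, "community_partition"))
  mem <- partition$membership
  sizes <- as.integer(table(factor(mem, levels = seq_len(max(mem)))))
  comms <- data.frame(id = seq_len(max(mem)), size = sizes)
  edges <- graph$edges
  if (is.null(edges) || !nrow(edges)) {
    return(list(communities = comms,
                edges = data.frame(a = integer(), b = integer(),
                                   weight = numeric(), strength = numeric(),
                                   n_links = integer())))
  }
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  if (is.null(edges$strength)) edges$strength <- edges$weight
  ca <- pmin(mem[edges$i], mem[edges$j])
  cb <- pmax(mem[edges$i], mem[edges$j])
  cross <- ca != cb
  if (!any(cross)) {
    ce <- data.frame(a = integer(), b = integer(), weight = numeric(),
                     strength = numeric(), n_links = integer())
  } else {
    key <- paste(ca[cross], cb[cross])
    agg <- function(v) vapply(split(v, key), sum, numeric(1))
    ce <- data.frame(a = as.integer(sub(" .*", "", names(agg(edges$weight[cross])))),
                     b = as.integer(sub(".* ", "", names(agg(edges$weight[cross])))),
                     weight = unname(agg(edges$weight[cross])),
                     strength = unname(agg(edges$strength[cross])),
                     n_links = unname(vapply(split(key, key), length, integer(1))))
    ce <- ce[order(ce$a, ce$b), , drop = FALSE]
    rownames(ce) <- NULL
  }
  list(communities = comms, edges = ce)
}
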