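# Network centralities on the residue interaction network, computed on
# hop counts (a path length is its number of edges):
#   degree       deg(r), the contact count of a residue
#   closeness    C_C(r) = [ sum_q d(q, r) / (K - 1) ]^-1
#   betweenness  C_B(r) = 2 / ((K-1)(K-2)) * sum_{a<b} sigma_ab(r) / sigma_ab
# with sigma_ab the number of shortest a-b paths and sigma_ab(r) those
# passing through r as an interior node (Brandes accumulation).
# Disconnected graphs use the Wasserman-Faust reachable-set scaling for
# closeness; node pairs spanning components contribute nothing to
# betweenness.

# normalise any supported graph input to list(K, edges(i, j))
as_graph <- function(x) {
  if (inherits(x, "rin")) return(list(K = x$K, edges = x$edges[, c("i", "j")]))
  if (inherits(x, "corr_graph")) return(list(K = x$K, edges = x$edges[, c("i", "j")]))
  if (is.list(x) && !is.null(x$K) && !is.null(x$edges))
    return(list(K = as.integer(x$K), edges = as.data.frame(x$edges)[, c("i", "j")]))
  stop("unsupported graph object")
}

adjacency_list <- function(g) {
  adj <- vector("list", g$K)
  for (v in seq_len(g$K)) adj[[v]] <- integer(0)
  if (nrow(g$edges)) {
    for (k in seq_len(nrow(g$edges))) {
      i <- g$edges$i[k]; j <- g$edges$j[k]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

#' Degree centrality
#' @param network A `rin`, correlation graph, or list with `K` and `edges`.
#' @return Integer vector of contact counts, one per node.
#' @export
degree_centrality <- function(network) {
  g <- as_graph(network)
  deg <- integer(g$K)
  if (nrow(g$edges)) {
    t1 <- tabulate(g$edges$i, g$K)
    t2 <- tabulate(g$edges$j, g$K)
    deg <- t1 + t2
  }
  deg
}

#' Hop-count shortest path lengths from one node
#'
#' Unit-weight Dijkstra (equivalently breadth-first search) distances from
#' `source` to every node; unreachable nodes are `Inf`.
#'
#' @param network A graph as in [degree_centrality()].
#' @param source Source node index.
#' @return Numeric vector of hop counts.
#' @export
shortest_path_lengths <- function(network, source) {
  g <- as_graph(network)
  if (source < 1 || source > g$K) stop("unknown source node ", source)
  adj <- adjacency_list(g)
  dist <- rep(Inf, g$K)
  dist[source] <- 0
  queue <- source
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.infinite(dist[w])) {
      dist[w] <- dist[v] + 1
      queue <- c(queue, w)
    }
  }
  dist
}

#' Closeness centrality
#'
#' `C_C(r) = [ sum_q d(q, r) / (K - 1) ]^-1` over hop-count distances. On
#' disconnected graphs the sum runs over the reachable set of `r` and the
#' value is scaled by `(n_reach - 1) / (K - 1)` (Wasserman-Faust), so
#' isolated nodes get 0 and the measure stays in \[0, 1\].
#'
#' @param network A graph as in [degree_centrality()].
#' @return Numeric vector of closeness values.
#' @export
closeness_centrality <- function(network) {
  g <- as_graph(network)
  if (g$K < 2) stop("closeness undefined for a single-node graph")
  vapply(seq_len(g$K), function(r) {
    d <- shortest_path_lengths(g, r)
    reach <- which(is.finite(d) & d > 0)
    if (!length(reach)) return(0)
    nr <- length(reach) + 1
    ((nr - 1) / (g$K - 1)) * (nr - 1) / sum(d[reach])
  }, numeric(1))
}

#' Betweenness centrality (Brandes)
#'
#' Normalised betweenness
#' `C_B(r) = 2/((K-1)(K-2)) * sum_{a<b, a,b != r} sigma_ab(r)/sigma_ab`,
#' endpoints excluded, computed by Brandes' dependency accumulation over
#' hop-count shortest paths. Pairs without a connecting path contribute 0.
#'
#' @param network A graph as in [degree_centrality()]; needs K >= 3.
#' @return Numeric vector of betweenness values in \[0, 1\].
#' @export
betweenness_centrality <- function(network) {
  g <- as_graph(network)
  K <- g$K
  if (K < 3) stop("betweenness normalisation undefined for K < 3")
  adj <- adjacency_list(g)
  cb <- numeric(K)
  for (s in seq_len(K)) {
    # BFS from s with path counting
    sigma <- numeric(K); sigma[s] <- 1
    dist <- rep(-1L, K); dist[s] <- 0L
    pred <- vector("list", K)
    order_visited <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
    delta <- numeric(K)
    for (w in rev(order_visited)) {
      for (v in pred[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  # each unordered pair was accumulated from both endpoints
  cb / 2 * 2 / ((K - 1) * (K - 2))
}

#' Combined per-residue centrality table
#'
#' @param network A `rin` object.
#' @param state Optional state label recorded with the table.
#' @return A `centrality_table`: data.frame with `resindex`, `label`,
#'   `chain`, `resno`, `C_D`, `C_C`, `C_B`.
#' @export
centrality_table <- function(network, state = NULL) {
  stopifnot(inherits(network, "rin"))
  out <- data.frame(resindex = network$nodes$resindex,
                    label = network$nodes$label,
                    chain = network$nodes$chain,
                    resno = network$nodes$resno,
                    C_D = degree_centrality(network),
                    C_C = closeness_centrality(network),
                    C_B = betweenness_centrality(network))
  attr(out, "state") <- state
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Allosteric hot-spot report
#'
#' Residues whose betweenness centrality meets the threshold (inclusive),
#' sorted by descending `C_B`. The conventional cutoff marking residues
#' critical for intramolecular signal flow is 0.05.
#'
#' @param table A `centrality_table`.
#' @param threshold Inclusive `C_B` cutoff (default 0.05).
#' @return A `hotspot_report`: data.frame of the selected rows with the
#'   threshold and state label as attributes.
#' @export
hotspots <- function(table, threshold = 0.05) {
  stopifnot(inherits(table, "centrality_table"))
  # inclusive cutoff; epsilon guards exact-boundary values against round-off
  sel <- table[table$C_B >= threshold - 1e-12, , drop = FALSE]
  sel <- sel[order(-sel$C_B, sel$resindex), , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "threshold") <- threshold
  attr(sel, "state") <- attr(table, "state")
  class(sel) <- c("hotspot_report", "data.frame")
  sel
}

#' State-difference report on betweenness centrality
#'
#' Residues whose betweenness changes by at least `threshold` (inclusive)
#' between two states, `|C_B^a - C_B^b| >= threshold`. Tables are joined
#' on residue labels; residues present in only one table enter with
#' `C_B = 0` and a warning.
#'
#' @param a,b `centrality_table` objects for the two states.
#' @param threshold Inclusive absolute-difference cutoff (default 0.02).
#' @return A `delta_report`: data.frame with `label`, `C_B_a`, `C_B_b`,
#'   `delta` (absolute difference), sorted by descending `delta`.
#' @export
delta_hotspots <- function(a, b, threshold = 0.02) {
  stopifnot(inherits(a, "centrality_table"), inherits(b, "centrality_table"))
  if (!length(intersect(a$label, b$label)))
    stop("centrality tables share no residues")
  if (!setequal(a$label, b$label))
    warning("tables differ in residue sets; missing residues enter with C_B = 0")
  labels <- union(a$label, b$label)
  ca <- a$C_B[match(labels, a$label)]; ca[is.na(ca)] <- 0
  cbv <- b$C_B[match(labels, b$label)]; cbv[is.na(cbv)] <- 0
  d <- abs(ca - cbv)
  out <- data.frame(label = labels, C_B_a = ca, C_B_b = cbv, delta = d)
  out <- out[out$delta >= threshold - 1e-12, , drop = FALSE]
  out <- out[order(-out$delta, out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "states") <- c(attr(a, "state"), attr(b, "state"))
  class(out) <- c("delta_report", "data.frame")
  out
}
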