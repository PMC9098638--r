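# Node centrality for weighted partial-correlation networks: strength,
# closeness, betweenness, with z-standardized versions for reporting.

#' Node strength
#'
#' Sum of absolute edge weights incident to each node — how well a node is
#' directly connected to the rest of the network. This is the headline
#' centrality index: the distance-based indices are computed and reported
#' too, but only strength is gated as interpretable by default (see
#' [case_dropping_stability()]).
#'
#' @param network An `ordnet_network`, or a symmetric weight matrix.
#' @return Named numeric vector of strengths.
#' @export
node_strength <- function(network) {
  w <- if (inherits(network, "ordnet_network")) network$weights else network
  rowSums(abs(w))
}

#' Global strength (overall connectivity)
#'
#' Absolute sum of all edge weights, i.e. half the sum of node strengths.
#'
#' @inheritParams node_strength
#' @return Scalar.
#' @export
global_strength <- function(network) {
  w <- if (inherits(network, "ordnet_network")) network$weights else network
  sum(abs(w[upper.tri(w)]))
}

#' Centrality table of a network
#'
#' Computes node strength, closeness and betweenness, plus z-standardized
#' versions. Path-based indices use edge length `1 / |weight|` and
#' Dijkstra shortest paths; betweenness gives fractional credit when
#' several shortest paths tie. Closeness is the reciprocal of the summed
#' shortest-path distances to the other nodes, restricted to the node's
#' connected component; an isolated node gets closeness 0. Networks with
#' unreachable pairs are flagged via attribute `disconnected`.
#'
#' @param network An `ordnet_network` or symmetric weight matrix.
#' @return Data frame with columns `node`, `strength`, `closeness`,
#'   `betweenness`, `z_strength`, `z_closeness`, `z_betweenness`.
#' @export
#' @examples
#' w <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
#' w["A", "B"] <- w["B", "A"] <- 0.5
#' w["B", "C"] <- w["C", "B"] <- 0.5
#' centrality_table(w)
centrality_table <- function(network) {
  w <- if (inherits(network, "ordnet_network")) network$weights else network
  p <- nrow(w)
  nodes <- rownames(w) %||% paste0("V", seq_len(p))
  a <- abs(w)
  strength <- rowSums(a)

  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0) {
    len <- 1 / igraph::E(g)$weight
    D <- igraph::distances(g, weights = len)
    btw <- igraph::betweenness(g, weights = len, directed = FALSE)
  } else {
    D <- matrix(Inf, p, p); diag(D) <- 0
    btw <- rep(0, p)
  }
  closeness <- vapply(seq_len(p), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0 || sum(d) == 0) 0 else 1 / sum(d)
  }, numeric(1))
  disconnected <- any(!is.finite(D))

  zs <- function(v) if (sd(v) > 0) as.numeric(scale(v)) else rep(0, length(v))
  out <- data.frame(node = nodes, strength = strength,
                    closeness = closeness, betweenness = unname(btw),
                    z_strength = zs(strength), z_closeness = zs(closeness),
                    z_betweenness = zs(btw), row.names = NULL)
  attr(out, "disconnected") <- disconnected
  out
}

# Fast internal path: centralities as a named list of vectors, used inside
# bootstrap loops.
centrality_vectors <- function(w) {
  tab <- centrality_table(w)
  list(strength = tab$strength, closeness = tab$closeness,
       betweenness = tab$betweenness)
}
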