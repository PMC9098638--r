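# Shared fixtures: small generating models and a slow brute-force
# centrality oracle used to validate the Dijkstra-based implementation.

chain_spec <- function(p = 8, pcor = 0.3) {
  precision_spec("chain", nodes = paste0("N", seq_len(p)), partial_cor = pcor)
}

chain_data <- function(n, p = 8, pcor = 0.3, seed = 1, k = 5) {
  theta <- build_precision(chain_spec(p, pcor))
  sample_ordinal(theta, discretization_spec(k),
                 group_design("all", n), seed = seed)
}

# All-pairs shortest paths and centralities by exhaustive enumeration of
# simple paths (feasible for <= 6 nodes). Distances are 1/|weight|;
# betweenness credits interior nodes fractionally across tied shortest
# paths.
brute_centrality <- function(w) {
  p <- nrow(w)
  a <- abs(w)
  len <- ifelse(a > 0, 1 / a, Inf)
  nodes <- seq_len(p)
  # enumerate all simple paths between each pair
  paths_between <- function(i, j) {
    out <- list()
    grow <- function(path) {
      last <- path[length(path)]
      if (last == j) { out[[length(out) + 1]] <<- path; return() }
      for (nxt in nodes[a[last, ] > 0]) {
        if (!(nxt %in% path)) grow(c(path, nxt))
      }
    }
    grow(i)
    out
  }
  plen <- function(path) {
    if (length(path) < 2) return(0)
    sum(len[cbind(path[-length(path)], path[-1])])
  }
  strength <- rowSums(a)
  D <- matrix(Inf, p, p); diag(D) <- 0
  btw <- rep(0, p)
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    ps <- paths_between(i, j)
    if (length(ps) == 0) next
    ls <- vapply(ps, plen, numeric(1))
    dmin <- min(ls)
    D[i, j] <- D[j, i] <- dmin
    shortest <- ps[abs(ls - dmin) < 1e-12]
    for (sp in shortest) {
      interior <- setdiff(sp, c(i, j))
      btw[interior] <- btw[interior] + 1 / length(shortest)
    }
  }
  closeness <- vapply(1:p, function(i) {
    d <- D[i, -i]; d <- d[is.finite(d)]
    if (length(d) == 0 || sum(d) == 0) 0 else 1 / sum(d)
  }, numeric(1))
  list(strength = strength, closeness = closeness, betweenness = btw,
       distances = D)
}

# named weight matrix builder
wmat <- function(p, edges, nodes = paste0("N", seq_len(p))) {
  w <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (e in edges) w[e[[1]], e[[2]]] <- w[e[[2]], e[[1]]] <- e[[3]]
  w
}
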