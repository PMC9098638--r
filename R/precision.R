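# Ground-truth precision matrices for the synthetic-data generator.

#' Specify a sparse latent precision matrix
#'
#' Describes the generating Gaussian graphical model for synthetic ordinal
#' data: which conditional-dependence edges exist and how strong they are.
#' Edges are parameterized on the partial-correlation scale, so the
#' generating model lives on the same scale as the estimated networks.
#'
#' @param structure One of `"chain"` (edges between consecutive nodes),
#'   `"hub"` (node 1 connected to all others), `"random-sparse"` (each
#'   possible edge present independently with probability `edge_density`),
#'   or `"explicit"` (a user-supplied precision matrix).
#' @param nodes Character vector of node labels; defaults to the eight
#'   S-QoL18 dimension codes.
#' @param partial_cor Target partial correlation of present edges, in
#'   (-1, 1). Ignored for `"explicit"`.
#' @param edge_density Fraction of the `p(p-1)/2` possible edges present;
#'   required for `"random-sparse"`.
#' @param matrix Symmetric positive-definite precision matrix; required for
#'   `"explicit"`.
#' @return An object of class `precision_spec`.
#' @seealso [build_precision()]
#' @export
#' @examples
#' precision_spec("chain", nodes = c("A", "B", "C"), partial_cor = 0.5)
precision_spec <- function(structure = c("chain", "hub", "random-sparse", "explicit"),
                           nodes = sqol18_nodes(),
                           partial_cor = 0.3,
                           edge_density = NULL,
                           matrix = NULL) {
  structure <- match.arg(structure)
  if (structure == "explicit") {
    if (is.null(matrix)) stop("structure 'explicit' requires `matrix`")
    if (!isSymmetric(unname(matrix), tol = 1e-10))
      stop("explicit precision matrix must be symmetric")
    ev <- min(eigen(matrix, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0)
      stop(sprintf(
        "explicit precision matrix is not positive definite (smallest eigenvalue %.3g)",
        ev))
    if (is.null(rownames(matrix))) dimnames(matrix) <- list(nodes, nodes)
    nodes <- rownames(matrix)
  } else {
    if (abs(partial_cor) >= 1) stop("`partial_cor` must be in (-1, 1)")
    if (structure == "random-sparse") {
      if (is.null(edge_density) || edge_density < 0 || edge_density > 1)
        stop("structure 'random-sparse' requires `edge_density` in [0, 1]")
    }
    if (length(nodes) < 2) stop("at least 2 nodes required")
  }
  structure(
    list(structure = structure, nodes = nodes, partial_cor = partial_cor,
         edge_density = edge_density, matrix = matrix),
    class = "precision_spec")
}

#' Build a positive-definite precision matrix from a specification
#'
#' Constructs the precision matrix whose implied partial correlations equal
#' `partial_cor` on the structural edges and are exactly zero elsewhere.
#' If the requested pattern/magnitude combination is indefinite, the matrix
#' is repaired by a diagonal shift followed by rescaling toward the target
#' magnitudes (at most 50 iterations); when no positive-definite matrix
#' with the exact target exists, the off-diagonals are uniformly shrunk to
#' the largest feasible magnitude (eigenvalue margin 0.05) and a warning is
#' issued, with the achieved value recorded in attribute `achieved_pcor`.
#'
#' @param spec A [precision_spec()].
#' @param seed Optional integer seed for the `"random-sparse"` edge draw.
#' @return Symmetric positive-definite matrix with node-name dimnames and
#'   attribute `edges` (two-column matrix of structural edge indices).
#' @export
#' @examples
#' theta <- build_precision(precision_spec("chain", nodes = c("A", "B", "C"),
#'                                         partial_cor = 0.5))
#' partial_cors(theta)
build_precision <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "precision_spec"))
  if (spec$structure == "explicit") {
    theta <- spec$matrix
    pc <- partial_cors(theta)
    edges <- which(abs(pc) > 1e-12 & upper.tri(pc), arr.ind = TRUE)
    attr(theta, "edges") <- unname(edges)
    return(theta)
  }
  p <- length(spec$nodes)
  edges <- switch(spec$structure,
    chain = cbind(seq_len(p - 1), seq_len(p - 1) + 1L),
    hub = cbind(1L, seq(2L, p)),
    "random-sparse" = {
      if (!is.null(seed)) set.seed(seed)
      all_pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
      keep <- runif(nrow(all_pairs)) < spec$edge_density
      all_pairs[keep, , drop = FALSE]
    })
  r <- spec$partial_cor
  pattern <- matrix(0, p, p)
  pattern[edges] <- 1
  pattern <- pattern + t(pattern)

  # precision with unit diagonal and -r at edges: implied pcor is exactly r
  omega <- diag(p) - r * pattern
  margin <- 0.05
  achieved <- r
  lmin <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (lmin <= 1e-8) {
    # shift by delta*I then renormalize to unit diagonal (equivalently a
    # uniform off-diagonal shrink by 1/(1+delta)); iterate until the
    # eigenvalue margin holds
    shrink <- 1
    for (iter in seq_len(50)) {
      delta <- max(0, -lmin + margin)
      if (delta == 0) break
      shrink <- shrink / (1 + delta)
      omega <- diag(p) - r * shrink * pattern
      lmin <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    }
    achieved <- r * shrink
    warning(sprintf(
      "requested partial correlation %.3f infeasible for this structure; shrunk to %.4f",
      r, achieved))
  }
  dimnames(omega) <- list(spec$nodes, spec$nodes)
  attr(omega, "edges") <- unname(edges)
  attr(omega, "achieved_pcor") <- achieved
  omega
}

#' Partial correlations implied by a precision matrix
#'
#' @param theta Symmetric positive-definite precision matrix.
#' @return Symmetric matrix of partial correlations
#'   `-theta_ij / sqrt(theta_ii * theta_jj)` with zero diagonal.
#' @export
partial_cors <- function(theta) {
  d <- 1 / sqrt(diag(theta))
  pc <- -(d * unclass(theta)) * rep(d, each = nrow(theta))
  pc[lower.tri(pc)] <- t(pc)[lower.tri(pc)]  # exact symmetry
  diag(pc) <- 0
  attributes(pc) <- list(dim = dim(pc), dimnames = dimnames(theta)[1:2])
  pc
}

#' Modify edges of a precision matrix
#'
#' Applies per-group edge perturbations: each row of `edits` sets the
#' partial correlation of one node pair (0 removes the edge). Diagonal
#' entries are kept, off-diagonals rescaled so the stated partial
#' correlation is attained exactly.
#'
#' @param theta Base precision matrix.
#' @param edits Data frame with columns `from`, `to` (node names or
#'   indices) and `pcor` (new partial correlation, in (-1, 1)).
#' @return Perturbed positive-definite precision matrix.
#' @export
perturb_precision <- function(theta, edits) {
  if (is.null(edits) || nrow(edits) == 0) return(theta)
  out <- theta
  nodes <- rownames(theta)
  for (k in seq_len(nrow(edits))) {
    i <- edits$from[k]; j <- edits$to[k]
    if (is.character(i)) i <- match(i, nodes)
    if (is.character(j)) j <- match(j, nodes)
    if (anyNA(c(i, j))) stop("perturbation names unknown node(s)")
    v <- -edits$pcor[k] * sqrt(out[i, i] * out[j, j])
    out[i, j] <- out[j, i] <- v
  }
  ev <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    stop(sprintf(
      "perturbed precision matrix is not positive definite (smallest eigenvalue %.3g)",
      ev))
  attr(out, "edges") <- NULL
  out
}
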