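# Regularized Gaussian graphical model estimation: graphical lasso over a
# log-spaced tuning-parameter path, extended-BIC model selection, and
# precision-to-partial-correlation conversion.

#' Log-spaced tuning-parameter path for the graphical lasso
#'
#' The largest value is the maximal absolute off-diagonal correlation (the
#' smallest penalty at which every edge is shrunk to zero); values descend
#' log-linearly to `lambda_max * lambda_min_ratio`.
#'
#' @param corr Correlation matrix.
#' @param n_lambda Number of path values (default 100).
#' @param lambda_min_ratio Smallest value as a fraction of the largest
#'   (default 0.01).
#' @return Numeric vector of penalties, descending. Length 0 if all
#'   off-diagonals are zero (degenerate path; the network is empty).
#' @export
lambda_path <- function(corr, n_lambda = 100, lambda_min_ratio = 0.01) {
  if (n_lambda < 2) stop("`n_lambda` must be >= 2")
  if (lambda_min_ratio <= 0 || lambda_min_ratio >= 1)
    stop("`lambda_min_ratio` must be in (0, 1)")
  lmax <- max(abs(corr[upper.tri(corr)]))
  if (lmax < 1e-12) return(numeric(0))
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' Graphical lasso at a single penalty
#'
#' Maximizes `log det(Theta) - tr(S Theta) - lambda * sum_{i != j}
#' |Theta_ij|` (off-diagonal penalty only) by block coordinate descent.
#'
#' @param corr Positive semi-definite correlation matrix `S`.
#' @param lambda Penalty (>= 0).
#' @param tol Convergence tolerance, scaled by the mean absolute
#'   off-diagonal of `S` (default 1e-4).
#' @param maxit Maximum outer iterations (default 200).
#' @return List with `theta` (estimated precision), `w` (its inverse, the
#'   estimated covariance) and `converged`.
#' @export
glasso_fit <- function(corr, lambda, tol = 1e-4, maxit = 200) {
  if (lambda < 0) stop("`lambda` must be >= 0")
  fit <- .glasso_cpp(unname(corr), lambda, tol, maxit)
  dimnames(fit$theta) <- dimnames(fit$w) <- dimnames(corr)
  if (!fit$converged) warning("glasso did not converge at lambda = ", lambda)
  fit
}

#' Extended Bayesian information criterion of a fitted precision matrix
#'
#' `EBIC = -n (log det Theta - tr(S Theta)) + E log n + 4 E gamma log p`,
#' where `E` is the number of nonzero off-diagonal entries (upper
#' triangle) and `p` the number of nodes. Only differences along a path
#' are meaningful; additive constants are dropped.
#'
#' @param theta Positive-definite precision matrix.
#' @param corr Correlation matrix `S` used in the fit.
#' @param n Sample size.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param edge_tol Absolute threshold below which an entry counts as zero.
#' @return EBIC value (scalar).
#' @export
ebic <- function(theta, corr, n, gamma = 0.5, edge_tol = 1e-8) {
  ld <- determinant(theta, logarithm = TRUE)
  if (ld$sign <= 0) stop("precision matrix must be positive definite")
  p <- nrow(theta)
  E <- sum(abs(theta[upper.tri(theta)]) > edge_tol)
  loglik <- as.numeric(ld$modulus) - sum(corr * theta)
  -n * loglik + E * log(n) + 4 * E * gamma * log(p)
}

empty_network <- function(nodes, n, gamma, method = "polychoric") {
  p <- length(nodes)
  structure(
    list(weights = matrix(0, p, p, dimnames = list(nodes, nodes)),
         nodes = nodes,
         lambda = 0, gamma = gamma, n = n, cor_method = method,
         path = data.frame(lambda = 0, edges = 0L, loglik = NA_real_,
                           ebic = NA_real_, converged = TRUE,
                           selected = TRUE)),
    class = "ordnet_network")
}

#' Estimate a regularized partial-correlation network
#'
#' Fits the graphical lasso over the full [lambda_path()], selects the
#' model with minimal [ebic()] (ties broken toward larger penalties, i.e.
#' sparser models), and converts the selected precision matrix to partial
#' correlations `-Theta_ij / sqrt(Theta_ii Theta_jj)`.
#'
#' @param x An `ordinal_dataset` (a polychoric correlation matrix is
#'   estimated first) or a correlation matrix (then `n` is required).
#' @param n Sample size for the EBIC; taken from the data when omitted.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda,lambda_min_ratio Path layout (defaults 100 and 0.01).
#' @param tol,maxit Solver control, see [glasso_fit()].
#' @param max_levels Passed to [polychoric_matrix()] when `x` is a dataset.
#' @param edge_tol Zero threshold for edge presence (default 1e-8).
#' @return An object of class `ordnet_network`: list with `weights`
#'   (symmetric partial-correlation matrix, zero diagonal), `nodes`,
#'   provenance fields (`lambda`, `gamma`, `n`, `cor_method`), and `path`
#'   (per-penalty diagnostics: lambda, edges, loglik, ebic, converged,
#'   selected).
#' @export
#' @examples
#' theta <- build_precision(precision_spec("chain", partial_cor = 0.3))
#' d <- sample_ordinal(theta, design = group_design("A", 800), seed = 3)
#' net <- select_network(d)
#' net
select_network <- function(x, n = NULL, gamma = 0.5, n_lambda = 100,
                           lambda_min_ratio = 0.01, tol = 1e-4, maxit = 200,
                           max_levels = 15, edge_tol = 1e-8) {
  if (inherits(x, "ordinal_dataset") ||
      (is.matrix(x) && !isSymmetric(unname(x), tol = 1e-8)) ||
      is.data.frame(x)) {
    corr <- polychoric_matrix(x, max_levels = max_levels)
    n <- n %||% attr(corr, "n")
    method <- "polychoric"
  } else {
    corr <- x
    if (is.null(n)) stop("`n` is required when passing a correlation matrix")
    method <- "supplied"
  }
  nodes <- rownames(corr) %||% paste0("V", seq_len(nrow(corr)))
  lambdas <- lambda_path(corr, n_lambda, lambda_min_ratio)
  if (length(lambdas) == 0) return(empty_network(nodes, n, gamma, method))

  fit <- .glasso_path_cpp(unname(corr), lambdas, tol, maxit)
  m <- length(lambdas)
  logliks <- fit$loglik
  ebics <- -n * logliks + fit$edges * log(n) +
    4 * fit$edges * gamma * log(length(nodes))
  usable <- which(fit$converged & is.finite(ebics))
  if (length(usable) == 0)
    stop("no usable model on the regularization path (solver failures)")
  sel <- usable[which.min(ebics[usable])]  # first minimum = largest lambda

  theta <- fit$thetas[, , sel]
  w <- partial_cors(theta)
  w[abs(w) < edge_tol] <- 0
  dimnames(w) <- list(nodes, nodes)
  path <- data.frame(lambda = lambdas, edges = fit$edges,
                     loglik = logliks, ebic = ebics,
                     converged = fit$converged,
                     selected = seq_len(m) == sel)
  structure(
    list(weights = w, nodes = nodes, lambda = lambdas[sel], gamma = gamma,
         n = n, cor_method = method, path = path),
    class = "ordnet_network")
}

#' @export
print.ordnet_network <- function(x, ...) {
  e <- sum(abs(x$weights[upper.tri(x$weights)]) > 0)
  cat(sprintf(
    "Partial-correlation network: %d nodes, %d edges (lambda = %.4g, gamma = %.2g, n = %d)\n",
    length(x$nodes), e, x$lambda, x$gamma, x$n))
  cat(sprintf("Global strength: %.3f\n", global_strength(x)))
  invisible(x)
}

#' Edge list of a network
#'
#' @param network An `ordnet_network`.
#' @param all If `TRUE`, include absent (zero-weight) node pairs.
#' @return Data frame with columns `node_i`, `node_j`, `weight`.
#' @export
network_edges <- function(network, all = FALSE) {
  w <- network$weights
  idx <- which(upper.tri(w), arr.ind = TRUE)
  out <- data.frame(node_i = network$nodes[idx[, 1]],
                    node_j = network$nodes[idx[, 2]],
                    weight = w[idx])
  if (!all) out <- out[out$weight != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a network and its path diagnostics to CSV
#'
#' Produces `<prefix>_edges.csv` (long-format weighted edge list),
#' `<prefix>_matrix.csv` (square weight matrix) and `<prefix>_path.csv`
#' (lambda, edge count, EBIC per path entry).
#'
#' @param network An `ordnet_network`.
#' @param prefix Output path prefix.
#' @return The three file paths, invisibly.
#' @export
write_network <- function(network, prefix) {
  paths <- paste0(prefix, c("_edges.csv", "_matrix.csv", "_path.csv"))
  write.csv(network_edges(network, all = TRUE), paths[1], row.names = FALSE)
  write.csv(data.frame(node = network$nodes, network$weights,
                       check.names = FALSE),
            paths[2], row.names = FALSE)
  write.csv(network$path, paths[3], row.names = FALSE)
  invisible(paths)
}
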