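# Two-step polychoric correlation estimation: thresholds from the observed
# marginals, then the latent correlation of each pair by bounded 1-D
# maximum likelihood over bivariate-normal rectangle probabilities.

#' Latent thresholds of an ordinal variable
#'
#' First stage of the two-step estimator: for observed categories with
#' cumulative proportions `c_1 < ... < c_{K-1} < 1`, the latent cut-points
#' are the standard-normal quantiles of the cumulative proportions.
#' Categories with zero marginal count are dropped before thresholding.
#'
#' @param x Vector of ordinal category codes (positive integers).
#' @return List with `thresholds` (length = observed categories - 1),
#'   `levels` (the observed category codes in increasing order) and
#'   `counts`.
#' @export
#' @examples
#' estimate_thresholds(rep(1:3, c(25, 50, 25)))$thresholds
estimate_thresholds <- function(x) {
  x <- as.integer(x)
  if (anyNA(x) || any(x < 1)) stop("category codes must be positive integers")
  counts <- tabulate(x)
  keep <- which(counts > 0)
  if (length(keep) < 2)
    stop("degenerate variable: fewer than 2 observed categories")
  counts <- counts[keep]
  cum <- cumsum(counts) / sum(counts)
  list(thresholds = qnorm(cum[-length(cum)]), levels = keep, counts = counts)
}

#' Polychoric correlation of one ordinal pair
#'
#' Second stage: with thresholds fixed from the marginals, the latent
#' correlation maximizes the multinomial likelihood of the contingency
#' table under a bivariate standard-normal model, by Brent search on
#' `[-1 + eps, 1 - eps]`.
#'
#' @param x,y Ordinal category codes.
#' @param bound_eps Distance of the search bounds from +/-1 (default 1e-4).
#' @param tol Optimizer tolerance on rho (default 1e-6).
#' @return List with `rho`, `loglik`, and `boundary` (`TRUE` when the
#'   estimate is clamped at a bound, e.g. for perfectly concordant tables).
#' @export
#' @examples
#' set.seed(1)
#' z <- matrix(rnorm(4000), ncol = 2) %*% chol(matrix(c(1, .5, .5, 1), 2))
#' polychoric_pair(findInterval(z[, 1], -1:1) + 1L,
#'                 findInterval(z[, 2], -1:1) + 1L)$rho
polychoric_pair <- function(x, y, bound_eps = 1e-4, tol = 1e-6) {
  tx <- estimate_thresholds(x)
  ty <- estimate_thresholds(y)
  xd <- match(as.integer(x), tx$levels)
  yd <- match(as.integer(y), ty$levels)
  kx <- length(tx$levels); ky <- length(ty$levels)
  counts <- matrix(tabulate((xd - 1L) * ky + yd, kx * ky),
                   nrow = kx, ncol = ky, byrow = TRUE)
  fit <- .polychoric_pair_cpp(counts, tx$thresholds, ty$thresholds,
                              bound_eps, tol)
  if (fit$boundary)
    warning("polychoric estimate at the boundary (degenerate association)")
  fit
}

#' Polychoric correlation matrix of an ordinal dataset
#'
#' Assembles all pairwise two-step polychoric estimates. Variables with
#' more than `max_levels` distinct observed values fall back to the Pearson
#' correlation of the raw codes (threshold estimation is unstable with many
#' sparse categories); affected pairs are recorded in the `method`
#' attribute. If the assembled matrix is not positive semi-definite it is
#' repaired by eigenvalue clipping at zero followed by unit-diagonal
#' rescaling (attribute `repaired`), since the graphical-lasso stage
#' requires a PSD input.
#'
#' @param data An `ordinal_dataset`, or a matrix/data frame of positive
#'   integer category codes (columns = variables).
#' @param max_levels Distinct-value count above which a variable is treated
#'   as continuous (default 15).
#' @param bound_eps,tol Passed to the pairwise estimator.
#' @return Correlation matrix with attributes `n` (subjects), `method`
#'   (per-pair character matrix), `repaired`, and `boundary_pairs`.
#' @export
polychoric_matrix <- function(data, max_levels = 15, bound_eps = 1e-4,
                              tol = 1e-6) {
  vals <- dataset_values(data)
  p <- ncol(vals)
  if (p < 2) stop("at least 2 variables required")
  nodes <- colnames(vals) %||% paste0("V", seq_len(p))
  n <- nrow(vals)

  dense <- vector("list", p)
  thr <- vector("list", p)
  nlev <- integer(p)
  degenerate <- character(0)
  fallback <- logical(p)
  for (j in seq_len(p)) {
    xj <- as.integer(vals[, j])
    counts <- tabulate(xj)
    lev <- which(counts > 0)
    if (length(lev) < 2) { degenerate <- c(degenerate, nodes[j]); next }
    nlev[j] <- length(lev)
    fallback[j] <- length(lev) > max_levels
    dense[[j]] <- match(xj, lev)
    if (!fallback[j]) {
      cum <- cumsum(counts[lev]) / n
      thr[[j]] <- qnorm(cum[-length(cum)])
    }
  }
  if (length(degenerate) > 0)
    stop("degenerate variable(s) with < 2 observed categories: ",
         paste(degenerate, collapse = ", "))
  if (any(fallback))
    message("Pearson fallback for variable(s) with > ", max_levels,
            " levels: ", paste(nodes[fallback], collapse = ", "))

  R <- diag(p)
  method <- matrix("polychoric", p, p, dimnames = list(nodes, nodes))
  boundary <- character(0)
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      if (fallback[i] || fallback[j]) {
        r <- cor(vals[, i], vals[, j])
        method[i, j] <- method[j, i] <- "pearson"
      } else {
        ki <- nlev[i]; kj <- nlev[j]
        counts <- matrix(tabulate((dense[[i]] - 1L) * kj + dense[[j]],
                                  ki * kj),
                         nrow = ki, ncol = kj, byrow = TRUE)
        fit <- .polychoric_pair_cpp(counts, thr[[i]], thr[[j]],
                                    bound_eps, tol)
        r <- fit$rho
        if (fit$boundary)
          boundary <- c(boundary, paste0(nodes[i], "--", nodes[j]))
      }
      R[i, j] <- R[j, i] <- r
    }
  }
  dimnames(R) <- list(nodes, nodes)

  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 0) {
    lam <- pmax(ev$values, 0)
    R <- ev$vectors %*% (lam * t(ev$vectors))
    R <- cov2cor(R)
    dimnames(R) <- list(nodes, nodes)
    repaired <- TRUE
    message("correlation matrix repaired to nearest PSD (eigenvalue clipping)")
  }
  structure(R, n = n, method = method, repaired = repaired,
            boundary_pairs = boundary)
}
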