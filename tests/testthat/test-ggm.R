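# Graphical lasso path, EBIC selection, partial-correlation conversion.

cor3 <- function() {
  theta <- build_precision(precision_spec("chain", nodes = c("A", "B", "C"),
                                          partial_cor = 0.4))
  cov2cor(solve(theta))
}

test_that("lambda path is log-spaced from the maximal correlation", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.8
  R[1, 3] <- R[3, 1] <- 0.2
  lam <- lambda_path(R, n_lambda = 100, lambda_min_ratio = 0.01)
  expect_length(lam, 100)
  expect_equal(lam[1], 0.8)
  expect_equal(lam[100], 0.008)
  expect_equal(diff(log(lam)), rep(diff(log(lam))[1], 99), tolerance = 1e-12)
  expect_equal(lambda_path(R, n_lambda = 2), c(0.8, 0.008))
  expect_length(lambda_path(diag(3)), 0)
})

test_that("glasso solves the penalized objective", {
  S <- cor3()
  # full shrinkage: diagonal precision at lambda >= lambda_max
  lmax <- max(abs(S[upper.tri(S)]))
  fit <- glasso_fit(S, lmax)
  expect_equal(unname(fit$theta), diag(1 / diag(S)), tolerance = 1e-8)
  # no penalty: direct inverse
  fit0 <- glasso_fit(S, 0, tol = 1e-7, maxit = 1000)
  expect_lt(max(abs(fit0$theta - solve(S))), 1e-4)
  # KKT optimality at an intermediate penalty: |W - S| <= lambda off the
  # support, = lambda * sign(Theta) on it
  lam <- lmax / 4
  fit1 <- glasso_fit(S, lam, tol = 1e-7, maxit = 2000)
  kkt <- solve(fit1$theta) - S
  off <- which(upper.tri(S), arr.ind = TRUE)
  for (k in seq_len(nrow(off))) {
    i <- off[k, 1]; j <- off[k, 2]
    if (abs(fit1$theta[i, j]) > 1e-8) {
      expect_equal(kkt[i, j], lam * sign(fit1$theta[i, j]), tolerance = 1e-5)
    } else {
      expect_lte(abs(kkt[i, j]), lam + 1e-5)
    }
  }
  # chain structure: the absent (1,3) edge is shrunk away before the chain
  # edges along the path
  fit2 <- glasso_fit(S, 0.05, tol = 1e-7, maxit = 2000)
  pc <- partial_cors(fit2$theta)
  expect_gt(min(abs(pc["A", "B"]), abs(pc["B", "C"])), abs(pc["A", "C"]))
})

test_that("EBIC follows the penalized-likelihood formula", {
  S <- cor3()
  th <- glasso_fit(S, 0.05)$theta
  n <- 500
  E <- sum(abs(th[upper.tri(th)]) > 1e-8)
  ll <- determinant(th)$modulus[1] - sum(S * th)
  expect_equal(ebic(th, S, n, gamma = 0.5),
               -n * ll + E * log(n) + 4 * E * 0.5 * log(3))
  # empty graph: penalty vanishes
  th0 <- diag(1 / diag(S))
  expect_equal(ebic(th0, S, n, gamma = 0.5),
               -n * (determinant(th0)$modulus[1] - sum(S * th0)))
  # gamma = 0 reduces to BIC on edges
  expect_equal(ebic(th, S, n, gamma = 0), -n * ll + E * log(n))
  # equal-likelihood models: EBIC difference is the edge-penalty difference
  n2 <- 500; p2 <- 8; g2 <- 0.5
  delta <- (5 - 3) * log(n2) + 4 * g2 * (5 - 3) * log(p2)
  expect_equal(delta, 2 * log(500) + 4 * log(8))
  expect_error(ebic(matrix(c(1, 2, 2, 1), 2), diag(2), 100),
               "positive definite")
})

test_that("partial-correlation conversion is exact and scale-invariant", {
  th <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(partial_cors(th)[1, 2], 0.5)
  # rescaling Theta -> D Theta D leaves partial correlations unchanged
  set.seed(1)
  theta <- build_precision(chain_spec(6, 0.3))
  D <- diag(runif(6, 0.5, 3))
  expect_equal(partial_cors(D %*% theta %*% D), partial_cors(theta),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("EBIC selection picks the sparsest minimum and records the path", {
  d <- chain_data(1500, p = 8, pcor = 0.3, seed = 21)
  net <- select_network(d)
  path <- net$path
  expect_equal(path$edges[1], 0L)            # largest lambda: empty graph
  usable <- path$converged & is.finite(path$ebic)
  expect_equal(min(path$ebic[usable]), path$ebic[path$selected])
  sel <- which(path$selected)
  expect_true(all(path$ebic[usable][seq_len(match(sel, which(usable)) - 1)] >
                    path$ebic[sel]))         # ties broken toward larger lambda
  expect_lte(path$edges[1], path$edges[nrow(path)])
  # weights: symmetric, zero diagonal, bounded
  expect_true(isSymmetric(net$weights))
  expect_equal(unname(diag(net$weights)), rep(0, 8))
  expect_true(all(abs(net$weights) < 1))
  # identity correlation: degenerate path, empty network
  empty <- select_network(diag(4), n = 200)
  expect_equal(sum(abs(empty$weights)), 0)
})

test_that("lambda = 0 partial correlations match the inverse-matrix oracle", {
  d <- chain_data(1500, p = 8, pcor = 0.3, seed = 22)
  R <- polychoric_matrix(d)
  fit <- glasso_fit(R, 0, tol = 1e-7, maxit = 5000)
  expect_lt(max(abs(partial_cors(fit$theta) - partial_cors(solve(R)))), 1e-4)
})

test_that("structure recovery on a chain GGM under EBIC selection", {
  hits <- vapply(1:10, function(s) {
    d <- chain_data(2000, p = 8, pcor = 0.3, seed = 100 + s)
    w <- select_network(d)$weights
    present <- abs(w[upper.tri(w)]) > 0
    true_edge <- (row(w) + 1 == col(w))[upper.tri(w)]
    all(present[true_edge]) && sum(present[!true_edge]) <= 4
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("null data yields an empty selected network most of the time", {
  empties <- vapply(1:10, function(s) {
    d <- sample_ordinal(diag(8), design = group_design("all", 2000),
                        seed = 200 + s)
    sum(abs(select_network(d)$weights)) == 0
  }, logical(1))
  expect_gte(mean(empties), 0.9)
})
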