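# Polychoric estimation: thresholds, pairwise MLE, matrix assembly.

test_that("thresholds are normal quantiles of cumulative proportions", {
  expect_equal(estimate_thresholds(rep(1:2, c(50, 50)))$thresholds, 0)
  thr <- estimate_thresholds(rep(1:3, c(25, 50, 25)))$thresholds
  expect_equal(thr, qnorm(c(0.25, 0.75)))
  expect_equal(thr[1], -thr[2])  # symmetric pair
  thr4 <- estimate_thresholds(rep(1:4, c(10, 20, 30, 40)))$thresholds
  expect_equal(thr4, qnorm(c(0.1, 0.3, 0.6)))
  # zero-count categories are dropped before thresholding
  skipcat <- estimate_thresholds(rep(c(1L, 5L), c(30, 70)))
  expect_equal(skipcat$thresholds, qnorm(0.3))
  expect_equal(skipcat$levels, c(1L, 5L))
  expect_error(estimate_thresholds(rep(2L, 50)), "degenerate")
})

test_that("bivariate-normal CDF kernel matches mvtnorm to 1e-7", {
  skip_if_not_installed("mvtnorm")
  hs <- c(-2.5, -1, -0.2, 0, 0.6, 1.7)
  rs <- c(-0.999, -0.95, -0.6, -0.2, 0, 0.35, 0.8, 0.924, 0.926, 0.99)
  for (r in rs) {
    S <- matrix(c(1, r, r, 1), 2)
    for (h in hs) for (k in hs) {
      expect_equal(
        ordnet:::.pbvn_cpp(h, k, r),
        mvtnorm::pmvnorm(upper = c(h, k), corr = S,
                         algorithm = mvtnorm::TVPACK())[1],
        tolerance = 1e-7)
    }
  }
})

test_that("pairwise estimates recover the latent correlation", {
  theta2 <- function(r) solve(matrix(c(1, r, r, 1), 2))
  gen <- function(r, n, seed, k = 5) {
    th <- build_precision(precision_spec(
      "explicit", matrix = theta2(r), nodes = c("X", "Y")))
    sample_ordinal(th, discretization_spec(k),
                   group_design("all", n), seed = seed)$values
  }
  # independence
  v0 <- gen(0, 5000, 1)
  expect_lt(abs(polychoric_pair(v0[, 1], v0[, 2])$rho), 0.05)
  # mean recovery at latent rho = 0.5 across replicates
  ests <- vapply(1:20, function(s) {
    v <- gen(0.5, 5000, s)
    polychoric_pair(v[, 1], v[, 2])$rho
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.5), 0.03)
  # exchangeability within optimizer tolerance
  expect_equal(polychoric_pair(v0[, 1], v0[, 2])$rho,
               polychoric_pair(v0[, 2], v0[, 1])$rho, tolerance = 1e-4)
})

test_that("perfect concordance is clamped at the boundary and flagged", {
  x <- rep(1:2, c(40, 60))
  expect_warning(fit <- polychoric_pair(x, x), "boundary")
  expect_equal(fit$rho, 1 - 1e-4, tolerance = 1e-3)
  expect_true(fit$boundary)
})

test_that("estimation error shrinks as n grows", {
  theta <- build_precision(chain_spec(3, 0.4))
  mae <- vapply(c(500, 2000, 8000), function(n) {
    errs <- vapply(1:10, function(s) {
      d <- sample_ordinal(theta, design = group_design("all", n), seed = s)
      R <- polychoric_matrix(d)
      max(abs(R - cov2cor(solve(theta))))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
})

test_that("matrix assembly matches the generator and the pairwise path", {
  theta <- build_precision(chain_spec(3, 0.4))
  d <- sample_ordinal(theta, design = group_design("all", 5000), seed = 3)
  R <- polychoric_matrix(d)
  expect_true(isSymmetric(unname(R)))
  expect_equal(unname(diag(R)), rep(1, 3))
  expect_lt(max(abs(R - cov2cor(solve(theta)))), 0.05)
  # identity latent correlation: near-identity estimate
  d0 <- sample_ordinal(diag(4), design = group_design("all", 4000), seed = 8)
  R0 <- polychoric_matrix(d0)
  expect_lt(max(abs(R0[upper.tri(R0)])), 3 / sqrt(4000))
  # 2-variable case agrees with the pairwise estimator
  two <- d$values[, 1:2]
  expect_equal(polychoric_matrix(two)[1, 2],
               polychoric_pair(two[, 1], two[, 2])$rho, tolerance = 1e-8)
  # degenerate column rejected with its name
  dd <- d; dd$values[, 2] <- 1L
  expect_error(polychoric_matrix(dd), "N2")
})

test_that("many-category variables fall back to Pearson", {
  set.seed(4)
  n <- 2000
  z <- matrix(rnorm(2 * n), n) %*% chol(matrix(c(1, .5, .5, 1), 2))
  many <- cbind(A = findInterval(z[, 1], qnorm((1:19) / 20)) + 1L,
                B = findInterval(z[, 2], qnorm((1:19) / 20)) + 1L,
                C = findInterval(rnorm(n), qnorm((1:4) / 5)) + 1L)
  expect_message(R <- polychoric_matrix(many, max_levels = 15), "Pearson")
  expect_equal(attr(R, "method")["A", "B"], "pearson")
  expect_equal(attr(R, "method")["B", "C"], "pearson")
  expect_equal(R["A", "B"], cor(many[, "A"], many[, "B"]))
  # with >= 15 equiprobable categories the polychoric estimate is close to
  # the Pearson correlation of the codes anyway
  R2 <- polychoric_matrix(many[, c("A", "B", "C")], max_levels = 30)
  expect_lt(abs(R2["A", "B"] - cor(many[, "A"], many[, "B"])), 0.03)
})
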