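# Generator: precision construction, discretization, reproducibility.

test_that("precision matrices realize the requested partial correlations", {
  # independence: no edges, identity precision
  spec0 <- precision_spec("explicit", matrix = diag(3),
                          nodes = c("A", "B", "C"))
  th0 <- build_precision(spec0)
  expect_equal(unname(partial_cors(th0)), matrix(0, 3, 3))

  # 3-node chain at 0.5; oracle = partial-correlation formula applied to
  # the implied latent correlation matrix
  th <- build_precision(precision_spec("chain", nodes = c("A", "B", "C"),
                                       partial_cor = 0.5))
  pc <- partial_cors(th)
  expect_equal(pc["A", "B"], 0.5, tolerance = 1e-6)
  expect_equal(pc["B", "C"], 0.5, tolerance = 1e-6)
  expect_equal(pc["A", "C"], 0)
  R <- cov2cor(solve(th))
  pc_oracle <- (R["A", "B"] - R["A", "C"] * R["B", "C"]) /
    sqrt((1 - R["A", "C"]^2) * (1 - R["B", "C"]^2))
  expect_equal(pc["A", "B"], pc_oracle, tolerance = 1e-10)

  # hub and chain at 8 nodes are feasible without repair
  for (s in c("chain", "hub")) {
    th8 <- build_precision(precision_spec(s, partial_cor = 0.3))
    ev <- eigen(th8, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    pc8 <- partial_cors(th8)
    edges <- attr(th8, "edges")
    expect_equal(unname(pc8[edges]), rep(0.3, nrow(edges)), tolerance = 1e-6)
    pc8[edges] <- 0; pc8[edges[, 2:1]] <- 0
    expect_true(all(pc8 == 0))
  }
})

test_that("random-sparse structures have binomial edge counts and are PD", {
  n_edges <- vapply(1:20, function(s) {
    th <- build_precision(precision_spec("random-sparse", partial_cor = 0.25,
                                         edge_density = 0.3), seed = s)
    expect_gt(min(eigen(th, symmetric = TRUE, only.values = TRUE)$values), 0)
    nrow(attr(th, "edges"))
  }, numeric(1))
  # Binomial(28, 0.3): mean 8.4; 20-draw mean within 4 sd of the mean
  expect_gt(mean(n_edges), 8.4 - 4 * sqrt(28 * 0.3 * 0.7 / 20))
  expect_lt(mean(n_edges), 8.4 + 4 * sqrt(28 * 0.3 * 0.7 / 20))
})

test_that("explicit non-PD matrices are rejected naming the eigenvalue", {
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(precision_spec("explicit", matrix = bad, nodes = c("A", "B")),
               "smallest eigenvalue")
  # infeasible pattern/magnitude is shrunk with a warning
  expect_warning(
    build_precision(precision_spec("hub", partial_cor = 0.6)),
    "infeasible")
})

test_that("discretization yields threshold-implied category frequencies", {
  # zero-correlation latent, equiprobable 5 categories
  d <- sample_ordinal(diag(4), discretization_spec(5),
                      group_design("all", 10000), seed = 11)
  freq <- prop.table(table(d$values[, 1]))
  expect_true(all(abs(freq - 0.2) < 0.02))

  # latent correlation 0.9, 2 categories: concentrated on the diagonal
  th <- build_precision(precision_spec(
    "explicit", nodes = c("X", "Y"),
    matrix = solve(matrix(c(1, .9, .9, 1), 2))))
  d2 <- sample_ordinal(th, discretization_spec(2),
                       group_design("all", 4000), seed = 2)
  tab <- table(d2$values[, 1], d2$values[, 2])
  expect_gt(sum(diag(tab)) / sum(tab), 0.8)
})

test_that("latent draws reproduce the generating correlation matrix", {
  theta <- build_precision(chain_spec(8, 0.3))
  n <- 8000
  d <- sample_ordinal(theta, design = group_design("all", n), seed = 5,
                      keep_latent = TRUE)
  R <- cov2cor(solve(theta))
  err <- max(abs(cor(attr(d, "latent")) - R))
  expect_lt(err, 3 / sqrt(n))
})

test_that("generation is seed-deterministic and group-stable", {
  theta <- build_precision(chain_spec(5, 0.3))
  des2 <- group_design(c("A", "B"), c(100, 150))
  d1 <- sample_ordinal(theta, design = des2, seed = 42)
  d2 <- sample_ordinal(theta, design = des2, seed = 42)
  expect_identical(d1$values, d2$values)
  expect_false(identical(
    d1$values, sample_ordinal(theta, design = des2, seed = 43)$values))

  # adding a third group never changes earlier groups' draws
  des3 <- group_design(c("A", "B", "C"), c(100, 150, 80))
  d3 <- sample_ordinal(theta, design = des3, seed = 42)
  expect_identical(d3$values[1:250, ], d1$values)

  # an empty perturbation list reproduces the base group's stream exactly
  des_pert <- group_design(c("A", "B"), c(100, 150),
                           perturbations = list(B = data.frame(
                             from = character(0), to = character(0),
                             pcor = numeric(0))))
  expect_identical(sample_ordinal(theta, design = des_pert, seed = 42)$values,
                   d1$values)
})

test_that("group perturbations change the generating model and stay PD", {
  theta <- build_precision(chain_spec(5, 0.3))
  edit <- data.frame(from = "N1", to = "N5", pcor = 0.4)
  pert <- perturb_precision(theta, edit)
  expect_equal(partial_cors(pert)["N1", "N5"], 0.4, tolerance = 1e-10)
  # removal
  gone <- perturb_precision(theta, data.frame(from = "N1", to = "N2",
                                              pcor = 0))
  expect_equal(partial_cors(gone)["N1", "N2"], 0)
  # a perturbation that breaks positive definiteness is rejected
  expect_error(perturb_precision(theta, data.frame(
    from = c("N1", "N1", "N1", "N1"), to = c("N2", "N3", "N4", "N5"),
    pcor = rep(0.9, 4))), "not positive definite")
})

test_that("CSV writer round-trips through the reader with truth sidecar", {
  theta <- build_precision(chain_spec(4, 0.3))
  d <- sample_ordinal(theta, discretization_spec(5),
                      group_design(c("A", "B"), c(40, 30)), seed = 9)
  path <- tempfile(fileext = ".csv")
  write_ordinal(d, path)
  back <- read_dataset(path)
  expect_identical(unname(back$values), unname(d$values))
  expect_identical(as.character(back$group), as.character(d$group))
  truth <- jsonlite::read_json(paste0(path, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 9)
  expect_equal(truth$precision$A, unclass(unname(theta)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # score mapping writes a 0-100 grid
  write_ordinal(d, path, score_mapping = c(0, 25))
  scored <- read.csv(path)
  expect_true(all(unlist(scored[1:4]) %in% seq(0, 100, by = 25)))
  unlink(c(path, paste0(path, ".truth.json")))
})
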