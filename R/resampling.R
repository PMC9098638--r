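# Accuracy and stability analyses: nonparametric bootstrap CIs for edge
# weights, bootstrapped difference tests, and case-dropping subset
# bootstrap with the correlation-stability (CS) coefficient.

edge_names <- function(nodes) {
  idx <- which(upper.tri(diag(length(nodes))), arr.ind = TRUE)
  paste0(nodes[idx[, 1]], "--", nodes[idx[, 2]])
}

upper_vec <- function(w) w[upper.tri(w)]

#' Nonparametric bootstrap of edge weights and node strengths
#'
#' Resamples subjects with replacement `B` times and reruns the full
#' estimation pipeline (polychoric correlations + EBIC graphical lasso) on
#' each replicate. Replicate-level failures are logged and excluded; more
#' than 10% failures triggers a warning.
#'
#' @param data An `ordinal_dataset` (one group).
#' @param B Number of bootstrap replicates (>= 100 for reporting; default
#'   1000).
#' @param seed Integer seed.
#' @param conf Confidence level for the percentile intervals (default
#'   0.95).
#' @param ... Estimation options passed to [select_network()] (`gamma`,
#'   `n_lambda`, ...).
#' @return An object of class `ordnet_boot`: the observed network, the
#'   replicate-level edge and strength samples, a per-edge CI table
#'   (`edge_ci`), and bookkeeping (`B`, `n_failed`, `seed`, `conf`).
#' @export
edge_ci_bootstrap <- function(data, B = 1000, seed = 1, conf = 0.95, ...) {
  stopifnot(inherits(data, "ordinal_dataset"))
  if (B < 2) stop("`B` must be >= 2")
  n <- nrow(data$values)
  observed <- select_network(data, ...)
  nodes <- observed$nodes
  en <- edge_names(nodes)
  edge_samples <- matrix(NA_real_, B, length(en), dimnames = list(NULL, en))
  strength_samples <- matrix(NA_real_, B, length(nodes),
                             dimnames = list(NULL, nodes))
  set.seed(seed)
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- tryCatch(
      suppressMessages(select_network(dataset_subset(data, idx), ...)),
      error = function(e) NULL)
    if (is.null(fit)) { failed <- failed + 1L; next }
    edge_samples[b, ] <- upper_vec(fit$weights)
    strength_samples[b, ] <- node_strength(fit)
  }
  ok <- !is.na(edge_samples[, 1])
  if (failed > 0.1 * B)
    warning(sprintf("%d of %d bootstrap replicates failed", failed, B))
  alpha <- (1 - conf) / 2
  es <- edge_samples[ok, , drop = FALSE]
  obs <- upper_vec(observed$weights)
  idx <- which(upper.tri(observed$weights), arr.ind = TRUE)
  edge_ci <- data.frame(
    edge = en,
    node_i = nodes[idx[, 1]], node_j = nodes[idx[, 2]],
    observed = obs,
    boot_mean = colMeans(es),
    lower = apply(es, 2, quantile, alpha),
    upper = apply(es, 2, quantile, 1 - alpha),
    row.names = NULL)
  structure(
    list(observed = observed, edge_samples = es,
         strength_samples = strength_samples[ok, , drop = FALSE],
         edge_ci = edge_ci, B = B, n_failed = failed, seed = seed,
         conf = conf),
    class = "ordnet_boot")
}

#' @export
print.ordnet_boot <- function(x, ...) {
  cat(sprintf(
    "Bootstrap of %d replicates (%d failed), %d%% percentile CIs, seed %d\n",
    x$B, x$n_failed, round(100 * x$conf), x$seed))
  invisible(x)
}

#' Bootstrapped difference tests between edges or node strengths
#'
#' For each (unordered) pair of targets, takes the replicate-wise
#' difference of bootstrapped values and builds a percentile CI around it;
#' the pair differs significantly exactly when zero lies outside the CI.
#' Also emits, per target, the number of others it is significantly
#' greater than. These within-network tests are not corrected for multiple
#' comparisons (see the output attribute `note`).
#'
#' @param boot An [edge_ci_bootstrap()] result with replicate-level
#'   samples.
#' @param target `"edges"` or `"strength"`.
#' @param conf Confidence level (default 0.95).
#' @param pairs Optional 2-column matrix/data frame of target names or
#'   indices; default all unordered pairs.
#' @return List of class `ordnet_difftest` with `table` (one row per pair:
#'   difference CI and significance flag) and `greater` (named count
#'   vector, the tabular twin of the edge/centrality difference plots).
#' @export
difference_tests <- function(boot, target = c("edges", "strength"),
                             conf = 0.95, pairs = NULL) {
  stopifnot(inherits(boot, "ordnet_boot"))
  target <- match.arg(target)
  mat <- if (target == "edges") boot$edge_samples else boot$strength_samples
  if (nrow(mat) < 100)
    stop("fewer than 100 usable bootstrap replicates; refusing to test")
  obs <- if (target == "edges") {
    stats::setNames(upper_vec(boot$observed$weights), colnames(mat))
  } else {
    node_strength(boot$observed)
  }
  nm <- colnames(mat)
  if (is.null(pairs)) {
    idx <- which(upper.tri(diag(ncol(mat))), arr.ind = TRUE)
  } else {
    idx <- cbind(match_idx(pairs[, 1], nm), match_idx(pairs[, 2], nm))
  }
  alpha <- (1 - conf) / 2
  lower <- upper <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    d <- mat[, idx[k, 1]] - mat[, idx[k, 2]]
    q <- quantile(d, c(alpha, 1 - alpha))
    lower[k] <- q[1]; upper[k] <- q[2]
  }
  sig <- lower > 0 | upper < 0
  tab <- data.frame(target_1 = nm[idx[, 1]], target_2 = nm[idx[, 2]],
                    observed_1 = unname(obs[idx[, 1]]),
                    observed_2 = unname(obs[idx[, 2]]),
                    diff = unname(obs[idx[, 1]] - obs[idx[, 2]]),
                    lower = lower, upper = upper, significant = sig,
                    row.names = NULL)
  greater <- stats::setNames(numeric(length(nm)), nm)
  for (k in which(sig)) {
    hi <- if (tab$diff[k] > 0) tab$target_1[k] else tab$target_2[k]
    greater[hi] <- greater[hi] + 1
  }
  structure(list(table = tab, greater = greater, target = target,
                 conf = conf,
                 note = "within-network tests; not corrected for multiple comparisons"),
            class = "ordnet_difftest")
}

match_idx <- function(x, nm) {
  if (is.numeric(x)) return(as.integer(x))
  i <- match(x, nm)
  if (anyNA(i)) stop("unknown target name(s): ", paste(x[is.na(i)], collapse = ", "))
  i
}

#' Case-dropping subset bootstrap and CS-coefficient
#'
#' For each drop proportion, repeatedly re-estimates the network on random
#' subsets of the cases and correlates the subset centralities with the
#' full-sample ones (Pearson, across nodes). The CS-coefficient of an
#' index is the largest proportion of cases that can be dropped such that
#' the subset-full correlation is at least `cor_threshold` with
#' probability at least `prob`; an index is deemed stable when at least
#' half of the cases can be dropped (`CS >= stable_cs`).
#'
#' @param data An `ordinal_dataset`.
#' @param grid Drop proportions (default 0.05 to 0.75 by 0.05).
#' @param B Subsets per proportion (default 1000).
#' @param seed Integer seed.
#' @param indices Centrality indices to track.
#' @param cor_threshold Correlation criterion (default 0.7).
#' @param prob Probability criterion (default 0.95).
#' @param stable_cs Stability verdict cutoff on CS (default 0.5).
#' @param ... Estimation options passed to [select_network()].
#' @return Object of class `ordnet_stability`: `curves` (proportion x
#'   index shares of correlations above threshold), `cs` (named vector; 0
#'   means below the smallest grid value), `below_min`, `verdict`, and
#'   `skipped` proportions (subset smaller than 3x the node count).
#'   Undefined correlations (zero variance) count against the criterion.
#' @export
case_dropping_stability <- function(data, grid = seq(0.05, 0.75, by = 0.05),
                                    B = 1000, seed = 1,
                                    indices = c("strength", "closeness",
                                                "betweenness"),
                                    cor_threshold = 0.7, prob = 0.95,
                                    stable_cs = 0.5, ...) {
  stopifnot(inherits(data, "ordinal_dataset"))
  grid <- sort(unique(grid))
  n <- nrow(data$values)
  p <- length(data$node_names)
  full <- centrality_vectors(
    suppressMessages(select_network(data, ...))$weights)
  skipped <- numeric(0)
  curves <- list()
  set.seed(seed)
  for (prop in grid) {
    m <- round((1 - prop) * n)
    if (m < 3 * p) {
      skipped <- c(skipped, prop)
      message(sprintf("drop proportion %.2f skipped: subset size %d < 3 x %d nodes",
                      prop, m, p))
      next
    }
    hits <- matrix(0, B, length(indices), dimnames = list(NULL, indices))
    mean_cor <- matrix(NA_real_, B, length(indices),
                       dimnames = list(NULL, indices))
    for (b in seq_len(B)) {
      idx <- sample.int(n, m)
      fit <- tryCatch(
        suppressMessages(select_network(dataset_subset(data, idx), ...)),
        error = function(e) NULL)
      if (is.null(fit)) next  # failure: hits stay 0
      sub <- centrality_vectors(fit$weights)
      for (ix in indices) {
        r <- suppressWarnings(cor(full[[ix]], sub[[ix]]))
        mean_cor[b, ix] <- r
        if (!is.na(r) && r >= cor_threshold) hits[b, ix] <- 1
      }
    }
    curves[[length(curves) + 1]] <- data.frame(
      proportion = prop, index = indices,
      share = colMeans(hits),
      mean_cor = colMeans(mean_cor, na.rm = TRUE),
      row.names = NULL)
  }
  curves <- do.call(rbind, curves)
  cs <- stats::setNames(numeric(length(indices)), indices)
  below_min <- stats::setNames(logical(length(indices)), indices)
  for (ix in indices) {
    ok <- curves$proportion[curves$index == ix &
                              curves$share >= prob]
    if (length(ok) == 0) {
      cs[ix] <- 0
      below_min[ix] <- TRUE
    } else {
      cs[ix] <- max(ok)
    }
  }
  structure(
    list(curves = curves, cs = cs, below_min = below_min,
         verdict = cs >= stable_cs, grid = grid, skipped = skipped, B = B,
         seed = seed, cor_threshold = cor_threshold, prob = prob,
         stable_cs = stable_cs),
    class = "ordnet_stability")
}

#' @export
print.ordnet_stability <- function(x, ...) {
  cat("Case-dropping stability (CS-coefficient):\n")
  for (ix in names(x$cs)) {
    cat(sprintf("  %-12s CS = %s%s  [%s]\n", ix,
                if (x$below_min[ix]) paste0("< ", min(x$grid))
                else format(x$cs[ix]),
                "",
                if (x$verdict[ix]) "stable" else "unstable"))
  }
  invisible(x)
}
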