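# Permutation-based network comparison between two groups: structure
# invariance (maximum edge difference), global-strength invariance,
# individual edges and node strengths, with Holm correction per family.

#' Holm step-down adjustment of p-values
#'
#' `adjusted_(i) = max_{j <= i} min(1, (m - j + 1) p_(j))` over the sorted
#' p-values, returned in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  p.adjust(p, method = "holm")
}

nct_stats <- function(net1, net2) {
  d <- abs(net1$weights - net2$weights)
  list(edges = upper_vec(d),
       structure = max(upper_vec(d)),
       global = abs(global_strength(net1) - global_strength(net2)),
       strength = abs(node_strength(net1) - node_strength(net2)))
}

perm_p <- function(perm, obs) (1 + sum(perm >= obs)) / (1 + length(perm))

#' Permutation network comparison test between two groups
#'
#' Re-runs the full estimation pipeline (polychoric correlations +
#' EBIC-selected graphical lasso) on repeated random regroupings of the
#' pooled subjects (original group sizes preserved) and compares four
#' families of absolute-difference statistics against their permutation
#' null distributions: network structure (maximum absolute edge
#' difference), global strength, each individual edge weight, and each
#' node strength. Two-sidedness is realized through the absolute-value
#' statistics; p-values use the add-one formula
#' `(1 + #{perm >= observed}) / (1 + n_permutations)`. The edge and
#' strength families are Holm-adjusted within family.
#'
#' @param data1,data2 `ordinal_dataset`s sharing the same node set.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Significance level recorded in the result (default 0.05).
#' @param seed Integer seed.
#' @param ... Estimation options passed to [select_network()].
#' @return Object of class `ordnet_nct`: `global` (data frame with the
#'   structure and global-strength tests), `edges` and `strength` (data
#'   frames with observed statistics, raw and Holm-adjusted p-values),
#'   the two estimated networks, and bookkeeping (`n_perm`, `n_failed`,
#'   `alpha`, `seed`).
#' @export
compare_networks <- function(data1, data2, n_perm = 1000, alpha = 0.05,
                             seed = 1, ...) {
  stopifnot(inherits(data1, "ordinal_dataset"),
            inherits(data2, "ordinal_dataset"))
  if (!identical(data1$node_names, data2$node_names))
    stop("the two groups must share the same node set")
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")

  est <- function(vals) suppressMessages(select_network(
    structure(list(values = vals, group = NULL,
                   node_names = colnames(vals)),
              class = "ordinal_dataset"), ...))
  net1 <- est(data1$values)
  net2 <- est(data2$values)
  obs <- nct_stats(net1, net2)

  pooled <- rbind(data1$values, data2$values)
  n1 <- nrow(data1$values); n <- nrow(pooled)
  en <- edge_names(net1$nodes)
  perm_edges <- matrix(NA_real_, n_perm, length(en))
  perm_struct <- perm_global <- rep(NA_real_, n_perm)
  perm_strength <- matrix(NA_real_, n_perm, length(net1$nodes))
  set.seed(seed)
  failed <- 0L
  for (b in seq_len(n_perm)) {
    s <- NULL
    for (attempt in 1:2) {  # one resample on replicate failure
      idx <- sample.int(n, n1)
      s <- tryCatch({
        p1 <- est(pooled[idx, , drop = FALSE])
        p2 <- est(pooled[-idx, , drop = FALSE])
        nct_stats(p1, p2)
      }, error = function(e) NULL)
      if (!is.null(s)) break
    }
    if (is.null(s)) { failed <- failed + 1L; next }
    perm_edges[b, ] <- s$edges
    perm_struct[b] <- s$structure
    perm_global[b] <- s$global
    perm_strength[b, ] <- s$strength
  }
  ok <- !is.na(perm_struct)
  if (failed > 0.05 * n_perm)
    warning(sprintf("%d of %d permutation replicates failed", failed, n_perm))

  p_edges <- vapply(seq_along(en), function(k)
    perm_p(perm_edges[ok, k], obs$edges[k]), numeric(1))
  p_strength <- vapply(seq_along(net1$nodes), function(k)
    perm_p(perm_strength[ok, k], obs$strength[k]), numeric(1))
  structure(
    list(
      global = data.frame(
        statistic = c("structure", "global_strength"),
        observed = c(obs$structure, obs$global),
        p = c(perm_p(perm_struct[ok], obs$structure),
              perm_p(perm_global[ok], obs$global)),
        row.names = NULL),
      edges = data.frame(edge = en, observed = obs$edges, p = p_edges,
                         p_holm = holm_adjust(p_edges), row.names = NULL),
      strength = data.frame(node = net1$nodes,
                            observed = unname(obs$strength),
                            p = p_strength,
                            p_holm = holm_adjust(p_strength),
                            row.names = NULL),
      network1 = net1, network2 = net2,
      n_perm = n_perm, n_used = sum(ok), n_failed = failed,
      alpha = alpha, seed = seed),
    class = "ordnet_nct")
}

#' @export
print.ordnet_nct <- function(x, ...) {
  cat(sprintf("Network comparison test (%d permutations, alpha = %.3g)\n",
              x$n_perm, x$alpha))
  g <- x$global
  cat(sprintf("  structure:       M = %.4f, p = %.4f\n",
              g$observed[1], g$p[1]))
  cat(sprintf("  global strength: S = %.4f, p = %.4f\n",
              g$observed[2], g$p[2]))
  cat(sprintf("  edges with Holm p < alpha: %d; strengths: %d\n",
              sum(x$edges$p_holm < x$alpha),
              sum(x$strength$p_holm < x$alpha)))
  invisible(x)
}

#' All pairwise network comparison tests across groups
#'
#' Runs [compare_networks()] for every pair of group levels (the k-group
#' comparison is a battery of two-group tests; no joint k-group model).
#' Within each comparison the edge and strength families are
#' Holm-adjusted; a second adjustment across the pairwise comparisons per
#' family is reported in `p_holm_across`, since a 6-group design yields 15
#' comparisons per family.
#'
#' @param data An `ordinal_dataset` with a group factor.
#' @param n_perm,alpha,seed,... Passed to [compare_networks()]; each pair
#'   gets a distinct seed derived from `seed`.
#' @return Object of class `ordnet_nct_battery`: `table` (one row per
#'   group pair x statistic with observed value, raw p, Holm p within
#'   family/comparison, Holm p across comparisons) and the per-pair
#'   `ordnet_nct` objects.
#' @export
compare_groups <- function(data, n_perm = 1000, alpha = 0.05, seed = 1, ...) {
  stopifnot(inherits(data, "ordinal_dataset"))
  lev <- levels(data$group)
  if (length(lev) < 2) stop("need at least 2 groups to compare")
  pairs <- utils::combn(lev, 2)
  tests <- vector("list", ncol(pairs))
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    tests[[k]] <- compare_networks(
      dataset_subset(data, group = g1), dataset_subset(data, group = g2),
      n_perm = n_perm, alpha = alpha,
      seed = (seed + 7919 * k) %% 2147483647, ...)
    tt <- tests[[k]]
    rows[[k]] <- rbind(
      data.frame(group_1 = g1, group_2 = g2, family = tt$global$statistic,
                 statistic = tt$global$statistic,
                 observed = tt$global$observed, p = tt$global$p,
                 p_holm_within = tt$global$p),
      data.frame(group_1 = g1, group_2 = g2, family = "edge",
                 statistic = tt$edges$edge, observed = tt$edges$observed,
                 p = tt$edges$p, p_holm_within = tt$edges$p_holm),
      data.frame(group_1 = g1, group_2 = g2, family = "strength",
                 statistic = tt$strength$node,
                 observed = tt$strength$observed, p = tt$strength$p,
                 p_holm_within = tt$strength$p_holm))
  }
  tab <- do.call(rbind, rows)
  tab$p_holm_across <- NA_real_
  for (fam in unique(tab$family)) {
    sel <- tab$family == fam
    tab$p_holm_across[sel] <- holm_adjust(tab$p[sel])
  }
  names(tests) <- apply(pairs, 2, paste, collapse = " vs ")
  structure(list(table = tab, tests = tests, alpha = alpha,
                 n_perm = n_perm, seed = seed),
            class = "ordnet_nct_battery")
}

#' @export
print.ordnet_nct_battery <- function(x, ...) {
  cat(sprintf("NCT battery: %d pairwise comparisons, %d permutations each\n",
              length(x$tests), x$n_perm))
  sig <- x$table[x$table$p_holm_within < x$alpha, , drop = FALSE]
  if (nrow(sig) == 0) {
    cat("No Holm-significant differences at alpha =", x$alpha, "\n")
  } else {
    cat("Holm-significant (within family/comparison):\n")
    print(sig[, c("group_1", "group_2", "family", "statistic",
                  "observed", "p_holm_within")], row.names = FALSE)
  }
  invisible(x)
}
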