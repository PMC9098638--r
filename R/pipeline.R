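# Study driver: per-group estimation, centrality, accuracy tests,
# stability gate, and the between-group comparison battery, from one
# configuration.

#' Read an ordinal dataset from CSV
#'
#' Expects one row per subject, numeric-coded ordinal node columns and a
#' categorical group column. Rows with a missing node value are dropped
#' (listwise deletion) with a logged count; category codes are re-indexed
#' densely per column (original values kept in attribute `levels`).
#'
#' @param path CSV file with a header row.
#' @param node_cols Node column names; default all columns except
#'   `group_col`.
#' @param group_col Name of the group column (default `"group"`); may be
#'   absent, in which case a single group `"all"` is assumed.
#' @return An `ordinal_dataset`.
#' @export
read_dataset <- function(path, node_cols = NULL, group_col = "group") {
  df <- read.csv(path, check.names = FALSE, comment.char = "#")
  if (is.null(node_cols))
    node_cols <- setdiff(names(df), group_col)
  missing_cols <- setdiff(c(node_cols,
                            if (group_col %in% names(df)) group_col),
                          names(df))
  if (length(missing_cols) > 0)
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  if (length(node_cols) < 3)
    stop("need at least 3 node columns, got ", length(node_cols))
  bad <- node_cols[!vapply(df[node_cols], is.numeric, logical(1))]
  if (length(bad) > 0)
    stop("non-numeric node column(s): ", paste(bad, collapse = ", "))

  keep <- stats::complete.cases(df[node_cols])
  if (any(!keep))
    message(sum(!keep), " row(s) with missing node values dropped")
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 2) stop("fewer than 2 usable rows")

  vals <- matrix(0L, nrow(df), length(node_cols),
                 dimnames = list(NULL, node_cols))
  levels_by_col <- vector("list", length(node_cols))
  names(levels_by_col) <- node_cols
  for (j in seq_along(node_cols)) {
    x <- df[[node_cols[j]]]
    lev <- sort(unique(x))
    levels_by_col[[j]] <- lev
    vals[, j] <- match(x, lev)
  }
  grp <- if (group_col %in% names(df)) factor(df[[group_col]])
         else factor(rep("all", nrow(df)))
  out <- structure(list(values = vals, group = grp, node_names = node_cols),
                   class = "ordinal_dataset")
  attr(out, "levels") <- levels_by_col
  out
}

#' Configuration for a full network study
#'
#' Collects every tunable of the pipeline with the study defaults: EBIC
#' gamma 0.5 over 100 log-spaced penalties, 1000-replicate bootstraps,
#' case-dropping stability with the 0.7-correlation / 95%-probability /
#' 50%-drop criterion, and a 1000-permutation comparison battery at alpha
#' 0.05 with Holm correction.
#'
#' @param gamma,n_lambda,lambda_min_ratio Network estimation, see
#'   [select_network()].
#' @param boot_B,stability_B,stability_grid Accuracy analyses, see
#'   [edge_ci_bootstrap()] and [case_dropping_stability()].
#' @param cor_threshold,prob,stable_cs Stability criterion.
#' @param n_perm,alpha Comparison battery, see [compare_groups()].
#' @param seed Global seed; stage seeds are derived from it.
#' @param do_bootstrap,do_stability,do_comparison Stage switches.
#' @return List of class `study_config`.
#' @export
study_config <- function(gamma = 0.5, n_lambda = 100,
                         lambda_min_ratio = 0.01, boot_B = 1000,
                         stability_B = 1000,
                         stability_grid = seq(0.05, 0.75, by = 0.05),
                         cor_threshold = 0.7, prob = 0.95, stable_cs = 0.5,
                         n_perm = 1000, alpha = 0.05, seed = 1,
                         do_bootstrap = TRUE, do_stability = TRUE,
                         do_comparison = TRUE) {
  structure(as.list(environment()), class = "study_config")
}

#' Run the full network study on a grouped ordinal dataset
#'
#' Executes, per group: network estimation (polychoric + EBIC glasso),
#' centrality, bootstrap edge CIs and difference tests, and case-dropping
#' stability (which gates which centrality indices are flagged
#' interpretable); then the pairwise permutation comparison battery across
#' groups. A stage failure aborts only its dependents; skipped sections
#' are recorded. Every serialized artifact is stamped with the
#' configuration hash and seed.
#'
#' @param data An `ordinal_dataset` or a CSV path (read via
#'   [read_dataset()]).
#' @param config A [study_config()].
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param group_col Group column name when `data` is a path.
#' @return Object of class `ordnet_study`: per-group results (`groups`),
#'   the comparison battery (`comparison`), a `headline` table (strongest
#'   node per group and the edges significantly stronger than most
#'   others), `skipped`, `config`, and `config_hash`.
#' @export
run_study <- function(data, config = study_config(), out_dir = NULL,
                      group_col = "group") {
  if (is.character(data)) data <- read_dataset(data, group_col = group_col)
  stopifnot(inherits(data, "ordinal_dataset"),
            inherits(config, "study_config"))
  hash <- config_hash(config)
  lev <- levels(data$group)
  est_args <- list(gamma = config$gamma, n_lambda = config$n_lambda,
                   lambda_min_ratio = config$lambda_min_ratio)
  groups <- list()
  skipped <- character(0)
  for (g in seq_along(lev)) {
    gd <- dataset_subset(data, group = lev[g])
    res <- list()
    res$network <- tryCatch(
      do.call(select_network, c(list(gd), est_args)),
      error = function(e) {
        message("estimation failed for group ", lev[g], ": ",
                conditionMessage(e))
        NULL
      })
    if (is.null(res$network)) {
      skipped <- c(skipped, paste0(lev[g], ":all"))
      groups[[lev[g]]] <- res
      next
    }
    res$centrality <- centrality_table(res$network)
    if (config$do_bootstrap) {
      res$bootstrap <- tryCatch(
        do.call(edge_ci_bootstrap,
                c(list(gd, B = config$boot_B,
                       seed = (config$seed + 31 * g) %% 2147483647),
                  est_args)),
        error = function(e) NULL)
      if (is.null(res$bootstrap)) {
        skipped <- c(skipped, paste0(lev[g], ":bootstrap"))
      } else {
        res$edge_diff <- difference_tests(res$bootstrap, "edges")
        res$strength_diff <- difference_tests(res$bootstrap, "strength")
      }
    }
    if (config$do_stability) {
      res$stability <- tryCatch(
        do.call(case_dropping_stability,
                c(list(gd, grid = config$stability_grid,
                       B = config$stability_B,
                       seed = (config$seed + 97 * g) %% 2147483647,
                       cor_threshold = config$cor_threshold,
                       prob = config$prob, stable_cs = config$stable_cs),
                  est_args)),
        error = function(e) NULL)
      if (is.null(res$stability))
        skipped <- c(skipped, paste0(lev[g], ":stability"))
    }
    groups[[lev[g]]] <- res
  }

  comparison <- NULL
  if (config$do_comparison) {
    if (length(lev) < 2) {
      message("single group: comparison stage disabled")
      skipped <- c(skipped, "comparison")
    } else {
      comparison <- tryCatch(
        do.call(compare_groups,
                c(list(data, n_perm = config$n_perm, alpha = config$alpha,
                       seed = config$seed), est_args)),
        error = function(e) { message("comparison stage failed: ",
                                      conditionMessage(e)); NULL })
      if (is.null(comparison)) skipped <- c(skipped, "comparison")
    }
  }

  headline <- do.call(rbind, lapply(names(groups), function(g) {
    res <- groups[[g]]
    if (is.null(res$network)) return(NULL)
    ct <- res$centrality
    strongest <- ct$node[which.max(ct$strength)]
    top_edges <- if (!is.null(res$edge_diff)) {
      gr <- res$edge_diff$greater
      paste(names(sort(gr, decreasing = TRUE))[seq_len(min(4, sum(gr > 0)))],
            collapse = "; ")
    } else NA_character_
    stable <- if (!is.null(res$stability))
      paste(names(which(res$stability$verdict)), collapse = "; ")
    else NA_character_
    data.frame(group = g, strongest_node = strongest,
               top_edges = top_edges, stable_indices = stable)
  }))

  report <- structure(
    list(groups = groups, comparison = comparison, headline = headline,
         skipped = skipped, config = config, config_hash = hash,
         seed = config$seed),
    class = "ordnet_study")
  if (!is.null(out_dir)) write_study(report, out_dir)
  report
}

#' @export
print.ordnet_study <- function(x, ...) {
  cat(sprintf("Network study: %d group(s), config %s, seed %d\n",
              length(x$groups), x$config_hash, x$seed))
  if (!is.null(x$headline)) print(x$headline, row.names = FALSE)
  if (!is.null(x$comparison)) print(x$comparison)
  if (length(x$skipped) > 0)
    cat("Skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

# Serialize all study tables; each CSV starts with a stamped comment line.
write_study <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# config=%s seed=%d", report$config_hash, report$seed)
  wcsv <- function(df, file) {
    path <- file.path(out_dir, file)
    writeLines(stamp, path)
    suppressWarnings(write.table(df, path, sep = ",", row.names = FALSE,
                                 append = TRUE, qmethod = "double"))
    path
  }
  for (g in names(report$groups)) {
    res <- report$groups[[g]]
    if (is.null(res$network)) next
    wcsv(network_edges(res$network, all = TRUE),
         paste0("network_", g, ".csv"))
    wcsv(res$centrality, paste0("centrality_", g, ".csv"))
    if (!is.null(res$bootstrap))
      wcsv(res$bootstrap$edge_ci, paste0("edge_ci_", g, ".csv"))
    if (!is.null(res$edge_diff))
      wcsv(res$edge_diff$table, paste0("edge_difftest_", g, ".csv"))
    if (!is.null(res$strength_diff))
      wcsv(res$strength_diff$table, paste0("strength_difftest_", g, ".csv"))
    if (!is.null(res$stability))
      wcsv(res$stability$curves, paste0("stability_", g, ".csv"))
  }
  if (!is.null(report$comparison))
    wcsv(report$comparison$table, "nct_battery.csv")
  summary <- list(
    config_hash = report$config_hash, seed = report$seed,
    groups = lapply(report$groups, function(res) {
      if (is.null(res$network)) return(list(estimated = FALSE))
      list(estimated = TRUE,
           edges = sum(abs(res$network$weights[
             upper.tri(res$network$weights)]) > 0),
           global_strength = global_strength(res$network),
           strongest_node =
             res$centrality$node[which.max(res$centrality$strength)],
           cs = if (!is.null(res$stability)) as.list(res$stability$cs),
           stable = if (!is.null(res$stability))
             as.list(res$stability$verdict))
    }),
    skipped = report$skipped)
  jsonlite::write_json(summary, file.path(out_dir, "study_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
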