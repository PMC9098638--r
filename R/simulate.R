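# Sampling grouped ordinal data from a latent Gaussian graphical model:
# the generative inverse of the polychoric measurement model.

#' Specify how latent scores are discretized into ordinal categories
#'
#' @param n_categories Number of response categories per variable (>= 2).
#'   The default of 5 reflects rating scales with a small number of
#'   response options.
#' @param thresholds Optional cut-points on the latent standard-normal
#'   scale: a single increasing numeric vector of length
#'   `n_categories - 1` applied to every variable, or a list with one such
#'   vector per variable. Default: equiprobable standard-normal quantiles.
#' @param score_mapping Optional affine map applied when *writing* data:
#'   either a numeric `c(intercept, slope)` applied to the zero-based
#'   category index, or `"percent"` for an even 0-100 grid. Analysis
#'   functions always operate on category codes; the mapping is an I/O
#'   convention.
#' @return An object of class `discretization_spec`.
#' @export
discretization_spec <- function(n_categories = 5, thresholds = NULL,
                                score_mapping = NULL) {
  if (n_categories < 2) stop("`n_categories` must be >= 2")
  check_thr <- function(t) {
    if (length(t) != n_categories - 1)
      stop("thresholds must have length n_categories - 1")
    if (any(diff(t) <= 0) || any(!is.finite(t)))
      stop("thresholds must be finite and strictly increasing")
    t
  }
  if (!is.null(thresholds)) {
    if (is.list(thresholds)) lapply(thresholds, check_thr) else check_thr(thresholds)
  }
  if (identical(score_mapping, "percent"))
    score_mapping <- c(0, 100 / (n_categories - 1))
  structure(list(n_categories = as.integer(n_categories),
                 thresholds = thresholds, score_mapping = score_mapping),
            class = "discretization_spec")
}

#' Specify the group layout of a synthetic dataset
#'
#' @param names Character vector of group labels.
#' @param sizes Integer vector of subjects per group (each >= 2).
#' @param perturbations Optional named list (by group) of edge
#'   modifications applied to the base precision matrix, each a data frame
#'   with columns `from`, `to`, `pcor` (see [perturb_precision()]). Groups
#'   without an entry (or with an empty one) use the base model unchanged.
#' @return An object of class `group_design`.
#' @export
#' @examples
#' group_design(c("A", "B"), c(900, 300))
group_design <- function(names, sizes, perturbations = NULL) {
  if (length(names) != length(sizes)) stop("`names` and `sizes` lengths differ")
  if (any(sizes < 2)) stop("group sizes must be >= 2")
  if (!is.null(perturbations) && !all(names(perturbations) %in% names))
    stop("perturbations refer to unknown group(s)")
  structure(list(names = as.character(names), sizes = as.integer(sizes),
                 perturbations = perturbations),
            class = "group_design")
}

threshold_list <- function(disc, p) {
  k <- disc$n_categories
  if (is.null(disc$thresholds)) {
    rep(list(qnorm(seq_len(k - 1) / k)), p)
  } else if (is.list(disc$thresholds)) {
    if (length(disc$thresholds) != p)
      stop("need one threshold vector per variable")
    disc$thresholds
  } else {
    rep(list(disc$thresholds), p)
  }
}

# Per-group seed offsets from one base seed, so that adding a group never
# changes the draws of earlier groups.
group_seed <- function(seed, g) (as.integer(seed) + 104729L * g) %% 2147483647L

#' Sample a grouped ordinal dataset from a latent GGM
#'
#' Draws latent multivariate-normal scores with correlation matrix equal to
#' the (unit-diagonal rescaled) inverse of the precision matrix, then
#' discretizes each variable at its thresholds. Each group uses the base
#' precision matrix, optionally perturbed per [group_design()].
#'
#' @param precision Positive-definite precision matrix (see
#'   [build_precision()]).
#' @param disc A [discretization_spec()].
#' @param design A [group_design()].
#' @param seed Integer seed; each group's draws are a fixed offset of it.
#' @param keep_latent If `TRUE`, the latent draws are attached as attribute
#'   `latent` (used for generator validation).
#' @return An object of class `ordinal_dataset`: list with `values`
#'   (subjects x variables integer category codes, 1-based), `group`
#'   (factor), and `node_names`. The ground-truth precision matrices and
#'   thresholds are attached as attribute `truth`.
#' @export
#' @examples
#' theta <- build_precision(precision_spec("chain", partial_cor = 0.3))
#' d <- sample_ordinal(theta, discretization_spec(5),
#'                     group_design("A", 200), seed = 1)
#' table(d$values[, "SEL"])
sample_ordinal <- function(precision, disc = discretization_spec(),
                           design = group_design("all", 500), seed = 1,
                           keep_latent = FALSE) {
  stopifnot(inherits(disc, "discretization_spec"),
            inherits(design, "group_design"))
  p <- nrow(precision)
  nodes <- rownames(precision) %||% paste0("V", seq_len(p))
  thr <- threshold_list(disc, p)
  per_group <- vector("list", length(design$names))
  latents <- if (keep_latent) vector("list", length(design$names))
  truth <- list(seed = seed, thresholds = thr, precision = list())
  for (g in seq_along(design$names)) {
    gname <- design$names[g]
    theta_g <- perturb_precision(precision, design$perturbations[[gname]])
    ev <- min(eigen(theta_g, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) stop("group precision matrix is not positive definite")
    rho <- cov2cor(solve(theta_g))
    n <- design$sizes[g]
    set.seed(group_seed(seed, g))
    z <- matrix(rnorm(n * p), n, p) %*% chol(rho)
    codes <- matrix(0L, n, p, dimnames = list(NULL, nodes))
    for (j in seq_len(p))
      codes[, j] <- findInterval(z[, j], thr[[j]]) + 1L
    per_group[[g]] <- codes
    if (keep_latent) latents[[g]] <- z
    truth$precision[[gname]] <- theta_g
  }
  out <- structure(
    list(values = do.call(rbind, per_group),
         group = factor(rep(design$names, design$sizes),
                        levels = design$names),
         node_names = nodes),
    class = "ordinal_dataset")
  attr(out, "truth") <- truth
  if (keep_latent) attr(out, "latent") <- do.call(rbind, latents)
  out
}

#' @export
print.ordinal_dataset <- function(x, ...) {
  cat(sprintf("Ordinal dataset: %d subjects x %d variables (%s)\n",
              nrow(x$values), length(x$node_names),
              paste(x$node_names, collapse = ", ")))
  gt <- table(x$group)
  cat("Groups:", paste(sprintf("%s (n=%d)", names(gt), gt), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.ordinal_dataset <- function(x, ...) {
  data.frame(x$values, group = x$group, check.names = FALSE)
}

# Accepts an ordinal_dataset, matrix or data.frame of codes.
dataset_values <- function(data) {
  if (inherits(data, "ordinal_dataset")) return(data$values)
  m <- as.matrix(data)
  if (!is.numeric(m)) stop("node columns must be numeric category codes")
  m
}

#' Subset an ordinal dataset by row index or group
#'
#' @param data An `ordinal_dataset`.
#' @param rows Integer row indices (resampling) or `NULL`.
#' @param group Group label(s) to keep, or `NULL`.
#' @return An `ordinal_dataset`.
#' @export
dataset_subset <- function(data, rows = NULL, group = NULL) {
  stopifnot(inherits(data, "ordinal_dataset"))
  if (!is.null(group)) rows <- which(data$group %in% group)
  structure(list(values = data$values[rows, , drop = FALSE],
                 group = droplevels(data$group[rows]),
                 node_names = data$node_names),
            class = "ordinal_dataset")
}

#' Write an ordinal dataset to CSV with a ground-truth sidecar
#'
#' Writes one row per subject (node columns plus `group`). Category codes
#' are written as-is unless the discretization's `score_mapping` is given,
#' in which case the affine map is applied. If the dataset carries
#' generator ground truth, a JSON sidecar `<path>.truth.json` stores the
#' per-group precision matrices, thresholds and seed.
#'
#' @param data An `ordinal_dataset`.
#' @param path Output CSV path.
#' @param score_mapping Optional `c(intercept, slope)` applied to the
#'   zero-based category index before writing.
#' @return `path`, invisibly.
#' @export
write_ordinal <- function(data, path, score_mapping = NULL) {
  stopifnot(inherits(data, "ordinal_dataset"))
  vals <- data$values
  if (!is.null(score_mapping))
    vals <- score_mapping[1] + score_mapping[2] * (vals - 1L)
  df <- data.frame(vals, group = as.character(data$group),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  truth <- attr(data, "truth")
  if (!is.null(truth)) {
    side <- list(seed = truth$seed,
                 node_names = data$node_names,
                 thresholds = truth$thresholds,
                 precision = lapply(truth$precision, function(m)
                   unclass(unname(m))))
    jsonlite::write_json(side, paste0(path, ".truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}
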