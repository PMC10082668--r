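# End-to-end analysis: markers -> target set -> distance matrices ->
# evaluation statistics, and the artificial two-group experiment used for
# benchmarking the local against the global distance.

#' Run the full local-alignment beta-diversity analysis
#'
#' Selects exact markers (unless a marker set is supplied), recruits
#' approximate markers from the neighbor index, computes pairwise distance
#' matrices in the requested modes (`"fms"`: exact + weighted approximate
#' markers; `"exact"`: exact markers only; `"global"`: whole community), and
#' evaluates each matrix by PERMANOVA, ANOSIM, multivariate dispersion and
#' (for two groups) leave-one-out KNN classification AUC.
#'
#' @param table normalized feature table (features x samples).
#' @param groups group labels, one per sample in column order.
#' @param tree rooted [ape::phylo] tree over the features.
#' @param index `fms_index` neighbor index (required for mode `"fms"`).
#' @param markers optional `fms_markers` (user-assigned); when `NULL`,
#'   markers are selected by [select_exact_markers()] at `alpha`.
#' @param alpha marker-selection significance cutoff (default 0.01).
#' @param modes subset of `c("fms", "exact", "global")`.
#' @param k KNN neighborhood size (default 3).
#' @param n_perm permutations for the significance tests (default 999).
#' @param seed optional seed for the permutation tests.
#' @param positive positive-class label for KNN/ROC; default last level.
#' @return object of class `fms_analysis`: list with `markers`, `target`,
#'   `distances` (named list of matrices), `tests` (summary data.frame) and
#'   `scores` (KNN scores per mode, two-group case only).
#' @examples
#' ds <- simulate_dataset(scenario_config(n_per_group = 10, seed = 3))
#' fit <- fms_analysis(ds$table, ds$metadata$group, ds$tree, ds$index,
#'   n_perm = 99, seed = 1)
#' fit$tests
#' @export
fms_analysis <- function(table, groups, tree, index = NULL, markers = NULL,
                         alpha = 0.01, modes = c("fms", "exact", "global"),
                         k = 3L, n_perm = 999, seed = NULL, positive = NULL) {
  modes <- match.arg(modes, several.ok = TRUE)
  groups <- factor(groups)
  if (length(groups) != ncol(table)) fms_validation_stop("one group label per sample required")
  if (any(c("fms", "exact") %in% modes) && is.null(markers)) {
    markers <- select_exact_markers(table, groups, alpha = alpha)
  }
  if ("fms" %in% modes && is.null(index)) {
    fms_validation_stop("mode 'fms' requires a neighbor index (use mode 'exact' to skip it)")
  }
  no_markers <- !is.null(markers) && length(markers$exact) == 0L
  if (no_markers && any(c("fms", "exact") %in% modes)) {
    warning("no exact markers selected; marker-based modes skipped")
    modes <- intersect(modes, "global")
  }
  target <- if ("fms" %in% modes) build_target_set(markers, index) else NULL
  distances <- list()
  for (mode in modes) {
    distances[[mode]] <- switch(mode,
      fms = fms_distance_matrix(table, tree, target),
      exact = fms_distance_matrix(table, tree, build_target_set(markers, NULL)),
      global = fms_distance_matrix(table, tree, NULL)
    )
  }
  two_groups <- nlevels(groups) == 2L
  scores <- list()
  rows <- lapply(names(distances), function(mode) {
    dm <- distances[[mode]]
    pa <- permanova_test(dm, groups, n_perm = n_perm, seed = seed)
    an <- anosim_test(dm, groups, n_perm = n_perm, seed = seed)
    di <- dispersion_test(dm, groups, n_perm = n_perm, seed = seed)
    auc <- NA_real_
    if (two_groups) {
      sc <- knn_loo_scores(dm, groups, k = k, positive = positive)
      scores[[mode]] <<- sc
      auc <- roc_auc(sc, groups, positive = positive)$auc
    }
    data.frame(
      mode = mode,
      permanova_F = pa$statistic, permanova_R2 = pa$R2, permanova_p = pa$p_value,
      anosim_R = an$statistic, anosim_p = an$p_value,
      dispersion_F = di$statistic, dispersion_p = di$p_value,
      knn_auc = auc, stringsAsFactors = FALSE
    )
  })
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  structure(
    list(
      markers = markers, target = target, distances = distances,
      tests = tests, scores = scores, groups = groups,
      params = list(alpha = alpha, k = k, n_perm = n_perm, seed = seed)
    ),
    class = "fms_analysis"
  )
}

#' @export
print.fms_analysis <- function(x, ...) {
  cat("Local-alignment beta-diversity analysis\n")
  if (!is.null(x$markers)) print(x$markers)
  if (!is.null(x$target)) print(x$target)
  cat(sprintf(
    "Distance modes: %s; groups: %s\n",
    paste(names(x$distances), collapse = ", "),
    paste(levels(x$groups), collapse = " vs ")
  ))
  print(x$tests, digits = 4)
  invisible(x)
}

#' @export
summary.fms_analysis <- function(object, ...) object$tests

#' Plot the PCoA ordination of a fitted analysis
#'
#' @param x an `fms_analysis`.
#' @param mode which distance matrix to ordinate (default the first).
#' @param ... passed to [graphics::plot()].
#' @export
plot.fms_analysis <- function(x, mode = names(x$distances)[1L], ...) {
  ord <- pcoa_ordination(x$distances[[mode]])
  co <- ord$coordinates
  if (ncol(co) < 2L) co <- cbind(co, 0)
  pe <- ord$proportion_explained
  graphics::plot(co[, 1L], co[, 2L],
    col = as.integer(x$groups), pch = 19,
    xlab = sprintf("PCo1 (%.1f%%)", 100 * pe[1L]),
    ylab = sprintf("PCo2 (%.1f%%)", if (length(pe) > 1L) 100 * pe[2L] else 0),
    main = sprintf("PCoA (%s distance)", mode), ...
  )
  graphics::legend("topright", legend = levels(x$groups),
                   col = seq_len(nlevels(x$groups)), pch = 19, bty = "n")
  invisible(x)
}

#' Re-run the artificial two-group experiment over seeds
#'
#' For each seed, simulates the default two-group scenario, selects exact
#' markers by Wilcoxon rank-sum at `alpha`, builds the target set from the
#' generated neighbor index, computes the local (FMS), exact-markers-only
#' and global distance matrices, and scores two-group classification by
#' leave-one-out KNN ROC AUC on each.
#'
#' @param n_seeds number of independent replicate datasets (default 20).
#' @param base_seed seeds used are `base_seed + 0:(n_seeds-1)`.
#' @param cfg scenario configuration; default [scenario_config()].
#' @param alpha marker-selection cutoff (default 0.01).
#' @param k KNN neighborhood size (default 3).
#' @return data.frame with one row per seed and columns `seed`, `auc_fms`,
#'   `auc_exact`, `auc_global`, `n_markers_selected`.
#' @export
artificial_experiment <- function(n_seeds = 20L, base_seed = 1L,
                                  cfg = scenario_config(), alpha = 0.01, k = 3L) {
  rows <- lapply(seq_len(n_seeds) - 1L, function(off) {
    seed <- base_seed + off
    ds <- simulate_dataset(cfg, seed = seed)
    g <- factor(ds$metadata$group)
    mk <- select_exact_markers(ds$table, g, alpha = alpha)
    auc_of <- function(dm) {
      roc_auc(knn_loo_scores(dm, g, k = k), g)$auc
    }
    auc_fms <- auc_exact <- NA_real_
    if (length(mk$exact) > 0L) {
      auc_fms <- auc_of(fms_distance_matrix(ds$table, ds$tree, build_target_set(mk, ds$index)))
      auc_exact <- suppressWarnings(
        auc_of(fms_distance_matrix(ds$table, ds$tree, build_target_set(mk, NULL)))
      )
    }
    auc_global <- auc_of(fms_distance_matrix(ds$table, ds$tree, NULL))
    data.frame(
      seed = seed, auc_fms = auc_fms, auc_exact = auc_exact,
      auc_global = auc_global, n_markers_selected = length(mk$exact)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
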