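# Evaluation battery for distance matrices: ordination, permutation tests,
# dispersion homogeneity, and distance-based KNN classification with ROC.

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric MDS: double-centering of the squared distances followed
#' by eigendecomposition ([stats::cmdscale()]). Axes are ordered by
#' descending eigenvalue; axes with non-positive eigenvalues are dropped
#' from the coordinates but all eigenvalues are reported.
#'
#' @param dm symmetric distance matrix with zero diagonal.
#' @return object of class `fms_pcoa`: list with `coordinates`
#'   (samples x positive axes), `eigenvalues` (all), and
#'   `proportion_explained` (relative to the positive-eigenvalue total).
#' @export
pcoa_ordination <- function(dm) {
  dm <- validate_distance_matrix(dm)
  n <- nrow(dm)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dm), k = max(1L, n - 1L), eig = TRUE)
  )
  eig <- fit$eig
  pos <- which(eig > 1e-9)
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  if (length(pos) > 0L) {
    colnames(coords) <- paste0("PCo", seq_along(pos))
  }
  structure(
    list(
      coordinates = coords,
      eigenvalues = eig,
      proportion_explained = if (length(pos) > 0L) eig[pos] / sum(eig[pos]) else numeric()
    ),
    class = "fms_pcoa"
  )
}

#' @export
print.fms_pcoa <- function(x, ...) {
  cat(sprintf(
    "PCoA: %d sample(s), %d positive axis/axes (first axis %.1f%% of positive inertia)\n",
    nrow(x$coordinates), ncol(x$coordinates),
    if (length(x$proportion_explained) > 0L) 100 * x$proportion_explained[1L] else 0
  ))
  invisible(x)
}

.permtest_result <- function(method, statistic, R2, p_value, n_perm, seed) {
  structure(
    list(
      method = method, statistic = statistic, R2 = R2,
      p_value = p_value, n_perm = n_perm, seed = seed
    ),
    class = "fms_permtest"
  )
}

#' @export
print.fms_permtest <- function(x, ...) {
  cat(sprintf(
    "%s: statistic = %.4g%s, p = %.4g (%d permutations)\n",
    x$method, x$statistic,
    if (!is.na(x$R2)) sprintf(", R2 = %.4g", x$R2) else "",
    x$p_value, x$n_perm
  ))
  invisible(x)
}

# an (all-but-)zero distance matrix supports no test: report no structure
# rather than 0/0 statistics
.degenerate_dm <- function(dm) {
  max(dm) < 1e-12
}

#' PERMANOVA on a distance matrix
#'
#' Anderson's permutational multivariate ANOVA via [vegan::adonis2()]:
#' pseudo-F from among/within sums of squared distances,
#' `R2 = SS_among / SS_total`, and `p = (1 + #{F_perm >= F_obs}) /
#' (1 + n_perm)` under label permutation. A matrix with no distance
#' variation returns statistic 0 and p = 1.
#'
#' @param dm symmetric distance matrix.
#' @param groups group labels, one per sample (>= 2 non-empty groups).
#' @param n_perm number of permutations (default 999, the reference
#'   setting).
#' @param seed optional integer seed for the permutation RNG.
#' @return an `fms_permtest` with the pseudo-F statistic and `R2`.
#' @export
permanova_test <- function(dm, groups, n_perm = 999, seed = NULL) {
  groups <- .check_test_inputs(dm, groups, n_perm)
  if (.degenerate_dm(dm)) {
    return(.permtest_result("PERMANOVA", 0, 0, 1, n_perm, seed))
  }
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(groups = groups)
  res <- vegan::adonis2(stats::as.dist(dm) ~ groups, data = df, permutations = n_perm)
  .permtest_result("PERMANOVA", res$F[1L], res$R2[1L], res$`Pr(>F)`[1L], n_perm, seed)
}

#' ANOSIM on a distance matrix
#'
#' Clarke's R from rank dissimilarities via [vegan::anosim()], with the same
#' permutation p-value convention as [permanova_test()]. `R` lies in
#' `[-1, 1]`; 0 means no separation.
#'
#' @inheritParams permanova_test
#' @return an `fms_permtest` with Clarke's R as the statistic (`R2` is
#'   `NA`).
#' @export
anosim_test <- function(dm, groups, n_perm = 999, seed = NULL) {
  groups <- .check_test_inputs(dm, groups, n_perm)
  if (.degenerate_dm(dm)) {
    return(.permtest_result("ANOSIM", 0, NA_real_, 1, n_perm, seed))
  }
  if (!is.null(seed)) set.seed(seed)
  res <- vegan::anosim(stats::as.dist(dm), groups, permutations = n_perm)
  .permtest_result("ANOSIM", res$statistic, NA_real_, res$signif, n_perm, seed)
}

#' Multivariate dispersion homogeneity test (PERMDISP)
#'
#' [vegan::betadisper()] embeds the samples by PCoA, measures each sample's
#' distance to its group centroid, and [vegan::permutest()] applies a
#' permutation F-test to those distances.
#'
#' @inheritParams permanova_test
#' @param bias_adjust apply the small-sample bias adjustment to the
#'   distances to centroids (default `TRUE`); without it the test is
#'   noticeably conservative for groups of ten or so samples.
#' @return an `fms_permtest` with the dispersion F statistic (`R2` is
#'   `NA`).
#' @export
dispersion_test <- function(dm, groups, n_perm = 999, seed = NULL, bias_adjust = TRUE) {
  groups <- .check_test_inputs(dm, groups, n_perm)
  if (.degenerate_dm(dm)) {
    return(.permtest_result("PERMDISP", 0, NA_real_, 1, n_perm, seed))
  }
  if (!is.null(seed)) set.seed(seed)
  bd <- vegan::betadisper(stats::as.dist(dm), groups, bias.adjust = bias_adjust)
  res <- vegan::permutest(bd, permutations = n_perm)
  tab <- res$tab
  .permtest_result("PERMDISP", tab$F[1L], NA_real_, tab$`Pr(>F)`[1L], n_perm, seed)
}

.check_test_inputs <- function(dm, groups, n_perm) {
  validate_distance_matrix(dm)
  groups <- factor(groups)
  if (length(groups) != nrow(dm)) fms_validation_stop("one group label per sample required")
  if (nlevels(groups) < 2L) fms_validation_stop("at least two groups required")
  if (any(table(groups) == 0L)) fms_validation_stop("empty group")
  if (n_perm < 1L) fms_validation_stop("n_perm must be at least 1")
  groups
}

#' Leave-one-out KNN positive-class scores from a distance matrix
#'
#' For each sample, the `k` nearest other samples vote; the score is the
#' fraction of votes for the positive class. Ties at the k-th distance are
#' broken by sample order (matrix column order), making the scores fully
#' deterministic.
#'
#' @param dm symmetric distance matrix.
#' @param labels group labels, one per sample.
#' @param k neighborhood size, `0 < k < n - 1`; default 3.
#' @param positive the label counted as positive; default the last factor
#'   level.
#' @return named numeric vector of per-sample scores in `[0, 1]`.
#' @export
knn_loo_scores <- function(dm, labels, k = 3L, positive = NULL) {
  dm <- validate_distance_matrix(dm)
  labels <- factor(labels)
  n <- nrow(dm)
  if (length(labels) != n) fms_validation_stop("one label per sample required")
  if (k <= 0L) fms_validation_stop("k must be positive")
  if (k >= n - 1L && n > 2L) k <- n - 1L
  positive <- positive %||% levels(labels)[nlevels(labels)]
  if (!positive %in% levels(labels)) fms_validation_stop("'positive' is not a label level")
  scores <- vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(dm[i, others], others)] # tie-break: sample order
    nb <- ord[seq_len(min(k, length(ord)))]
    mean(labels[nb] == positive)
  }, numeric(1L))
  stats::setNames(scores, colnames(dm))
}

#' ROC curve and AUC for positive-class scores
#'
#' AUC by the Mann-Whitney identity (tied scores get half credit), with the
#' full ROC coordinates, via the pROC package.
#'
#' @param scores numeric classifier scores, higher = more positive.
#' @param labels binary labels, one per score.
#' @param positive the positive label; default the last factor level.
#' @return object of class `fms_roc`: list with `auc`, `thresholds`, `tpr`,
#'   `fpr`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) fms_validation_stop("ROC requires exactly two label levels")
  if (length(scores) != length(labels)) fms_validation_stop("one score per label required")
  positive <- positive %||% levels(labels)[2L]
  negative <- setdiff(levels(labels), positive)
  r <- pROC::roc(
    response = labels, predictor = as.numeric(scores),
    levels = c(negative, positive), direction = "<", quiet = TRUE
  )
  structure(
    list(
      auc = as.numeric(r$auc),
      thresholds = r$thresholds,
      tpr = r$sensitivities,
      fpr = 1 - r$specificities
    ),
    class = "fms_roc"
  )
}

#' @export
print.fms_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d threshold(s))\n", x$auc, length(x$thresholds)))
  invisible(x)
}
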