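# Exact-marker selection by rank tests between sample groups.

#' Select exact markers by rank tests
#'
#' Runs a per-feature two-sided Wilcoxon rank-sum test (two groups) or
#' Kruskal-Wallis test (three or more groups) on relative abundances and
#' keeps features with p strictly below `alpha`. No multiple-testing
#' correction is applied by default, matching the reference procedure;
#' `adjust = "BH"` enables Benjamini-Hochberg for users who want it.
#' Features that are zero in every sample are skipped, not tested.
#'
#' @param table feature table matrix (features x samples, columns
#'   normalized), e.g. from [read_feature_table()].
#' @param groups factor (or coercible) of group labels, one per sample in
#'   column order; at least 2 groups with at least 2 samples each.
#' @param alpha significance cutoff in (0, 1); default 0.01.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return an object of class `fms_markers`: list with `exact` (selected
#'   feature IDs), `p_values` (named, all tested features), `alpha`, `test`.
#' @examples
#' tab <- rbind(
#'   m1 = c(5, 6, 7, 8, 1, 1, 2, 1),
#'   bg = c(5, 5, 5, 5, 5, 5, 5, 5)
#' )
#' colnames(tab) <- paste0("s", 1:8)
#' tab <- validate_feature_table(tab)
#' g <- rep(c("A", "B"), each = 4)
#' select_exact_markers(tab, g, alpha = 0.05)
#' @export
select_exact_markers <- function(table, groups, alpha = 0.01, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  if (length(groups) != ncol(table)) {
    fms_validation_stop("one group label per sample required")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    fms_validation_stop("alpha must lie in (0, 1)")
  }
  sizes <- table(groups)
  if (nlevels(groups) < 2L) fms_validation_stop("at least two groups required")
  if (any(sizes < 2L)) {
    fms_validation_stop(paste0(
      "group(s) with fewer than 2 samples: ",
      paste(names(sizes)[sizes < 2L], collapse = ", ")
    ))
  }
  tested <- rownames(table)[rowSums(table) > 0]
  two <- nlevels(groups) == 2L
  pv <- vapply(tested, function(f) {
    x <- table[f, ]
    if (two) {
      suppressWarnings(stats::wilcox.test(x ~ groups)$p.value)
    } else {
      stats::kruskal.test(x ~ groups)$p.value
    }
  }, numeric(1L))
  pv[is.na(pv)] <- 1 # constant features give undefined tests: never selected
  padj <- if (adjust == "BH") stats::p.adjust(pv, "BH") else pv
  structure(
    list(
      exact = sort(names(padj)[padj < alpha]),
      p_values = pv,
      alpha = alpha,
      test = if (two) "wilcoxon" else "kruskal"
    ),
    class = "fms_markers"
  )
}

#' @export
print.fms_markers <- function(x, ...) {
  if (identical(x$test, "manual")) {
    cat(sprintf("Marker set: %d user-assigned exact marker(s)\n", length(x$exact)))
  } else {
    cat(sprintf(
      "Marker set: %d exact marker(s) of %d tested (%s test, p < %g)\n",
      length(x$exact), length(x$p_values), x$test, x$alpha
    ))
  }
  invisible(x)
}
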