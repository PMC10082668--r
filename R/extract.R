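# Flexible extraction: recruit approximate markers from the neighbor index,
# weight their abundances by similarity to the nearest exact marker, and
# assemble the target member set T.

#' Build the target member set T
#'
#' T is the union of the exact markers (weight 1) and every approximate
#' neighbor of an exact marker (weight = the maximal sequence similarity over
#' all exact markers listing it -- the similarity to the nearest exact
#' marker). A feature that is both an exact marker and a neighbor of another
#' exact marker keeps weight 1: its own abundance is already evidence.
#'
#' @param markers an `fms_markers` object ([select_exact_markers()],
#'   [load_marker_list()]) or a character vector of exact marker IDs.
#' @param index an `fms_index` object, or `NULL` for the exact-markers-only
#'   baseline (T = exact markers).
#' @return object of class `fms_target_set`: data.frame with columns
#'   `feature`, `weight`, `provenance` (`"exact"` or `"approximate"`),
#'   ordered exact-first then by feature ID.
#' @examples
#' idx <- new_neighbor_index(0.9, 0.11,
#'   data.frame(feature = "m1", neighbor = "a1", similarity = 0.95))
#' build_target_set("m1", idx)
#' @export
build_target_set <- function(markers, index = NULL) {
  exact <- if (inherits(markers, "fms_markers")) markers$exact else as.character(markers)
  if (length(exact) == 0L) fms_validation_stop("empty exact-marker set")
  exact <- sort(unique(exact))
  approx <- data.frame(feature = character(), weight = numeric())
  if (!is.null(index)) {
    nb <- index$neighbors[index$neighbors$feature %in% exact, , drop = FALSE]
    nb <- nb[!(nb$neighbor %in% exact), , drop = FALSE]
    if (nrow(nb) > 0L) {
      w <- tapply(nb$similarity, nb$neighbor, max)
      approx <- data.frame(feature = names(w), weight = as.numeric(w))
    }
  }
  out <- rbind(
    data.frame(feature = exact, weight = 1, provenance = "exact",
               stringsAsFactors = FALSE),
    if (nrow(approx) > 0L) {
      data.frame(feature = approx$feature, weight = approx$weight,
                 provenance = "approximate", stringsAsFactors = FALSE)
    }
  )
  out <- out[order(out$provenance != "exact", out$feature), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("fms_target_set", "data.frame"))
}

#' @export
print.fms_target_set <- function(x, ...) {
  cat(sprintf(
    "Target member set: %d exact + %d approximate marker(s)\n",
    sum(x$provenance == "exact"), sum(x$provenance == "approximate")
  ))
  invisible(x)
}

#' Weighted abundance vector of one sample over T
#'
#' For each member j of T present in the sample, the weighted abundance is
#' `weight(j) * Abd_j`; members absent from the sample contribute 0.
#'
#' @param sample named numeric vector of relative abundances (one feature
#'   table column) or a one-column slice of the table.
#' @param target an `fms_target_set`.
#' @return named numeric vector over the members of T.
#' @export
extract_weighted_vector <- function(sample, target) {
  v <- stats::setNames(numeric(nrow(target)), target$feature)
  present <- intersect(target$feature, names(sample))
  v[present] <- target$weight[match(present, target$feature)] * sample[present]
  v
}

# weighted abundance matrix over T for every sample (members x samples)
target_weight_matrix <- function(table, target) {
  missing <- setdiff(target$feature, rownames(table))
  w <- matrix(0, nrow(target), ncol(table),
              dimnames = list(target$feature, colnames(table)))
  present <- setdiff(target$feature, missing)
  w[present, ] <- table[present, , drop = FALSE] *
    target$weight[match(present, target$feature)]
  w
}

#' Write the target member set as an audit TSV
#'
#' @param target an `fms_target_set`.
#' @param path file path.
#' @export
write_target_set <- function(target, path) {
  lines <- c(
    paste(c("feature", "provenance", "weight"), collapse = "\t"),
    sprintf("%s\t%s\t%.6f", target$feature, target$provenance, target$weight)
  )
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
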