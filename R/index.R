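# Quantitative-relation index among features: phylogeny neighbors (sequence
# similarity + identical taxonomy), functional neighbors (hierarchical
# functional distance), approximate neighbors (their intersection), and the
# percentile rule that derives the thresholds t_s and d_f.

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment with match = 1, mismatch = 0, gap = 0
#' (i.e. the alignment maximizes the number of matched columns), reported as
#' identity = matches / alignment columns. Among all alignments achieving
#' the maximal match count, the one with the most aligned pairs (fewest
#' columns, `nchar(a) + nchar(b) - pairs`) defines the column count, making
#' the identity well-defined and symmetric without traceback conventions.
#'
#' @param seq_a,seq_b non-empty IUPAC DNA strings.
#' @return identity fraction in `[0, 1]`.
#' @examples
#' sequence_similarity("ACGT", "ACGT") # 1
#' sequence_similarity("ACGT", "ACGA") # 0.75
#' @export
sequence_similarity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) fms_validation_stop("empty sequence")
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  la <- length(a)
  lb <- length(b)
  # two-criterion DP: M = max matches; P = max aligned pairs given M
  M <- matrix(0L, la + 1L, lb + 1L)
  P <- matrix(0L, la + 1L, lb + 1L)
  P[1L, ] <- 0L
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      eq <- as.integer(a[i] == b[j])
      cand_m <- c(M[i, j] + eq, M[i, j + 1L], M[i + 1L, j])
      cand_p <- c(P[i, j] + 1L, P[i, j + 1L], P[i + 1L, j])
      best <- max(cand_m)
      M[i + 1L, j + 1L] <- best
      P[i + 1L, j + 1L] <- max(cand_p[cand_m == best])
    }
  }
  matches <- M[la + 1L, lb + 1L]
  columns <- la + lb - P[la + 1L, lb + 1L]
  matches / columns
}

#' Phylogeny neighbors of a feature
#'
#' Neighbors are the features `j != i` whose sequence similarity to `i` is at
#' least `t_s` (inclusive) AND whose full taxonomy lineage string is
#' identical to `i`'s. Unannotated trailing ranks (e.g. `s__`) compare equal
#' only to equally blank ranks, because comparison is on the full string.
#'
#' @param i feature ID.
#' @param sims symmetric numeric matrix of pairwise sequence similarities
#'   with feature IDs as dimnames.
#' @param tax named character vector, feature ID -> lineage string; must
#'   cover every candidate.
#' @param t_s similarity threshold in `[0, 1]` (default the reference value
#'   0.92).
#' @return sorted character vector of neighbor IDs.
#' @export
phylogeny_neighbors <- function(i, sims, tax, t_s = 0.92) {
  cand <- setdiff(colnames(sims), i)
  missing <- setdiff(c(i, cand), names(tax))
  if (length(missing) > 0L) {
    fms_stop(paste0("features missing from taxonomy: ", paste(missing, collapse = ", ")))
  }
  keep <- cand[sims[i, cand] >= t_s & tax[cand] == tax[[i]]]
  sort(keep)
}

#' Hierarchical functional distance between two KO profiles
#'
#' A level-weighted Bray-Curtis dissimilarity over the KO hierarchy: each
#' profile is renormalized to sum 1, aggregated to every hierarchy level
#' (KO itself, level-2 category, level-1 category by default), and the
#' Bray-Curtis dissimilarities of the aggregated profiles are combined with
#' weights summing to 1. Result is symmetric, lies in `[0, 1]`, and is 0
#' exactly when the aggregated profiles agree at all levels.
#'
#' @param p_i,p_j named non-negative numeric vectors over one KO namespace.
#' @param hierarchy data.frame with columns `ko`, `level2`, `level1`
#'   ([read_ko_hierarchy()]). KOs absent from the hierarchy are assigned to
#'   an `"unclassified"` bucket per level, with a warning.
#' @param level_weights numeric weights for the (KO, level-2, level-1)
#'   aggregations; normalized to sum 1. Default equal weights.
#' @return dissimilarity in `[0, 1]`.
#' @export
functional_distance <- function(p_i, p_j, hierarchy, level_weights = c(1, 1, 1) / 3) {
  if (length(level_weights) != 3L || any(level_weights < 0) || sum(level_weights) == 0) {
    fms_validation_stop("level_weights must be 3 non-negative values with positive sum")
  }
  w <- level_weights / sum(level_weights)
  kos <- union(names(p_i), names(p_j))
  if (is.null(kos)) fms_validation_stop("function profiles must be named by KO")
  x <- stats::setNames(numeric(length(kos)), kos)
  y <- x
  x[names(p_i)] <- p_i
  y[names(p_j)] <- p_j
  if (sum(x) == 0 || sum(y) == 0) fms_validation_stop("zero-sum function profile")
  x <- x / sum(x)
  y <- y / sum(y)
  map2 <- stats::setNames(hierarchy$level2, hierarchy$ko)
  map1 <- stats::setNames(hierarchy$level1, hierarchy$ko)
  unknown <- setdiff(kos, hierarchy$ko)
  if (length(unknown) > 0L) {
    warning(sprintf("%d KO(s) absent from hierarchy assigned to 'unclassified'", length(unknown)))
  }
  lvl2 <- ifelse(kos %in% hierarchy$ko, map2[kos], "unclassified")
  lvl1 <- ifelse(kos %in% hierarchy$ko, map1[kos], "unclassified")
  bc <- function(u, v) as.numeric(vegan::vegdist(rbind(u, v), method = "bray"))
  agg <- function(v, f) tapply(v, f, sum)
  d0 <- bc(x, y)
  d2 <- bc(agg(x, lvl2), agg(y, lvl2))
  d1 <- bc(agg(x, lvl1), agg(y, lvl1))
  as.numeric(w[1L] * d0 + w[2L] * d2 + w[3L] * d1)
}

#' Functional neighbors of a feature
#'
#' @param i feature ID.
#' @param fdists symmetric matrix of pairwise functional distances with
#'   feature IDs as dimnames.
#' @param d_f functional-distance threshold, inclusive (default the
#'   reference value 0.11).
#' @return sorted character vector of the `j != i` with distance `<= d_f`.
#' @export
functional_neighbors <- function(i, fdists, d_f = 0.11) {
  cand <- setdiff(colnames(fdists), i)
  sort(cand[fdists[i, cand] <= d_f])
}

#' Approximate neighbors: intersection of phylogeny and functional neighbors
#'
#' @param pn,fn character vectors of phylogeny / functional neighbor IDs of
#'   one feature.
#' @param sims named similarities (or the full similarity matrix plus `i`)
#'   used to attach each approximate neighbor's sequence similarity.
#' @param i the focal feature ID when `sims` is a matrix.
#' @return data.frame with columns `neighbor`, `similarity`, ordered by
#'   descending similarity then lexicographic ID.
#' @export
approximate_neighbors <- function(pn, fn, sims, i = NULL) {
  ids <- intersect(pn, fn)
  if (is.matrix(sims)) {
    if (is.null(i)) fms_validation_stop("focal feature 'i' required with a similarity matrix")
    s <- sims[i, ids]
  } else {
    s <- sims[ids]
  }
  out <- data.frame(neighbor = ids, similarity = unname(s), stringsAsFactors = FALSE)
  out[order(-out$similarity, out$neighbor), , drop = FALSE]
}

#' Derive similarity / functional-distance thresholds from pooled values
#'
#' Mirrors the reference-database rule: `t_s` is the similarity with exactly
#' the top `q` percent of pairs at or above it (nearest-rank convention:
#' the `floor(q/100 * n)`-th largest value), and `d_f` is the mirrored rule
#' on functional distances (the `floor(q/100 * n)`-th smallest). With fewer
#' than `100/q` values the rule degenerates and the maximum similarity /
#' minimum distance is returned with a warning.
#'
#' @param all_sims numeric vector of pairwise sequence similarities.
#' @param all_fdists numeric vector of pairwise functional distances.
#' @param q percentile in percent (default 0.1, the top-0.1\% rule).
#' @return list with elements `t_s` and `d_f`.
#' @export
derive_thresholds <- function(all_sims, all_fdists, q = 0.1) {
  top_k <- function(x, decreasing) {
    n <- length(x)
    if (n == 0L) fms_validation_stop("empty value list")
    k <- floor(q / 100 * n)
    if (k < 1L) {
      warning(sprintf("fewer than %d values for the %g%% rule; using extreme value", ceiling(100 / q), q))
      k <- 1L
    }
    sort(x, decreasing = decreasing)[k]
  }
  list(t_s = top_k(all_sims, TRUE), d_f = top_k(all_fdists, FALSE))
}

#' Build a neighbor index from sequences, taxonomy and function profiles
#'
#' All-vs-all computation of sequence similarities and hierarchical
#' functional distances, threshold derivation (unless thresholds are given),
#' and assembly of each feature's approximate-neighbor list
#' (phylogeny neighbors intersected with functional neighbors, carrying the
#' sequence similarity).
#'
#' @param seqs named character vector of DNA sequences
#'   ([read_fasta_sequences()]).
#' @param tax taxonomy lineage map ([read_taxonomy()]).
#' @param profiles function-profile matrix ([read_function_profiles()]).
#' @param hierarchy KO hierarchy ([read_ko_hierarchy()]).
#' @param t_s,d_f optional fixed thresholds; when `NULL` both are derived
#'   from the pooled pairwise values via [derive_thresholds()].
#' @param q percentile (percent) for threshold derivation.
#' @param level_weights passed to [functional_distance()].
#' @return an `fms_index` object: list with `t_s`, `d_f` and `neighbors`, a
#'   data.frame of (`feature`, `neighbor`, `similarity`) rows.
#' @export
build_neighbor_index <- function(seqs, tax, profiles, hierarchy,
                                 t_s = NULL, d_f = NULL, q = 0.1,
                                 level_weights = c(1, 1, 1) / 3) {
  ids <- names(seqs)
  if (!all(ids %in% names(tax))) fms_stop("taxonomy must cover every sequence")
  if (!all(ids %in% rownames(profiles))) fms_stop("function profiles must cover every sequence")
  n <- length(ids)
  sims <- matrix(1, n, n, dimnames = list(ids, ids))
  fd <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n - 1L)) {
    for (b in seq(a + 1L, n)) {
      s <- sequence_similarity(seqs[[a]], seqs[[b]])
      d <- functional_distance(profiles[ids[a], ], profiles[ids[b], ], hierarchy, level_weights)
      sims[a, b] <- sims[b, a] <- s
      fd[a, b] <- fd[b, a] <- d
    }
  }
  ut <- upper.tri(sims)
  if (is.null(t_s) || is.null(d_f)) {
    thr <- derive_thresholds(sims[ut], fd[ut], q = q)
    t_s <- t_s %||% thr$t_s
    d_f <- d_f %||% thr$d_f
  }
  rows <- lapply(ids, function(i) {
    pn <- phylogeny_neighbors(i, sims, tax, t_s)
    fn <- functional_neighbors(i, fd, d_f)
    an <- approximate_neighbors(pn, fn, sims, i)
    if (nrow(an) == 0L) return(NULL)
    data.frame(feature = i, neighbor = an$neighbor, similarity = an$similarity,
               stringsAsFactors = FALSE)
  })
  neighbors <- do.call(rbind, rows) %||%
    data.frame(feature = character(), neighbor = character(), similarity = numeric())
  rownames(neighbors) <- NULL
  new_neighbor_index(t_s, d_f, neighbors)
}

#' Construct a neighbor index object
#'
#' @param t_s,d_f thresholds in `[0, 1]`.
#' @param neighbors data.frame with columns `feature`, `neighbor`,
#'   `similarity`; every stored similarity must be `>= t_s` and no feature
#'   may list itself.
#' @return an object of class `fms_index`.
#' @export
new_neighbor_index <- function(t_s, d_f, neighbors) {
  need <- c("feature", "neighbor", "similarity")
  if (!all(need %in% colnames(neighbors))) {
    fms_validation_stop("neighbors needs columns feature, neighbor, similarity")
  }
  neighbors <- neighbors[need]
  if (any(neighbors$feature == neighbors$neighbor)) {
    fms_validation_stop("a feature may not be its own approximate neighbor")
  }
  if (any(neighbors$similarity < t_s - 1e-12)) {
    fms_validation_stop("stored similarity below t_s")
  }
  if (any(neighbors$similarity > 1 + 1e-12) || t_s < 0 || t_s > 1 || d_f < 0 || d_f > 1) {
    fms_validation_stop("similarities and thresholds must lie in [0, 1]")
  }
  o <- order(neighbors$feature, -neighbors$similarity, neighbors$neighbor)
  neighbors <- neighbors[o, , drop = FALSE]
  rownames(neighbors) <- NULL
  structure(list(t_s = t_s, d_f = d_f, neighbors = neighbors), class = "fms_index")
}

#' @export
print.fms_index <- function(x, ...) {
  cat(sprintf(
    "Neighbor index: %d relation(s) over %d feature(s); t_s = %g, d_f = %g\n",
    nrow(x$neighbors), length(unique(x$neighbors$feature)), x$t_s, x$d_f
  ))
  invisible(x)
}

#' Write / read a neighbor index file
#'
#' Plain TSV with `#t_s=` / `#d_f=` comment header lines followed by
#' (`feature`, `neighbor`, `similarity`) rows.
#'
#' @param index an `fms_index` object.
#' @param path file path.
#' @export
write_neighbor_index <- function(index, path) {
  lines <- c(
    sprintf("#t_s=%.6f", index$t_s),
    sprintf("#d_f=%.6f", index$d_f),
    paste(c("feature", "neighbor", "similarity"), collapse = "\t"),
    sprintf("%s\t%s\t%.6f", index$neighbors$feature, index$neighbors$neighbor,
            index$neighbors$similarity)
  )
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' @rdname write_neighbor_index
#' @export
read_neighbor_index <- function(path) {
  raw <- readLines(path, warn = FALSE)
  grab <- function(tag) {
    ln <- grep(paste0("^#", tag, "="), raw, value = TRUE)
    if (length(ln) != 1L) fms_validation_stop(sprintf("index file must carry one #%s= line", tag))
    as.numeric(sub(paste0("^#", tag, "="), "", ln))
  }
  t_s <- grab("t_s")
  d_f <- grab("d_f")
  body <- raw[!startsWith(raw, "#")]
  if (length(body) < 1L) fms_validation_stop("index file has no header row")
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  new_neighbor_index(t_s, d_f, df)
}

# neighbor rows of one feature, ordered by descending similarity then ID
index_neighbors_of <- function(index, feature) {
  index$neighbors[index$neighbors$feature == feature, , drop = FALSE]
}
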