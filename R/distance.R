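# Consistency-score phylogenetic distance.
#
# Two samples are compared by matching abundance mass bottom-up over a rooted
# tree: at each leaf the shared mass min(S1, S2) is matched outright; the
# surplus of either sample survives as a residual, climbs the tree attenuated
# by max(0, 1 - branch length) per edge, and is matched against
# opposite-sample surpluses met at internal nodes. The matched mass
# accumulated at the root is the consistency score Con(root); on per-sample
# renormalized input the local distance is 1 - Con(root).

#' Leaf-level consistency of one species in two samples
#'
#' @param a1,a2 non-negative relative abundances of the species in samples
#'   1 and 2.
#' @return list with `con` (matched mass `min(a1, a2)`), `r1` (sample-1
#'   surplus) and `r2` (sample-2 surplus); at most one residual is positive.
#' @examples
#' leaf_consistency(0.3, 0.2) # con 0.2, r1 0.1, r2 0
#' @export
leaf_consistency <- function(a1, a2) {
  if (any(c(a1, a2) < 0)) fms_validation_stop("negative abundance")
  list(con = min(a1, a2), r1 = max(a1 - a2, 0), r2 = max(a2 - a1, 0))
}

#' Combine child consistency states at an internal node
#'
#' Each child's residuals are attenuated by `max(0, 1 - d)` where `d` is the
#' child's branch length to this node, pooled across children by direction,
#' and opposite-direction surpluses are matched:
#' `extra = min(pooled attenuated r1, pooled attenuated r2)`. The node's
#' consistency is the sum of the child consistencies plus `extra`; surviving
#' residuals propagate upward. Pooling the children is equivalent to
#' combining them pairwise left-to-right through zero-length internal edges,
#' so multifurcations need no special casing.
#'
#' @param child_states list of states as returned by [leaf_consistency()] or
#'   this function.
#' @param branch_lengths numeric vector of the children's branch lengths.
#' @return a combined state (`con`, `r1`, `r2`).
#' @examples
#' s1 <- leaf_consistency(0.1, 0) # r1 surplus
#' s2 <- leaf_consistency(0, 0.08) # r2 surplus
#' combine_children(list(s1, s2), c(0.1, 0.1)) # extra = min(0.09, 0.072)
#' @export
combine_children <- function(child_states, branch_lengths) {
  if (length(child_states) < 2L) fms_validation_stop("at least two children required")
  if (length(branch_lengths) != length(child_states)) {
    fms_validation_stop("one branch length per child required")
  }
  if (any(branch_lengths < 0)) fms_validation_stop("negative branch length")
  f <- pmax(0, 1 - branch_lengths)
  p1 <- sum(f * vapply(child_states, `[[`, numeric(1L), "r1"))
  p2 <- sum(f * vapply(child_states, `[[`, numeric(1L), "r2"))
  extra <- min(p1, p2)
  con <- sum(vapply(child_states, `[[`, numeric(1L), "con")) + extra
  r1 <- p1 - extra
  r2 <- p2 - extra
  if (r1 < 1e-12) r1 <- 0
  if (r2 < 1e-12) r2 <- 0
  list(con = con, r1 = r1, r2 = r2)
}

# Vectorized post-order consistency recursion.
# A, B: (tips x P) matrices of paired abundance profiles, rows in
# tree$tip.label order; returns the root consistency per pair.
.consistency_engine <- function(tree, A, B, flush = 1e-12) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  P <- ncol(A)
  ntot <- nt + nn
  conf <- matrix(0, ntot, P)
  r1f <- matrix(0, ntot, P)
  r2f <- matrix(0, ntot, P)
  conf[seq_len(nt), ] <- pmin(A, B)
  dd <- A - B
  r1f[seq_len(nt), ] <- pmax(dd, 0)
  r2f[seq_len(nt), ] <- pmax(-dd, 0)
  pool1 <- matrix(0, ntot, P)
  pool2 <- matrix(0, ntot, P)
  conacc <- matrix(0, ntot, P)
  tr <- stats::reorder(tree, "postorder")
  E <- tr$edge
  len <- tr$edge.length
  if (is.null(len)) len <- rep(0, nrow(E))
  done <- logical(ntot)
  for (e in seq_len(nrow(E))) {
    par <- E[e, 1L]
    ch <- E[e, 2L]
    if (ch > nt && !done[ch]) {
      extra <- pmin(pool1[ch, ], pool2[ch, ])
      conf[ch, ] <- conacc[ch, ] + extra
      a <- pool1[ch, ] - extra
      b <- pool2[ch, ] - extra
      a[a < flush] <- 0
      b[b < flush] <- 0
      r1f[ch, ] <- a
      r2f[ch, ] <- b
      done[ch] <- TRUE
    }
    f <- max(0, 1 - len[e])
    pool1[par, ] <- pool1[par, ] + f * r1f[ch, ]
    pool2[par, ] <- pool2[par, ] + f * r2f[ch, ]
    conacc[par, ] <- conacc[par, ] + conf[ch, ]
  }
  root <- E[nrow(E), 1L]
  extra <- pmin(pool1[root, ], pool2[root, ])
  con <- conacc[root, ] + extra
  con[con < flush] <- 0
  con
}

# place named abundance vectors on tree leaves; members must exist as leaves
.leaf_matrix <- function(tree, vectors, require_all = TRUE, context = "target member") {
  tips <- tree$tip.label
  out <- matrix(0, length(tips), length(vectors), dimnames = list(tips, NULL))
  dropped <- 0
  for (k in seq_along(vectors)) {
    v <- vectors[[k]]
    missing <- setdiff(names(v)[v > 0], tips)
    if (length(missing) > 0L) {
      if (require_all) {
        fms_stop(paste0(context, "(s) missing from tree: ", paste(missing, collapse = ", ")))
      }
      dropped <- dropped + sum(v[missing])
      v <- v[setdiff(names(v), missing)]
    }
    present <- intersect(names(v), tips)
    out[present, k] <- v[present]
  }
  if (dropped > 0) {
    message(sprintf("dropped %.4g total abundance on features absent from tree", dropped))
  }
  out
}

#' Tree-wide consistency score of two abundance vectors
#'
#' Runs the post-order recursion ([leaf_consistency()] at the tips,
#' [combine_children()] at internal nodes) and returns the consistency score
#' accumulated at the root, a value in `[0, min(sum(v1), sum(v2))]`. No
#' renormalization is applied here.
#'
#' @param v1,v2 named non-negative numeric vectors; names must be leaves of
#'   `tree` (members with positive abundance absent from the tree are an
#'   error). Leaves absent from a vector count as 0.
#' @param tree rooted [ape::phylo] tree with non-negative branch lengths.
#' @return the root consistency score.
#' @export
tree_consistency <- function(v1, v2, tree) {
  tree <- validate_tree(tree)
  if (any(v1 < 0) || any(v2 < 0)) fms_validation_stop("negative abundance")
  M <- .leaf_matrix(tree, list(v1, v2))
  .consistency_engine(tree, M[, 1L, drop = FALSE], M[, 2L, drop = FALSE])[1L]
}

# shared core: distances for arbitrary sample pairs over a weighted matrix.
# W: members x samples weighted abundances; pairs: 2 x P index matrix.
.pair_distances <- function(tree, W, pairs, context = "target member") {
  s <- colSums(W)
  zero <- s == 0
  if (any(zero)) {
    warning(sprintf(
      "%d sample(s) with zero abundance mass on the member set; distances involving them are 1",
      sum(zero)
    ))
  }
  Wn <- W
  Wn[, !zero] <- sweep(W[, !zero, drop = FALSE], 2L, s[!zero], "/")
  tips <- tree$tip.label
  missing <- setdiff(rownames(W)[rowSums(W) > 0], tips)
  if (length(missing) > 0L) {
    fms_stop(paste0(context, "(s) missing from tree: ", paste(missing, collapse = ", ")))
  }
  M <- matrix(0, length(tips), ncol(Wn), dimnames = list(tips, colnames(Wn)))
  common <- intersect(rownames(Wn), tips)
  M[common, ] <- Wn[common, , drop = FALSE]
  con <- .consistency_engine(tree, M[, pairs[1L, ], drop = FALSE], M[, pairs[2L, ], drop = FALSE])
  d <- 1 - con
  d[zero[pairs[1L, ]] & zero[pairs[2L, ]]] <- 1
  pmin(pmax(d, 0), 1)
}

#' Local-alignment (marker-restricted) distance between two samples
#'
#' The weighted abundance vectors of the two samples over the target member
#' set T are extracted, each renormalized to sum 1 over T, and compared by
#' the consistency recursion; the distance is `1 - Con(root)`, a value in
#' `[0, 1]`, symmetric, and 0 for identical restricted profiles. If both
#' samples carry zero mass on T the distance is defined as 1 (maximally
#' dissimilar on absent evidence) with a warning.
#'
#' @param s1,s2 sample IDs (columns of `table`).
#' @param target an `fms_target_set` from [build_target_set()].
#' @param tree rooted [ape::phylo]; every target member must be a leaf.
#' @param table normalized feature table (features x samples).
#' @return distance in `[0, 1]`.
#' @export
fms_distance <- function(s1, s2, target, tree, table) {
  tree <- validate_tree(tree)
  W <- target_weight_matrix(table[, c(s1, s2), drop = FALSE], target)
  suppressWarnings(d <- .pair_distances(tree, W, matrix(c(1L, 2L), 2L)))
  if (sum(W[, 1L]) == 0 && sum(W[, 2L]) == 0) {
    warning("both samples have zero abundance mass on T; distance defined as 1")
  }
  unname(d)
}

#' Whole-community (global) consistency distance between two samples
#'
#' [fms_distance()] with T = all features at weight 1. Features absent from
#' the tree are silently dropped (their total mass is reported via
#' `message()`).
#'
#' @inheritParams fms_distance
#' @return distance in `[0, 1]`.
#' @export
global_distance <- function(s1, s2, tree, table) {
  dm <- fms_distance_matrix(table[, c(s1, s2), drop = FALSE], tree, target = NULL)
  unname(dm[1L, 2L])
}

#' Pairwise distance matrix
#'
#' Computes all unordered sample pairs of a feature table under the
#' local-alignment distance (when `target` is given) or the global
#' whole-community distance (`target = NULL`). The recursion is vectorized
#' across pairs and fully deterministic: results are independent of
#' `threads`, which is accepted for interface compatibility only.
#'
#' @param table normalized feature table (features x samples), >= 2 samples.
#' @param tree rooted [ape::phylo].
#' @param target `fms_target_set` or `NULL` for global mode.
#' @param threads ignored; the computation is vectorized and deterministic.
#' @return symmetric distance matrix (samples x samples) with zero diagonal,
#'   entries in `[0, 1]`.
#' @export
fms_distance_matrix <- function(table, tree, target = NULL, threads = 1L) {
  tree <- validate_tree(tree)
  n <- ncol(table)
  if (n < 2L) fms_validation_stop("at least two samples required")
  if (is.null(target)) {
    # global mode: all features, weight 1; drop tree-absent features silently
    keep <- intersect(rownames(table), tree$tip.label)
    dropped <- sum(table[setdiff(rownames(table), keep), , drop = FALSE])
    if (dropped > 0) {
      message(sprintf("dropped %.4g total abundance on features absent from tree", dropped))
    }
    W <- table[keep, , drop = FALSE]
    context <- "feature"
  } else {
    W <- target_weight_matrix(table, target)
    context <- "target member"
  }
  pairs <- utils::combn(n, 2L)
  d <- .pair_distances(tree, W, pairs, context = context)
  dm <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  dm[t(pairs)] <- d
  dm[t(pairs)[, 2:1, drop = FALSE]] <- d
  dm
}
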