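# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the alignment oracle enumerates every monotone
# matching, and the consistency oracle is a direct recursive transcription
# of the node rule, unrelated to the package's vectorized engine.

# exhaustive global-alignment oracle: over ALL monotone matchings of the two
# strings, maximize (matches, aligned pairs) lexicographically; identity is
# matches / (la + lb - pairs). Feasible for strings up to ~8 characters.
oracle_alignment_identity <- function(sa, sb) {
  a <- strsplit(toupper(sa), "")[[1]]
  b <- strsplit(toupper(sb), "")[[1]]
  best <- c(matches = -1L, pairs = -1L)
  rec <- function(i, j, matches, pairs) {
    if (i > length(a) || j > length(b)) {
      if (matches > best[["matches"]] ||
        (matches == best[["matches"]] && pairs > best[["pairs"]])) {
        best <<- c(matches = matches, pairs = pairs)
      }
      return(invisible())
    }
    rec(i + 1L, j + 1L, matches + (a[i] == b[j]), pairs + 1L) # align
    rec(i + 1L, j, matches, pairs) # gap in b
    rec(i, j + 1L, matches, pairs) # gap in a
  }
  rec(1L, 1L, 0L, 0L)
  best[["matches"]] / (length(a) + length(b) - best[["pairs"]])
}

# straight-line recursive consistency oracle: leaf rule min/surplus, node
# rule "attenuate child residuals by clamp(1 - d), pool, match opposite
# surpluses, accumulate child consistencies".
oracle_tree_consistency <- function(tree, v1, v2) {
  nt <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node) {
    if (node <= nt) {
      lbl <- tree$tip.label[node]
      x <- if (lbl %in% names(v1)) unname(v1[[lbl]]) else 0
      y <- if (lbl %in% names(v2)) unname(v2[[lbl]]) else 0
      return(c(con = min(x, y), r1 = max(x - y, 0), r2 = max(y - x, 0)))
    }
    edges <- kids[[as.character(node)]]
    p1 <- p2 <- conacc <- 0
    for (e in edges) {
      st <- rec(tree$edge[e, 2])
      f <- max(0, 1 - tree$edge.length[e])
      p1 <- p1 + f * st[["r1"]]
      p2 <- p2 + f * st[["r2"]]
      conacc <- conacc + st[["con"]]
    }
    extra <- min(p1, p2)
    c(con = conacc + extra, r1 = p1 - extra, r2 = p2 - extra)
  }
  rec(nt + 1L)[["con"]]
}

# random abundance table over given feature IDs, columns normalized
random_table <- function(features, n_samples, prefix = "s") {
  m <- matrix(stats::rexp(length(features) * n_samples),
    length(features), n_samples,
    dimnames = list(features, paste0(prefix, seq_len(n_samples)))
  )
  validate_feature_table(m)
}

# random rooted tree with non-negative branch lengths on given tip labels
random_tree <- function(tips, max_len = 1.5) {
  tr <- ape::rtree(length(tips), tip.label = tips)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0, max_len)
  tr
}

fixture_path <- function(...) {
  system.file("extdata", "fig1_mini", ..., package = "flexms", mustWork = TRUE)
}
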