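test_that("alignment identity matches the exhaustive oracle", {
  expect_equal(sequence_similarity("ACGT", "ACGT"), 1)
  expect_equal(sequence_similarity("ACGT", "ACGA"), 0.75)
  expect_equal(sequence_similarity("ACGTACGT", "ACGACGT"), oracle_alignment_identity("ACGTACGT", "ACGACGT"))
  expect_equal(sequence_similarity("ACGTACGT", "ACGACGT"), 0.875)

  set.seed(7)
  for (i in 1:25) {
    sa <- paste(sample(c("A", "C", "G", "T"), sample(2:6, 1), replace = TRUE), collapse = "")
    sb <- paste(sample(c("A", "C", "G", "T"), sample(2:6, 1), replace = TRUE), collapse = "")
    expect_equal(sequence_similarity(sa, sb), oracle_alignment_identity(sa, sb),
      info = paste(sa, sb)
    )
    expect_equal(sequence_similarity(sa, sb), sequence_similarity(sb, sa))
  }
  expect_error(sequence_similarity("", "ACG"), "empty")
})

test_that("phylogeny neighbors require both similarity >= t_s and identical lineage", {
  ids <- c("i", "j", "k", "l")
  sims <- matrix(1, 4, 4, dimnames = list(ids, ids))
  sims["i", "j"] <- sims["j", "i"] <- 0.95
  sims["i", "k"] <- sims["k", "i"] <- 0.92 # boundary: inclusive
  sims["i", "l"] <- sims["l", "i"] <- 0.91
  tax <- c(
    i = "k__B;p__P;g__G;s__", j = "k__B;p__P;g__G;s__",
    k = "k__B;p__P;g__G;s__", l = "k__B;p__P;g__G;s__"
  )
  expect_equal(phylogeny_neighbors("i", sims, tax, t_s = 0.92), c("j", "k"))
  tax["j"] <- "k__B;p__P;g__OTHER;s__" # lineage differs at genus
  expect_equal(phylogeny_neighbors("i", sims, tax, t_s = 0.92), "k")
  expect_error(phylogeny_neighbors("i", sims, tax[-4], t_s = 0.92), "l")
})

test_that("hierarchical functional distance behaves as a level-weighted Bray-Curtis", {
  hier <- data.frame(
    ko = c("k1", "k2", "k3", "k4"),
    level2 = c("c1", "c1", "c2", "c3"),
    level1 = c("m1", "m1", "m1", "m2")
  )
  p <- c(k1 = 2, k2 = 1, k3 = 1)
  expect_equal(functional_distance(p, p, hier), 0)

  # disjoint supports mapping to disjoint categories at every level
  expect_equal(functional_distance(c(k3 = 1), c(k4 = 2), hier), 1)

  # hand-computed per-level Bray-Curtis: profiles share the level-2 parent c1
  # x = (k1 .5, k2 .5), y = (k1 .25, k2 .25, k3 .5)
  # KO level: BC = 1 - 2*min_sum = 1 - 2*(.25+.25)/2 = 0.5
  # level2: x = (c1 1), y = (c1 .5, c2 .5) -> BC = 0.5
  # level1: both all m1 -> 0
  x <- c(k1 = 1, k2 = 1)
  y <- c(k1 = 1, k2 = 1, k3 = 2)
  expect_equal(functional_distance(x, y, hier), (0.5 + 0.5 + 0) / 3)

  # symmetry and range on random profiles
  set.seed(3)
  for (i in 1:10) {
    a <- stats::setNames(rexp(4), hier$ko)
    b <- stats::setNames(rexp(4), hier$ko)
    d1 <- functional_distance(a, b, hier)
    expect_equal(d1, functional_distance(b, a, hier))
    expect_gte(d1, 0)
    expect_lte(d1, 1)
  }
  expect_warning(functional_distance(c(zz = 1), c(k1 = 1), hier), "unclassified")
  expect_error(functional_distance(c(k1 = 0), c(k1 = 1), hier), "zero-sum")
})

test_that("functional neighbors use an inclusive distance threshold", {
  ids <- c("i", "a", "b", "c")
  fd <- matrix(0, 4, 4, dimnames = list(ids, ids))
  fd["i", "a"] <- fd["a", "i"] <- 0.05
  fd["i", "b"] <- fd["b", "i"] <- 0.11 # boundary: inclusive
  fd["i", "c"] <- fd["c", "i"] <- 0.5
  expect_equal(functional_neighbors("i", fd, d_f = 0.11), c("a", "b"))
})

test_that("approximate neighbors are the PN/FN intersection, similarity-ordered", {
  sims <- c(a = 0.93, b = 0.97, c = 0.95)
  an <- approximate_neighbors(c("a", "b"), c("b", "c"), sims)
  expect_equal(an$neighbor, "b")
  expect_equal(an$similarity, 0.97)
  expect_equal(nrow(approximate_neighbors(character(), c("b", "c"), sims)), 0L)
  an2 <- approximate_neighbors(c("a", "b"), c("a", "b"), sims)
  expect_equal(an2$neighbor, c("b", "a")) # descending similarity
})

test_that("threshold derivation follows the nearest-rank top-q% rule", {
  sims <- seq_len(1000) / 1000 # 1000 equally spaced values in (0, 1]
  fd <- seq_len(1000) / 1000
  thr <- derive_thresholds(sims, fd, q = 0.1)
  expect_equal(thr$t_s, 1) # top 0.1% of 1000 values = the single largest
  expect_equal(thr$d_f, 0.001) # mirrored: the single smallest distance
  thr2 <- derive_thresholds(rep(0.9, 2000), rep(0.2, 2000), q = 0.1)
  expect_equal(thr2$t_s, 0.9)
  expect_warning(
    expect_warning(thr3 <- derive_thresholds(c(0.5, 0.7), c(0.1, 0.2), q = 0.1), "fewer"),
    "fewer" # both the similarity and the distance list fall back
  )
  expect_equal(thr3$t_s, 0.7)
})

test_that("index construction ties the operators together and round-trips", {
  seqs <- c(
    m1 = "ACGTACGTACGTACGTACGT",
    a1 = "ACGTACGTACGTACGTACGA", # 1 mismatch: sim 0.95
    b1 = "TTTTTTTTTTGGGGGGGGGG"
  )
  tax <- c(
    m1 = "k__B;g__X;s__", a1 = "k__B;g__X;s__", b1 = "k__B;g__Y;s__"
  )
  hier <- data.frame(ko = c("k1", "k2"), level2 = c("c1", "c2"), level1 = c("m", "m"))
  prof <- rbind(m1 = c(1, 1), a1 = c(1.02, 1), b1 = c(5, 0))
  colnames(prof) <- hier$ko
  idx <- build_neighbor_index(seqs, tax, prof, hier, t_s = 0.92, d_f = 0.11)
  expect_s3_class(idx, "fms_index")
  expect_equal(idx$neighbors$feature, c("a1", "m1"))
  expect_equal(idx$neighbors$neighbor, c("m1", "a1"))
  expect_equal(idx$neighbors$similarity, c(0.95, 0.95))

  tf <- withr::local_tempfile(fileext = ".tsv")
  write_neighbor_index(idx, tf)
  back <- read_neighbor_index(tf)
  expect_equal(back$t_s, idx$t_s, tolerance = 1e-6)
  expect_equal(back$neighbors, idx$neighbors, tolerance = 1e-6)
})

test_that("tightening thresholds never enlarges a neighbor set", {
  set.seed(21)
  ids <- paste0("f", 1:8)
  s <- matrix(runif(64, 0.85, 1), 8, 8, dimnames = list(ids, ids))
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  diag(s) <- 1
  fd <- matrix(runif(64, 0, 0.3), 8, 8, dimnames = list(ids, ids))
  fd[lower.tri(fd)] <- t(fd)[lower.tri(fd)]
  diag(fd) <- 0
  tax <- stats::setNames(rep("k__B;s__", 8), ids)
  for (i in ids) {
    pn_loose <- phylogeny_neighbors(i, s, tax, 0.9)
    pn_tight <- phylogeny_neighbors(i, s, tax, 0.95)
    fn_loose <- functional_neighbors(i, fd, 0.2)
    fn_tight <- functional_neighbors(i, fd, 0.1)
    expect_true(all(pn_tight %in% pn_loose))
    expect_true(all(fn_tight %in% fn_loose))
    an_loose <- approximate_neighbors(pn_loose, fn_loose, s, i)$neighbor
    an_tight <- approximate_neighbors(pn_tight, fn_tight, s, i)$neighbor
    expect_true(all(an_tight %in% an_loose))
    # AN is contained in both parents
    expect_true(all(an_loose %in% pn_loose) && all(an_loose %in% fn_loose))
  }
})
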