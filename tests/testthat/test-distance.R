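test_that("leaf consistency matches shared mass and routes the surplus", {
  expect_equal(leaf_consistency(0.3, 0.2), list(con = 0.2, r1 = 0.1, r2 = 0))
  expect_equal(leaf_consistency(0, 0.4), list(con = 0, r1 = 0, r2 = 0.4))
  expect_equal(leaf_consistency(0.25, 0.25), list(con = 0.25, r1 = 0, r2 = 0))
  expect_error(leaf_consistency(-0.1, 0.2), "negative")
})

test_that("child combination attenuates residuals and matches opposite surpluses", {
  s1 <- leaf_consistency(0.1, 0)
  s2 <- leaf_consistency(0, 0.08)
  st <- combine_children(list(s1, s2), c(0.1, 0.1))
  expect_equal(st$con, min(0.9 * 0.1, 0.9 * 0.08)) # 0.072
  expect_equal(st$r1, 0.9 * 0.1 - 0.072)
  expect_equal(st$r2, 0)

  # same-direction surpluses: nothing to match, residuals pool
  st2 <- combine_children(list(leaf_consistency(0.1, 0), leaf_consistency(0.2, 0)), c(0, 0))
  expect_equal(st2$con, 0)
  expect_equal(st2$r1, 0.3)

  # branch length >= 1 clamps the attenuation factor to 0
  st3 <- combine_children(list(s1, s2), c(1.5, 0.1))
  expect_equal(st3$con, 0)
  expect_equal(st3$r2, 0.9 * 0.08)
  expect_error(combine_children(list(s1, s2), c(-0.1, 0)), "negative")
})

test_that("tree consistency reproduces hand-derived cherry values", {
  tr <- ape::read.tree(text = "(A:0.25,B:0.25);")
  expect_equal(tree_consistency(c(A = 0.3), c(B = 0.2), tr), min(0.3 * 0.75, 0.2 * 0.75))
  # identical vectors: the full mass matches at the leaves
  v <- c(A = 0.6, B = 0.4)
  expect_equal(tree_consistency(v, v, tr), 1)
  # disjoint supports under saturating branch lengths
  tr2 <- ape::read.tree(text = "(A:1.2,B:1.0);")
  expect_equal(tree_consistency(c(A = 0.5), c(B = 0.5), tr2), 0)
  expect_error(tree_consistency(c(Z = 0.5), v, tr), "Z")
})

test_that("the vectorized engine agrees with the straight-line recursion oracle", {
  set.seed(42)
  for (rep in 1:30) {
    n_tips <- sample(3:16, 1)
    tips <- paste0("t", seq_len(n_tips))
    tr <- random_tree(tips)
    v1 <- stats::setNames(round(runif(n_tips), 3), tips)
    v2 <- stats::setNames(round(runif(n_tips), 3), tips)
    v1[sample(n_tips, n_tips %/% 3)] <- 0
    v2[sample(n_tips, n_tips %/% 3)] <- 0
    expect_equal(tree_consistency(v1, v2, tr), oracle_tree_consistency(tr, v1, v2),
      tolerance = 1e-9
    )
  }
})

test_that("consistency respects conservation and branch-length monotonicity", {
  set.seed(13)
  for (rep in 1:15) {
    tips <- paste0("t", 1:8)
    tr <- random_tree(tips, max_len = 0.8)
    v1 <- stats::setNames(runif(8), tips)
    v2 <- stats::setNames(runif(8), tips)
    con <- tree_consistency(v1, v2, tr)
    expect_lte(con, min(sum(v1), sum(v2)) + 1e-12)
    expect_gte(con, 0)
    # lengthening any single branch never increases Con(root)
    e <- sample(nrow(tr$edge), 1)
    tr2 <- tr
    tr2$edge.length[e] <- tr2$edge.length[e] + 0.3
    expect_lte(tree_consistency(v1, v2, tr2), con + 1e-12)
  }
})

test_that("multifurcations equal their left-to-right binary resolution", {
  multi <- ape::read.tree(text = "(A:0.2,B:0.3,C:0.4);")
  binary <- ape::read.tree(text = "((A:0.2,B:0.3):0,C:0.4);")
  set.seed(5)
  for (rep in 1:10) {
    v1 <- stats::setNames(runif(3), c("A", "B", "C"))
    v2 <- stats::setNames(runif(3), c("A", "B", "C"))
    expect_equal(
      tree_consistency(v1, v2, multi),
      tree_consistency(v1, v2, binary),
      tolerance = 1e-12
    )
  }
})

test_that("local distance renormalizes over T and matches hand values", {
  tr <- ape::read.tree(text = "(A:0.25,B:0.25);")
  tab <- validate_feature_table(matrix(c(0.3, 0.7, 0.2, 0.8), 2,
    dimnames = list(c("A", "B"), c("s1", "s2"))
  ))
  tgt <- build_target_set(c("A", "B"))
  expect_equal(fms_distance("s1", "s1", tgt, tr, tab), 0)
  # restricted to A only: renormalized profiles are identical unit masses
  tgtA <- build_target_set("A")
  expect_equal(fms_distance("s1", "s2", tgtA, tr, tab), 0)

  # opposite single-leaf supports at d = 0.25 each: distance 1 - 0.75
  tab2 <- validate_feature_table(matrix(c(1, 1e-12, 1e-12, 1), 2,
    dimnames = list(c("A", "B"), c("s1", "s2"))
  ))
  expect_equal(fms_distance("s1", "s2", tgt, tr, tab2), 0.25, tolerance = 1e-6)

  # zero mass on T in both samples: distance defined as 1, with a warning
  tab3 <- validate_feature_table(matrix(c(1, 1, 1, 1), 2,
    dimnames = list(c("bg1", "bg2"), c("s1", "s2"))
  ))
  tr3 <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(bg1:0.1,bg2:0.1):0.1);")
  expect_warning(d <- fms_distance("s1", "s2", tgt, tr3, tab3), "zero")
  expect_equal(d, 1)
})

test_that("distance matrices are symmetric, bounded, and thread-invariant", {
  set.seed(31)
  ds <- simulate_dataset(scenario_config(n_per_group = 6, seed = 31))
  mk <- select_exact_markers(ds$table, ds$metadata$group, alpha = 0.05)
  tgt <- build_target_set(mk, ds$index)
  dm <- fms_distance_matrix(ds$table, ds$tree, tgt)
  expect_true(isSymmetric(dm))
  expect_equal(unname(diag(dm)), rep(0, ncol(dm)))
  expect_true(all(dm >= 0 & dm <= 1))
  expect_identical(dm, fms_distance_matrix(ds$table, ds$tree, tgt, threads = 4L))

  # three identical samples give the zero matrix
  tab <- ds$table[, c(1, 1, 1)]
  colnames(tab) <- c("x", "y", "z")
  expect_equal(max(fms_distance_matrix(tab, ds$tree, tgt)), 0)
})

test_that("the local distance with T = all features equals the global distance", {
  set.seed(77)
  ds <- simulate_dataset(scenario_config(n_per_group = 4, seed = 77))
  all_t <- build_target_set(rownames(ds$table))
  expect_equal(
    fms_distance_matrix(ds$table, ds$tree, all_t),
    fms_distance_matrix(ds$table, ds$tree, NULL)
  )
  # continuity: perturbing one leaf mass by epsilon moves the distance to 0
  s <- ds$table[, 1]
  tab2 <- cbind(a = s, b = s)
  tab2["bg_01", "b"] <- tab2["bg_01", "b"] + 1e-7
  tab2 <- validate_feature_table(tab2)
  expect_lt(global_distance("a", "b", ds$tree, tab2), 1e-5)
})
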