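eq_dm <- function(n, d = 0.5) {
  m <- matrix(d, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  diag(m) <- 0
  m
}

two_cluster_dm <- function(n_per = 10, within = 0.1, between = 0.9) {
  n <- 2 * n_per
  m <- matrix(between, n, n)
  m[1:n_per, 1:n_per] <- within
  m[(n_per + 1):n, (n_per + 1):n] <- within
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  m
}

test_that("PCoA reproduces closed-form configurations", {
  # 2 samples at distance 1: coordinates +/- 0.5 on one axis
  p2 <- pcoa_ordination(eq_dm(2, 1))
  expect_equal(sort(unname(p2$coordinates[, 1])), c(-0.5, 0.5))
  # equilateral triple: two equal positive eigenvalues
  p3 <- pcoa_ordination(eq_dm(3, 1))
  pos <- p3$eigenvalues[p3$eigenvalues > 1e-9]
  expect_length(pos, 2L)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)
  expect_lte(sum(p3$proportion_explained), 1 + 1e-9)
  # degenerate zero matrix
  p0 <- pcoa_ordination(eq_dm(4, 0))
  expect_true(all(abs(p0$eigenvalues) < 1e-9))
})

test_that("PERMANOVA separates clusters and is invariant to scaling and ordering", {
  dm <- two_cluster_dm()
  g <- rep(c("A", "B"), each = 10)
  res <- permanova_test(dm, g, n_perm = 999, seed = 1)
  expect_equal(res$p_value, 0.001) # minimum attainable at 999 permutations
  expect_gt(res$R2, 0.5)

  # R2 invariant to multiplying all distances by a constant
  res2 <- permanova_test(dm * 0.5, g, n_perm = 99, seed = 1)
  expect_equal(res2$R2, res$R2, tolerance = 1e-12)

  # statistic invariant to a consistent sample reordering
  perm <- sample(20)
  res3 <- permanova_test(dm[perm, perm], g[perm], n_perm = 99, seed = 1)
  expect_equal(res3$statistic, res$statistic, tolerance = 1e-12)
  expect_equal(res3$R2, res$R2, tolerance = 1e-12)

  # all pairwise distances equal (balanced 2 x 4 design): closed-form
  # SS_total = 28 d^2 / 8, SS_within = 2 * 6 d^2 / 4 -> R2 = 1/7, F = 1,
  # and every permutation gives the same F, so p = 1
  res4 <- permanova_test(eq_dm(8), rep(c("A", "B"), each = 4), n_perm = 99, seed = 2)
  expect_equal(res4$R2, 1 / 7, tolerance = 1e-9)
  expect_equal(res4$statistic, 1, tolerance = 1e-9)
  expect_equal(res4$p_value, 1)
})

test_that("ANOSIM mirrors the separation semantics with Clarke's R", {
  dm <- two_cluster_dm()
  g <- rep(c("A", "B"), each = 10)
  res <- anosim_test(dm, g, n_perm = 999, seed = 1)
  expect_equal(res$statistic, 1) # perfect separation: all between > all within
  expect_equal(res$p_value, 0.001)
  # equal distances: R = 0 region, nothing to detect
  res0 <- anosim_test(eq_dm(8), rep(c("A", "B"), each = 4), n_perm = 99, seed = 1)
  expect_equal(res0$p_value, 1)
})

test_that("dispersion test flags scale differences and passes homogeneous groups", {
  set.seed(8)
  x <- rbind(
    matrix(rnorm(20 * 2, sd = 1), 20),
    matrix(rnorm(20 * 2, sd = 3), 20) # group B: 3x wider
  )
  dm <- as.matrix(stats::dist(x))
  dm <- dm / max(dm)
  dimnames(dm) <- list(paste0("s", 1:40), paste0("s", 1:40))
  g <- rep(c("A", "B"), each = 20)
  res <- dispersion_test(dm, g, n_perm = 199, seed = 3)
  expect_lt(res$p_value, 0.05)

  # identical groups (duplicated points): F in the 0 region
  y <- matrix(rnorm(10 * 2), 10)
  dup <- rbind(y, y)
  dmd <- as.matrix(stats::dist(dup))
  dmd <- dmd / max(dmd)
  dimnames(dmd) <- list(paste0("s", 1:20), paste0("s", 1:20))
  resd <- dispersion_test(dmd, rep(c("A", "B"), each = 10), n_perm = 99, seed = 4)
  expect_lt(resd$statistic, 1e-9)
})

test_that("KNN leave-one-out scores are deterministic and degrade gracefully", {
  dm <- two_cluster_dm(5)
  g <- rep(c("A", "B"), each = 5)
  sc <- knn_loo_scores(dm, g, k = 3)
  expect_equal(unname(sc), c(rep(0, 5), rep(1, 5))) # positive class = "B"
  expect_equal(roc_auc(sc, g)$auc, 1)
  expect_identical(sc, knn_loo_scores(dm, g, k = 3))

  # k = n - 1: every score equals the positive prevalence among the others
  sc_all <- knn_loo_scores(dm, g, k = 9)
  expect_equal(unname(sc_all), ifelse(g == "B", 4 / 9, 5 / 9))
  expect_error(knn_loo_scores(dm, g, k = 0), "positive")
})

test_that("AUC follows the Mann-Whitney identity with half-credit ties", {
  scores <- c(0.9, 0.8, 0.8, 0.1)
  labels <- c("pos", "pos", "neg", "neg")
  # pairs: (.9,.8)+, (.9,.1)+, (.8,.8) tie, (.8,.1)+ -> 3.5/4
  expect_equal(roc_auc(scores, labels, positive = "pos")$auc, 0.875)
  expect_equal(roc_auc(c(1, 0.9, 0.2, 0.1), c("p", "p", "n", "n"), positive = "p")$auc, 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.9, 1), c("p", "p", "n", "n"), positive = "p")$auc, 0)
  # complement symmetry
  set.seed(6)
  s <- runif(20)
  l <- rep(c("n", "p"), 10)
  expect_equal(
    roc_auc(s, l, positive = "p")$auc + roc_auc(-s, l, positive = "p")$auc, 1
  )
})

test_that("shuffled labels give chance-level AUC on average", {
  set.seed(15)
  aucs <- replicate(200, {
    x <- matrix(rnorm(20 * 3), 20)
    dm <- as.matrix(stats::dist(x))
    dm <- dm / max(dm)
    dimnames(dm) <- list(paste0("s", 1:20), paste0("s", 1:20))
    g <- sample(rep(c("A", "B"), each = 10))
    roc_auc(knn_loo_scores(dm, g, k = 3), g)$auc
  })
  # leave-one-out voting is slightly pessimistic on balanced null labels
  # (removing a sample depletes its own class among the neighbors), so the
  # chance band is centered just below 0.5
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})
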