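test_that("CLR transform satisfies its defining identities", {
  m <- rbind(s1 = c(1, 1, 1, 1), s2 = c(10, 20, 30, 40))
  colnames(m) <- paste0("a", 1:4)
  cl <- clr_transform(m)
  expect_equal(unname(cl["s1", ]), rep(0, 4))
  expect_true(all(abs(rowSums(cl)) < 1e-9))
  ## closed form: with pseudocount c, row (e*k - c, k - c, k - c, k - c)
  ## has first clr coordinate exceeding the others by exactly 1 - 1/4 * 1...
  k <- 50; cc <- 1
  row <- matrix(c(exp(1) * k - cc, k - cc, k - cc, k - cc), 1,
                dimnames = list("s", paste0("a", 1:4)))
  cl2 <- clr_transform(round(row) * 0 + row, pseudocount = cc)
  expect_equal(cl2[1, 1] - cl2[1, 2], 1, tolerance = 1e-12)
  expect_equal(cl2[1, 1], 0.75, tolerance = 1e-12)
  ## scale invariance in the zero-pseudocount limit
  m2 <- rbind(a = c(2, 4, 8), b = c(2, 4, 8) * 7)
  colnames(m2) <- paste0("a", 1:3)
  cl3 <- clr_transform(m2, pseudocount = 1e-12)
  expect_equal(unname(cl3[1, ]), unname(cl3[2, ]), tolerance = 1e-9)
  ## all-zero ASVs dropped first
  m3 <- cbind(m, a5 = 0)
  expect_equal(ncol(clr_transform(m3)), 4)
})

test_that("PCA reproduces distances, orders eigenvalues and fixes PC1 sign", {
  set.seed(11)
  m <- random_table(10, 8) + 1
  cl <- clr_transform(m)
  pc <- clr_pca(cl)
  expect_true(all(diff(pc$eigenvalues) <= 1e-9))
  expect_equal(unname(colMeans(pc$scores)), rep(0, ncol(pc$scores)),
               tolerance = 1e-9)
  ## isometry: full-rank scores reproduce Euclidean distances exactly
  expect_equal(as.matrix(dist(pc$scores)), as.matrix(dist(cl)),
               tolerance = 1e-9, ignore_attr = TRUE)
  ## two distinct samples: PC1 explains everything
  pc2 <- clr_pca(cl[1:2, ])
  expect_equal(pc2$prop_var[1], 1, tolerance = 1e-9)
  ## sign convention: terrestrial mean forced negative
  pcs <- clr_pca(cl, terrestrial_samples = rownames(cl)[which.max(pc$scores[, 1])])
  expect_lt(mean(pcs$scores[which.max(pc$scores[, 1]), 1]), 0)
  expect_error(clr_pca(matrix(3, 4, 2)), "constant")
})

test_that("PERMANOVA pseudo-F and R2 match the coordinate-space oracle", {
  set.seed(21)
  for (i in 1:10) {
    X <- clr_transform(random_table(9, 7) + 1)
    lab <- sample(rep(c("g1", "g2", "g3"), 3))
    r <- permanova(dist(X), lab, n_permutations = 19, seed = i)
    expect_equal(r$pseudo_F, oracle_permanova_F(X, lab), tolerance = 1e-9)
    expect_true(r$R2 >= 0 && r$R2 <= 1)
    expect_true(r$p >= 1 / 20 && r$p <= 1)
  }
})

test_that("PERMANOVA agrees with vegan::adonis2 and respects separation", {
  skip_if_not_installed("vegan")
  set.seed(31)
  X <- clr_transform(random_table(12, 9) + 1)
  lab <- rep(c("a", "b", "c"), each = 4)
  mine <- permanova(dist(X), lab, n_permutations = 99, seed = 1)
  ref <- vegan::adonis2(dist(X) ~ lab, permutations = 99)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-9)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-9)
  ## perfectly separated toy case: R2 = 1
  Y <- rbind(c(0, 0), c(0, 0), c(10, 0), c(10, 0)) +
    matrix(rnorm(8, 0, 1e-8), 4)
  r <- permanova(dist(Y), c("u", "u", "v", "v"), n_permutations = 9, seed = 1)
  expect_equal(r$R2, 1, tolerance = 1e-6)
  expect_error(permanova(dist(Y), c("u", "v", "v", "v"), 9), "single sample")
})

test_that("total sum of squares equals (n-1) times total CLR variance", {
  set.seed(41)
  X <- clr_transform(random_table(10, 6) + 1)
  lab <- rep(c("a", "b"), 5)
  r <- permanova(dist(X), lab, n_permutations = 9, seed = 1)
  expect_equal(r$ss_between + r$ss_within,
               sum(apply(X, 2, var)) * (nrow(X) - 1), tolerance = 1e-9)
  ## invariance to sample reordering
  perm <- sample(10)
  r2 <- permanova(as.matrix(dist(X))[perm, perm], lab[perm],
                  n_permutations = 9, seed = 1)
  expect_equal(r2$pseudo_F, r$pseudo_F, tolerance = 1e-12)
})

test_that("pairwise PERMANOVA is consistent with direct subset runs", {
  set.seed(51)
  X <- clr_transform(random_table(12, 8) + 1)
  lab <- rep(c("a", "b", "c"), each = 4)
  pw <- pairwise_permanova(dist(X), lab, n_permutations = 49, seed = 5)
  expect_equal(nrow(pw), 3)
  idx <- lab %in% c("a", "b")
  direct <- permanova(as.matrix(dist(X))[idx, idx], lab[idx],
                      n_permutations = 49, seed = stage_seed(5, "a_b"))
  expect_equal(pw$pseudo_F[pw$term == "a vs b"], direct$pseudo_F)
  expect_equal(pw$p[pw$term == "a vs b"], direct$p)
  expect_true(all(pw$p_adjusted >= pw$p))
})

test_that("dispersion distances match vegan::betadisper", {
  skip_if_not_installed("vegan")
  set.seed(61)
  X <- clr_transform(random_table(14, 10) + 1)
  lab <- rep(c("a", "b"), 7)
  mine <- dispersion_test(dist(X), lab, n_permutations = 19, seed = 1)
  ref <- vegan::betadisper(dist(X), lab, type = "centroid")
  expect_equal(mine$distances$dist_to_centroid, unname(ref$distances),
               tolerance = 1e-6)
  ## a group collapsed onto its centroid has zero mean distance
  Y <- rbind(matrix(rep(c(1, 2), 3), 3, byrow = TRUE),
             matrix(rnorm(6), 3))
  rownames(Y) <- paste0("s", 1:6)
  r <- dispersion_test(dist(Y), rep(c("tight", "loose"), each = 3),
                       n_permutations = 19, seed = 1)
  tight <- r$distances$dist_to_centroid[r$distances$group == "tight"]
  expect_equal(tight, rep(0, 3), tolerance = 1e-9)
  expect_true(all(r$pairwise$p_bonferroni >= r$pairwise$p_tukey - 1e-12 |
                    r$pairwise$p_bonferroni <= 1))
})
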