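test_that("core taxa respect both thresholds and the prevalence boundary", {
  ## 100 samples: ASV a in all, ASV b in 69, ASV c in 70, ASV d abundant-but-rare
  n <- 100
  m <- matrix(0, n, 4, dimnames = list(sprintf("s%03d", 1:n),
                                       c("a", "b", "c", "d")))
  m[, "a"] <- 50
  m[1:69, "b"] <- 50
  m[1:70, "c"] <- 50
  m[1:90, "d"] <- 1e-7 * 50  # below rel_abund once normalized
  m[, "d"] <- 0; m[1:90, "d"] <- 0  # d stays absent
  m[cbind(1:n, 1)] <- m[, 1] + 1    # keep rows nonzero
  grp <- rep(c("g1", "g2"), each = 50)
  ct <- core_taxa(m, grp, prevalence = 0.70, rel_abund = 1e-5)
  expect_true("a" %in% ct$overall)
  expect_true("c" %in% ct$overall)   # exactly 70% retained (>= threshold)
  expect_false("b" %in% ct$overall)  # 69% misses it
  expect_true(all(c("a") %in% ct$by_group$g1))
})

test_that("share partition handles disjoint and identical pools exactly", {
  ## 3 phenotypes, 2 birds each, disjoint ASV pools
  mk <- function(vals) matrix(vals, 6, 6, byrow = TRUE,
                              dimnames = list(sprintf("s%d", 1:6),
                                              sprintf("a%d", 1:6)))
  m <- mk(0)
  m[1:2, 1:2] <- 5; m[3:4, 3:4] <- 5; m[5:6, 5:6] <- 5
  birds <- sprintf("b%d", 1:6)
  md <- toy_metadata(m, birds)
  asg <- data.frame(bird_id = birds, n_sightings = 6,
                    phenotype = rep(c("marine", "switcher", "terrestrial"),
                                    each = 2),
                    prop_marine = 0.5)
  part <- bootstrap_share_partition(m, md, asg, n_iter = 40, seed = 1)
  su <- part$summary; rownames(su) <- su$subset
  expect_equal(su[c("MS", "MT", "TS", "MTS"), "mean_percent"], rep(0, 4),
               ignore_attr = TRUE)
  expect_equal(sum(su$mean_percent), 100, tolerance = 1e-9)
  ## identical deep pools: everything lands in MTS
  m2 <- mk(5)
  part2 <- bootstrap_share_partition(m2, md, asg, n_iter = 20, seed = 1)
  su2 <- part2$summary; rownames(su2) <- su2$subset
  expect_equal(su2["MTS", "mean_percent"], 100)
  ## per-iteration percentages always sum to 100
  expect_true(all(abs(rowSums(part$per_iteration) - 100) < 1e-9))
})

test_that("bipartite network export conserves edges and round-trips GraphML", {
  pool <- matrix(c(TRUE, TRUE, TRUE,   # a1 in all three -> degree 3
                   TRUE, FALSE, FALSE,
                   FALSE, TRUE, TRUE), 3, 3,
                 dimnames = list(c("marine", "switcher", "terrestrial"),
                                 c("a1", "a2", "a3")))
  net <- export_bipartite_network(pool)
  expect_equal(nrow(net$edges), sum(pool))
  deg <- table(net$edges$asv_id)
  expect_equal(unname(deg[["a1"]]), 3)
  expect_equal(net$nodes$subset[net$nodes$id == "a1"], "MTS")
  f <- withr::local_tempfile(fileext = ".graphml")
  export_bipartite_network(pool, graphml_path = f)
  g2 <- igraph::read_graph(f, format = "graphml")
  e1 <- apply(igraph::as_edgelist(net$graph), 1, paste, collapse = "|")
  e2 <- apply(igraph::as_edgelist(g2), 1, paste, collapse = "|")
  expect_setequal(e1, e2)
})

test_that("Jaccard matches hand counts, conventions and the set oracle", {
  m <- rbind(s1 = c(1, 2, 0), s2 = c(1, 2, 0), s3 = c(0, 0, 4),
             s4 = c(3, 0, 1))
  colnames(m) <- c("a", "b", "c")
  J <- as.matrix(pairwise_jaccard(m))
  expect_equal(J["s1", "s2"], 1)      # identical
  expect_equal(J["s1", "s3"], 0)      # disjoint
  expect_equal(J["s2", "s4"], 1 / 3)  # {a,b} vs {a,c}
  set.seed(4)
  for (i in 1:5) {
    r <- random_table(6, 8)
    Jr <- as.matrix(pairwise_jaccard(r))
    i1 <- sample(6, 2)
    expect_equal(Jr[i1[1], i1[2]], oracle_jaccard(r[i1[1], ], r[i1[2], ]))
  }
})

test_that("Jaccard permutation t-tests are exact on degenerate data and label-invariant", {
  ## identical samples everywhere -> every J = 1, t = 0, p near 1
  m <- matrix(5, 12, 6, dimnames = list(sprintf("s%02d", 1:12),
                                        sprintf("a%d", 1:6)))
  birds <- rep(sprintf("b%d", 1:6), each = 2)
  md <- toy_metadata(m, birds)
  asg <- data.frame(bird_id = sprintf("b%d", 1:6), n_sightings = 6,
                    phenotype = rep(c("marine", "switcher", "terrestrial"), 2),
                    prop_marine = 0.5)
  jt <- jaccard_permutation_ttests(pairwise_jaccard(m), md, asg,
                                   n_permutations = 99, seed = 1)
  expect_equal(nrow(jt), 3)
  expect_equal(jt$t, rep(0, 3))
  expect_true(all(jt$p > 0.9))
  ## within-bird pairs excluded from counts
  expect_true(all(jt$n_pairs_a + jt$n_pairs_b <= choose(12, 2) - 6))
})

test_that("indval matches the brute-force oracle and its textbook cases", {
  ## exclusive indicator: A = B = indval = 1
  m <- rbind(matrix(c(10, 0), 3, 2, byrow = TRUE),
             matrix(c(0, 10), 3, 2, byrow = TRUE))
  dimnames(m) <- list(sprintf("s%d", 1:6), c("a", "b"))
  grp <- rep(c("g1", "g2"), each = 3)
  iv <- indval(m, grp, n_permutations = 19, seed = 1)
  expect_equal(iv$A, c(1, 1))
  expect_equal(iv$B, c(1, 1))
  expect_equal(iv$indval, c(1, 1))
  expect_equal(iv$group, c("g1", "g2"))
  ## uniform ASV over 3 groups: A = 1/3, B = 1 -> indval = 1/3
  m3 <- matrix(4, 9, 2, dimnames = list(sprintf("s%d", 1:9), c("a", "b")))
  iv3 <- indval(m3, rep(c("g1", "g2", "g3"), each = 3), n_permutations = 19)
  expect_equal(iv3$indval, rep(1 / 3, 2), tolerance = 1e-12)
  ## random tables: exact equality with the independent oracle
  set.seed(13)
  for (i in 1:10) {
    r <- random_table(10, 5)
    g <- sample(rep(c("g1", "g2", "g3"), length.out = 10))
    ivr <- indval(r, g, n_permutations = 1, seed = i)
    orc <- oracle_indval(r, g)
    best <- apply(orc$indval, 2, max)
    expect_equal(ivr$indval, unname(best[ivr$asv_id]), tolerance = 1e-12)
  }
})

test_that("indval is invariant to per-sample depth rescaling", {
  set.seed(17)
  r <- random_table(9, 6)
  g <- rep(c("g1", "g2", "g3"), 3)
  iv1 <- indval(r, g, n_permutations = 1, seed = 3)
  iv2 <- indval(r * rep(c(1, 10, 100), length.out = 9), g,
                n_permutations = 1, seed = 3)
  expect_equal(iv1$indval, iv2$indval, tolerance = 1e-12)
})
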