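test_that("simulated studies honour the sampling design", {
  ## mean samples per bird near the design value 2.05 (averaged over studies)
  means <- vapply(1:40, function(s) {
    st <- simulate_study(small_sim_config(seed = s))
    md <- st$metadata[!st$metadata$is_negative_control, ]
    mean(table(md$bird_id))
  }, 0)
  expect_gt(mean(means), 1.8)
  expect_lt(mean(means), 2.3)
})

test_that("the generator is deterministic under a fixed seed", {
  s1 <- simulate_study(small_sim_config(seed = 7))
  s2 <- simulate_study(small_sim_config(seed = 7))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(s1$resightings, s2$resightings)
  s3 <- simulate_study(small_sim_config(seed = 8))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("structural invariants of the generated study hold", {
  st <- simulate_study(small_sim_config(seed = 11))
  md <- st$metadata[!st$metadata$is_negative_control, ]
  ## every sample belongs to a known bird with a phenotype
  expect_true(all(md$bird_id %in% names(st$truth$phenotype)))
  ## samples per bird within 1..4
  expect_true(all(table(md$bird_id) >= 1 & table(md$bird_id) <= 4))
  ## contaminant ids disjoint from phenotype-unique pools
  expect_length(intersect(st$truth$contaminant_ids,
                          unlist(st$truth$unique_pools)), 0)
  ## API on the ordinal 1-7 scale
  expect_true(all(md$api >= 1 & md$api <= 7))
  ## day window is the May staging period
  expect_true(all(md$day_of_year >= 121 & md$day_of_year <= 151))
  ## negative controls carry planted contaminants at elevated prevalence
  neg <- st$counts[st$metadata$sample_id[st$metadata$is_negative_control], ,
                   drop = FALSE]
  prev_contam <- mean(neg[, st$truth$contaminant_ids] > 0)
  prev_real <- mean(neg[, st$truth$unique_pools$marine] > 0)
  expect_gt(prev_contam, prev_real)
})

test_that("without switchers no bird is ever resighted on both habitats", {
  cfg <- small_sim_config(seed = 13,
                          phenotype_probs = c(marine = 0.5, switcher = 0,
                                              terrestrial = 0.5))
  st <- simulate_study(cfg)
  habs <- tapply(st$resightings$habitat, st$resightings$bird_id,
                 function(h) length(unique(h)))
  expect_true(all(habs == 1))
})

test_that("higher Dirichlet precision tightens within-group dispersion", {
  ## monotone over a 3-point precision grid, marine group
  mean_disp <- vapply(c(5, 30, 150), function(prec) {
    cfg <- small_sim_config(seed = 17,
                            dirichlet_concentration = c(marine = prec,
                                                        switcher = 30,
                                                        terrestrial = 60))
    st <- simulate_study(cfg)
    md <- st$metadata[!st$metadata$is_negative_control, ]
    phen <- st$truth$phenotype[md$bird_id]
    m <- st$counts[md$sample_id[phen == "marine"], , drop = FALSE]
    cl <- clr_transform(m)
    cen <- colMeans(cl)
    mean(sqrt(rowSums(sweep(cl, 2, cen)^2)))
  }, 0)
  expect_true(all(diff(mean_disp) < 0))
})

test_that("null-pair draws are exchangeable, bird-structured and reproducible", {
  np <- simulate_null_pairs(24, 40, seed = 3, n_groups = 3,
                            samples_per_bird = 2)
  expect_equal(dim(np$counts), c(24, 40))
  expect_equal(length(unique(np$bird_id)), 12)
  ## both samples of a bird share its label
  expect_true(all(tapply(np$labels, np$bird_id,
                         function(l) length(unique(l))) == 1))
  np2 <- simulate_null_pairs(24, 40, seed = 3, n_groups = 3,
                             samples_per_bird = 2)
  expect_identical(np$counts, np2$counts)
  expect_identical(np$labels, np2$labels)
  expect_error(simulate_null_pairs(4, 10, seed = 1), "n_samples >= 6")
})
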