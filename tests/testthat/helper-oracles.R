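## Independent brute-force oracles and small fixture builders shared across
## the test files. Oracles are deliberately naive (explicit loops, textbook
## formulas) and never call the implementation they check.

## pseudo-F from coordinates: explicit group-centroid sums of squares
## (valid for Euclidean distances; a different route than the distance-sum
## partition used by the implementation)
oracle_permanova_F <- function(X, labels) {
  labels <- as.character(labels)
  grand <- colMeans(X)
  ss_total <- sum(sweep(X, 2, grand)^2)
  ss_within <- 0
  for (g in unique(labels)) {
    Xg <- X[labels == g, , drop = FALSE]
    ss_within <- ss_within + sum(sweep(Xg, 2, colMeans(Xg))^2)
  }
  a <- length(unique(labels))
  n <- nrow(X)
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

## exact permutation p for two groups: enumerate every distinct assignment
## of group-1 positions (observed assignment included)
oracle_exact_permanova_p <- function(X, labels) {
  labels <- as.character(labels)
  lev <- unique(labels)
  n1 <- sum(labels == lev[1])
  f_obs <- oracle_permanova_F(X, labels)
  sets <- utils::combn(nrow(X), n1, simplify = FALSE)
  f_all <- vapply(sets, function(s) {
    lab <- rep(lev[2], nrow(X))
    lab[s] <- lev[1]
    oracle_permanova_F(X, lab)
  }, 0)
  mean(f_all >= f_obs - 1e-12)
}

## Dufrene-Legendre indicator values by explicit loops
oracle_indval <- function(counts, groups) {
  rel <- counts / rowSums(counts)
  lev <- sort(unique(groups))
  out <- matrix(0, length(lev), ncol(counts), dimnames = list(lev, colnames(counts)))
  A <- B <- out
  for (j in seq_len(ncol(counts))) {
    means <- vapply(lev, function(g) mean(rel[groups == g, j]), 0)
    for (gi in seq_along(lev)) {
      g <- lev[gi]
      A[gi, j] <- if (sum(means) > 0) means[gi] / sum(means) else 0
      B[gi, j] <- mean(counts[groups == g, j] > 0)
      out[gi, j] <- A[gi, j] * B[gi, j]
    }
  }
  list(indval = out, A = A, B = B)
}

## per-sample distance to own bird's centroid, explicit loops
oracle_centroid_distances <- function(X, bird) {
  d <- rep(NA_real_, nrow(X))
  for (b in unique(bird)) {
    idx <- which(bird == b)
    if (length(idx) < 2) next
    cen <- colMeans(X[idx, , drop = FALSE])
    for (i in idx) d[i] <- sqrt(sum((X[i, ] - cen)^2))
  }
  d
}

## Jaccard similarity by explicit set operations
oracle_jaccard <- function(a, b) {
  A <- which(a > 0); B <- which(b > 0)
  if (length(A) == 0 && length(B) == 0) return(1)
  length(intersect(A, B)) / length(union(A, B))
}

## random small count table with ids
random_table <- function(n, k, max_count = 20, p_zero = 0.4) {
  m <- matrix(ifelse(stats::runif(n * k) < p_zero, 0,
                     stats::rpois(n * k, max_count / 3) + 1), n, k)
  if (any(rowSums(m) == 0)) m[rowSums(m) == 0, 1] <- 1
  dimnames(m) <- list(sprintf("s%02d", seq_len(n)), sprintf("a%02d", seq_len(k)))
  m
}

## a small, cheap study configuration for structural tests
small_sim_config <- function(seed = 1, ...) {
  sim_config(n_birds = 30, n_asvs = 90, n_shared_core = 20,
             n_unique_per_phenotype = c(marine = 40, switcher = 8,
                                        terrestrial = 8),
             n_contaminants = 5, n_offtarget = 3,
             depth_lognormal = c(meanlog = log(4000), sdlog = 0.4),
             min_reads = 1000, p_low_depth = 0.1,
             seed = seed, ...)
}

## minimal metadata/assignment pair for sharing/trajectory tests
toy_metadata <- function(counts, birds_per_sample) {
  data.frame(sample_id = rownames(counts), bird_id = birds_per_sample,
             day_of_year = seq_len(nrow(counts)) + 120,
             habitat_at_collection = "marine", sex = "F",
             api = NA_integer_, flock_size = NA_integer_,
             is_negative_control = FALSE, stringsAsFactors = FALSE)
}
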