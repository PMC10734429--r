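## beta_diversity: CLR transformation, ordination, permutational
## multivariate ANOVA (global and pairwise) on Euclidean distances, and
## multivariate dispersion testing.

#' Centred log-ratio transformation
#'
#' `clr(x)_i = ln((x_i + c) / g(x + c))` with pseudocount `c` and `g` the
#' geometric mean over retained ASVs. ASVs with zero total count across all
#' samples are removed first. Every row of the result sums to zero.
#'
#' @param counts samples x ASVs matrix.
#' @param pseudocount additive pseudocount (default 1).
#' @return samples x ASVs real matrix.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  lx <- log(counts + pseudocount)
  sweep(lx, 1, rowMeans(lx))
}

#' Principal component analysis of a CLR matrix
#'
#' Eigendecomposition of the sample covariance (via SVD of the centred
#' matrix). For reproducibility the sign of PC1 is fixed so that the mean
#' score of terrestrial-collected samples is negative; other axes keep the
#' arbitrary SVD sign.
#'
#' @param clr CLR matrix (samples x ASVs).
#' @param terrestrial_samples sample ids used to anchor the PC1 sign; NULL
#'   skips the convention.
#' @return list: `scores` (samples x PCs), `eigenvalues`, `prop_var`,
#'   `sign_fixed` flag.
#' @export
clr_pca <- function(clr, terrestrial_samples = NULL) {
  stopifnot(nrow(clr) >= 2)
  if (all(apply(clr, 2, stats::sd) < 1e-12))
    stop_val("constant matrix: PCA undefined")
  pc <- stats::prcomp(clr, center = TRUE, scale. = FALSE)
  scores <- pc$x
  eig <- pc$sdev^2
  sign_fixed <- FALSE
  if (!is.null(terrestrial_samples)) {
    idx <- rownames(scores) %in% terrestrial_samples
    if (any(idx) && mean(scores[idx, 1]) > 0) {
      scores[, 1] <- -scores[, 1]
      sign_fixed <- TRUE
    }
  }
  list(scores = scores, eigenvalues = eig, prop_var = eig / sum(eig),
       sign_fixed = sign_fixed)
}

## sum of squared distances within each level / group partition
## (Anderson's distance-based partition: SS_total = sum d^2 / n,
##  SS_within = sum over groups of within-group sum d^2 / n_g)
permanova_ss <- function(D2, labels) {
  n <- nrow(D2)
  ss_total <- sum(D2) / (2 * n)
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

permanova_F <- function(D2, labels, a = length(unique(labels))) {
  n <- nrow(D2)
  ss <- permanova_ss(D2, labels)
  (ss[["among"]] / (a - 1)) / (ss[["within"]] / (n - a))
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Distance-based partition of variance among groups with pseudo-F
#' `(SS_among/df_among) / (SS_within/df_within)` and a permutation p-value
#' `(b + 1) / (m + 1)` where `b` counts permuted statistics at least as
#' large as the observed one. Permutation is free by default; supplying
#' `strata` (e.g. bird ids) permutes group labels at the stratum level so
#' that all samples of one bird move together.
#'
#' @param d `dist` or square symmetric distance matrix.
#' @param labels group label per sample (>= 2 levels, each with >= 2
#'   samples).
#' @param n_permutations number of permutations (default 999).
#' @param strata optional stratum id per sample for restricted permutation.
#' @param seed integer seed.
#' @return data.frame: `term`, `df_between`, `df_within`, `ss_between`,
#'   `ss_within`, `pseudo_F`, `R2`, `p`, `n_permutations`.
#' @export
permanova <- function(d, labels, n_permutations = 999, strata = NULL,
                      seed = 1) {
  D <- as.matrix(d)
  n <- nrow(D)
  stopifnot(length(labels) == n)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop_val("need >= 2 groups")
  if (any(tab < 2))
    stop_val("group(s) with a single sample: %s",
             paste(names(tab)[tab < 2], collapse = ", "))
  D2 <- D^2
  a <- length(tab)
  ss <- permanova_ss(D2, labels)
  f_obs <- (ss[["among"]] / (a - 1)) / (ss[["within"]] / (n - a))
  set.seed(seed)
  f_perm <- replicate(n_permutations, {
    permanova_F(D2, permute_labels(labels, strata), a)
  })
  p <- (sum(f_perm >= f_obs) + 1) / (n_permutations + 1)
  data.frame(term = "group", df_between = a - 1, df_within = n - a,
             ss_between = ss[["among"]], ss_within = ss[["within"]],
             pseudo_F = f_obs, R2 = ss[["among"]] / ss[["total"]], p = p,
             n_permutations = n_permutations, stringsAsFactors = FALSE)
}

## permute labels freely, or jointly within strata (all samples of a
## stratum receive that stratum's permuted label)
permute_labels <- function(labels, strata = NULL) {
  if (is.null(strata)) return(sample(labels))
  u <- unique(strata)
  lab_u <- labels[match(u, strata)]
  perm <- sample(lab_u)
  perm[match(strata, u)]
}

#' Pairwise PERMANOVA over all unordered group pairs
#'
#' @inheritParams permanova
#' @param adjust p adjustment method (default `"bonferroni"`).
#' @return data.frame with one row per pair; columns as [permanova()] plus
#'   `p_adjusted`.
#' @export
pairwise_permanova <- function(d, labels, n_permutations = 999,
                               adjust = "bonferroni", strata = NULL,
                               seed = 1) {
  D <- as.matrix(d)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(seq_along(pairs), function(k) {
    pr <- pairs[[k]]
    idx <- labels %in% pr
    r <- permanova(D[idx, idx], labels[idx], n_permutations,
                   strata = strata[idx], seed = stage_seed(seed, paste(pr, collapse = "_")))
    r$term <- paste(pr, collapse = " vs ")
    r
  }))
  out$p_adjusted <- pmin(1, stats::p.adjust(out$p, method = adjust))
  out
}

#' Multivariate dispersion test (distance to group centroid)
#'
#' Samples are embedded by principal coordinates of the distance matrix;
#' each sample's distance to its group centroid is computed with the usual
#' correction for negative eigenvalues (squared distances in the imaginary
#' subspace subtract). The omnibus one-way F on these distances gets a
#' permutation p-value (labels permuted over the distances); pairwise group
#' differences are reported with Tukey HSD intervals and, alongside,
#' Bonferroni-adjusted pairwise t-test p-values.
#'
#' @inheritParams permanova
#' @return list: `distances` (data.frame sample_id, group, dist_to_centroid),
#'   `F`, `p`, `pairwise` (data.frame pair, diff, lwr, upr, p_tukey,
#'   p_bonferroni), `n_permutations`.
#' @export
dispersion_test <- function(d, labels, n_permutations = 999, seed = 1) {
  D <- as.matrix(d)
  n <- nrow(D)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop_val("need >= 2 groups")
  if (any(table(labels) < 2)) stop_val("group(s) with a single sample")
  ## principal-coordinate embedding (Gower double-centring)
  G <- -0.5 * scale(t(scale(t(D^2), center = TRUE, scale = FALSE)),
                    center = TRUE, scale = FALSE)
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  keep <- abs(e$values) > max(abs(e$values)) * 1e-10
  vals <- e$values[keep]
  vecs <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(abs(vals)),
                                                   sum(keep))
  pos <- vals > 0
  z <- numeric(n)
  for (g in levels(labels)) {
    idx <- which(labels == g)
    cen <- colMeans(vecs[idx, , drop = FALSE])
    dev2 <- sweep(vecs[idx, , drop = FALSE], 2, cen)^2
    z2 <- rowSums(dev2[, pos, drop = FALSE]) -
      rowSums(dev2[, !pos, drop = FALSE])
    z[idx] <- sqrt(pmax(z2, 0))
  }
  fit <- stats::aov(z ~ labels)
  f_obs <- summary(fit)[[1]][["F value"]][1]
  set.seed(seed)
  f_perm <- replicate(n_permutations, anova_F(sample(z), labels))
  p <- (sum(f_perm >= f_obs) + 1) / (n_permutations + 1)
  tk <- stats::TukeyHSD(fit)$labels
  ## pairwise t-tests on the same one-way fit, Bonferroni-adjusted
  ptt <- with(stats::pairwise.t.test(z, labels, p.adjust.method = "bonferroni"),
              p.value)
  pair_names <- rownames(tk)
  p_bonf <- vapply(strsplit(pair_names, "-"), function(pr)
    ptt[max(pr), min(pr)], 0)
  list(distances = data.frame(sample_id = rownames(D) %||%
                                as.character(seq_len(n)),
                              group = as.character(labels),
                              dist_to_centroid = z,
                              stringsAsFactors = FALSE),
       F = f_obs, p = p,
       pairwise = data.frame(pair = pair_names,
                             diff = tk[, "diff"], lwr = tk[, "lwr"],
                             upr = tk[, "upr"], p_tukey = tk[, "p adj"],
                             p_bonferroni = pmin(1, p_bonf),
                             row.names = NULL, stringsAsFactors = FALSE),
       n_permutations = n_permutations)
}

## fast one-way ANOVA F (avoids lm overhead inside permutation loops)
anova_F <- function(y, f) {
  n <- length(y)
  a <- nlevels(f)
  gm <- mean(y)
  m_g <- tapply(y, f, mean)
  n_g <- tabulate(f)
  ss_b <- sum(n_g * (m_g - gm)^2)
  ss_w <- sum((y - m_g[as.integer(f)])^2)
  (ss_b / (a - 1)) / (ss_w / (n - a))
}
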