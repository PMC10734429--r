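## trajectory: within-individual microbiome stability measured as per-sample
## Euclidean distance to the individual's centroid in CLR space, compared
## across foraging phenotypes with a random-intercept model and a
## bird-blocked permutation test.

#' Distances to individual centroids in CLR space
#'
#' For every bird with at least two retained samples, the centroid is the
#' coordinate-wise mean of its CLR rows and each sample's stability value
#' is its Euclidean distance to that centroid. Birds with a single sample
#' are excluded.
#'
#' @param clr CLR matrix (samples x ASVs).
#' @param metadata data.frame with `sample_id`, `bird_id`, `day_of_year`.
#' @param assignments optional data.frame from [assign_phenotypes()] to
#'   attach phenotypes.
#' @return data.frame: `sample_id`, `bird_id`, `phenotype`, `day_of_year`,
#'   `dist_to_centroid`.
#' @export
individual_centroid_distances <- function(clr, metadata, assignments = NULL) {
  bird <- metadata$bird_id[match(rownames(clr), metadata$sample_id)]
  keep <- !is.na(bird)
  clr <- clr[keep, , drop = FALSE]
  bird <- bird[keep]
  multi <- names(which(table(bird) >= 2))
  if (!length(multi)) stop_val("no bird has >= 2 retained samples")
  rows <- which(bird %in% multi)
  out <- data.frame(sample_id = rownames(clr)[rows],
                    bird_id = bird[rows],
                    stringsAsFactors = FALSE)
  cen <- rowsum(clr[rows, , drop = FALSE], bird[rows]) /
    as.vector(table(bird[rows])[sort(unique(bird[rows]))])
  dev <- clr[rows, , drop = FALSE] - cen[out$bird_id, , drop = FALSE]
  out$dist_to_centroid <- sqrt(rowSums(dev^2))
  out$day_of_year <- metadata$day_of_year[match(out$sample_id,
                                                metadata$sample_id)]
  out$phenotype <- if (!is.null(assignments))
    assignments$phenotype[match(out$bird_id, assignments$bird_id)]
  else NA_character_
  out[c("sample_id", "bird_id", "phenotype", "day_of_year",
        "dist_to_centroid")]
}

#' Group test of within-individual stability
#'
#' Fits a Gaussian random-intercept model of distance-to-centroid on
#' phenotype (bird as random intercept), computes the Wald F for the
#' phenotype terms and a p-value from bird-blocked permutation of phenotype
#' labels, plus pairwise phenotype mean differences with standard errors.
#'
#' @param stability data.frame from [individual_centroid_distances()] with
#'   non-missing `phenotype`.
#' @param n_permutations permutations (default 999).
#' @param seed integer seed.
#' @return list: `F`, `df_num`, `df_den`, `p`, `pairwise` (data.frame
#'   pair / diff / se / p_normal), `fit` (the `lmm_fit`).
#' @export
stability_group_test <- function(stability, n_permutations = 999, seed = 1) {
  df <- stability[stability$phenotype %in% phen3, ]
  df$phenotype <- factor(df$phenotype)
  if (nlevels(df$phenotype) < 2) stop_val("need >= 2 phenotypes")
  fit <- fit_lmm(dist_to_centroid ~ phenotype, df, group = "bird_id")
  f_obs <- lmm_wald_F(fit, grep("^phenotype", names(fit$beta)))
  ## bird-blocked permutation of phenotype labels
  u <- unique(df$bird_id)
  phen_u <- as.character(df$phenotype[match(u, df$bird_id)])
  set.seed(seed)
  f_perm <- replicate(n_permutations, {
    dfp <- df
    dfp$phenotype <- factor(sample(phen_u)[match(df$bird_id, u)])
    fp <- fit_lmm(dist_to_centroid ~ phenotype, dfp, group = "bird_id")
    lmm_wald_F(fp, grep("^phenotype", names(fp$beta)))
  })
  p <- (sum(f_perm >= f_obs) + 1) / (n_permutations + 1)
  lev <- levels(df$phenotype)
  prs <- utils::combn(lev, 2, simplify = FALSE)
  cm <- contrast_matrix(fit, lev, prs)
  diffs <- as.numeric(cm %*% fit$beta)
  ses <- sqrt(diag(cm %*% fit$vcov_beta %*% t(cm)))
  a <- nlevels(df$phenotype)
  list(F = f_obs, df_num = a - 1,
       df_den = fit$n - a - length(unique(df$bird_id)) + 1,
       p = p,
       pairwise = data.frame(
         pair = vapply(prs, paste, "", collapse = " vs "),
         diff = diffs, se = ses,
         p_normal = 2 * stats::pnorm(-abs(diffs / ses)),
         stringsAsFactors = FALSE),
       fit = fit)
}

## Wald F for a subset of fixed-effect coefficients
lmm_wald_F <- function(fit, idx) {
  b <- fit$beta[idx]
  V <- fit$vcov_beta[idx, idx, drop = FALSE]
  as.numeric(crossprod(b, solve(V, b))) / length(idx)
}

## rows = pairwise differences of group means on the treatment-coded scale
contrast_matrix <- function(fit, lev, prs) {
  p <- length(fit$beta)
  mean_row <- function(g) {
    r <- numeric(p)
    r[1] <- 1
    nm <- paste0("phenotype", g)
    if (nm %in% names(fit$beta)) r[match(nm, names(fit$beta))] <- 1
    r
  }
  do.call(rbind, lapply(prs, function(pr) mean_row(pr[2]) - mean_row(pr[1])))
}
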