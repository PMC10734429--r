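## alpha_diversity (richness half): rarefaction interpolation, Good-Turing
## coverage, and group comparison balanced to the minimum group size.

#' Expected richness at a rarefied depth (interpolation)
#'
#' Classical hypergeometric rarefaction:
#' `E[S_m] = sum_i (1 - C(n - n_i, m) / C(n, m))`, evaluated via log-gamma
#' for numerical stability. Interpolation only: `m` may not exceed the
#' sample's depth `n`.
#'
#' @param counts_row non-negative integer vector of one sample's ASV counts.
#' @param m rarefaction depth.
#' @return expected number of ASVs observed in a subsample of `m` reads.
#' @export
rarefied_richness <- function(counts_row, m) {
  x <- counts_row[counts_row > 0]
  n <- sum(x)
  if (m > n) stop_val("m (%d) exceeds sample depth (%d); no extrapolation", m, n)
  if (m == n) return(length(x))
  ## log C(n - x_i, m) - log C(n, m); terms with n - x_i < m contribute 1
  lc <- function(a, b) lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)
  keep <- (n - x) >= m
  p_absent <- numeric(length(x))
  p_absent[keep] <- exp(lc(n - x[keep], m) - lc(n, m))
  sum(1 - p_absent)
}

#' Good-Turing sample coverage
#'
#' `C_hat = 1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2))` where `f1`, `f2`
#' are singleton and doubleton counts and `n` the depth.
#'
#' @param counts_row one sample's ASV counts.
#' @return coverage estimate in `[0, 1]`.
#' @export
sample_coverage <- function(counts_row) {
  x <- counts_row[counts_row > 0]
  n <- sum(x)
  stopifnot(n >= 1)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  if (f1 == 0) return(1)
  denom <- (n - 1) * f1 + 2 * f2
  a <- if (denom > 0) (n - 1) * f1 / denom else 1
  1 - (f1 / n) * a
}

#' Per-sample richness table
#'
#' @param counts samples x ASVs matrix.
#' @param m common rarefaction depth; defaults to the minimum sample depth.
#' @return data.frame: `sample_id`, `depth`, `s_obs`, `f1`, `f2`,
#'   `coverage`, `richness` (`E[S_m]`).
#' @export
richness_table <- function(counts, m = NULL) {
  depth <- rowSums(counts)
  m <- m %||% min(depth)
  if (any(depth < m))
    stop_val("rarefaction depth %d exceeds the depth of %d sample(s)",
             m, sum(depth < m))
  data.frame(
    sample_id = rownames(counts),
    depth = as.numeric(depth),
    s_obs = as.numeric(rowSums(counts > 0)),
    f1 = as.numeric(rowSums(counts == 1)),
    f2 = as.numeric(rowSums(counts == 2)),
    coverage = apply(counts, 1, sample_coverage),
    richness = apply(counts, 1, rarefied_richness, m = m),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Bootstrap group-mean richness balanced to the minimum group size
#'
#' Per iteration and phenotype: draw `n_min` birds without replacement
#' (`n_min` = smallest number of birds in any phenotype), take one random
#' sample per drawn bird, and record the mean richness. Fresh randomness
#' across iterations yields a bootstrap distribution of balanced group
#' means.
#'
#' @param richness data.frame from [richness_table()].
#' @param metadata data.frame with `sample_id`, `bird_id`.
#' @param assignments data.frame from [assign_phenotypes()].
#' @param n_iter iterations (default 1000).
#' @param seed integer seed.
#' @return list: `draws` (n_iter x phenotypes matrix of bootstrap means),
#'   `summary` (data.frame with mean and 2.5/50/97.5 percentiles),
#'   `n_min` (balancing group size, in birds).
#' @export
balanced_richness_bootstrap <- function(richness, metadata, assignments,
                                        n_iter = 1000, seed = 1) {
  df <- merge(richness, metadata[c("sample_id", "bird_id")], by = "sample_id")
  df <- merge(df, assignments[c("bird_id", "phenotype")], by = "bird_id")
  df <- df[df$phenotype %in% c("marine", "switcher", "terrestrial"), ]
  birds_by_phen <- lapply(split(df$bird_id, df$phenotype), unique)
  if (any(lengths(birds_by_phen) == 0)) stop_val("a phenotype has zero birds")
  n_min <- min(lengths(birds_by_phen))
  by_bird <- split(df$richness, df$bird_id)
  set.seed(seed)
  phen <- names(birds_by_phen)
  draws <- matrix(NA_real_, n_iter, length(phen), dimnames = list(NULL, phen))
  for (it in seq_len(n_iter)) {
    for (g in phen) {
      birds <- sample(birds_by_phen[[g]], n_min, replace = FALSE)
      vals <- vapply(by_bird[birds], function(v)
        if (length(v) == 1) v else sample(v, 1), 0)
      draws[it, g] <- mean(vals)
    }
  }
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  list(draws = draws,
       summary = data.frame(phenotype = phen,
                            mean = colMeans(draws),
                            q2.5 = qs[1, ], q50 = qs[2, ], q97.5 = qs[3, ],
                            row.names = NULL, stringsAsFactors = FALSE),
       n_min = n_min)
}
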