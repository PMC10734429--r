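## taxa_sharing: core-taxon detection, bootstrap shared/unique ASV
## partitioning with bipartite network export, permutational Jaccard
## t-tests between pair categories, and indicator value analysis.

phen3 <- c("marine", "switcher", "terrestrial")

#' Core taxa by prevalence and relative abundance
#'
#' An ASV is core when it is present at >= `rel_abund` relative abundance
#' in at least a `prevalence` fraction of samples, evaluated overall and
#' within each group. The default reads the "0.001%" abundance threshold
#' literally as the fraction 1e-5.
#'
#' @param counts samples x ASVs matrix.
#' @param groups group label per sample.
#' @param prevalence prevalence threshold in (0,1).
#' @param rel_abund relative-abundance threshold in (0,1).
#' @return list: `overall` (character vector of core ASV ids) and
#'   `by_group` (named list of per-group core sets).
#' @export
core_taxa <- function(counts, groups, prevalence = 0.70, rel_abund = 1e-5) {
  stopifnot(prevalence > 0, prevalence < 1, rel_abund > 0, rel_abund < 1)
  rel <- counts / rowSums(counts)
  pres <- rel >= rel_abund
  core_of <- function(rows) {
    prev <- colMeans(pres[rows, , drop = FALSE])
    colnames(counts)[prev >= prevalence]
  }
  list(overall = core_of(seq_len(nrow(counts))),
       by_group = lapply(split(seq_len(nrow(counts)), groups), core_of))
}

#' Bootstrap shared/unique ASV partition across foraging phenotypes
#'
#' Per iteration: for each phenotype, draw the minimum group size of birds
#' *with replacement*, take one random sample per drawn bird, and pool
#' presence/absence per phenotype; every ASV present anywhere that
#' iteration is classified into its cell of the three-set Venn partition
#' (M, S, T, MS, MT, TS, MTS) and cell counts are expressed as percentages
#' of the ASVs present. Within each iteration the seven percentages sum
#' to 100.
#'
#' @param counts samples x ASVs matrix (unrarefied).
#' @param metadata data.frame with `sample_id`, `bird_id`.
#' @param assignments data.frame from [assign_phenotypes()].
#' @param n_iter bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @return list: `summary` (data.frame subset / mean_percent / sd_percent /
#'   mean_count), `per_iteration` (n_iter x 7 percentage matrix),
#'   `network_iteration` (pooled presence sets, phenotype x ASV logical
#'   matrix, from one randomly selected iteration), `n_min`.
#' @export
bootstrap_share_partition <- function(counts, metadata, assignments,
                                      n_iter = 1000, seed = 17072020) {
  df <- merge(data.frame(sample_id = rownames(counts),
                         stringsAsFactors = FALSE),
              metadata[c("sample_id", "bird_id")], by = "sample_id")
  df <- merge(df, assignments[c("bird_id", "phenotype")], by = "bird_id")
  df <- df[df$phenotype %in% phen3, ]
  birds_by_phen <- lapply(split(df$bird_id, df$phenotype), unique)
  if (length(birds_by_phen) < 3 || any(lengths(birds_by_phen) == 0))
    stop_val("all three phenotypes need >= 1 bird with samples")
  n_min <- min(lengths(birds_by_phen))
  samples_by_bird <- split(df$sample_id, df$bird_id)
  pres <- counts > 0
  subsets <- c("M", "S", "T", "MS", "MT", "TS", "MTS")
  perc <- matrix(0, n_iter, 7, dimnames = list(NULL, subsets))
  cnt <- matrix(0, n_iter, 7, dimnames = list(NULL, subsets))
  set.seed(seed)
  keep_it <- sample.int(n_iter, 1)  # iteration flagged for network export
  network_iteration <- NULL
  for (it in seq_len(n_iter)) {
    pool <- matrix(FALSE, 3, ncol(counts),
                   dimnames = list(phen3, colnames(counts)))
    for (g in phen3) {
      birds <- sample(birds_by_phen[[g]], n_min, replace = TRUE)
      ss <- vapply(samples_by_bird[birds], function(s)
        if (length(s) == 1) s else sample(s, 1), "")
      pool[g, ] <- colSums(pres[ss, , drop = FALSE]) > 0
    }
    code <- pool["marine", ] + 2 * pool["switcher", ] + 4 * pool["terrestrial", ]
    ## code 1..7 -> M, S, MS, T, MT, TS, MTS
    map <- c("M", "S", "MS", "T", "MT", "TS", "MTS")
    tab <- table(factor(map[code[code > 0]], levels = subsets))
    cnt[it, ] <- as.numeric(tab)
    perc[it, ] <- 100 * cnt[it, ] / sum(cnt[it, ])
    if (it == keep_it) network_iteration <- pool
  }
  list(summary = data.frame(subset = subsets,
                            mean_percent = colMeans(perc),
                            sd_percent = apply(perc, 2, stats::sd),
                            mean_count = colMeans(cnt),
                            row.names = NULL, stringsAsFactors = FALSE),
       per_iteration = perc,
       network_iteration = network_iteration,
       n_min = n_min)
}

#' Export the phenotype-ASV bipartite network of one bootstrap iteration
#'
#' Nodes are the three foraging phenotypes plus every ASV present in the
#' iteration; an edge links a phenotype to each ASV present in any of its
#' pooled samples. ASV nodes carry their phylum and Venn-subset label.
#'
#' @param network_iteration phenotype x ASV logical presence matrix (the
#'   `network_iteration` element of [bootstrap_share_partition()]).
#' @param taxonomy optional taxonomy data.frame supplying phylum labels.
#' @param graphml_path optional path; when given the network is also
#'   written as GraphML via igraph.
#' @return list: `edges` (data.frame phenotype / asv_id), `nodes`
#'   (data.frame id / type / phylum / subset), `graph` (igraph object).
#' @export
export_bipartite_network <- function(network_iteration, taxonomy = NULL,
                                     graphml_path = NULL) {
  pool <- network_iteration
  present <- colSums(pool) > 0
  pool <- pool[, present, drop = FALSE]
  code <- pool["marine", ] + 2 * pool["switcher", ] + 4 * pool["terrestrial", ]
  map <- c("M", "S", "MS", "T", "MT", "TS", "MTS")
  subset_lab <- map[code]
  edges <- do.call(rbind, lapply(rownames(pool), function(g)
    data.frame(phenotype = g, asv_id = colnames(pool)[pool[g, ]],
               stringsAsFactors = FALSE)))
  phylum <- if (!is.null(taxonomy))
    taxonomy$phylum[match(colnames(pool), taxonomy$asv_id)]
  else rep(NA_character_, ncol(pool))
  nodes <- data.frame(
    id = c(rownames(pool), colnames(pool)),
    type = rep(c("phenotype", "asv"), c(nrow(pool), ncol(pool))),
    phylum = c(rep(NA_character_, nrow(pool)), phylum),
    subset = c(rep(NA_character_, nrow(pool)), subset_lab),
    stringsAsFactors = FALSE)
  nodes[is.na(nodes)] <- ""
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  list(edges = edges, nodes = nodes, graph = g)
}

#' Pairwise Jaccard index on presence/absence
#'
#' `J(a, b) = |A intersect B| / |A union B|` with presence defined as
#' count > 0. Two empty presence sets get `J = 1` by convention.
#'
#' @param counts samples x ASVs matrix.
#' @return `dist` object of Jaccard similarities.
#' @export
pairwise_jaccard <- function(counts) {
  stopifnot(nrow(counts) >= 2)
  P <- (counts > 0) * 1
  inter <- P %*% t(P)
  sz <- rowSums(P)
  uni <- outer(sz, sz, `+`) - inter
  J <- ifelse(uni == 0, 1, inter / pmax(uni, 1))
  stats::as.dist(J)
}

## sample-pair category lookup: same phenotype (MM/TT), switcher-specialist
## (SM/ST), different specialists (MT); SS pairs and within-bird pairs are
## excluded (NA)
pair_category_matrix <- function(phen_per_sample) {
  lv <- c("marine", "switcher", "terrestrial")
  i <- match(phen_per_sample, lv)
  cat_lut <- matrix(NA_character_, 3, 3)
  cat_lut[1, 1] <- cat_lut[3, 3] <- "same_phenotype"
  cat_lut[2, 1] <- cat_lut[1, 2] <- cat_lut[2, 3] <- cat_lut[3, 2] <-
    "switcher_specialist"
  cat_lut[1, 3] <- cat_lut[3, 1] <- "different_specialists"
  matrix(cat_lut[cbind(rep(i, length(i)), rep(i, each = length(i)))],
         length(i), length(i))
}

welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  num <- mean(x) - mean(y)
  den <- sqrt(stats::var(x) / nx + stats::var(y) / ny)
  if (den == 0) return(if (num == 0) 0 else sign(num) * Inf)
  num / den
}

#' Permutational t-tests of Jaccard similarity between pair categories
#'
#' Sample pairs (within-individual pairs removed) are grouped into three
#' categories: same phenotype (marine-marine / terrestrial-terrestrial),
#' switcher-specialist (switcher-marine / switcher-terrestrial) and
#' different specialists (marine-terrestrial). For each of the three
#' category contrasts a Welch t statistic on the Jaccard values is
#' computed; the null distribution permutes phenotype labels over *birds*
#' (all samples of a bird move together), re-deriving the pair categories
#' each time. Two-sided `p = (b + 1) / (m + 1)`. Sample-level permutation
#' is available via `permute_unit = "sample"` for comparison, but it breaks
#' the dependence between pairs sharing a sample and is not the default.
#'
#' @param jaccard `dist` from [pairwise_jaccard()] (or square matrix).
#' @param metadata data.frame with `sample_id`, `bird_id`.
#' @param assignments data.frame from [assign_phenotypes()].
#' @param n_permutations permutations (default 1000).
#' @param permute_unit `"bird"` (default) or `"sample"`.
#' @param seed integer seed.
#' @return data.frame: one row per contrast with the two categories, mean
#'   Jaccard and pair count per category, observed `t`, and permutation `p`.
#' @export
jaccard_permutation_ttests <- function(jaccard, metadata, assignments,
                                       n_permutations = 1000,
                                       permute_unit = c("bird", "sample"),
                                       seed = 17072020) {
  permute_unit <- match.arg(permute_unit)
  J <- as.matrix(jaccard)
  ids <- rownames(J)
  bird <- metadata$bird_id[match(ids, metadata$sample_id)]
  phen_by_bird <- stats::setNames(assignments$phenotype, assignments$bird_id)
  keep <- !is.na(bird) & phen_by_bird[bird] %in% phen3
  J <- J[keep, keep, drop = FALSE]
  bird <- bird[keep]
  n <- nrow(J)
  ut <- upper.tri(J)
  same_bird <- outer(bird, bird, `==`)
  jvals <- J[ut & !same_bird]
  pair_idx <- which(ut & !same_bird)
  u_birds <- unique(bird)
  bird_pos <- match(bird, u_birds)
  obs_phen <- unname(phen_by_bird[u_birds])
  contrasts <- list(c("same_phenotype", "switcher_specialist"),
                    c("same_phenotype", "different_specialists"),
                    c("switcher_specialist", "different_specialists"))
  t_for <- function(phen_birds) {
    cats <- pair_category_matrix(phen_birds[bird_pos])[pair_idx]
    vapply(contrasts, function(ct) {
      x <- jvals[!is.na(cats) & cats == ct[1]]
      y <- jvals[!is.na(cats) & cats == ct[2]]
      if (length(x) < 2 || length(y) < 2) NA_real_ else welch_t(x, y)
    }, 0)
  }
  t_obs <- t_for(obs_phen)
  if (anyNA(t_obs))
    stop_val("a pair category is empty after removing within-bird pairs")
  set.seed(seed)
  b <- numeric(3)
  redraws <- 0L
  m_done <- 0L
  while (m_done < n_permutations) {
    tp <- t_for(if (permute_unit == "bird") sample(obs_phen) else obs_phen[sample(length(obs_phen))])
    if (anyNA(tp)) {            # a category emptied: redraw this permutation
      redraws <- redraws + 1L
      if (redraws > 50 * n_permutations) stop_val("too many empty-category redraws")
      next
    }
    b <- b + (abs(tp) >= abs(t_obs))
    m_done <- m_done + 1L
  }
  cats_obs <- pair_category_matrix(obs_phen[bird_pos])[pair_idx]
  cat_mean <- tapply(jvals, cats_obs, mean)
  cat_n <- table(cats_obs)
  data.frame(
    category_a = vapply(contrasts, `[`, "", 1),
    category_b = vapply(contrasts, `[`, "", 2),
    mean_jaccard_a = as.numeric(cat_mean[vapply(contrasts, `[`, "", 1)]),
    mean_jaccard_b = as.numeric(cat_mean[vapply(contrasts, `[`, "", 2)]),
    n_pairs_a = as.integer(cat_n[vapply(contrasts, `[`, "", 1)]),
    n_pairs_b = as.integer(cat_n[vapply(contrasts, `[`, "", 2)]),
    t = t_obs,
    p = (b + 1) / (n_permutations + 1),
    n_permutations = n_permutations,
    stringsAsFactors = FALSE)
}

#' Indicator value analysis (Dufrene-Legendre)
#'
#' Specificity `A_ij` is the mean relative abundance of ASV `i` in group
#' `j` divided by the sum of those means over groups; fidelity `B_ij` is
#' the fraction of group-`j` samples containing the ASV;
#' `IndVal_ij = A_ij * B_ij`. Each ASV is reported for its best group with
#' a permutation p-value from group-label shuffles (bird-blocked when
#' `bird_id` is supplied). ASVs absent everywhere are excluded.
#'
#' @param counts samples x ASVs matrix.
#' @param groups group label per sample.
#' @param n_permutations permutations (default 1000).
#' @param bird_id optional bird id per sample for blocked permutation.
#' @param seed integer seed.
#' @return data.frame: `asv_id`, `group`, `A`, `B`, `indval`,
#'   `indval_percent`, `p`.
#' @export
indval <- function(counts, groups, n_permutations = 1000, bird_id = NULL,
                   seed = 17072020) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) < 2) stop_val("need >= 2 groups")
  nonzero <- colSums(counts) > 0
  counts <- counts[, nonzero, drop = FALSE]
  rel <- counts / rowSums(counts)
  stat <- function(g) {
    gm <- rowsum(rel, g) / as.vector(table(g)[sort(unique(g))])
    A <- t(t(gm) / pmax(colSums(gm), 1e-300))
    B <- rowsum((counts > 0) * 1, g) / as.vector(table(g)[sort(unique(g))])
    A * B
  }
  iv_obs <- stat(groups)
  best <- apply(iv_obs, 2, which.max)
  iv_best <- iv_obs[cbind(best, seq_len(ncol(iv_obs)))]
  set.seed(seed)
  exceed <- numeric(ncol(counts))
  for (k in seq_len(n_permutations)) {
    gp <- if (is.null(bird_id)) sample(groups) else {
      u <- unique(bird_id)
      gb <- groups[match(u, bird_id)]
      sample(gb)[match(bird_id, u)]
    }
    ivp <- stat(gp)
    exceed <- exceed + (apply(ivp, 2, max) >= iv_best)
  }
  ab <- extract_AB(rel, counts, groups, best)
  data.frame(asv_id = colnames(counts),
             group = rownames(iv_obs)[best],
             A = ab$A,
             B = ab$B,
             indval = iv_best,
             indval_percent = 100 * iv_best,
             p = (exceed + 1) / (n_permutations + 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

extract_AB <- function(rel, counts, groups, best) {
  lev <- sort(unique(groups))
  gm <- rowsum(rel, groups) / as.vector(table(groups)[lev])
  A <- t(t(gm) / pmax(colSums(gm), 1e-300))
  B <- rowsum((counts > 0) * 1, groups) / as.vector(table(groups)[lev])
  j <- seq_len(ncol(counts))
  list(A = A[cbind(best, j)], B = B[cbind(best, j)])
}
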