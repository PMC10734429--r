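## synthetic_data: generate complete synthetic studies (ASV table, taxonomy,
## metadata, resightings, negative controls) with the statistical structure
## the downstream analysis assumes, plus a null-data harness for type-I-error
## calibration.
##
## Count model: Dirichlet-multinomial. Marine and terrestrial base
## compositions share a core pool and own unique pools; each switcher
## sample's Dirichlet mean is a convex combination of the two specialist
## bases with a weight tracking that bird's recent habitat sequence, plus a
## small switcher-own pool. Per-phenotype Dirichlet precision controls
## dispersion (terrestrial largest, hence least dispersed).

#' Configuration for a synthetic study
#'
#' Defaults emulate the study design: ~92 phenotyped birds, 1-4 faecal
#' samples per bird with mean 2.05, a ~31-day May staging window
#' (days 121-151), three foraging phenotypes with switcher composition
#' intermediate between marine and terrestrial, terrestrial communities
#' least dispersed, negative controls carrying planted contaminants, and an
#' abdominal profile index (API, 1-7) generated from a random-intercept
#' linear model with a phenotype-by-day interaction (terrestrial slope
#' largest).
#'
#' @param n_birds number of phenotyped birds.
#' @param phenotype_probs named 3-simplex over marine/switcher/terrestrial.
#' @param samples_per_bird_probs probabilities of 1..4 samples per bird
#'   (defaults give mean 2.05).
#' @param n_asvs total ASV count including core, unique pools, filler,
#'   contaminants and off-target (chloroplast etc.) ASVs.
#' @param n_shared_core ASVs shared by both specialist base compositions.
#' @param n_unique_per_phenotype named triple of unique-pool sizes.
#' @param dirichlet_concentration named per-phenotype Dirichlet precision
#'   (terrestrial largest so its communities are tightest).
#' @param switcher_mix_lag weight in `[0,1]` given to the bird's earlier
#'   habitat record when mixing bases for a switcher sample; `1 - lag` goes
#'   to the habitat on the collection day. Small values mean the community
#'   tracks the current diet closely.
#' @param switcher_own_mass base-composition mass of the switcher-own pool.
#' @param depth_lognormal `c(meanlog, sdlog)` of sequencing depth.
#' @param p_low_depth fraction of samples forced below `min_reads`.
#' @param min_reads depth threshold the analysis will later apply.
#' @param n_neg_controls,n_contaminants,n_offtarget negative-control count,
#'   planted reagent contaminants, and off-target (chloroplast /
#'   mitochondria / archaea) ASVs.
#' @param contam_prev_control,contam_prev_sample planting prevalence of
#'   contaminants in negative controls and in true samples.
#' @param api_betas named coefficients of the API model on the z-day scale:
#'   intercept, sex_F, zday, zday2, phenotype offsets and phenotype-by-day
#'   interactions (marine is the reference level).
#' @param sigma_bird,sigma_resid bird random-intercept SD and residual SD.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_birds = 92,
                       phenotype_probs = c(marine = 0.15, switcher = 0.31,
                                           terrestrial = 0.54),
                       samples_per_bird_probs = c(0.35, 0.37, 0.16, 0.12),
                       n_asvs = 430,
                       n_shared_core = 45,
                       n_unique_per_phenotype = c(marine = 320, switcher = 20,
                                                  terrestrial = 22),
                       dirichlet_concentration = c(marine = 30, switcher = 28,
                                                   terrestrial = 70),
                       switcher_mix_lag = 0.15,
                       switcher_own_mass = 0.05,
                       depth_lognormal = c(meanlog = log(15000), sdlog = 0.5),
                       p_low_depth = 0.18,
                       min_reads = 5000,
                       n_neg_controls = 8,
                       n_contaminants = 8,
                       n_offtarget = 6,
                       contam_prev_control = 0.9,
                       contam_prev_sample = 0.15,
                       api_betas = c(intercept = 3.4, sex_F = 0.45,
                                     zday = 0.7, zday2 = -0.15,
                                     phenotype_switcher = -0.2,
                                     phenotype_terrestrial = -0.4,
                                     zday_x_switcher = -0.25,
                                     zday_x_terrestrial = 0.40),
                       sigma_bird = 0.35,
                       sigma_resid = 0.45,
                       seed = 20170501) {
  cfg <- as.list(environment())
  if (abs(sum(phenotype_probs) - 1) > 1e-8)
    stop_val("phenotype_probs must sum to 1")
  if (abs(sum(samples_per_bird_probs) - 1) > 1e-8)
    stop_val("samples_per_bird_probs must sum to 1")
  if (any(dirichlet_concentration <= 0))
    stop_val("dirichlet_concentration must be positive")
  if (sigma_bird < 0 || sigma_resid < 0)
    stop_val("variance components must be non-negative")
  if (switcher_mix_lag < 0 || switcher_mix_lag > 1)
    stop_val("switcher_mix_lag must lie in [0,1]")
  n_pool <- n_shared_core + sum(n_unique_per_phenotype) +
    n_contaminants + n_offtarget
  if (n_pool > n_asvs)
    stop_val("ASV pools (%d) exceed n_asvs (%d)", n_pool, n_asvs)
  class(cfg) <- "sim_config"
  cfg
}

## Dirichlet draw via normalized gammas; tiny shapes underflow to 0, which
## is the sparsity the rare tail needs.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s == 0) g[sample.int(length(alpha), 1)] <- 1 else g <- g / s
  g
}

## lognormal within-pool abundance weights, normalized
pool_weights <- function(n, sdlog = 1) {
  w <- stats::rlnorm(n, 0, sdlog)
  w / sum(w)
}

#' Simulate a complete synthetic study
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (samples x ASVs matrix, including negative
#'   controls), `taxonomy`, `metadata`, `resightings` (data.frames) and
#'   `truth` (ground-truth list: per-bird phenotype and proportion-marine,
#'   contaminant/off-target/unique-pool ASV ids, true API coefficients and
#'   variance components).
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  days <- 121:151
  phen_levels <- c("marine", "switcher", "terrestrial")

  ## ---- ASV pools ----
  n_filler <- cfg$n_asvs - cfg$n_shared_core - sum(cfg$n_unique_per_phenotype) -
    cfg$n_contaminants - cfg$n_offtarget
  ids <- sprintf("ASV%04d", seq_len(cfg$n_asvs))
  idx <- split_pools(cfg, n_filler)
  pools <- lapply(idx, function(i) ids[i])

  ## base relative-abundance templates (study-level constants)
  base_m <- base_t <- base_s_own <- numeric(cfg$n_asvs)
  core_w <- pool_weights(cfg$n_shared_core)
  base_m[idx$core] <- 0.30 * core_w
  base_m[idx$marine] <- 0.62 * pool_weights(length(idx$marine), sdlog = 1.2)
  base_m[idx$filler] <- 0.08 * pool_weights(length(idx$filler))
  base_t[idx$core] <- 0.60 * core_w
  base_t[idx$terrestrial] <- 0.32 * pool_weights(length(idx$terrestrial))
  base_t[idx$filler] <- 0.08 * pool_weights(length(idx$filler))
  base_s_own[idx$switcher] <- pool_weights(length(idx$switcher))

  ## ---- birds ----
  bird_ids <- sprintf("B%03d", seq_len(cfg$n_birds))
  phen <- sample(phen_levels, cfg$n_birds, replace = TRUE,
                 prob = cfg$phenotype_probs[phen_levels])
  sex <- sample(c("F", "M"), cfg$n_birds, replace = TRUE)
  bird_re <- stats::rnorm(cfg$n_birds, 0, cfg$sigma_bird)

  ## ---- resightings ----
  res <- vector("list", cfg$n_birds)
  for (i in seq_len(cfg$n_birds)) {
    n_sight <- min(5 + stats::rpois(1, 4), length(days))
    d <- sort(sample(days, n_sight))
    h <- switch(phen[i],
                marine = rep("marine", n_sight),
                terrestrial = rep("terrestrial", n_sight),
                switcher = markov_habitats(n_sight, persist = 0.7))
    res[[i]] <- data.frame(bird_id = bird_ids[i], day_of_year = d,
                           habitat = h, stringsAsFactors = FALSE)
  }
  resightings <- do.call(rbind, res)
  prop_marine <- vapply(res, function(r) mean(r$habitat == "marine"), 0)

  ## ---- faecal samples ----
  samp <- list()
  for (i in seq_len(cfg$n_birds)) {
    n_s <- sample(1:4, 1, prob = cfg$samples_per_bird_probs)
    r <- res[[i]]
    n_s <- min(n_s, nrow(r))
    take <- sort(sample(nrow(r), n_s))
    for (k in take)
      samp[[length(samp) + 1L]] <- list(bird = i, day = r$day_of_year[k],
                                        habitat = r$habitat[k], sight_row = k)
  }
  n_samp <- length(samp)
  sample_ids <- sprintf("S%04d", seq_len(n_samp))

  counts <- matrix(0, n_samp + cfg$n_neg_controls, cfg$n_asvs,
                   dimnames = list(c(sample_ids,
                                     sprintf("NEG%02d", seq_len(cfg$n_neg_controls))),
                                   ids))
  zday_all <- (vapply(samp, `[[`, 0, "day") - mean(days)) / stats::sd(days)
  api <- integer(n_samp)
  for (j in seq_len(n_samp)) {
    s <- samp[[j]]
    ph <- phen[s$bird]
    base <- switch(ph,
                   marine = base_m,
                   terrestrial = base_t,
                   switcher = {
                     r <- res[[s$bird]]
                     prev <- r$habitat[seq_len(s$sight_row - 1)]
                     p_terr_prev <- if (length(prev)) mean(prev == "terrestrial") else 0.5
                     w <- (1 - cfg$switcher_mix_lag) * (s$habitat == "terrestrial") +
                       cfg$switcher_mix_lag * p_terr_prev
                     mix <- (1 - w) * base_m + w * base_t
                     (1 - cfg$switcher_own_mass) * mix +
                       cfg$switcher_own_mass * base_s_own
                   })
    alpha <- cfg$dirichlet_concentration[[ph]] * base
    p <- rdirichlet1(alpha)
    depth <- if (stats::runif(1) < cfg$p_low_depth)
      sample(500:(cfg$min_reads - 1), 1)
    else
      max(cfg$min_reads, round(stats::rlnorm(1, cfg$depth_lognormal[[1]],
                                             cfg$depth_lognormal[[2]])))
    counts[j, ] <- stats::rmultinom(1, depth, p)
    ## planted contaminants and off-target taxa at low abundance
    hit_c <- stats::runif(cfg$n_contaminants) < cfg$contam_prev_sample
    counts[j, idx$contaminant[hit_c]] <-
      counts[j, idx$contaminant[hit_c]] + stats::rpois(sum(hit_c), 25) + 1
    hit_o <- stats::runif(cfg$n_offtarget) < 0.3
    counts[j, idx$offtarget[hit_o]] <-
      counts[j, idx$offtarget[hit_o]] + stats::rpois(sum(hit_o), 15) + 1
    ## API from the random-intercept linear model, rounded onto the 1-7 scale
    b <- cfg$api_betas
    mu <- b[["intercept"]] + b[["sex_F"]] * (sex[s$bird] == "F") +
      b[["zday"]] * zday_all[j] + b[["zday2"]] * zday_all[j]^2 +
      b[["phenotype_switcher"]] * (ph == "switcher") +
      b[["phenotype_terrestrial"]] * (ph == "terrestrial") +
      b[["zday_x_switcher"]] * zday_all[j] * (ph == "switcher") +
      b[["zday_x_terrestrial"]] * zday_all[j] * (ph == "terrestrial")
    api[j] <- min(7L, max(1L, as.integer(round(
      mu + bird_re[s$bird] + stats::rnorm(1, 0, cfg$sigma_resid)))))
  }

  ## ---- negative controls: contaminants at high prevalence + sparse
  ## carry-over of real (mostly abundant) ASVs ----
  mean_base <- (base_m + base_t) / 2
  for (j in seq_len(cfg$n_neg_controls)) {
    row <- n_samp + j
    hit <- stats::runif(cfg$n_contaminants) < cfg$contam_prev_control
    counts[row, idx$contaminant[hit]] <- stats::rpois(sum(hit), 80) + 1
    carry <- stats::rmultinom(1, 150, rdirichlet1(5 * mean_base))
    counts[row, ] <- counts[row, ] + carry
  }

  metadata <- data.frame(
    sample_id = rownames(counts),
    bird_id = c(bird_ids[vapply(samp, `[[`, 0L, "bird")],
                rep(NA_character_, cfg$n_neg_controls)),
    day_of_year = c(vapply(samp, `[[`, 0, "day"),
                    rep(NA_real_, cfg$n_neg_controls)),
    habitat_at_collection = c(vapply(samp, `[[`, "", "habitat"),
                              rep(NA_character_, cfg$n_neg_controls)),
    sex = c(sex[vapply(samp, `[[`, 0L, "bird")],
            rep(NA_character_, cfg$n_neg_controls)),
    api = c(api, rep(NA_integer_, cfg$n_neg_controls)),
    flock_size = c(stats::rpois(n_samp, 40) + 2,
                   rep(NA_integer_, cfg$n_neg_controls)),
    is_negative_control = rep(c(FALSE, TRUE), c(n_samp, cfg$n_neg_controls)),
    stringsAsFactors = FALSE)

  taxonomy <- make_taxonomy(ids, idx)

  truth <- list(
    phenotype = stats::setNames(phen, bird_ids),
    prop_marine = stats::setNames(prop_marine, bird_ids),
    contaminant_ids = pools$contaminant,
    offtarget_ids = pools$offtarget,
    core_ids = pools$core,
    unique_pools = list(marine = pools$marine, switcher = pools$switcher,
                        terrestrial = pools$terrestrial),
    api_betas = cfg$api_betas,
    sigma_bird = cfg$sigma_bird,
    sigma_resid = cfg$sigma_resid)

  list(counts = counts, taxonomy = taxonomy, metadata = metadata,
       resightings = resightings, truth = truth)
}

split_pools <- function(cfg, n_filler) {
  n <- c(core = cfg$n_shared_core,
         marine = cfg$n_unique_per_phenotype[["marine"]],
         switcher = cfg$n_unique_per_phenotype[["switcher"]],
         terrestrial = cfg$n_unique_per_phenotype[["terrestrial"]],
         filler = n_filler,
         contaminant = cfg$n_contaminants,
         offtarget = cfg$n_offtarget)
  ends <- cumsum(n)
  starts <- c(1, utils::head(ends, -1) + 1)
  out <- mapply(function(s, e) if (e >= s) s:e else integer(0),
                starts, ends, SIMPLIFY = FALSE)
  names(out) <- names(n)
  out
}

markov_habitats <- function(n, persist = 0.7) {
  h <- character(n)
  h[1] <- sample(c("marine", "terrestrial"), 1)
  for (k in seq_len(n - 1) + 1)
    h[k] <- if (stats::runif(1) < persist) h[k - 1] else
      setdiff(c("marine", "terrestrial"), h[k - 1])
  ## a switcher must have used both habitats at least once
  if (length(unique(h)) == 1 && n >= 2)
    h[sample(n, 1)] <- setdiff(c("marine", "terrestrial"), h[1])
  h
}

make_taxonomy <- function(ids, idx) {
  phyla <- c("Actinobacteria", "Bacteroidetes", "Firmicutes",
             "Proteobacteria", "Tenericutes")
  n <- length(ids)
  tax <- data.frame(asv_id = ids, kingdom = rep("Bacteria", n),
                    phylum = sample(phyla, n, replace = TRUE,
                                    prob = c(.15, .2, .25, .3, .1)),
                    class = "", order = "", family = "",
                    genus = sprintf("Genus%03d", seq_len(n)),
                    stringsAsFactors = FALSE)
  ## taxonomic bias mirroring the study: terrestrial-associated ASVs enriched
  ## for Firmicutes, marine-associated for Proteobacteria
  tax$phylum[idx$terrestrial] <- sample(phyla, length(idx$terrestrial), TRUE,
                                        prob = c(.1, .15, .55, .1, .1))
  tax$phylum[idx$marine] <- sample(phyla, length(idx$marine), TRUE,
                                   prob = c(.1, .15, .1, .55, .1))
  ## off-target ASVs removable by taxonomy pruning
  k <- length(idx$offtarget)
  if (k) {
    kind <- rep_len(c("chloroplast", "mitochondria", "archaea"), k)
    tax$order[idx$offtarget][kind == "chloroplast"] <- "Chloroplast"
    tax$family[idx$offtarget][kind == "mitochondria"] <- "Mitochondria"
    tax$kingdom[idx$offtarget][kind == "archaea"] <- "Archaea"
  }
  tax
}

#' Simulate exchangeable null data for calibration harnesses
#'
#' All samples are i.i.d. Dirichlet-multinomial draws from one composition;
#' group labels are random, so any test of the labels should reject at its
#' nominal rate.
#'
#' @param n_samples number of samples (>= 6).
#' @param n_asvs number of ASVs.
#' @param seed integer seed.
#' @param n_groups number of exchangeable group labels.
#' @param samples_per_bird samples per bird; labels are assigned at the bird
#'   level so bird-blocked permutation tests can be calibrated.
#' @param depth sequencing depth per sample.
#' @param precision Dirichlet precision.
#' @return list with `counts`, `labels` (per sample), `bird_id` (per
#'   sample) and `bird_labels` (per bird).
#' @export
simulate_null_pairs <- function(n_samples, n_asvs, seed, n_groups = 2,
                                samples_per_bird = 1, depth = 2000,
                                precision = 20) {
  stopifnot(n_samples >= 6, n_samples %% samples_per_bird == 0)
  set.seed(seed)
  base <- 0.93 ^ seq_len(n_asvs)
  base <- base / sum(base)
  counts <- t(vapply(seq_len(n_samples), function(i)
    stats::rmultinom(1, depth, rdirichlet1(precision * base))[, 1],
    numeric(n_asvs)))
  dimnames(counts) <- list(sprintf("S%03d", seq_len(n_samples)),
                           sprintf("ASV%03d", seq_len(n_asvs)))
  n_birds <- n_samples / samples_per_bird
  bird_id <- rep(sprintf("B%03d", seq_len(n_birds)), each = samples_per_bird)
  grp <- c("marine", "switcher", "terrestrial")[seq_len(n_groups)]
  bird_labels <- stats::setNames(
    sample(rep_len(grp, n_birds)), sprintf("B%03d", seq_len(n_birds)))
  list(counts = counts, labels = unname(bird_labels[bird_id]),
       bird_id = bird_id, bird_labels = bird_labels)
}
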