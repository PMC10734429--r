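## pipeline_cli: orchestrate the full analysis end-to-end. Stages run in
## the order filtering -> phenotyping -> alpha -> beta -> sharing ->
## trajectory -> condition; each stage draws from its own seed stream
## (stage_seed) so a staged rerun reproduces its slice of a full run.

pipeline_stages <- c("filtering", "phenotyping", "alpha", "beta",
                     "sharing", "trajectory", "condition")

#' Run the full analysis pipeline
#'
#' @param inputs either a list of file paths (`asv_table`, `taxonomy`,
#'   `metadata`, `resightings`) or an in-memory study list as returned by
#'   [simulate_study()] (elements `counts`, `taxonomy`, `metadata`,
#'   `resightings`).
#' @param config a [run_config()].
#' @param out_dir output directory for per-stage TSV/JSON results.
#' @param simulate optional [sim_config()]; when given, inputs are replaced
#'   by a synthetic study.
#' @return data.frame manifest of all written files, one stage block each.
#' @export
run_pipeline <- function(inputs = NULL, config = run_config(),
                         out_dir = tempfile("forageome_run_"),
                         simulate = NULL) {
  if (!is.null(simulate)) inputs <- simulate_study(simulate)
  state <- load_inputs(inputs)
  state$config <- config
  manifest <- list()
  for (stg in pipeline_stages) {
    res <- tryCatch(run_stage_impl(stg, state, config),
                    error = function(e)
                      stop_val("stage '%s' failed: %s", stg, conditionMessage(e)))
    state <- res$state
    manifest[[stg]] <- write_result_tables(res$results, out_dir,
                                           stage = stg, config = config)
  }
  ## persist analysis-ready state so single stages can be rerun
  save_state(state, out_dir)
  out <- do.call(rbind, manifest)
  rownames(out) <- NULL
  out
}

#' Run a single pipeline stage against a previous run's outputs
#'
#' @param stage one of `filtering`, `phenotyping`, `alpha`, `beta`,
#'   `sharing`, `trajectory`, `condition`.
#' @param out_dir directory holding a previous [run_pipeline()] run.
#' @param config the same [run_config()] used for the run.
#' @return manifest data.frame for the stage.
#' @export
run_stage <- function(stage, out_dir, config = run_config()) {
  stage <- match.arg(stage, pipeline_stages)
  state <- tryCatch(load_state(out_dir),
                    error = function(e)
                      stop_val("missing upstream artifacts in %s: %s",
                               out_dir, conditionMessage(e)))
  state$config <- config
  res <- run_stage_impl(stage, state, config)
  write_result_tables(res$results, out_dir, stage = stage, config = config)
}

load_inputs <- function(inputs) {
  if (is.null(inputs)) stop_val("no inputs given (supply paths or simulate)")
  if (is.character(inputs$asv_table %||% "")
      && length(inputs$asv_table) == 1 && !is.matrix(inputs$asv_table)) {
    list(counts = read_asv_table(inputs$asv_table),
         taxonomy = read_taxonomy(inputs$taxonomy),
         metadata = read_metadata(inputs$metadata),
         resightings = read_resightings(inputs$resightings))
  } else {
    list(counts = asv_table(inputs$counts),
         taxonomy = inputs$taxonomy,
         metadata = validate_metadata(inputs$metadata),
         resightings = inputs$resightings)
  }
}

run_stage_impl <- function(stage, state, config) {
  seed <- stage_seed(config$random_seed, stage)
  switch(stage,
         filtering = stage_filtering(state, config),
         phenotyping = stage_phenotyping(state, config),
         alpha = stage_alpha(state, config, seed),
         beta = stage_beta(state, config, seed),
         sharing = stage_sharing(state, config, seed),
         trajectory = stage_trajectory(state, config, seed),
         condition = stage_condition(state, config))
}

stage_filtering <- function(state, config) {
  if (is.null(state$counts)) stop_val("no ASV table loaded")
  pr <- prune_taxa_by_terms(state$counts, state$taxonomy)
  counts <- pr$counts
  report <- pr$report
  has_neg <- any(state$metadata$is_negative_control)
  if (has_neg) {
    contam <- identify_contaminants_prevalence(counts, state$metadata,
                                               config$prevalence_threshold)
    bad <- contam$asv_id[contam$contaminant]
    counts <- counts[, !colnames(counts) %in% bad, drop = FALSE]
    report$contaminant_asv_ids <- bad
    report$n_contaminant_asvs <- length(bad)
  } else {
    contam <- NULL
    report$contaminant_asv_ids <- character(0)
    report$n_contaminant_asvs <- 0L
  }
  neg_ids <- state$metadata$sample_id[state$metadata$is_negative_control]
  counts <- counts[!rownames(counts) %in% neg_ids, , drop = FALSE]
  fd <- filter_depth(counts, config$min_reads)
  report <- c(report, fd$report)
  message(sprintf(
    "filtering: removed %d ASV(s) by taxonomy, %d contaminant ASV(s), %d sample(s) with < %d reads",
    report$n_asvs_removed_taxonomy, report$n_contaminant_asvs,
    report$n_samples_removed_depth, config$min_reads))
  state$filtered <- fd$counts
  results <- list(filter_report = report)
  if (!is.null(contam)) results$contaminant_scores <- contam
  list(state = state, results = results)
}

stage_phenotyping <- function(state, config) {
  ## the faecal-collection observation counts as one sighting
  coll <- state$metadata[!state$metadata$is_negative_control,
                         c("bird_id", "day_of_year", "habitat_at_collection")]
  names(coll)[3] <- "habitat"
  rec <- rbind(state$resightings, coll[stats::complete.cases(coll), ])
  state$assignments <- assign_phenotypes(rec)
  list(state = state, results = list(phenotype_assignments = state$assignments))
}

stage_alpha <- function(state, config, seed) {
  need_state(state, "filtered", "assignments")
  rt <- richness_table(state$filtered, m = config$min_reads)
  state$richness <- rt
  boot <- balanced_richness_bootstrap(rt, state$metadata, state$assignments,
                                      n_iter = config$n_bootstrap, seed = seed)
  ## group contrasts on log richness via the shared mixed-model engine
  df <- merge(rt, state$metadata[c("sample_id", "bird_id")], by = "sample_id")
  df <- merge(df, state$assignments[c("bird_id", "phenotype")], by = "bird_id")
  df <- df[df$phenotype %in% phen3, ]
  df$log_richness <- log(df$richness)
  df$phenotype <- factor(df$phenotype, levels = phen3)
  fit <- fit_lmm(log_richness ~ phenotype, df, group = "bird_id",
                 method = "REML")
  coefs <- data.frame(term = names(fit$beta), estimate = unname(fit$beta),
                      se = unname(fit$se), stringsAsFactors = FALSE)
  list(state = state,
       results = list(richness = rt,
                      richness_bootstrap = boot$summary,
                      richness_model = coefs))
}

stage_beta <- function(state, config, seed) {
  need_state(state, "filtered", "assignments")
  clr <- clr_transform(state$filtered)
  terr <- state$metadata$sample_id[
    !is.na(state$metadata$habitat_at_collection) &
      state$metadata$habitat_at_collection == "terrestrial"]
  pca <- clr_pca(clr, terrestrial_samples = terr)
  state$clr <- clr
  scores <- data.frame(sample_id = rownames(pca$scores),
                       bird_id = state$metadata$bird_id[
                         match(rownames(pca$scores), state$metadata$sample_id)],
                       pc1 = pca$scores[, 1], pc2 = pca$scores[, 2],
                       stringsAsFactors = FALSE)
  state$scores <- scores
  d <- stats::dist(clr)
  phen <- sample_phenotypes(state)
  keep <- !is.na(phen)
  dsub <- as.matrix(d)[keep, keep]
  pm <- permanova(dsub, phen[keep], config$n_permutations,
                  seed = stage_seed(seed, "permanova"))
  pw <- pairwise_permanova(dsub, phen[keep], config$n_permutations,
                           seed = stage_seed(seed, "pairwise"))
  disp <- dispersion_test(dsub, phen[keep], config$n_permutations,
                          seed = stage_seed(seed, "dispersion"))
  reg <- per_bird_mean_pc1_regression(state$assignments, scores)
  list(state = state,
       results = list(
         ordination_scores = scores,
         ordination_variance = data.frame(
           pc = seq_along(pca$prop_var), prop_var = pca$prop_var),
         permanova_global = pm,
         permanova_pairwise = pw,
         dispersion_distances = disp$distances,
         dispersion_test = data.frame(F = disp$F, p = disp$p),
         dispersion_pairwise = disp$pairwise,
         pc1_prop_marine = data.frame(slope = reg$slope,
                                      intercept = reg$intercept,
                                      ci_lower = reg$conf_int[1],
                                      ci_upper = reg$conf_int[2],
                                      n_birds = reg$n_birds)))
}

stage_sharing <- function(state, config, seed) {
  need_state(state, "filtered", "assignments")
  phen <- sample_phenotypes(state)
  keep <- !is.na(phen)
  counts <- state$filtered[keep, , drop = FALSE]
  core <- core_taxa(counts, phen[keep], config$core_prevalence,
                    config$core_rel_abund)
  part <- bootstrap_share_partition(counts, state$metadata,
                                    state$assignments,
                                    n_iter = config$n_bootstrap, seed = seed)
  net <- export_bipartite_network(part$network_iteration, state$taxonomy)
  jac <- pairwise_jaccard(counts)
  jt <- jaccard_permutation_ttests(jac, state$metadata, state$assignments,
                                   n_permutations = config$n_permutations,
                                   seed = stage_seed(seed, "jaccard"))
  iv <- indval(counts, phen[keep], n_permutations = config$n_permutations,
               bird_id = state$metadata$bird_id[match(rownames(counts),
                                                      state$metadata$sample_id)],
               seed = stage_seed(seed, "indval"))
  jm <- as.matrix(jac)
  list(state = state,
       results = list(
         core_taxa = list(overall = core$overall, by_group = core$by_group),
         share_partition = part$summary,
         network_edges = net$edges,
         network_nodes = net$nodes,
         jaccard_matrix = data.frame(sample_id = rownames(jm), jm,
                                     check.names = FALSE,
                                     stringsAsFactors = FALSE),
         jaccard_tests = jt,
         indicator_values = iv[iv$p < 0.05 | rank(-iv$indval) <= 20, ]))
}

stage_trajectory <- function(state, config, seed) {
  need_state(state, "filtered", "assignments")
  if (is.null(state$clr)) state$clr <- clr_transform(state$filtered)
  stab <- individual_centroid_distances(state$clr, state$metadata,
                                        state$assignments)
  state$stability <- stab
  test <- stability_group_test(stab, n_permutations = config$n_permutations,
                               seed = seed)
  traj <- stab[c("sample_id", "bird_id", "phenotype", "day_of_year")]
  if (!is.null(state$richness))
    traj$richness <- state$richness$richness[match(traj$sample_id,
                                                   state$richness$sample_id)]
  if (!is.null(state$scores))
    traj$pc1 <- state$scores$pc1[match(traj$sample_id,
                                       state$scores$sample_id)]
  list(state = state,
       results = list(stability = stab,
                      stability_test = data.frame(F = test$F,
                                                  df_num = test$df_num,
                                                  p = test$p),
                      stability_pairwise = test$pairwise,
                      trajectory_long = traj))
}

stage_condition <- function(state, config) {
  need_state(state, "assignments")
  md <- state$metadata[!state$metadata$is_negative_control, ]
  md$phenotype <- state$assignments$phenotype[match(md$bird_id,
                                                    state$assignments$bird_id)]
  res <- api_trajectory_analysis(md)
  coefs <- data.frame(term = names(res$global_fit$beta),
                      estimate = unname(res$global_fit$beta),
                      se = unname(res$global_fit$se),
                      stringsAsFactors = FALSE)
  list(state = state,
       results = list(
         api_model_selection = res$selection$table,
         api_global_coefficients = coefs,
         api_slopes = res$slopes,
         api_interaction_lrt = data.frame(X2 = res$interaction_lrt$X2,
                                          df = res$interaction_lrt$df,
                                          p = res$interaction_lrt$p),
         api_predictions = res$predictions))
}

sample_phenotypes <- function(state) {
  bird <- state$metadata$bird_id[match(rownames(state$filtered),
                                       state$metadata$sample_id)]
  phen <- state$assignments$phenotype[match(bird, state$assignments$bird_id)]
  phen[!phen %in% phen3] <- NA
  phen
}

need_state <- function(state, ...) {
  miss <- setdiff(c(...), names(state)[!vapply(state, is.null, TRUE)])
  if (length(miss))
    stop_val("missing upstream artifact(s): %s (run earlier stages first)",
             paste(miss, collapse = ", "))
}

save_state <- function(state, out_dir) {
  write_asv_table(state$filtered, file.path(out_dir, "state_filtered.tsv"))
  for (nm in c("metadata", "resightings", "taxonomy", "assignments",
               "richness", "scores"))
    if (!is.null(state[[nm]]))
      utils::write.table(state[[nm]], file.path(out_dir,
                                                paste0("state_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

load_state <- function(out_dir) {
  f <- function(nm) file.path(out_dir, paste0("state_", nm, ".tsv"))
  if (!file.exists(f("filtered"))) stop_val("state_filtered.tsv not found")
  state <- list(filtered = read_asv_table(f("filtered")))
  for (nm in c("metadata", "resightings", "taxonomy", "assignments",
               "richness", "scores")) {
    if (!file.exists(f(nm))) next
    if (nm == "metadata") {
      ## same typing rules as read_metadata ("F" must stay character)
      df <- utils::read.delim(f(nm), stringsAsFactors = FALSE,
                              na.strings = c("NA", ""),
                              colClasses = "character")
      for (col in intersect(c("day_of_year", "api", "flock_size"), names(df)))
        df[[col]] <- as.numeric(df[[col]])
      df$is_negative_control <- as.logical(df$is_negative_control)
      state[[nm]] <- df
    } else {
      state[[nm]] <- utils::read.delim(f(nm), stringsAsFactors = FALSE,
                                       na.strings = c("NA", ""))
    }
  }
  state$counts <- state$filtered
  state
}
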