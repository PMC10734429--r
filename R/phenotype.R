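## phenotyping: assign foraging phenotypes from resighting records and
## relate per-bird habitat use to ordination position.

#' Assign foraging phenotypes from resighting records
#'
#' Birds observed at least `min_sightings` times are classified: seen on
#' both habitat types at least once -> `switcher`; seen on one habitat only
#' -> `marine` or `terrestrial` specialist. Birds below the threshold are
#' `unassigned` and excluded downstream. Duplicate same-day same-habitat
#' records are collapsed to one sighting (day-level counting), so the
#' classifier is invariant to record order and to paired-observer
#' duplication.
#'
#' @param records data.frame with `bird_id`, `day_of_year`, `habitat`
#'   (marine/terrestrial); the faecal-collection observation counts as a
#'   sighting and should be included.
#' @param min_sightings minimum sightings for assignment (default 5).
#' @return data.frame: `bird_id`, `n_sightings`, `phenotype`, `prop_marine`.
#' @export
assign_phenotypes <- function(records, min_sightings = 5) {
  stopifnot(nrow(records) > 0)
  bad <- !records$habitat %in% c("marine", "terrestrial")
  if (any(bad))
    stop_val("unknown habitat value(s): %s",
             paste(unique(records$habitat[bad]), collapse = ", "))
  key <- !duplicated(records[c("bird_id", "day_of_year", "habitat")])
  rec <- records[key, ]
  rec <- rec[order(rec$bird_id), ]
  out <- do.call(rbind, lapply(split(rec, rec$bird_id), function(r) {
    n <- nrow(r)
    n_mar <- sum(r$habitat == "marine")
    phen <- if (n < min_sightings) "unassigned"
    else if (n_mar > 0 && n_mar < n) "switcher"
    else if (n_mar == n) "marine" else "terrestrial"
    data.frame(bird_id = r$bird_id[1], n_sightings = n, phenotype = phen,
               prop_marine = n_mar / n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Regress per-bird mean PC1 on proportion of marine habitat use
#'
#' Ordinary least squares of each bird's mean first-principal-component
#' score (from the CLR ordination) on its proportion of marine sightings,
#' with a t-based 95% confidence interval on the slope. With the PC1 sign
#' convention (terrestrial-collected samples negative on average) a positive
#' slope means birds using marine sites more sit higher on PC1.
#'
#' @param assignments output of [assign_phenotypes()].
#' @param scores data.frame with `sample_id`, `bird_id` and `pc1` columns
#'   (per-sample PC1 scores).
#' @param conf confidence level.
#' @return list: `slope`, `intercept`, `conf_int` (slope CI), `se`, `n_birds`,
#'   `per_bird` (data.frame of the regression inputs), and the `lm` fit.
#' @export
per_bird_mean_pc1_regression <- function(assignments, scores, conf = 0.95) {
  mean_pc1 <- tapply(scores$pc1, scores$bird_id, mean)
  df <- data.frame(bird_id = names(mean_pc1), mean_pc1 = as.numeric(mean_pc1),
                   stringsAsFactors = FALSE)
  df <- merge(df, assignments[c("bird_id", "prop_marine", "phenotype")],
              by = "bird_id")
  df <- df[!is.na(df$prop_marine) & df$phenotype != "unassigned", ]
  if (nrow(df) < 3) stop_val("need >= 3 birds with PC1 and prop_marine")
  if (stats::sd(df$prop_marine) == 0)
    stop_val("degenerate design: all prop_marine identical")
  fit <- stats::lm(mean_pc1 ~ prop_marine, data = df)
  ci <- stats::confint(fit, "prop_marine", level = conf)
  list(slope = unname(stats::coef(fit)["prop_marine"]),
       intercept = unname(stats::coef(fit)[1]),
       conf_int = as.numeric(ci),
       se = summary(fit)$coefficients["prop_marine", "Std. Error"],
       n_birds = nrow(df), per_bird = df, fit = fit)
}
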