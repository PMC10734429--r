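## alpha_diversity (filtering half): taxon pruning, prevalence-based
## contaminant identification against negative controls, and read-depth
## filtering to analysis-ready samples.

#' Remove ASVs whose taxonomy matches exclusion terms
#'
#' An ASV is removed when any of its rank strings matches one of
#' `exclude_terms` case-insensitively (whole-string match). The defaults
#' remove chloroplast, mitochondrial and archaeal sequences.
#'
#' @param counts samples x ASVs matrix.
#' @param taxonomy data.frame as from [read_taxonomy()].
#' @param exclude_terms character vector of taxon names to remove.
#' @return list: `counts` (pruned), `report` (`n_asvs_removed_taxonomy`,
#'   `removed_asv_ids`).
#' @export
prune_taxa_by_terms <- function(counts, taxonomy,
                                exclude_terms = c("chloroplast",
                                                  "mitochondria", "archaea")) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  tax <- taxonomy[match(colnames(counts), taxonomy$asv_id), ranks, drop = FALSE]
  hit <- Reduce(`|`, lapply(tax, function(col)
    tolower(trimws(ifelse(is.na(col), "", col))) %in% tolower(exclude_terms)))
  removed <- colnames(counts)[hit]
  kept <- counts[, !hit, drop = FALSE]
  if (ncol(kept) == 0) stop_val("no ASVs left after taxonomy pruning")
  list(counts = kept,
       report = list(n_asvs_removed_taxonomy = length(removed),
                     removed_asv_ids = removed))
}

#' Identify reagent contaminants by prevalence in negative controls
#'
#' Per ASV, a 2x2 presence table (negative controls vs true samples) is
#' tested by chi-square, or by Fisher's exact test when any expected cell is
#' below 5. The p-value is the contaminant score (contaminant-like ASVs,
#' more prevalent in controls, score low). An ASV is flagged when
#' `score < threshold` *and* its control prevalence exceeds its sample
#' prevalence.
#'
#' @param counts samples x ASVs matrix including negative-control rows.
#' @param metadata data.frame with `sample_id` and `is_negative_control`.
#' @param threshold score threshold (default 0.5).
#' @return data.frame per ASV: `asv_id`, `prev_control`, `prev_sample`,
#'   `score`, `contaminant`.
#' @export
identify_contaminants_prevalence <- function(counts, metadata,
                                             threshold = 0.5) {
  is_neg <- metadata$is_negative_control[match(rownames(counts),
                                               metadata$sample_id)]
  if (anyNA(is_neg)) stop_val("metadata missing for some samples")
  if (!any(is_neg))
    stop_val("no negative controls present; skip contaminant identification explicitly")
  if (all(is_neg)) stop_val("no true samples present")
  pres <- counts > 0
  n_c <- sum(is_neg); n_s <- sum(!is_neg)
  k_c <- colSums(pres[is_neg, , drop = FALSE])
  k_s <- colSums(pres[!is_neg, , drop = FALSE])
  score <- vapply(seq_along(k_c), function(j) {
    tab <- matrix(c(k_c[j], n_c - k_c[j], k_s[j], n_s - k_s[j]), 2)
    if (sum(tab) == 0) return(1)
    expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expct < 5))
      stats::fisher.test(tab)$p.value
    else
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }, 0)
  prev_c <- k_c / n_c
  prev_s <- k_s / n_s
  data.frame(asv_id = colnames(counts),
             prev_control = unname(prev_c), prev_sample = unname(prev_s),
             score = score,
             contaminant = score < threshold & prev_c > prev_s,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Drop samples below a read-depth threshold
#'
#' Samples with *fewer than* `min_reads` total reads are removed; a sample
#' with exactly `min_reads` is retained.
#'
#' @param counts samples x ASVs matrix.
#' @param min_reads depth threshold (default 5000).
#' @return list: `counts`, `report` (`n_samples_removed_depth`,
#'   `removed_sample_ids`, `min_reads`).
#' @export
filter_depth <- function(counts, min_reads = 5000) {
  stopifnot(min_reads >= 1)
  depth <- rowSums(counts)
  drop <- depth < min_reads
  if (all(drop)) stop_val("all samples below %d reads", min_reads)
  list(counts = counts[!drop, , drop = FALSE],
       report = list(n_samples_removed_depth = sum(drop),
                     removed_sample_ids = rownames(counts)[drop],
                     min_reads = min_reads))
}
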