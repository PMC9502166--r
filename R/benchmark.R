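#' Per-sample gain in viral contig recovery
#'
#' Compares a baseline detection run with one using an augmented reference
#' database. Per sample: counts, absolute gain, and percent increase
#' `100 * (n_aug - n_base) / n_base` (absent when the baseline is empty).
#' The aggregate rows report mean and median counts of both runs and the
#' percent increase of the mean counts.
#'
#' @param baseline,augmented detection-run tables
#'   (see [read_detection_run()]).
#' @return list with `per_sample` (data.frame) and `aggregate`.
#' @export
per_sample_gain <- function(baseline, augmented) {
  samples <- sort(union(baseline$sample_id, augmented$sample_id))
  nb <- vapply(samples, function(s) sum(baseline$sample_id == s), integer(1))
  na_ <- vapply(samples, function(s) sum(augmented$sample_id == s),
                integer(1))
  pct <- ifelse(nb > 0, 100 * (na_ - nb) / nb, NA_real_)
  per_sample <- data.frame(sample_id = samples, n_baseline = nb,
                           n_augmented = na_, gain = na_ - nb,
                           pct_increase = pct, row.names = NULL,
                           stringsAsFactors = FALSE)
  aggregate <- list(
    mean_baseline = mean(nb), mean_augmented = mean(na_),
    median_baseline = median(nb), median_augmented = median(na_),
    mean_pct_increase = if (all(nb > 0)) mean(pct) else NA_real_,
    pct_increase_of_means = if (mean(nb) > 0)
      100 * (mean(na_) - mean(nb)) / mean(nb) else NA_real_)
  list(per_sample = per_sample, aggregate = aggregate)
}

#' Percent increase in recovery per contig-length bin
#'
#' Default bins straddle the 5 kb boundary most relevant to gene-content
#' detectors: `[1.5, 3)`, `[3, 5)`, `[5, 10)`, `[10, 20)`, `[20, Inf)` kb.
#'
#' @param baseline,augmented detection-run tables.
#' @param bin_edges strictly increasing lower bin edges in kb; the last bin
#'   is open-ended.
#' @return data.frame with per-bin counts and `pct_increase` (`NA` when the
#'   baseline bin is empty).
#' @export
length_binned_gain <- function(baseline, augmented,
                               bin_edges = c(1.5, 3, 5, 10, 20)) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  edges <- c(bin_edges * 1000, Inf)
  labels <- paste0("[", bin_edges, ",",
                   c(bin_edges[-1L], Inf), ")")
  binof <- function(len) cut(len, breaks = edges, labels = labels,
                             right = FALSE)
  nb <- table(binof(baseline$length))
  na_ <- table(binof(augmented$length))
  pct <- ifelse(nb > 0, 100 * (as.numeric(na_) - as.numeric(nb)) /
                  as.numeric(nb), NA_real_)
  data.frame(bin_kb = labels, n_baseline = as.integer(nb),
             n_augmented = as.integer(na_), pct_increase = pct,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Confidence-category transition table between two runs
#'
#' Full 7x7 counts of contigs moving between confidence categories
#' (category 0 = not detected in that run), plus derived percentages: per
#' baseline category, the share moving to the high-confidence categories 1-2
#' and the share undetected or downgraded.
#'
#' @param baseline,augmented detection-run tables with comparable contig ids.
#' @return list with `counts` (7x7 matrix, `from` rows 0-6, `to` columns
#'   0-6) and `derived` (data.frame per baseline category).
#' @export
category_transitions <- function(baseline, augmented) {
  ids <- union(paste(baseline$sample_id, baseline$contig_id),
               paste(augmented$sample_id, augmented$contig_id))
  catof <- function(run) {
    key <- paste(run$sample_id, run$contig_id)
    out <- setNames(rep(0L, length(ids)), ids)
    out[key] <- run$category
    out
  }
  from <- catof(baseline); to <- catof(augmented)
  counts <- table(factor(from, levels = 0:6), factor(to, levels = 0:6))
  counts <- unclass(counts)
  dimnames(counts) <- list(from = 0:6, to = 0:6)
  # low-confidence categories in the 6-category scheme are 3, 5 and 6;
  # "downgraded" = reassigned into one of them from elsewhere
  low_conf <- c(3L, 5L, 6L)
  derived <- do.call(rbind, lapply(1:6, function(k) {
    n_k <- sum(counts[k + 1L, ])
    down_cols <- as.character(c(0L, setdiff(low_conf, k)))
    data.frame(
      from_category = k, n_baseline = n_k,
      pct_to_high_confidence = if (n_k)
        100 * sum(counts[k + 1L, c("1", "2")]) / n_k else NA_real_,
      pct_undetected_or_downgraded = if (n_k)
        100 * sum(counts[k + 1L, down_cols]) / n_k else NA_real_,
      stringsAsFactors = FALSE)
  }))
  list(counts = counts, derived = derived)
}

#' Validation fractions for newly recovered contigs
#'
#' For contigs detected only with the augmented database: the fraction also
#' called viral by an independent tool at relaxed thresholds (DeepVirFinder
#' score > 0.7 and p < 0.05, or MARVEL score > 0.70; a contig with no score
#' rows fails), the fraction with 0% contamination, and the fraction with
#' at least 50% contamination.
#'
#' @param new_ids contig ids newly detected with the augmented database.
#' @param scores tool-score table covering (some of) the new contigs.
#' @param contamination data.frame (`contig_id`, `contamination_pct`).
#' @param dvf_score,dvf_p,marvel_score relaxed validation thresholds.
#' @return list of fractions (as percentages) and counts; all `NA` when
#'   `new_ids` is empty.
#' @export
validate_new_contigs <- function(new_ids, scores = NULL,
                                 contamination = NULL,
                                 dvf_score = 0.7, dvf_p = 0.05,
                                 marvel_score = 0.70) {
  n <- length(new_ids)
  if (!n)
    return(list(n_new = 0L, pct_validated = NA_real_,
                pct_zero_contamination = NA_real_,
                pct_high_contamination = NA_real_))
  pct_validated <- NA_real_
  if (!is.null(scores)) {
    s <- scores[scores$contig_id %in% new_ids, , drop = FALSE]
    pass_dvf <- s$tool == "deepvirfinder" &
      !is.na(s$score) & s$score > dvf_score &
      !is.na(s$p_value) & s$p_value < dvf_p
    pass_marvel <- s$tool == "marvel" & !is.na(s$score) &
      s$score > marvel_score
    passing_ids <- unique(s$contig_id[pass_dvf | pass_marvel])
    pct_validated <- 100 * sum(new_ids %in% passing_ids) / n
  }
  pct_zero <- pct_high <- NA_real_
  if (!is.null(contamination)) {
    cont <- contamination$contamination_pct[
      match(new_ids, contamination$contig_id)]
    pct_zero <- 100 * sum(!is.na(cont) & cont == 0) / n
    pct_high <- 100 * sum(!is.na(cont) & cont >= 50) / n
  }
  list(n_new = n, pct_validated = pct_validated,
       pct_zero_contamination = pct_zero,
       pct_high_contamination = pct_high)
}
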