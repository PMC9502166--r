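#' Threshold PSMs at a decoy-estimated FDR
#'
#' Within each sample (each independent search), PSMs are sorted by score
#' descending and `FDR(s) = #decoys(score >= s) / max(1, #targets(score >= s))`
#' is evaluated at every observed score; the cutoff is the one with
#' `FDR <= target` that keeps the most target PSMs. Decoy rows never survive.
#' The alternative estimator `2D / (T + D)` is available via `method`.
#'
#' @param psms PSM table (see [read_psms()]).
#' @param target FDR target (1% by default).
#' @param method `"decoys_over_targets"` (default) or `"two_d_over_total"`.
#' @return list with `survivors` (target PSM rows across samples) and
#'   `cutoffs` (named numeric score cutoff per sample; `Inf` when nothing
#'   survives).
#' @export
fdr_threshold <- function(psms, target = 0.01,
                          method = c("decoys_over_targets",
                                     "two_d_over_total")) {
  method <- match.arg(method)
  if (!nrow(psms))
    return(list(survivors = psms, cutoffs = setNames(numeric(), character())))
  cutoffs <- c()
  keep <- logical(nrow(psms))
  for (sid in unique(psms$sample_id)) {
    idx <- which(psms$sample_id == sid)
    sub <- psms[idx, , drop = FALSE]
    ord <- order(-sub$score)
    dec <- cumsum(sub$is_decoy[ord])
    tgt <- cumsum(!sub$is_decoy[ord])
    fdr <- switch(method,
                  decoys_over_targets = dec / pmax(1, tgt),
                  two_d_over_total = 2 * dec / pmax(1, tgt + dec))
    ok <- which(fdr <= target)
    if (!length(ok) || max(tgt[ok]) == 0L) {
      cutoffs[sid] <- Inf
      next
    }
    best <- ok[which.max(tgt[ok])]
    cutoff <- sub$score[ord][best]
    cutoffs[sid] <- cutoff
    keep[idx] <- psms$score[idx] >= cutoff & !psms$is_decoy[idx]
  }
  survivors <- psms[keep, , drop = FALSE]
  rownames(survivors) <- NULL
  list(survivors = survivors, cutoffs = cutoffs)
}

#' Map peptides to proteins and clusters by exact substring
#'
#' A peptide matches a protein when it occurs as an exact substring, with
#' isoleucine and leucine treated as equivalent on both sides when
#' `il_equivalent` (they are isobaric and indistinguishable by mass).
#' Matching runs against the dereplicated representatives and fans out to
#' duplicate members through `derep_map`, so member sequences are labeled
#' too.
#'
#' @param peptides character vector of peptide sequences.
#' @param proteins protein table (dereplicated representatives, or the full
#'   set when `derep_map` is `NULL`).
#' @param membership optional data.frame (`cluster_id`, `member_id`) used to
#'   report matched clusters.
#' @param derep_map optional data.frame (`member_id`, `representative_id`).
#' @param il_equivalent treat I and L as the same residue.
#' @return data.frame with columns `peptide`, `matched_protein_ids`,
#'   `matched_cluster_ids` (comma-joined; empty string when none).
#' @export
map_peptides <- function(peptides, proteins, membership = NULL,
                         derep_map = NULL, il_equivalent = TRUE) {
  norm <- function(x) if (il_equivalent) chartr("I", "L", toupper(x))
                      else toupper(x)
  seqs <- norm(proteins$sequence)
  peptides <- unique(as.character(peptides))
  fanout <- if (!is.null(derep_map))
    split(derep_map$member_id, derep_map$representative_id) else NULL
  res <- lapply(peptides, function(pep) {
    hit <- proteins$id[grepl(norm(pep), seqs, fixed = TRUE)]
    if (!is.null(fanout))
      hit <- sort(unique(unlist(c(hit, fanout[hit]), use.names = FALSE)))
    clusters <- if (!is.null(membership))
      sort(unique(membership$cluster_id[membership$member_id %in% hit]))
    else character()
    data.frame(peptide = pep,
               matched_protein_ids = paste(hit, collapse = ","),
               matched_cluster_ids = paste(clusters, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Annotate peptide-matched clusters as virion-associated
#'
#' Every cluster recruited by at least one surviving peptide gains
#' `virion_associated = TRUE`. The statistics report: the fraction of
#' clusters matched; among matched clusters, how many had no prior
#' informative annotation (the de-novo virion-associated set); and among
#' matched clusters with a prior annotation, the fraction whose annotation
#' is not structural (the discordance between mass-spec evidence and
#' database annotation).
#'
#' @param matches result of [map_peptides()].
#' @param annotations list of `cluster_annotation` objects.
#' @return list with `annotations` (updated) and `stats`.
#' @export
annotate_virion <- function(matches, annotations) {
  matched <- unique(unlist(strsplit(
    matches$matched_cluster_ids[nzchar(matches$matched_cluster_ids)], ",")))
  known <- names(annotations)
  unknown <- setdiff(matched, known)
  if (length(unknown))
    message(length(unknown), " matched cluster(s) unknown to the ",
            "annotation set skipped")
  matched <- intersect(matched, known)
  for (cid in matched) annotations[[cid]]$virion_associated <- TRUE
  prior <- vapply(annotations[matched], `[[`, TRUE, "previously_annotated")
  structural <- vapply(annotations[matched], `[[`, TRUE, "structural")
  n_matched <- length(matched)
  n_denovo <- sum(!prior)
  n_prior <- sum(prior)
  stats <- list(
    n_clusters = length(annotations),
    n_matched = n_matched,
    frac_matched = if (length(annotations))
      n_matched / length(annotations) else NA_real_,
    n_denovo = n_denovo,
    frac_denovo_of_matched = if (n_matched) n_denovo / n_matched
                             else NA_real_,
    n_matched_with_prior = n_prior,
    frac_discordant = if (n_prior) sum(prior & !structural) / n_prior
                      else NA_real_)
  list(annotations = annotations, stats = stats)
}
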