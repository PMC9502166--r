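#' Default viral-keyword whitelist for the prokaryotic-identity filter
#'
#' Reference hits whose annotation contains one of these words
#' (case-insensitive substring) do not count as evidence of prokaryotic
#' origin, even above the identity threshold.
#'
#' @export
VIRAL_KEYWORDS <- c("tail", "capsid", "portal", "virus", "virion", "viral",
                    "phage", "bacteriophage", "terminase")

#' Flag proteins with strong local identity to prokaryotic references
#'
#' A protein is flagged for removal iff any of its reference hits has percent
#' identity strictly above `min_pident` (no coverage requirement, all hits
#' considered), unless that hit's subject annotation contains a whitelisted
#' viral keyword. Each disqualifying hit must be excepted on its own: a
#' protein with one whitelisted and one non-whitelisted >95% hit is removed.
#'
#' @param hits annotated reference-search hits (see
#'   [read_blast_tab()] with `annotated = TRUE`).
#' @param whitelist viral keyword vector; matched case-insensitively as
#'   substrings of the subject annotation.
#' @param min_pident identity threshold (percent, strict inequality).
#' @return character vector of protein ids to remove.
#' @export
flag_prokaryotic <- function(hits, whitelist = VIRAL_KEYWORDS,
                             min_pident = 95) {
  if (!nrow(hits)) return(character())
  if (all(is.na(hits$subject_annotation)))
    stop("reference-search hits must carry a subject_annotation column")
  strong <- hits$pident > min_pident
  ann <- tolower(ifelse(is.na(hits$subject_annotation), "",
                        hits$subject_annotation))
  excepted <- Reduce(`|`, lapply(tolower(whitelist), function(kw)
    grepl(kw, ann, fixed = TRUE)), init = logical(nrow(hits)))
  sort(unique(hits$query_id[strong & !excepted]))
}

#' Dereplicate proteins at 100% identity
#'
#' Full-length exact sequence equality (after the ingest normalization:
#' uppercase, trailing stop stripped) defines duplicates; the first-seen id
#' becomes the representative. Idempotent.
#'
#' @param proteins protein table.
#' @return list with `map` (data.frame `member_id`, `representative_id`),
#'   `unique_count` and `duplicate_count`.
#' @export
dereplicate <- function(proteins) {
  if (!nrow(proteins))
    return(list(map = data.frame(member_id = character(),
                                 representative_id = character(),
                                 stringsAsFactors = FALSE),
                unique_count = 0L, duplicate_count = 0L))
  first <- !duplicated(proteins$sequence)
  reps <- proteins$id[first]
  rep_of <- setNames(reps, proteins$sequence[first])
  map <- data.frame(member_id = proteins$id,
                    representative_id = unname(rep_of[proteins$sequence]),
                    stringsAsFactors = FALSE)
  list(map = map, unique_count = sum(first),
       duplicate_count = sum(!first))
}

#' Filter and dereplicate a tier's protein set
#'
#' @param proteins protein table.
#' @param ref_hits annotated reference hits.
#' @param whitelist viral keyword whitelist.
#' @return list with `kept` (protein table of unique survivors), `removed`
#'   (flagged ids), and `derep` (the dereplication result).
#' @export
filter_proteins <- function(proteins, ref_hits,
                            whitelist = VIRAL_KEYWORDS) {
  removed <- flag_prokaryotic(ref_hits, whitelist)
  surv <- proteins[!proteins$id %in% removed, , drop = FALSE]
  derep <- dereplicate(surv)
  kept <- surv[surv$id %in% derep$map$representative_id[
    derep$map$member_id == derep$map$representative_id], , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed, derep = derep)
}
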