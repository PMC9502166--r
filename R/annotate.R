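#' Is a description informative?
#'
#' Uninformative descriptions are empty, or contain (case-insensitively)
#' "uncharacterized", "hypothetical", "no annotation", or a DUF token (duf
#' followed by digits or a word boundary, short for domain of unknown
#' function).
#'
#' @param description character vector.
#' @return logical vector.
#' @export
is_informative <- function(description) {
  d <- tolower(ifelse(is.na(description), "", description))
  nzchar(trimws(d)) &
    !grepl("uncharacterized", d, fixed = TRUE) &
    !grepl("hypothetical", d, fixed = TRUE) &
    !grepl("no annotation", d, fixed = TRUE) &
    !grepl("\\bduf(\\d|\\b)", d)
}

# structural keyword sets: long keywords are plain substrings; short or
# ambiguous ones ("mu", "gp9", ...) match at word boundaries only, to avoid
# e.g. "murein" firing on "mu" (a documented divergence from a plain
# substring search, toggleable via word_boundary = FALSE)
STRUCTURAL_SUBSTRINGS <- c("capsid", "virion", "fiber", "sheath", "spike",
                           "baseplate", "structur")
STRUCTURAL_WORDS <- c("coat", "head", "neck", "mu", "tail", "gp23", "gp9")

#' Does an informative description name a virion structural role?
#'
#' Matches the structural keyword vocabulary (coat, capsid, virion, head,
#' neck, mu, fiber, tail, sheath, structur*, spike, baseplate, gp23, gp9),
#' case-insensitively. `structur` is a prefix wildcard; short keywords match
#' at word boundaries unless `word_boundary = FALSE` (pure substring mode).
#'
#' @param description character vector (intended for informative
#'   descriptions).
#' @param word_boundary use word-boundary matching for short keywords.
#' @return logical vector.
#' @export
is_structural <- function(description, word_boundary = TRUE) {
  d <- tolower(ifelse(is.na(description), "", description))
  hit <- Reduce(`|`, lapply(STRUCTURAL_SUBSTRINGS, function(kw)
    grepl(kw, d, fixed = TRUE)), init = logical(length(d)))
  short <- if (word_boundary)
    Reduce(`|`, lapply(STRUCTURAL_WORDS, function(kw)
      grepl(paste0("\\b", kw, "\\b"), d)), init = logical(length(d)))
  else
    Reduce(`|`, lapply(STRUCTURAL_WORDS, function(kw)
      grepl(kw, d, fixed = TRUE)), init = logical(length(d)))
  hit | short
}

normalize_description <- function(d) {
  d <- tolower(ifelse(is.na(d), "", d))
  d <- gsub("[[:punct:]]", " ", d)
  trimws(gsub("\\s+", " ", d))
}

#' Collapse per-protein annotations to per-cluster annotations
#'
#' For each cluster: `detailed` lists every unique (source db, description)
#' with its member count; `consensus` lists normalized descriptions
#' (lowercased, punctuation stripped) supported by at least `min_dbs`
#' distinct source databases; `previously_annotated` is true when any member
#' carries an informative description in any database, and `structural` when
#' any informative description matches the structural vocabulary. Records for
#' proteins outside the membership are skipped with a message.
#'
#' @param records annotation table (see [read_annotations()]).
#' @param membership data.frame (`cluster_id`, `member_id`).
#' @param min_dbs databases required to agree for a consensus description.
#' @return list of per-cluster annotation objects (class
#'   `cluster_annotation`), named by cluster id; every cluster in
#'   `membership` is present.
#' @export
collapse_cluster <- function(records, membership, min_dbs = 2L) {
  unknown <- !records$protein_id %in% membership$member_id
  if (any(unknown)) {
    message(sum(unknown), " annotation record(s) for unknown proteins ",
            "skipped")
    records <- records[!unknown, , drop = FALSE]
  }
  records$cluster_id <- membership$cluster_id[
    match(records$protein_id, membership$member_id)]
  out <- list()
  for (cid in unique(membership$cluster_id)) {
    rec <- records[records$cluster_id == cid, , drop = FALSE]
    n_prot <- sum(membership$cluster_id == cid)
    detailed <- if (nrow(rec)) {
      agg <- stats::aggregate(rec$protein_id,
                              by = list(source_db = rec$db,
                                        description = rec$description),
                              FUN = function(x) length(unique(x)))
      names(agg)[3L] <- "count"
      agg <- agg[order(agg$source_db, agg$description), , drop = FALSE]
      rownames(agg) <- NULL
      agg
    } else {
      data.frame(source_db = character(), description = character(),
                 count = integer(), stringsAsFactors = FALSE)
    }
    inform <- rec$description[is_informative(rec$description)]
    norm <- normalize_description(rec$description)
    db_per_desc <- tapply(rec$db, norm, function(x) length(unique(x)))
    consensus <- sort(names(db_per_desc)[db_per_desc >= min_dbs &
                                           nzchar(names(db_per_desc))])
    out[[cid]] <- structure(list(
      cluster_id = cid, n_proteins = n_prot, detailed = detailed,
      consensus = consensus,
      previously_annotated = length(inform) > 0L,
      structural = any(is_structural(inform)),
      virion_associated = FALSE), class = "cluster_annotation")
  }
  out
}

#' Summarize annotation coverage against cluster sizes
#'
#' Counts clusters annotated by any database and by each single database, and
#' compares cluster sizes between annotated and unannotated groups (medians
#' and a two-sided Mann-Whitney U test; the test is skipped with a note when
#' a group is empty).
#'
#' @param annotations list of `cluster_annotation` objects.
#' @param cluster_sizes named integer vector of cluster sizes covering all
#'   clusters.
#' @return list with `n_annotated_any`, `per_db` counts, `median_annotated`,
#'   `median_unannotated`, `p_value` (NA when skipped) and `note`.
#' @export
annotation_summary <- function(annotations, cluster_sizes) {
  ids <- vapply(annotations, `[[`, "", "cluster_id")
  if (!all(ids %in% names(cluster_sizes)))
    stop("cluster_sizes must cover all clusters")
  annotated <- vapply(annotations, `[[`, TRUE, "previously_annotated")
  per_db <- vapply(c("kegg", "uniref90", "pfam", "vogdb"), function(db)
    sum(vapply(annotations, function(a) {
      d <- a$detailed
      any(d$source_db == db & is_informative(d$description))
    }, TRUE)), integer(1))
  sz_ann <- as.numeric(cluster_sizes[ids[annotated]])
  sz_un <- as.numeric(cluster_sizes[ids[!annotated]])
  note <- NA_character_
  p <- NA_real_
  if (length(sz_ann) && length(sz_un)) {
    p <- stats::wilcox.test(sz_ann, sz_un, exact = FALSE)$p.value
  } else {
    note <- "one group empty; size test skipped"
  }
  list(n_clusters = length(annotations),
       n_annotated_any = sum(annotated),
       per_db = per_db,
       median_annotated = if (length(sz_ann)) median(sz_ann) else NA_real_,
       median_unannotated = if (length(sz_un)) median(sz_un) else NA_real_,
       p_value = p, note = note)
}

#' Flatten cluster annotations to the companion-metadata table
#'
#' @param annotations list of `cluster_annotation` objects.
#' @return data.frame with one row per cluster (detailed annotations joined
#'   as `db:description (count)` strings, consensus `;`-joined).
#' @export
annotation_table <- function(annotations) {
  do.call(rbind, lapply(annotations, function(a) {
    d <- a$detailed
    data.frame(
      cluster_id = a$cluster_id, n_proteins = a$n_proteins,
      detailed = paste(sprintf("%s:%s (%d)", d$source_db, d$description,
                               d$count), collapse = "; "),
      consensus = paste(a$consensus, collapse = "; "),
      previously_annotated = a$previously_annotated,
      structural = a$structural,
      virion_associated = a$virion_associated,
      stringsAsFactors = FALSE, row.names = NULL)
  }))
}
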