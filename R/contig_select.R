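#' Length filter for viral contigs
#'
#' Linear contigs must be at least 5 kb; circular contigs (complete genomes
#' recovered as circles) at least 1.5 kb.
#'
#' @param contigs contig table (see [contig_table()]).
#' @param min_linear,min_circular length thresholds in bp.
#' @return logical vector, one per contig.
#' @export
passes_length <- function(contigs, min_linear = 5000L, min_circular = 1500L) {
  bad <- !contigs$topology %in% c("linear", "circular")
  if (any(bad))
    stop("unknown topology for contig(s): ",
         paste(head(contigs$id[bad], 5), collapse = ", "))
  ifelse(contigs$topology == "linear",
         contigs$length >= min_linear,
         contigs$length >= min_circular)
}

#' Per-tool stringency filter
#'
#' Applies the strictest per-tool cut-offs: VirSorter category 1,
#' DeepVirFinder score > 0.9 and p-value < 0.05, MARVEL score > 0.90.
#' Both score inequalities are strict.
#'
#' @param scores tool-score table (see [read_tool_scores()]).
#' @return logical vector, one per row.
#' @export
passes_stringency <- function(scores) {
  n <- nrow(scores)
  out <- logical(n)
  for (i in seq_len(n)) {
    tool <- scores$tool[i]
    out[i] <- switch(tool,
      virsorter = {
        if (is.na(scores$category[i]))
          stop("parse error [virsorter_missing_category]: contig ",
               scores$contig_id[i])
        scores$category[i] == 1L
      },
      deepvirfinder = {
        if (is.na(scores$score[i]) || is.na(scores$p_value[i]))
          stop("parse error [deepvirfinder_missing_score_or_p]: contig ",
               scores$contig_id[i])
        scores$score[i] > 0.9 && scores$p_value[i] < 0.05
      },
      marvel = {
        if (is.na(scores$score[i]))
          stop("parse error [marvel_missing_score]: contig ",
               scores$contig_id[i])
        scores$score[i] > 0.90
      },
      stop("parse error [unknown_tool]: ", tool))
  }
  out
}

#' Assign consensus tiers from per-contig passing tools
#'
#' Contigs called viral at the strict cut-off by all three tools form the
#' `unanimous` tier; by at least two, the `majority` tier (a superset of
#' `unanimous`); fewer than two, `none`. Duplicate conflicting rows for one
#' (contig, tool) are resolved most-permissively (the tool counts as passing
#' if any of its rows passes) with a warning.
#'
#' @param scores tool-score table restricted to length-passing contigs.
#' @param contig_ids ids to report tiers for; defaults to ids seen in
#'   `scores`.
#' @return data.frame with columns `contig_id`, `tier`
#'   (`none`/`majority`/`unanimous`), `n_tools`, `passing_tools`
#'   (comma-separated).
#' @export
assign_tier <- function(scores, contig_ids = NULL) {
  if (is.null(contig_ids)) contig_ids <- sort(unique(scores$contig_id))
  dup <- duplicated(scores[c("contig_id", "tool")])
  if (any(dup))
    warning("duplicate (contig, tool) score rows resolved ",
            "most-permissively for: ",
            paste(unique(scores$contig_id[dup]), collapse = ", "))
  pass <- passes_stringency(scores)
  passing <- unique(scores[pass, c("contig_id", "tool")])
  tools_by_contig <- split(passing$tool, passing$contig_id)
  n_tools <- vapply(contig_ids, function(id) {
    length(tools_by_contig[[id]])
  }, integer(1))
  tier <- ifelse(n_tools == 3L, "unanimous",
                 ifelse(n_tools == 2L, "majority", "none"))
  ptools <- vapply(contig_ids, function(id) {
    paste(sort(tools_by_contig[[id]]), collapse = ",")
  }, character(1))
  data.frame(contig_id = contig_ids, tier = tier, n_tools = n_tools,
             passing_tools = ptools, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Excise host-typed regions from a contig
#'
#' Viral-typed spans become child contigs (ids suffixed `_<region index>`),
#' host spans are removed. Children inherit `topology = "linear"` because
#' excision breaks any circle. A contig with no region rows passes through
#' unchanged; an entirely host-typed contig yields no children.
#'
#' @param contigs contig table.
#' @param regions region table (see [read_regions()]); may cover a subset of
#'   contigs.
#' @return contig table of surviving (possibly trimmed) contigs with
#'   provenance columns `parent_id`, `parent_start`, `parent_end`.
#' @export
trim_contamination <- function(contigs, regions) {
  out <- list()
  reg_by_contig <- split(regions, regions$contig_id)
  for (i in seq_len(nrow(contigs))) {
    cid <- contigs$id[i]
    reg <- reg_by_contig[[cid]]
    if (is.null(reg)) {
      row <- contigs[i, c("id", "sequence", "topology", "length")]
      row$parent_id <- cid; row$parent_start <- 1L
      row$parent_end <- contigs$length[i]
      out[[length(out) + 1L]] <- row
      next
    }
    L <- contigs$length[i]
    if (any(reg$start < 1L | reg$end > L | reg$start > reg$end))
      stop("region outside contig bounds for ", cid)
    if (any(reg$start[-1L] <= reg$end[-nrow(reg)]))
      stop("overlapping regions for ", cid)
    viral <- reg[reg$region_type == "viral", , drop = FALSE]
    for (j in seq_len(nrow(viral))) {
      child_seq <- substr(contigs$sequence[i], viral$start[j], viral$end[j])
      child_id <- if (nrow(reg) == 1L && viral$start[j] == 1L &&
                      viral$end[j] == L) cid else
        paste0(cid, "_", which(reg$start == viral$start[j]))
      out[[length(out) + 1L]] <- data.frame(
        id = child_id, sequence = child_seq,
        topology = if (nrow(reg) == 1L && viral$start[j] == 1L &&
                       viral$end[j] == L) contigs$topology[i] else "linear",
        length = nchar(child_seq), parent_id = cid,
        parent_start = viral$start[j], parent_end = viral$end[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(id = character(), sequence = character(),
                      topology = character(), length = integer(),
                      parent_id = character(), parent_start = integer(),
                      parent_end = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select high-confidence viral contigs
#'
#' Full selection driver: apply the length filter, compute per-tool passes
#' and consensus tiers, trim contamination on tiered contigs, and re-apply
#' the length filter to trimmed children (so sub-threshold fragments never
#' reach clustering).
#'
#' @param contigs contig table.
#' @param scores tool-score table.
#' @param regions optional contamination region table.
#' @return list with `tiers` (tier per input contig id) and `contigs`
#'   (surviving trimmed contig table with a `tier` column).
#' @export
select_contigs <- function(contigs, scores, regions = NULL) {
  keep <- passes_length(contigs)
  pool <- contigs[keep, , drop = FALSE]
  tiers <- assign_tier(scores[scores$contig_id %in% pool$id, , drop = FALSE],
                       contig_ids = pool$id)
  tiered <- pool[tiers$tier[match(pool$id, tiers$contig_id)] != "none", ,
                 drop = FALSE]
  trimmed <- if (is.null(regions)) {
    t0 <- tiered[c("id", "sequence", "topology", "length")]
    t0$parent_id <- t0$id; t0$parent_start <- 1L; t0$parent_end <- t0$length
    t0
  } else {
    trim_contamination(tiered, regions[regions$contig_id %in% tiered$id, ,
                                       drop = FALSE])
  }
  trimmed <- trimmed[passes_length(trimmed), , drop = FALSE]
  trimmed$tier <- tiers$tier[match(trimmed$parent_id, tiers$contig_id)]
  rownames(trimmed) <- NULL
  list(tiers = tiers, contigs = trimmed)
}
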