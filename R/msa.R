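#' Align the sequences of one protein cluster
#'
#' Two backends. `builtin` is a deterministic center-star progressive
#' aligner: the center sequence maximizes the summed global pairwise
#' alignment score (BLOSUM62, affine gaps, open -11 / extend -1) against all
#' others, every other sequence is aligned globally to the center, and the
#' pairwise alignments are merged under the once-a-gap-always-a-gap rule.
#' Rows are sorted by id first, so the result is invariant to input order.
#' `external` shells out to a multiple aligner (by default `muscle
#' -maxiters 4`, the accuracy/speed balance used for family databases) and
#' parses its FASTA alignment.
#'
#' @param proteins protein table with at least `id` and `sequence`; two or
#'   more rows required.
#' @param backend `"builtin"` or `"external"`.
#' @param cluster_id identifier stored on the alignment.
#' @param exe,args external aligner command and arguments (alignment read
#'   from stdout).
#' @return object of class `msa`: list with `cluster_id`, `ids`, `rows`
#'   (gapped strings, gap symbol `-`), `n_cols`.
#' @export
align_cluster <- function(proteins, backend = c("builtin", "external"),
                          cluster_id = "cluster",
                          exe = "muscle", args = c("-maxiters", "4")) {
  backend <- match.arg(backend)
  if (nrow(proteins) < 2L)
    stop("alignment requires at least 2 sequences")
  ord <- order(proteins$id)
  ids <- proteins$id[ord]
  seqs <- toupper(proteins$sequence[ord])
  if (backend == "external") {
    rows <- run_external_aligner(ids, seqs, exe, args)
  } else {
    rows <- center_star_align(ids, seqs)
  }
  rows <- chartr(".", "-", rows)
  new_msa(cluster_id, ids, rows)
}

new_msa <- function(cluster_id, ids, rows) {
  n_cols <- unique(nchar(rows))
  if (length(n_cols) != 1L) stop("alignment rows differ in length")
  structure(list(cluster_id = cluster_id, ids = ids, rows = rows,
                 n_cols = n_cols), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("alignment ", x$cluster_id, ": ", length(x$rows), " rows x ",
      x$n_cols, " columns\n", sep = "")
  invisible(x)
}

run_external_aligner <- function(ids, seqs, exe, args) {
  if (Sys.which(exe) == "")
    stop("external aligner '", exe, "' not found on PATH; use ",
         "backend = \"builtin\" for the native center-star aligner")
  tf <- tempfile(fileext = ".faa")
  on.exit(unlink(tf))
  writeLines(paste0(">", ids, "\n", seqs), tf)
  out <- system2(exe, c(args, tf), stdout = TRUE, stderr = FALSE)
  aln <- parse_fasta_lines(out)
  if (!setequal(names(aln), ids))
    stop("external aligner did not return all input sequences")
  unname(aln[ids])
}

parse_fasta_lines <- function(lines) {
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in aligner output")
  grp <- cumsum(hdr)
  ids <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  setNames(toupper(seqs), ids)
}

# deterministic center-star progressive alignment
center_star_align <- function(ids, seqs) {
  n <- length(seqs)
  aa <- Biostrings::AAStringSet(seqs)
  pair_score <- function(i, j)
    Biostrings::pairwiseAlignment(
      aa[[i]], aa[[j]], type = "global",
      substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 1, scoreOnly = TRUE)
  total <- numeric(n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j) total[i] <- total[i] + pair_score(i, j)
  center <- order(-total, ids)[1L]
  L <- nchar(seqs[center])
  others <- setdiff(seq_len(n), center)
  # ins[[i]][p+1] = gap columns inserted after center residue p (p = 0..L)
  ins <- vector("list", n)
  gapped_center <- gapped_other <- vector("list", n)
  for (i in others) {
    pa <- Biostrings::pairwiseAlignment(
      aa[[center]], aa[[i]], type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1)
    cstr <- as.character(Biostrings::alignedPattern(pa))
    ostr <- as.character(Biostrings::alignedSubject(pa))
    gapped_center[[i]] <- cstr
    gapped_other[[i]] <- ostr
    ins[[i]] <- insertion_profile(cstr, L)
  }
  master <- integer(L + 1L)
  for (i in others) master <- pmax(master, ins[[i]])
  rows <- character(n)
  rows[center] <- expand_by_insertions(seqs[center], integer(L) * 0L + 0L,
                                       master, L)
  for (i in others)
    rows[i] <- expand_other(gapped_center[[i]], gapped_other[[i]],
                            ins[[i]], master, L)
  rows
}

# number of gap columns in a gapped center string after each center residue
insertion_profile <- function(gapped_center, L) {
  chars <- strsplit(gapped_center, "")[[1]]
  prof <- integer(L + 1L)
  pos <- 0L
  for (ch in chars) {
    if (ch == "-") prof[pos + 1L] <- prof[pos + 1L] + 1L
    else pos <- pos + 1L
  }
  stopifnot(pos == L)
  prof
}

expand_by_insertions <- function(seq, own_prof, master, L) {
  chars <- strsplit(seq, "")[[1]]
  out <- character(0)
  out <- c(out, rep("-", master[1L]))
  for (p in seq_len(L))
    out <- c(out, chars[p], rep("-", master[p + 1L]))
  paste(out, collapse = "")
}

# re-pad a pairwise-aligned row to the master insertion profile
expand_other <- function(gapped_center, gapped_other, own_prof, master, L) {
  cch <- strsplit(gapped_center, "")[[1]]
  och <- strsplit(gapped_other, "")[[1]]
  segs <- vector("list", L + 1L)   # other-row chars in each insertion slot
  resid <- character(L)            # other-row char aligned to center residue
  pos <- 0L
  for (k in seq_along(cch)) {
    if (cch[k] == "-") segs[[pos + 1L]] <- c(segs[[pos + 1L]], och[k])
    else { pos <- pos + 1L; resid[pos] <- och[k] }
  }
  out <- character(0)
  pad <- function(slot, width) {
    s <- segs[[slot]]
    c(s, rep("-", width - length(s)))
  }
  out <- c(out, pad(1L, master[1L]))
  for (p in seq_len(L))
    out <- c(out, resid[p], pad(p + 1L, master[p + 1L]))
  paste(out, collapse = "")
}
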