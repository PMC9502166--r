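# HMMER3 flat-file serialization. Probabilities are stored as negative
# natural logs with 5 decimals; `*` encodes probability zero. Only the
# fields this package sets are written (no statistical calibration lines);
# the result is a valid, uncalibrated HMMER3/f ASCII database.

fmt_prob <- function(p) {
  ifelse(p <= 0, "*", sprintf("%.5f", pmax(-log(pmin(p, 1)), 0)))
}

parse_prob <- function(tok) {
  out <- numeric(length(tok))
  num <- tok != "*"
  out[num] <- exp(-as.numeric(tok[num]))
  out
}

#' Write profile HMMs to a HMMER3 ASCII flat file
#'
#' Concatenates one HMMER3/f text record per profile (header, NAME, LENG,
#' ALPH amino, model lines, `//` terminator). The file is parseable back by
#' [read_hmm_db()] with round-trip probability error below 1e-4, and by
#' standard HMMER3 tooling as an uncalibrated model database.
#'
#' @param profiles list of `profile_hmm` objects with unique names.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hmm_db <- function(profiles, path) {
  if (inherits(profiles, "profile_hmm")) profiles <- list(profiles)
  nms <- vapply(profiles, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate profile names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  for (p in profiles) {
    validate_profile(p, tol = 1e-6)
    writeLines(format_hmm_record(p), con)
  }
  invisible(path)
}

format_hmm_record <- function(p) {
  lines <- c(
    "HMMER3/f [3.1b2 | February 2015]",
    paste0("NAME  ", p$name),
    paste0("LENG  ", p$K),
    "ALPH  amino",
    "RF    no",
    "MM    no",
    "CONS  yes",
    "CS    no",
    "MAP   no",
    paste0("NSEQ  ", p$n_seqs),
    sprintf("EFFN  %.6f", p$n_seqs),
    paste0("HMM     ",
           paste(sprintf("%8s", AMINO_ALPHABET), collapse = " ")),
    paste0("        ",
           paste(sprintf("%8s",
                         c("m->m", "m->i", "m->d", "i->m", "i->i",
                           "d->m", "d->d")), collapse = " ")))
  emit <- function(x) paste(sprintf("%8s", fmt_prob(x)), collapse = " ")
  # node 0: COMPO-style background line omitted; insert-0 emissions and
  # begin transitions
  lines <- c(lines,
             sprintf("  COMPO  %s", emit(p$background)),
             sprintf("         %s", emit(p$insert_emissions[1L, ])),
             sprintf("         %s", emit(p$transitions[1L, ])))
  for (k in seq_len(p$K)) {
    cons <- AMINO_ALPHABET[which.max(p$match_emissions[k, ])]
    lines <- c(lines,
               sprintf("%7d  %s %6s %s %s %s %s", k,
                       emit(p$match_emissions[k, ]), "-",
                       tolower(cons), "-", "-", "-"),
               sprintf("         %s", emit(p$insert_emissions[k + 1L, ])),
               sprintf("         %s", emit(p$transitions[k + 1L, ])))
  }
  c(lines, "//")
}

#' Read a HMMER3 ASCII flat file of profile HMMs
#'
#' Parses the subset of the HMMER3/f dialect written by [write_hmm_db()]
#' (also tolerant of `hmmbuild` output: annotation columns after the match
#' emissions and STATS/DATE/CKSUM header lines are ignored).
#'
#' @param path flat-file path.
#' @return list of `profile_hmm` objects.
#' @export
read_hmm_db <- function(path) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "//")))
  out <- list()
  for (rec in recs) {
    rec <- rec[rec != "//" & nzchar(trimws(rec))]
    if (!length(rec)) next
    out[[length(out) + 1L]] <- parse_hmm_record(rec)
  }
  out
}

parse_hmm_record <- function(rec) {
  hdr_val <- function(key) {
    ln <- grep(paste0("^", key, "\\s"), rec, value = TRUE)
    if (!length(ln)) return(NA_character_)
    trimws(sub(paste0("^", key, "\\s+"), "", ln[1L]))
  }
  name <- hdr_val("NAME")
  K <- as.integer(hdr_val("LENG"))
  n_seqs <- suppressWarnings(as.integer(hdr_val("NSEQ")))
  if (is.na(name) || is.na(K)) stop("malformed HMM record (NAME/LENG)")
  if (!identical(hdr_val("ALPH"), "amino"))
    stop("only the amino alphabet is supported")
  body_start <- grep("^HMM\\s", rec)[1L] + 2L   # skip transition header
  body <- rec[body_start:length(rec)]
  toks <- lapply(strsplit(trimws(body), "\\s+"), identity)
  i <- 1L
  bg <- background_frequencies()
  if (toks[[i]][1L] == "COMPO") {
    bg <- setNames(parse_prob(toks[[i]][2:21]), AMINO_ALPHABET)
    i <- i + 1L
  }
  insert_emissions <- matrix(0, K + 1L, 20L,
                             dimnames = list(NULL, AMINO_ALPHABET))
  match_emissions <- matrix(0, K, 20L,
                            dimnames = list(NULL, AMINO_ALPHABET))
  transitions <- matrix(0, K + 1L, 7L,
                        dimnames = list(NULL, c("MM", "MI", "MD", "IM",
                                                "II", "DM", "DD")))
  insert_emissions[1L, ] <- parse_prob(toks[[i]][1:20]); i <- i + 1L
  transitions[1L, ] <- parse_prob(toks[[i]][1:7]); i <- i + 1L
  for (k in seq_len(K)) {
    stopifnot(as.integer(toks[[i]][1L]) == k)
    match_emissions[k, ] <- parse_prob(toks[[i]][2:21]); i <- i + 1L
    insert_emissions[k + 1L, ] <- parse_prob(toks[[i]][1:20]); i <- i + 1L
    transitions[k + 1L, ] <- parse_prob(toks[[i]][1:7]); i <- i + 1L
  }
  renorm <- function(m) m / rowSums(m)
  tr <- transitions
  tr[, c("MM", "MI", "MD")] <- renorm(tr[, c("MM", "MI", "MD"), drop = FALSE])
  tr[, c("IM", "II")] <- renorm(tr[, c("IM", "II"), drop = FALSE])
  tr[, c("DM", "DD")] <- renorm(tr[, c("DM", "DD"), drop = FALSE])
  structure(list(name = name, K = K,
                 match_emissions = renorm(match_emissions),
                 insert_emissions = renorm(insert_emissions),
                 transitions = tr,
                 background = bg / sum(bg),
                 n_seqs = if (is.na(n_seqs)) NA_integer_ else n_seqs),
            class = "profile_hmm")
}

#' Build, align and serialize profiles for every cluster
#'
#' Convenience driver from a cluster membership table and a protein table to
#' a profile-HMM flat file: aligns each cluster with [align_cluster()],
#' assigns match columns, builds the profile and writes the database.
#'
#' @param membership data.frame (`cluster_id`, `member_id`).
#' @param proteins protein table covering all members.
#' @param path output flat-file path.
#' @param backend alignment backend, see [align_cluster()].
#' @param symfrac match-column threshold.
#' @return list of `profile_hmm` objects, invisibly (the file is written).
#' @export
build_hmm_db <- function(membership, proteins, path,
                         backend = "builtin", symfrac = 0.5) {
  profiles <- list()
  for (cid in unique(membership$cluster_id)) {
    ids <- membership$member_id[membership$cluster_id == cid]
    sub <- proteins[match(ids, proteins$id), , drop = FALSE]
    if (anyNA(sub$id)) stop("cluster ", cid, " has members missing from ",
                            "the protein table")
    msa <- align_cluster(sub, backend = backend, cluster_id = cid)
    profiles[[length(profiles) + 1L]] <-
      build_profile(msa, assign_match_columns(msa, symfrac))
  }
  write_hmm_db(profiles, path)
  invisible(profiles)
}
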