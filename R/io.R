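#' Read contigs with explicit topology
#'
#' Reads a nucleotide FASTA and attaches a topology (`linear`/`circular`) to
#' each contig. Topology is never inferred from sequence: it comes either from
#' a sidecar TSV (columns `contig_id`, `topology`) covering every contig, or
#' from the header token `circular=true` (its absence marks a linear contig,
#' the declared header convention).
#'
#' @param fasta path to a FASTA file of contigs.
#' @param topology path to a two-column TSV (`contig_id`, `topology`), or
#'   `NULL` to use the header-token convention.
#' @return a data.frame with columns `id`, `sequence`, `topology`, `length`.
#' @export
read_contigs <- function(fasta, topology = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) stop("duplicate contig ids in ", fasta)
  if (!is.null(topology)) {
    tab <- read.delim(topology, stringsAsFactors = FALSE)
    if (!all(c("contig_id", "topology") %in% names(tab)))
      stop("topology sidecar must have columns contig_id, topology")
    topo <- tab$topology[match(ids, tab$contig_id)]
    if (anyNA(topo)) stop("topology sidecar missing contigs: ",
                          paste(head(ids[is.na(topo)], 5), collapse = ", "))
  } else {
    topo <- ifelse(grepl("circular=true", headers, fixed = TRUE),
                   "circular", "linear")
  }
  contig_table(ids, as.character(seqs), topo)
}

#' Build a validated contig table
#'
#' @param id,sequence,topology parallel vectors describing the contigs.
#' @return data.frame with columns `id`, `sequence`, `topology`, `length`.
#' @export
contig_table <- function(id, sequence, topology) {
  topology <- as.character(topology)
  bad <- !topology %in% c("linear", "circular")
  if (any(bad))
    stop("unknown topology for contig(s): ",
         paste(head(id[bad], 5), collapse = ", "))
  sequence <- toupper(as.character(sequence))
  len <- nchar(sequence)
  if (any(len == 0L)) stop("empty contig sequence")
  data.frame(id = as.character(id), sequence = sequence,
             topology = topology, length = len,
             stringsAsFactors = FALSE)
}

#' Read per-tool prediction score rows
#'
#' TSV columns: `contig_id`, `tool`, `category`, `score`, `p_value`; empty
#' cells are allowed and become `NA`. Tools are `virsorter` (carries
#' `category`), `deepvirfinder` (carries `score` and `p_value`) and `marvel`
#' (carries `score`).
#'
#' @param path TSV path.
#' @return data.frame of tool-score rows.
#' @export
read_tool_scores <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  need <- c("contig_id", "tool", "category", "score", "p_value")
  if (!all(need %in% names(tab)))
    stop("score table must have columns: ", paste(need, collapse = ", "))
  tab$tool <- tolower(tab$tool)
  bad <- !tab$tool %in% c("virsorter", "deepvirfinder", "marvel")
  if (any(bad)) stop("unknown tool name(s): ",
                     paste(unique(tab$tool[bad]), collapse = ", "))
  tab[need]
}

#' Read contamination region tables
#'
#' TSV columns `contig_id`, `start`, `end`, `region_type`
#' (`viral`/`host`), with 1-based inclusive coordinates as produced by
#' CheckV-style contamination output.
#'
#' @param path TSV path.
#' @return data.frame of regions, sorted by contig then start.
#' @export
read_regions <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig_id", "start", "end", "region_type")
  if (!all(need %in% names(tab)))
    stop("region table must have columns: ", paste(need, collapse = ", "))
  if (!all(tab$region_type %in% c("viral", "host")))
    stop("region_type must be 'viral' or 'host'")
  tab <- tab[order(tab$contig_id, tab$start), need]
  rownames(tab) <- NULL
  tab
}

#' Read gene-caller proteins from FASTA
#'
#' Accepts plain headers or the gene-caller dialect
#' `>contig_1_3 # start # end # strand # ...`; when coordinates are absent the
#' corresponding columns are `NA`. Sequences are uppercased and a trailing
#' stop symbol `*` is stripped. The contig id is the protein id with its
#' trailing `_<gene index>` removed.
#'
#' @param fasta path to a protein FASTA.
#' @return data.frame with columns `id`, `sequence`, `contig_id`, `start`,
#'   `end`, `strand`.
#' @export
read_proteins <- function(fasta) {
  seqs <- Biostrings::readAAStringSet(fasta)
  headers <- names(seqs)
  parts <- strsplit(headers, "\\s+#\\s+")
  ids <- sub("\\s.*$", "", vapply(parts, `[`, "", 1L))
  getnum <- function(i) {
    v <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= i) p[[i]] else NA_character_, "")))
    v
  }
  start <- getnum(2L); end <- getnum(3L)
  strand_raw <- vapply(parts, function(p)
    if (length(p) >= 4L) p[[4L]] else NA_character_, "")
  strand <- ifelse(is.na(strand_raw), NA_character_,
                   ifelse(trimws(strand_raw) %in% c("-1", "-"), "-", "+"))
  protein_table(ids, as.character(seqs), start = start, end = end,
                strand = strand)
}

#' Build a validated, normalized protein table
#'
#' @param id,sequence protein ids and amino-acid strings.
#' @param contig_id parent contig id; derived from `id` when `NULL`.
#' @param start,end,strand optional gene coordinates.
#' @return data.frame of normalized protein records.
#' @export
protein_table <- function(id, sequence, contig_id = NULL,
                          start = NA_integer_, end = NA_integer_,
                          strand = NA_character_) {
  sequence <- toupper(as.character(sequence))
  sequence <- sub("\\*+$", "", sequence)
  if (!length(id))
    return(data.frame(id = character(), sequence = character(),
                      contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  if (any(nchar(sequence) == 0L)) stop("empty protein sequence after ingest")
  if (is.null(contig_id)) contig_id <- sub("_[0-9]+$", "", as.character(id))
  data.frame(id = as.character(id), sequence = sequence,
             contig_id = as.character(contig_id),
             start = as.integer(start), end = as.integer(end),
             strand = as.character(strand), stringsAsFactors = FALSE)
}

BLAST12 <- c("query_id", "subject_id", "pident", "aln_len", "mismatch",
             "gapopen", "qstart", "qend", "sstart", "send", "evalue",
             "bitscore")

#' Read pairwise hits in BLAST tabular (outfmt-6) dialect
#'
#' Accepts 12 standard columns; a 13th column is read as the subject
#' annotation (reference-search dialect) unless it is numeric, in which case
#' columns 13-14 are read as `qlen`/`slen` (all-vs-all dialect with appended
#' sequence lengths).
#'
#' @param path TSV path without header line.
#' @param annotated require the subject-annotation column (reject otherwise).
#' @return data.frame of homology hits.
#' @export
read_blast_tab <- function(path, annotated = FALSE) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    quote = "")
  nc <- ncol(tab)
  if (nc < 12L) stop("BLAST tabular file must have >= 12 columns: ", path)
  names(tab)[1:12] <- BLAST12
  hits <- tab[1:12]
  hits$qlen <- NA_integer_; hits$slen <- NA_integer_
  hits$subject_annotation <- NA_character_
  if (nc >= 14L && !anyNA(suppressWarnings(as.integer(tab[[13L]])))) {
    hits$qlen <- as.integer(tab[[13L]])
    hits$slen <- as.integer(tab[[14L]])
  } else if (nc >= 13L) {
    hits$subject_annotation <- as.character(tab[[13L]])
  }
  if (annotated && all(is.na(hits$subject_annotation)))
    stop("reference-search dialect requires a 13th subject-annotation ",
         "column: ", path)
  hits$evalue <- as.numeric(hits$evalue)
  if (any(hits$evalue < 0)) stop("negative e-value in ", path)
  if (any(hits$aln_len < 1L)) stop("alignment length < 1 in ", path)
  hits
}

#' Write a protein or contig table to FASTA
#'
#' @param tab data.frame with `id` and `sequence` columns.
#' @param path output path.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(tab, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::AAStringSet(tab$sequence)
       else Biostrings::DNAStringSet(tab$sequence)
  names(x) <- tab$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read peptide-spectrum matches
#'
#' TSV columns `spectrum_id`, `sample_id`, `peptide`, `score`, `is_decoy`.
#' Flanking-residue notation `X.PEPTIDE.Y` is stripped at ingest; peptides
#' outside the 6-50 residue window are dropped (count reported via message).
#'
#' @param path TSV path.
#' @param min_len,max_len peptide length window retained after ingest.
#' @return data.frame of PSMs.
#' @export
read_psms <- function(path, min_len = 6L, max_len = 50L) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "sample_id", "peptide", "score", "is_decoy")
  if (!all(need %in% names(tab)))
    stop("PSM table must have columns: ", paste(need, collapse = ", "))
  tab$peptide <- strip_flanks(tab$peptide)
  tab$is_decoy <- as.logical(tab$is_decoy)
  keep <- nchar(tab$peptide) >= min_len & nchar(tab$peptide) <= max_len
  if (any(!keep))
    message(sum(!keep), " PSM(s) dropped for peptide length outside [",
            min_len, ", ", max_len, "]")
  tab <- tab[keep, need]
  rownames(tab) <- NULL
  tab
}

strip_flanks <- function(peptide) {
  peptide <- toupper(as.character(peptide))
  flk <- grepl("^[A-Z-]\\..+\\.[A-Z-]$", peptide)
  peptide[flk] <- sub("^[A-Z-]\\.", "", sub("\\.[A-Z-]$", "", peptide[flk]))
  peptide
}

#' Read DRAM-style per-protein annotation records
#'
#' TSV columns `protein_id`, `db`, `accession`, `description`, `rank`
#' (`rank` optional). `db` must be one of kegg, uniref90, pfam, vogdb.
#'
#' @param path TSV path.
#' @return data.frame of annotation records.
#' @export
read_annotations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA"))
  need <- c("protein_id", "db", "accession", "description")
  if (!all(need %in% names(tab)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  tab$db <- tolower(tab$db)
  bad <- !tab$db %in% c("kegg", "uniref90", "pfam", "vogdb")
  if (any(bad)) stop("unknown source db: ",
                     paste(unique(tab$db[bad]), collapse = ", "))
  if (!"rank" %in% names(tab)) tab$rank <- NA_character_
  tab$description[is.na(tab$description)] <- ""
  tab[c(need, "rank")]
}

#' Read detection-run tables
#'
#' TSV columns `sample_id`, `contig_id`, `length`, `category` (1-6).
#'
#' @param path TSV path.
#' @return data.frame of detection calls.
#' @export
read_detection_run <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "contig_id", "length", "category")
  if (!all(need %in% names(tab)))
    stop("detection run must have columns: ", paste(need, collapse = ", "))
  if (!all(tab$category %in% 1:6)) stop("categories must be in 1..6")
  if (anyDuplicated(tab[c("sample_id", "contig_id")]))
    stop("one call per contig per run is required")
  tab[need]
}

write_tsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
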