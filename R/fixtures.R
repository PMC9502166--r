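#' Configuration for the synthetic-fixture generators
#'
#' Defaults describe the stated world the generators emulate: planted
#' families whose within-family e-values are far below the graph cut-off
#' (1e-180..1e-20) with spurious between-family hits at or above 1e-3;
#' member divergence 0.1 substitutions/site; PSM scores with targets
#' N(15, 2) and decoys N(8, 2) at n = 2000.
#'
#' @param seed integer seed; the same seed gives byte-identical outputs.
#' @param n_families number of planted protein families.
#' @param family_size_range min/max members per family.
#' @param divergence per-site substitution probability (0-0.5).
#' @param indel_rate per-site single-residue indel probability.
#' @param n_contaminants independent prokaryotic decoy proteins.
#' @param whitelisted_frac fraction of contaminants whose planted reference
#'   hit carries a whitelisted viral keyword (these must survive filtering).
#' @param contigs_per_sample,n_samples detection-run dimensions.
#' @param frac_structural fraction of planted annotations drawn from the
#'   structural vocabulary.
#' @param psm_params target/decoy score distributions and PSM count.
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, n_families = 10L,
                           family_size_range = c(3L, 8L),
                           divergence = 0.1, indel_rate = 0.01,
                           n_contaminants = 10L, whitelisted_frac = 0.3,
                           contigs_per_sample = 100L, n_samples = 6L,
                           frac_structural = 0.5,
                           psm_params = list(target_mean = 15,
                                             target_sd = 2,
                                             decoy_mean = 8, decoy_sd = 2,
                                             n = 2000L)) {
  stopifnot(divergence >= 0, indel_rate >= 0, indel_rate <= 1,
            frac_structural >= 0, frac_structural <= 1,
            whitelisted_frac >= 0, whitelisted_frac <= 1,
            family_size_range[1L] >= 2L)
  if (divergence > 0.5) stop("divergence must be <= 0.5")
  structure(list(seed = as.integer(seed), n_families = n_families,
                 family_size_range = family_size_range,
                 divergence = divergence, indel_rate = indel_rate,
                 n_contaminants = n_contaminants,
                 whitelisted_frac = whitelisted_frac,
                 contigs_per_sample = contigs_per_sample,
                 n_samples = n_samples, frac_structural = frac_structural,
                 psm_params = psm_params), class = "fixture_config")
}

sample_residues <- function(n) {
  bg <- background_frequencies()
  sample(AMINO_ALPHABET, n, replace = TRUE, prob = bg)
}

mutate_sequence <- function(chars, divergence, indel_rate) {
  n <- length(chars)
  sub <- runif(n) < divergence
  if (any(sub)) {
    repl <- sample_residues(sum(sub))
    same <- repl == chars[sub]
    while (any(same)) {                 # force a different residue
      repl[same] <- sample_residues(sum(same))
      same <- repl == chars[sub]
    }
    chars[sub] <- repl
  }
  out <- list()
  for (i in seq_along(chars)) {
    r <- runif(1)
    if (r < indel_rate / 2) next                        # deletion
    if (r < indel_rate) out[[length(out) + 1L]] <- sample_residues(1L)
    out[[length(out) + 1L]] <- chars[i]
  }
  unlist(out)
}

#' Generate planted protein families and contaminant decoys
#'
#' Each family descends from an ancestor (length 80-400, background
#' composition); members apply per-site substitutions at `divergence` and
#' single-residue indels at `indel_rate`. Contaminants are sampled
#' independently of any family.
#'
#' @param config a [fixture_config()].
#' @return list with `proteins` (protein table) and `truth` (data.frame
#'   `protein_id`, `family`, `is_contaminant`).
#' @export
generate_families <- function(config) {
  set.seed(config$seed)
  ids <- seqs <- fams <- character(0)
  for (f in seq_len(config$n_families)) {
    anc <- sample_residues(sample(80:400, 1L))
    size <- sample(config$family_size_range[1L]:config$family_size_range[2L],
                   1L)
    fam <- sprintf("fam%03d", f)
    for (m in seq_len(size)) {
      chars <- if (config$divergence == 0 && config$indel_rate == 0) anc
               else mutate_sequence(anc, config$divergence,
                                    config$indel_rate)
      ids <- c(ids, sprintf("%s_%d", fam, m))
      seqs <- c(seqs, paste(chars, collapse = ""))
      fams <- c(fams, fam)
    }
  }
  for (ctr in seq_len(config$n_contaminants)) {
    ids <- c(ids, sprintf("contam%03d_1", ctr))
    seqs <- c(seqs, paste(sample_residues(sample(80:400, 1L)),
                          collapse = ""))
    fams <- c(fams, NA_character_)
  }
  proteins <- protein_table(ids, seqs)
  truth <- data.frame(protein_id = ids, family = fams,
                      is_contaminant = is.na(fams),
                      stringsAsFactors = FALSE)
  list(proteins = proteins, truth = truth)
}

#' Generate planted all-vs-all and reference hit tables
#'
#' Within-family pairs receive e-values log-uniform in `[1e-180, 1e-20]`
#' with coverage >= 0.8 of both sequences; between-family pairs receive
#' spurious e-values >= 1e-3 at rate 0.01 (these fall above the graph
#' cut-off). Every contaminant gets a reference hit with identity > 95;
#' a `whitelisted_frac` of them carry a whitelisted viral keyword in the
#' subject annotation. Family proteins get harmless low-identity reference
#' hits.
#'
#' @param proteins,truth output of [generate_families()].
#' @param config a [fixture_config()].
#' @return list with `all_vs_all` and `reference` hit tables (dialect of
#'   [read_blast_tab()], with `qlen`/`slen` resp. `subject_annotation`).
#' @export
generate_hits <- function(proteins, truth, config) {
  set.seed(config$seed + 1L)
  lens <- setNames(nchar(proteins$sequence), proteins$id)
  mkhit <- function(q, s, pident, aln_len, evalue, annotation = NA) {
    data.frame(query_id = q, subject_id = s, pident = pident,
               aln_len = aln_len, mismatch = 0L, gapopen = 0L,
               qstart = 1L, qend = aln_len, sstart = 1L, send = aln_len,
               evalue = evalue, bitscore = round(-log10(pmax(evalue,
                                                             1e-300)) * 2),
               qlen = unname(lens[q]), slen = unname(lens[s]),
               subject_annotation = annotation, stringsAsFactors = FALSE)
  }
  ava <- list()
  fams <- split(truth$protein_id[!truth$is_contaminant],
                truth$family[!truth$is_contaminant])
  for (members in fams) {
    pairs <- utils::combn(sort(members), 2L)
    for (p in seq_len(ncol(pairs))) {
      q <- pairs[1L, p]; s <- pairs[2L, p]
      ev <- 10^-runif(1L, 20, 180)
      aln <- max(lens[q], lens[s])
      ava[[length(ava) + 1L]] <- mkhit(q, s, round(runif(1L, 60, 95), 1),
                                       unname(aln), ev)
    }
  }
  fam_ids <- unlist(fams, use.names = FALSE)
  n_noise <- round(0.01 * length(fam_ids)^2 / 2)
  fam_of <- setNames(truth$family, truth$protein_id)
  for (i in seq_len(n_noise)) {
    q <- sample(fam_ids, 1L); s <- sample(fam_ids, 1L)
    if (q == s || fam_of[q] == fam_of[s]) next
    ava[[length(ava) + 1L]] <- mkhit(q, s, round(runif(1L, 25, 40), 1),
                                     round(0.3 * min(lens[q], lens[s])),
                                     10^runif(1L, -3, 1))
  }
  all_vs_all <- do.call(rbind, ava)
  prokaryotic_annotations <- c("DNA polymerase III subunit alpha",
                               "ribosomal protein S4",
                               "ABC transporter permease",
                               "cell division protein FtsZ")
  whitelisted_annotations <- c("major capsid protein",
                               "phage tail fiber protein",
                               "terminase large subunit",
                               "portal vertex protein")
  ref <- list()
  contam <- truth$protein_id[truth$is_contaminant]
  n_white <- round(config$whitelisted_frac * length(contam))
  white <- if (n_white) sample(contam, n_white) else character()
  for (cid in contam) {
    ann <- if (cid %in% white) sample(whitelisted_annotations, 1L)
           else sample(prokaryotic_annotations, 1L)
    ref[[length(ref) + 1L]] <- mkhit(cid, paste0("REF_", cid),
                                     round(runif(1L, 95.1, 100), 1),
                                     unname(lens[cid]), 10^-runif(1L, 20, 80),
                                     ann)
  }
  for (fid in sample(fam_ids, min(20L, length(fam_ids)))) {
    ref[[length(ref) + 1L]] <- mkhit(fid, paste0("REF_", fid),
                                     round(runif(1L, 40, 80), 1),
                                     round(0.5 * lens[fid]),
                                     10^-runif(1L, 3, 10),
                                     sample(prokaryotic_annotations, 1L))
  }
  reference <- do.call(rbind, ref)
  rownames(all_vs_all) <- rownames(reference) <- NULL
  list(all_vs_all = all_vs_all, reference = reference,
       whitelisted_contaminants = sort(white))
}

#' Generate a contig-selection fixture with planted tiers
#'
#' Plants, per contig: topology and length (some below threshold), the
#' number of tools passing the strict cut-offs, and (for a subset) a host
#' contamination region. Score rows are generated to pass or fail each
#' tool's threshold exactly as planted.
#'
#' @param config a [fixture_config()].
#' @param n_contigs number of contigs.
#' @return list with `contigs`, `scores`, `regions` tables and `truth`
#'   (planted per-tool passes, expected tier).
#' @export
generate_contig_fixture <- function(config, n_contigs = 40L) {
  set.seed(config$seed + 2L)
  tools <- c("virsorter", "deepvirfinder", "marvel")
  rows <- truth <- regions <- list()
  ids <- sprintf("contig%03d", seq_len(n_contigs))
  topo <- sample(c("linear", "circular"), n_contigs, replace = TRUE,
                 prob = c(0.8, 0.2))
  len <- ifelse(topo == "linear",
                sample(c(3000L, 5000L, 8000L, 20000L), n_contigs, TRUE,
                       prob = c(0.15, 0.2, 0.4, 0.25)),
                sample(c(1200L, 1500L, 4000L), n_contigs, TRUE,
                       prob = c(0.15, 0.35, 0.5)))
  seqs <- vapply(len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""), "")
  n_pass <- sample(0:3, n_contigs, TRUE, prob = c(0.2, 0.2, 0.3, 0.3))
  for (i in seq_len(n_contigs)) {
    passing <- sample(tools, n_pass[i])
    for (tool in tools) {
      pass <- tool %in% passing
      row <- switch(tool,
        virsorter = data.frame(contig_id = ids[i], tool = tool,
                               category = if (pass) 1L
                                          else sample(2:6, 1L),
                               score = NA_real_, p_value = NA_real_),
        deepvirfinder = data.frame(contig_id = ids[i], tool = tool,
                                   category = NA_integer_,
                                   score = if (pass) runif(1, 0.91, 1)
                                           else runif(1, 0, 0.9),
                                   p_value = if (pass) runif(1, 0, 0.049)
                                             else runif(1, 0.05, 1)),
        marvel = data.frame(contig_id = ids[i], tool = tool,
                            category = NA_integer_,
                            score = if (pass) runif(1, 0.905, 1)
                                    else runif(1, 0, 0.9),
                            p_value = NA_real_))
      rows[[length(rows) + 1L]] <- row
    }
    min_len <- if (topo[i] == "linear") 5000L else 1500L
    expected_tier <- if (len[i] < min_len) "none"
      else if (n_pass[i] == 3L) "unanimous"
      else if (n_pass[i] == 2L) "majority" else "none"
    truth[[i]] <- data.frame(contig_id = ids[i], n_pass = n_pass[i],
                             passes_length = len[i] >= min_len,
                             tier = expected_tier, stringsAsFactors = FALSE)
    if (runif(1) < 0.25 && len[i] >= 6000L) {
      cut <- as.integer(round(len[i] * 0.6))
      regions[[length(regions) + 1L]] <- data.frame(
        contig_id = ids[i],
        start = c(1L, cut + 1L), end = c(cut, len[i]),
        region_type = c("viral", "host"), stringsAsFactors = FALSE)
    }
  }
  list(contigs = contig_table(ids, seqs, topo),
       scores = do.call(rbind, rows),
       regions = if (length(regions)) do.call(rbind, regions)
                 else data.frame(contig_id = character(), start = integer(),
                                 end = integer(), region_type = character(),
                                 stringsAsFactors = FALSE),
       truth = do.call(rbind, truth))
}

#' Generate baseline/augmented detection runs with planted transitions
#'
#' Baseline contigs get log-uniform lengths (1.5-100 kb) and categories;
#' the augmented run reproduces planted bookkeeping: 60% of baseline
#' category-6 contigs move to category 2 and the rest to category 3, a
#' planted fraction of contigs in the shortest bins is newly detected (more
#' new short contigs than long), and all other calls are unchanged.
#'
#' @param config a [fixture_config()].
#' @return list with `baseline`, `augmented` tables and `truth` (planted
#'   per-bin new-contig counts and category-6 fate counts).
#' @export
generate_detection_runs <- function(config) {
  set.seed(config$seed + 3L)
  base <- aug <- list()
  new_rates <- c(0.5, 0.4, 0.3, 0.2, 0.1)    # per length bin, short to long
  edges <- c(1500, 3000, 5000, 10000, 20000, Inf)
  truth_new <- setNames(integer(5L), paste0("bin", 1:5))
  cat6_to2 <- 0L; cat6_total <- 0L
  for (s in seq_len(config$n_samples)) {
    sid <- sprintf("sample%02d", s)
    n <- config$contigs_per_sample
    len <- as.integer(round(exp(runif(n, log(1500), log(1e5)))))
    cat <- sample(1:6, n, TRUE)
    cid <- sprintf("%s_c%04d", sid, seq_len(n))
    base[[s]] <- data.frame(sample_id = sid, contig_id = cid,
                            length = len, category = cat,
                            stringsAsFactors = FALSE)
    newcat <- cat
    is6 <- which(cat == 6L)
    n_up <- as.integer(floor(0.6 * length(is6)))
    up <- head(is6, n_up)
    newcat[up] <- 2L
    newcat[setdiff(is6, up)] <- 3L
    cat6_to2 <- cat6_to2 + n_up; cat6_total <- cat6_total + length(is6)
    aug_rows <- data.frame(sample_id = sid, contig_id = cid, length = len,
                           category = newcat, stringsAsFactors = FALSE)
    extra <- list()
    for (b in 1:5) {
      n_bin <- sum(len >= edges[b] & len < edges[b + 1L])
      n_new <- as.integer(round(new_rates[b] * n_bin))
      truth_new[b] <- truth_new[b] + n_new
      if (!n_new) next
      nlen <- as.integer(round(runif(n_new, edges[b],
                                     min(edges[b + 1L], 1e5) - 1)))
      extra[[b]] <- data.frame(
        sample_id = sid,
        contig_id = sprintf("%s_new%d_%04d", sid, b, seq_len(n_new)),
        length = nlen, category = sample(1:2, n_new, TRUE),
        stringsAsFactors = FALSE)
    }
    aug[[s]] <- rbind(aug_rows, do.call(rbind, extra))
  }
  list(baseline = do.call(rbind, base), augmented = do.call(rbind, aug),
       truth = list(new_per_bin = truth_new, cat6_total = cat6_total,
                    cat6_to_cat2 = cat6_to2))
}

#' Fully tryptic peptides of a protein sequence
#'
#' Cleaves after K or R except when the next residue is P.
#'
#' @param sequence amino-acid string.
#' @return character vector of peptides in order.
#' @export
tryptic_peptides <- function(sequence) {
  strsplit(toupper(sequence), "(?<=[KR])(?!P)", perl = TRUE)[[1]]
}

#' Generate a PSM table with planted score distributions
#'
#' Target PSMs carry tryptic peptides (length 6-50) of the supplied
#' proteins with scores from the planted target distribution; decoy PSMs
#' carry reversed peptides with scores from the decoy distribution.
#'
#' @param config a [fixture_config()]; `psm_params` sets the score
#'   distributions and total PSM count (split evenly target/decoy).
#' @param proteins protein table supplying the true (virion) peptide pool;
#'   when `NULL`, random background peptides are used.
#' @return list with `psms` (table of [read_psms()] dialect) and `truth`
#'   (the planted target peptide pool).
#' @export
generate_psms <- function(config, proteins = NULL) {
  set.seed(config$seed + 4L)
  pp <- config$psm_params
  n_t <- ceiling(pp$n / 2); n_d <- pp$n - n_t
  pool <- if (!is.null(proteins)) {
    peps <- unlist(lapply(proteins$sequence, tryptic_peptides))
    peps[nchar(peps) >= 6 & nchar(peps) <= 50]
  } else character()
  if (!length(pool))
    pool <- vapply(seq_len(200L),
                   function(i) paste(c(sample_residues(sample(6:20, 1L)),
                                       "K"), collapse = ""), "")
  t_pep <- sample(pool, n_t, replace = TRUE)
  d_pep <- vapply(sample(pool, n_d, replace = TRUE), function(p)
    paste(rev(strsplit(p, "")[[1]]), collapse = ""), "",
    USE.NAMES = FALSE)
  psms <- data.frame(
    spectrum_id = sprintf("spec%05d", seq_len(pp$n)),
    sample_id = "search1",
    peptide = c(t_pep, d_pep),
    score = c(rnorm(n_t, pp$target_mean, pp$target_sd),
              rnorm(n_d, pp$decoy_mean, pp$decoy_sd)),
    is_decoy = rep(c(FALSE, TRUE), c(n_t, n_d)),
    stringsAsFactors = FALSE)
  psms <- psms[sample(nrow(psms)), ]
  rownames(psms) <- NULL
  list(psms = psms, truth = list(target_peptides = unique(t_pep)))
}

#' Generate planted per-protein annotation records
#'
#' Assigns each planted family a description (structural vocabulary with
#' probability `frac_structural`, an uninformative one otherwise) and emits
#' per-member records from 2-3 source databases, so consensus,
#' informativeness and structural flags have known truth.
#'
#' @param truth family truth table from [generate_families()].
#' @param config a [fixture_config()].
#' @return list with `records` (annotation table) and `truth` (per-family
#'   planted description and structural flag).
#' @export
generate_annotations <- function(truth, config) {
  set.seed(config$seed + 5L)
  structural_pool <- c("major capsid protein", "tail fiber protein",
                       "portal protein", "baseplate wedge subunit",
                       "head-tail connector protein")
  other_pool <- c("DNA primase", "thymidylate synthase",
                  "ribonucleotide reductase", "integrase",
                  "single-stranded DNA binding protein")
  uninformative_pool <- c("hypothetical protein", "uncharacterized protein",
                          "DUF1234 domain-containing protein")
  fams <- unique(truth$family[!truth$is_contaminant])
  recs <- list(); planted <- list()
  for (fam in fams) {
    members <- truth$protein_id[!is.na(truth$family) & truth$family == fam]
    r <- runif(1)
    desc <- if (r < config$frac_structural) sample(structural_pool, 1L)
      else if (r < config$frac_structural +
                 (1 - config$frac_structural) / 2) sample(other_pool, 1L)
      else sample(uninformative_pool, 1L)
    dbs <- sample(c("kegg", "uniref90", "pfam", "vogdb"),
                  sample(2:3, 1L))
    for (db in dbs)
      recs[[length(recs) + 1L]] <- data.frame(
        protein_id = sample(members, min(length(members),
                                         sample(1:3, 1L))),
        db = db, accession = paste0(toupper(db), "_", fam),
        description = desc, rank = NA_character_,
        stringsAsFactors = FALSE)
    planted[[fam]] <- data.frame(
      family = fam, description = desc,
      informative = is_informative(desc),
      structural = is_informative(desc) && is_structural(desc),
      stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, recs), truth = do.call(rbind, planted))
}
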