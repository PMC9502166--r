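test_that("informativeness keyword rules fire case-insensitively", {
  expect_false(is_informative("hypothetical protein"))
  expect_false(is_informative("Uncharacterized conserved protein"))
  expect_false(is_informative("No Annotation"))
  expect_false(is_informative("DUF1234 family protein"))
  expect_false(is_informative(""))
  expect_false(is_informative(NA))
  expect_true(is_informative("terminase large subunit"))
  # duf requires a token boundary: unrelated words containing 'duf' pass
  expect_true(is_informative("dufourase-like enzyme"))
  expect_false(is_informative("domain of unknown function (duf) protein"))
})

test_that("structural keywords respect word boundaries for short terms", {
  expect_true(is_structural("major capsid protein"))
  expect_true(is_structural("structural protein gp5"))
  expect_true(is_structural("putative structure-associated factor"))
  expect_true(is_structural("Mu-like prophage protein"))
  expect_true(is_structural("tail sheath"))
  expect_true(is_structural("gp23 major capsid"))
  expect_false(is_structural("murein hydrolase"))
  expect_false(is_structural("gp9000 unrelated"))
  expect_false(is_structural("DNA polymerase"))
  # substring mode reproduces the plain string-search behaviour
  expect_true(is_structural("murein hydrolase", word_boundary = FALSE))
})

test_that("cluster collapse builds detailed, consensus and flag fields", {
  membership <- data.frame(cluster_id = c("c1", "c1", "c2"),
                           member_id = c("p1", "p2", "p3"))
  records <- data.frame(
    protein_id = c("p1", "p2", "p3", "p3"),
    db = c("kegg", "vogdb", "kegg", "pfam"),
    accession = c("K1", "V1", "K2", "PF1"),
    description = c("capsid protein", "Capsid protein.",
                    "hypothetical protein", "hypothetical protein"),
    rank = NA_character_, stringsAsFactors = FALSE)
  ann <- collapse_cluster(records, membership)
  expect_identical(ann$c1$consensus, "capsid protein")
  expect_true(ann$c1$structural)
  expect_true(ann$c1$previously_annotated)
  # all-uninformative cluster
  expect_false(ann$c2$previously_annotated)
  expect_false(ann$c2$structural)
  # no records at all
  m3 <- data.frame(cluster_id = "c9", member_id = "p9")
  ann3 <- collapse_cluster(records[0, ], m3)
  expect_false(ann3$c9$previously_annotated)
  expect_identical(nrow(ann3$c9$detailed), 0L)
  # unknown proteins are skipped with a message
  bad <- records; bad$protein_id[1] <- "ghost"
  expect_message(collapse_cluster(bad, membership), "unknown")
})

test_that("collapse is invariant to record order and keeps flag implication", {
  cfg <- fixture_config(seed = 17)
  fam <- generate_families(cfg)
  keep <- !fam$truth$is_contaminant
  membership <- data.frame(cluster_id = fam$truth$family[keep],
                           member_id = fam$truth$protein_id[keep])
  gen <- generate_annotations(fam$truth, cfg)
  a1 <- collapse_cluster(gen$records, membership)
  perm <- gen$records[sample(nrow(gen$records)), ]
  a2 <- collapse_cluster(perm, membership)
  expect_identical(a1[sort(names(a1))], a2[sort(names(a2))])
  for (a in a1) {
    if (a$structural) expect_true(a$previously_annotated)
  }
  # planted truth: structural/informative flags match the generator's plan
  for (fam_id in gen$truth$family) {
    expect_identical(a1[[fam_id]]$previously_annotated,
                     gen$truth$informative[gen$truth$family == fam_id])
    expect_identical(a1[[fam_id]]$structural,
                     gen$truth$structural[gen$truth$family == fam_id])
  }
})

test_that("summary reports medians, per-db counts and the U test", {
  mk_ann <- function(id, n, desc, db = "kegg") {
    structure(list(cluster_id = id, n_proteins = n,
                   detailed = data.frame(source_db = db, description = desc,
                                         count = 1L),
                   consensus = character(),
                   previously_annotated = is_informative(desc),
                   structural = FALSE, virion_associated = FALSE),
              class = "cluster_annotation")
  }
  anns <- c(lapply(1:3, function(i)
              mk_ann(paste0("a", i), c(6, 6, 8)[i], "portal protein")),
            lapply(1:3, function(i)
              mk_ann(paste0("u", i), c(3, 3, 2)[i], "hypothetical protein")))
  sizes <- setNames(c(6, 6, 8, 3, 3, 2), c("a1", "a2", "a3", "u1", "u2", "u3"))
  s <- annotation_summary(anns, sizes)
  expect_identical(s$median_annotated, 6)
  expect_identical(s$median_unannotated, 3)
  expect_identical(s$n_annotated_any, 3L)
  expect_identical(unname(s$per_db["kegg"]), 3L)
  # any-db count dominates every single-db count
  expect_true(all(s$n_annotated_any >= s$per_db))
  # empty group: medians still reported, test skipped with note
  s2 <- annotation_summary(anns[1:3], sizes[1:3])
  expect_true(is.na(s2$p_value))
  expect_match(s2$note, "skipped")
})

test_that("wilcoxon statistic agrees with brute-force U enumeration", {
  set.seed(31)
  x <- sample(1:20, 8); y <- sample(1:20, 6)
  u_brute <- sum(outer(x, y, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(unname(stats::wilcox.test(x, y, exact = FALSE)$statistic),
               u_brute)
})

test_that("preferential annotation of large clusters is detected", {
  set.seed(53)
  n <- 200
  sizes <- setNames(rpois(n, 4) + 2, sprintf("c%03d", 1:n))
  big <- sizes >= stats::median(sizes)
  annotated <- runif(n) < ifelse(big, 0.8, 0.3)
  anns <- lapply(seq_len(n), function(i) {
    desc <- if (annotated[i]) "tail fiber protein" else "hypothetical protein"
    structure(list(cluster_id = names(sizes)[i], n_proteins = sizes[i],
                   detailed = data.frame(source_db = "vogdb",
                                         description = desc, count = 1L),
                   consensus = character(),
                   previously_annotated = is_informative(desc),
                   structural = FALSE, virion_associated = FALSE),
              class = "cluster_annotation")
  })
  s <- annotation_summary(anns, sizes)
  expect_lt(s$p_value, 0.05)
  expect_gt(s$median_annotated, s$median_unannotated)
})
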