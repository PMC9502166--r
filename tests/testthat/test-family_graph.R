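mk_ava_hit <- function(q, s, evalue, qlen = 100L, slen = 120L,
                       aln_len = NULL) {
  if (is.null(aln_len)) aln_len <- max(qlen, slen)
  data.frame(query_id = q, subject_id = s, pident = 80, aln_len = aln_len,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = aln_len,
             sstart = 1L, send = aln_len, evalue = evalue, bitscore = 100,
             qlen = qlen, slen = slen, subject_annotation = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("edge filtering, transformation and capping follow the rules", {
  g <- build_graph(mk_ava_hit("a", "b", 1e-6, 100L, 120L,
                              aln_len = round(0.8 * 120)))
  expect_equal(g$edges$weight, 6.0)
  # cap at 200 for extreme and zero e-values
  expect_equal(build_graph(mk_ava_hit("a", "b", 1e-250))$edges$weight, 200)
  expect_equal(build_graph(mk_ava_hit("a", "b", 0))$edges$weight, 200)
  # short sequences are excluded entirely
  expect_identical(nrow(build_graph(mk_ava_hit("a", "b", 1e-6,
                                               qlen = 45L))$edges), 0L)
  # coverage must hold for BOTH sequences
  low_cov <- mk_ava_hit("a", "b", 1e-6, 100L, 200L, aln_len = 100L)
  expect_identical(nrow(build_graph(low_cov)$edges), 0L)
  # non-positive transformed weights (evalue >= 1) are dropped
  kept <- mk_ava_hit("a", "b", 1, 100L, 100L)
  expect_identical(nrow(build_graph(kept, evalue_max = 10)$edges), 0L)
  # self-hits never become edges
  expect_identical(nrow(build_graph(mk_ava_hit("a", "a", 1e-9))$edges), 0L)
  # reciprocal duplicates collapse to the max weight
  recip <- rbind(mk_ava_hit("a", "b", 1e-6), mk_ava_hit("b", "a", 1e-9))
  g2 <- build_graph(recip)
  expect_identical(nrow(g2$edges), 1L)
  expect_equal(g2$edges$weight, 9.0)
})

test_that("edge filters are monotone under tightening", {
  cfg <- fixture_config(seed = 3)
  fam <- generate_families(cfg)
  hits <- generate_hits(fam$proteins, fam$truth, cfg)$all_vs_all
  base <- build_graph(hits)
  key <- function(g) paste(g$edges$u, g$edges$v)
  for (g2 in list(build_graph(hits, evalue_max = 1e-30),
                  build_graph(hits, min_cov = 0.9),
                  build_graph(hits, min_len = 150L))) {
    expect_true(all(key(g2) %in% key(base)))
  }
})

test_that("Markov clustering matches the long-horizon flow oracle", {
  # two 4-cliques joined by a weak bridge
  c1 <- clique_edges(paste0("a", 1:4)); c2 <- clique_edges(paste0("b", 1:4))
  g <- toy_graph(c(c1$u, c2$u, "a1"), c(c1$v, c2$v, "b1"),
                 c(c1$w, c2$w, 0.1))
  cs <- mcl_cluster(g)
  expect_identical(canon_clusters(cs$clusters),
                   canon_clusters(mcl_flow_oracle(g)))
  expect_identical(lengths(cs$clusters), c(4L, 4L))

  # oracle equivalence on random small weighted graphs
  set.seed(99)
  for (i in 1:8) {
    n <- sample(5:12, 1)
    ids <- paste0("n", seq_len(n))
    pairs <- t(combn(ids, 2))
    keep <- runif(nrow(pairs)) < 0.35
    if (sum(keep) < 2) next
    g <- toy_graph(pairs[keep, 1], pairs[keep, 2],
                   round(runif(sum(keep), 0.5, 5), 2))
    got <- mcl_cluster(g, min_size = 1L)
    expect_identical(canon_clusters(got$clusters),
                     canon_clusters(mcl_flow_oracle(g)),
                     info = paste("graph", i))
  }
})

test_that("Markov clustering handles components and singletons", {
  t1 <- clique_edges(c("x1", "x2", "x3")); t2 <- clique_edges(c("y1", "y2", "y3"))
  g <- toy_graph(c(t1$u, t2$u), c(t1$v, t2$v), c(t1$w, t2$w))
  cs <- mcl_cluster(g)
  expect_identical(lengths(cs$clusters), c(3L, 3L))
  g1 <- toy_graph("a", "b", 2)
  cs1 <- mcl_cluster(g1)
  expect_identical(cs1$clusters, list(c("a", "b")))
  expect_identical(cs1$singleton_count, 0L)
  # clusters never overlap
  memb <- cluster_membership(cs)
  expect_false(anyDuplicated(memb$member_id) > 0)
})

test_that("cohesiveness matches the closed form on cliques", {
  cq <- clique_edges(paste0("k", 1:5))
  g <- toy_graph(cq$u, cq$v, cq$w)
  expect_equal(cohesiveness(g, paste0("k", 1:5), penalty = 2), 0.5)
  expect_equal(cohesiveness(g, paste0("k", 1:5), penalty = 0), 1.0)
  # boundary weight counts edges leaving the set
  expect_equal(cohesiveness(g, paste0("k", 1:4), penalty = 2),
               6 / (6 + 4 + 8))
})

test_that("greedy growth recovers disjoint cliques without merging", {
  c1 <- clique_edges(c("a1", "a2", "a3")); c2 <- clique_edges(c("b1", "b2", "b3"))
  g <- toy_graph(c(c1$u, c2$u), c(c1$v, c2$v), c(c1$w, c2$w))
  cs <- cone_cluster(g)
  expect_identical(canon_clusters(cs$clusters),
                   list(c("a1", "a2", "a3"), c("b1", "b2", "b3")))
  # every member has internal weight
  W <- famforge:::graph_matrix(g)
  for (cl in cs$clusters) {
    idx <- match(cl, g$nodes)
    expect_true(all(Matrix::rowSums(W[idx, idx, drop = FALSE]) > 0))
  }
  # empty graph is allowed
  empty <- structure(list(nodes = character(),
                          edges = data.frame(u = character(),
                                             v = character(),
                                             weight = numeric())),
                     class = "protein_graph")
  expect_identical(length(cone_cluster(empty)$clusters), 0L)
})

test_that("overlap merging unifies near-identical candidates", {
  # overlap score 4^2 / (4 * 5) = 0.8 reaches the threshold
  expect_identical(
    famforge:::merge_overlapping(list(1:4, c(1:4, 5L)), 0.8),
    list(1:5))
  # 4^2 / (5 * 5) = 0.64 does not
  expect_identical(
    famforge:::merge_overlapping(list(1:5, c(1:4, 6L)), 0.8),
    list(1:5, c(1:4, 6L)))
  expect_identical(
    famforge:::merge_overlapping(list(1:3, 4:6), 0.8),
    list(1:3, 4:6))
})

test_that("both algorithms restricted to a component equal the full run", {
  cfg <- fixture_config(seed = 21, n_families = 4)
  fam <- generate_families(cfg)
  hits <- generate_hits(fam$proteins, fam$truth, cfg)$all_vs_all
  g <- build_graph(hits)
  comp <- igraph::components(igraph::graph_from_data_frame(
    g$edges[c("u", "v")], directed = FALSE, vertices = g$nodes))
  full_mcl <- mcl_cluster(g)
  full_cone <- cone_cluster(g)
  got_mcl <- got_cone <- list()
  for (k in seq_len(comp$no)) {
    ids <- names(comp$membership)[comp$membership == k]
    sub <- structure(list(
      nodes = sort(ids),
      edges = g$edges[g$edges$u %in% ids & g$edges$v %in% ids, ]),
      class = "protein_graph")
    got_mcl <- c(got_mcl, mcl_cluster(sub)$clusters)
    got_cone <- c(got_cone, cone_cluster(sub)$clusters)
  }
  expect_identical(canon_clusters(full_mcl$clusters),
                   canon_clusters(got_mcl))
  expect_identical(canon_clusters(full_cone$clusters),
                   canon_clusters(got_cone))
})

test_that("adjusted Rand index agrees with the pair-counting oracle", {
  expect_equal(adjusted_rand_index(
    setNames(c(1, 1, 2, 2), letters[1:4]),
    setNames(c("x", "x", "y", "y"), letters[1:4])), 1)
  # all-singletons vs one block is maximally discordant
  n <- 8
  singles <- setNames(seq_len(n), letters[1:n])
  block <- setNames(rep(1, n), letters[1:n])
  expect_true(adjusted_rand_index(singles, block) <= 0)
  set.seed(13)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    a <- setNames(sample(1:3, n, TRUE), paste0("i", 1:n))
    b <- setNames(sample(1:3, n, TRUE), paste0("i", 1:n))
    expect_equal(adjusted_rand_index(a, b), ari_pair_oracle(a, b))
  }
})

test_that("comparison table reports counts, sizes and restricted ARI", {
  c1 <- clique_edges(c("a1", "a2", "a3")); c2 <- clique_edges(c("b1", "b2", "b3"))
  g <- toy_graph(c(c1$u, c2$u), c(c1$v, c2$v), c(c1$w, c2$w))
  a <- mcl_cluster(g); b <- cone_cluster(g)
  cmp <- compare_clusterings(a, b)
  expect_equal(cmp$ari, 1)
  expect_identical(cmp$counts, c(a = 2L, b = 2L))
  expect_identical(cmp$summary$median_size, c(3, 3))
  # disjoint node sets are rejected
  other <- mcl_cluster(toy_graph("z1", "z2", 1))
  expect_error(compare_clusterings(a, other), "disjoint")
})

test_that("blast tabular reader distinguishes dialects", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(paste(c("q1", "s1", 90, 100, 0, 0, 1, 100, 1, 100, "1e-30",
                     200, 110, 120), collapse = "\t"), tf)
  h <- read_blast_tab(tf)
  expect_identical(h$qlen, 110L)
  writeLines(paste(c("q1", "s1", 90, 100, 0, 0, 1, 100, 1, 100, "1e-30",
                     200, "major capsid protein"), collapse = "\t"), tf)
  h2 <- read_blast_tab(tf, annotated = TRUE)
  expect_identical(h2$subject_annotation, "major capsid protein")
  writeLines(paste(c("q1", "s1", 90, 100, 0, 0, 1, 100, 1, 100, "1e-30",
                     200), collapse = "\t"), tf)
  expect_error(read_blast_tab(tf, annotated = TRUE), "annotation")
})
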