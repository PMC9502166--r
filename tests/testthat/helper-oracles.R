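# Shared helpers and independent oracles. Oracles here deliberately avoid
# the package's code paths they are used to check.

# build a protein_graph directly from an edge list
toy_graph <- function(u, v, w) {
  edges <- data.frame(u = pmin(u, v), v = pmax(u, v), weight = w,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$u, edges$v), ]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(u, v))), edges = edges),
            class = "protein_graph")
}

clique_edges <- function(ids, w = 1) {
  pairs <- t(combn(ids, 2))
  list(u = pairs[, 1], v = pairs[, 2], w = rep(w, nrow(pairs)))
}

# long-horizon flow-simulation oracle for Markov clustering: dense base-R
# matrices, fixed large iteration count, no pruning shortcuts
mcl_flow_oracle <- function(graph, inflation = 2, iters = 200) {
  nodes <- graph$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(graph$edges))) {
    e <- graph$edges[r, ]
    A[e$u, e$v] <- A[e$v, e$u] <- e$weight
  }
  loops <- apply(A, 1, max)
  loops[loops == 0] <- 1
  diag(A) <- loops
  M <- sweep(A, 2, colSums(A), "/")
  for (i in seq_len(iters)) {
    M <- M %*% M
    M <- M^inflation
    M <- sweep(M, 2, colSums(M), "/")
    M[M < 1e-9] <- 0
    cs <- colSums(M)
    M <- sweep(M, 2, ifelse(cs == 0, 1, cs), "/")
  }
  # clusters: connected components of the nonzero pattern
  reach <- (M > 0) | t(M > 0)
  diag(reach) <- TRUE
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    frontier <- s
    while (length(frontier)) {
      comp[frontier] <- cur
      nxt <- unique(unlist(lapply(frontier, function(i) which(reach[i, ]))))
      frontier <- nxt[is.na(comp[nxt])]
    }
  }
  unname(split(nodes, comp))
}

# normalize a cluster list for comparison
canon_clusters <- function(clusters) {
  cl <- lapply(clusters, function(x) sort(as.character(x)))
  cl[order(vapply(cl, `[`, "", 1))]
}

# brute-force pair-counting adjusted Rand index
ari_pair_oracle <- function(a, b) {
  common <- intersect(names(a), names(b))
  a <- a[common]; b <- b[common]
  n <- length(common)
  s_ab <- s_a <- s_b <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
      s_ab <- s_ab + (same_a && same_b)
      s_a <- s_a + same_a; s_b <- s_b + same_b
    }
  }
  tot <- n * (n - 1) / 2
  exp_idx <- s_a * s_b / tot
  max_idx <- (s_a + s_b) / 2
  if (max_idx == exp_idx) return(1)
  unname((s_ab - exp_idx) / (max_idx - exp_idx))
}

# brute-force substring scan (no regex/grepl): position-by-position compare
substring_scan_oracle <- function(peptide, sequence) {
  np <- nchar(peptide); ns <- nchar(sequence)
  if (np > ns) return(FALSE)
  for (s in seq_len(ns - np + 1)) {
    if (substr(sequence, s, s + np - 1) == peptide) return(TRUE)
  }
  FALSE
}

# random valid profile for round-trip testing
random_profile <- function(k, name = "rnd") {
  rdist <- function(n) { x <- stats::rexp(n); x / sum(x) }
  me <- t(vapply(seq_len(k), function(i) rdist(20), numeric(20)))
  colnames(me) <- famforge::AMINO_ALPHABET
  ie <- t(vapply(seq_len(k + 1), function(i) rdist(20), numeric(20)))
  colnames(ie) <- famforge::AMINO_ALPHABET
  tr <- matrix(0, k + 1, 7,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                       "DM", "DD")))
  for (r in seq_len(k + 1)) {
    m <- rdist(3); i <- rdist(2); d <- rdist(2)
    if (r == k + 1) { m[3] <- 0; m <- m / sum(m); d <- c(1, 0) }
    if (r == 1) d <- c(1, 0)
    tr[r, ] <- c(m, i, d)
  }
  structure(list(name = name, K = k, match_emissions = me,
                 insert_emissions = ie, transitions = tr,
                 background = famforge::background_frequencies(),
                 n_seqs = 3L),
            class = "profile_hmm")
}

# length-preserving residue shuffle
shuffle_seq <- function(s) {
  paste(sample(strsplit(s, "")[[1]]), collapse = "")
}
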