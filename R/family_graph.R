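#' Build the weighted protein-similarity graph
#'
#' Filters all-vs-all hits and turns surviving pairs into undirected weighted
#' edges. A hit is kept iff its e-value is at most `evalue_max`, the alignment
#' covers at least `min_cov` of BOTH sequences, both sequences are at least
#' `min_len` residues, and query differs from subject. The edge weight is the
#' negative log10 of the e-value, with e-values below `10^-ceiling` (including
#' exact zeros) capped at `ceiling`; non-positive transformed weights are
#' dropped; reciprocal/duplicate pairs collapse to the maximum weight.
#'
#' @param hits all-vs-all hit table (see [read_blast_tab()]). `qlen`/`slen`
#'   must be present in the table or supplied via `seq_lengths`.
#' @param evalue_max e-value cut-off (the conventional 1e-5 by default).
#' @param min_cov minimum alignment coverage of either sequence.
#' @param min_len minimum sequence length in residues.
#' @param ceiling cap on the transformed weight.
#' @param seq_lengths optional named integer vector of sequence lengths used
#'   to fill missing `qlen`/`slen`.
#' @return an object of class `protein_graph`: list with `nodes` (character)
#'   and `edges` (data.frame `u`, `v`, `weight` with `u < v`).
#' @export
build_graph <- function(hits, evalue_max = 1e-5, min_cov = 0.70,
                        min_len = 50L, ceiling = 200, seq_lengths = NULL) {
  if (!is.null(seq_lengths)) {
    hits$qlen <- ifelse(is.na(hits$qlen),
                        seq_lengths[hits$query_id], hits$qlen)
    hits$slen <- ifelse(is.na(hits$slen),
                        seq_lengths[hits$subject_id], hits$slen)
  }
  if (anyNA(hits$qlen) || anyNA(hits$slen))
    stop("qlen/slen unavailable; supply 14-column hits or seq_lengths")
  keep <- hits$evalue <= evalue_max &
    hits$aln_len / hits$qlen >= min_cov &
    hits$aln_len / hits$slen >= min_cov &
    hits$qlen >= min_len & hits$slen >= min_len &
    hits$query_id != hits$subject_id
  h <- hits[keep, , drop = FALSE]
  w <- ifelse(h$evalue <= 10^(-ceiling), ceiling,
              pmin(-log10(h$evalue), ceiling))
  pos <- w > 0
  h <- h[pos, , drop = FALSE]; w <- w[pos]
  u <- pmin(h$query_id, h$subject_id)
  v <- pmax(h$query_id, h$subject_id)
  key <- paste(u, v, sep = "\r")
  best <- tapply(w, key, max)
  edges <- if (length(best)) {
    uv <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
    data.frame(u = uv[, 1L], v = uv[, 2L], weight = as.numeric(best),
               stringsAsFactors = FALSE)
  } else data.frame(u = character(), v = character(), weight = numeric(),
                    stringsAsFactors = FALSE)
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$u, edges$v))), edges = edges),
            class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  cat("protein similarity graph:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

# symmetric sparse weight matrix of a protein_graph (nodes in sorted order)
graph_matrix <- function(graph) {
  n <- length(graph$nodes)
  i <- match(graph$edges$u, graph$nodes)
  j <- match(graph$edges$v, graph$nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                       x = rep(graph$edges$weight, 2L),
                       dims = c(n, n),
                       dimnames = list(graph$nodes, graph$nodes))
}

new_cluster_set <- function(clusters, algorithm, params, n_nodes,
                            min_size = 2L, overlapping = FALSE,
                            converged = TRUE) {
  clusters <- unname(lapply(clusters, function(m) sort(as.character(m))))
  keep <- vapply(clusters, length, integer(1)) >= min_size
  clusters <- clusters[keep]
  ord <- order(-vapply(clusters, length, integer(1)),
               vapply(clusters, `[`, "", 1L))
  clusters <- clusters[ord]
  covered <- unique(unlist(clusters))
  structure(list(clusters = clusters, min_size = min_size,
                 algorithm = algorithm, params = params,
                 overlapping = overlapping,
                 singleton_count = n_nodes - length(covered),
                 n_nodes = n_nodes, converged = converged),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- vapply(x$clusters, length, integer(1))
  cat(x$algorithm, " clustering: ", length(x$clusters), " clusters (sizes ",
      if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "none",
      "), ", x$singleton_count, " singleton nodes\n", sep = "")
  invisible(x)
}

#' Cluster membership as a two-column table
#'
#' @param cs a `cluster_set`.
#' @return data.frame with columns `cluster_id`, `member_id`.
#' @export
cluster_membership <- function(cs) {
  if (!length(cs$clusters))
    return(data.frame(cluster_id = character(), member_id = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    cluster_id = rep(sprintf("cluster_%04d", seq_along(cs$clusters)),
                     vapply(cs$clusters, length, integer(1))),
    member_id = unlist(cs$clusters, use.names = FALSE),
    stringsAsFactors = FALSE)
}

#' Markov clustering of the similarity graph
#'
#' Native Markov clustering (flow simulation on the graph): a column-stochastic
#' flow matrix with per-node self-loops (loop weight = the node's maximum
#' incident edge weight) is alternately expanded (matrix squared) and inflated
#' (entrywise power `inflation`, columns renormalized) with pruning of entries
#' below `prune`, until the largest entry change drops under `tol` or
#' `max_iter` is reached. Clusters are the connected components of the
#' attractor interpretation of the limit matrix; size-1 components count as
#' singletons and are not reported.
#'
#' @param graph a `protein_graph`.
#' @param inflation inflation exponent (2 = the tool's default granularity).
#' @param prune flow entries below this are dropped each iteration.
#' @param max_iter,tol iteration cap and convergence tolerance.
#' @param min_size minimum reported cluster size.
#' @return a `cluster_set` (non-overlapping); `converged` is `FALSE` when the
#'   iteration cap was hit (a warning is raised).
#' @export
mcl_cluster <- function(graph, inflation = 2.0, prune = 1e-5,
                        max_iter = 100L, tol = 1e-6, min_size = 2L) {
  n <- length(graph$nodes)
  if (!n) stop("empty graph")
  A <- graph_matrix(graph)
  loops <- apply(A, 1L, max)
  loops[loops == 0] <- 1
  diag(A) <- loops
  M <- normalize_cols(A)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2@x <- M2@x^inflation
    M2 <- normalize_cols(M2)
    M2 <- Matrix::drop0(M2 * (M2 >= prune))
    M2 <- normalize_cols(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Markov clustering did not converge within ", max_iter,
            " iterations; interpreting current flow matrix")
  nz <- Matrix::which(M > 0, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$nodes[nz[, 1L]], to = graph$nodes[nz[, 2L]]),
    directed = FALSE, vertices = graph$nodes)
  comp <- igraph::components(g)
  clusters <- split(graph$nodes, comp$membership)
  new_cluster_set(clusters, "mcl",
                  list(inflation = inflation, prune = prune,
                       max_iter = max_iter, tol = tol),
                  n_nodes = n, min_size = min_size, overlapping = FALSE,
                  converged = converged)
}

normalize_cols <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

#' Cohesiveness of a candidate cluster
#'
#' `f(C) = W_in / (W_in + W_bound + penalty * |C|)` where `W_in` is the total
#' internal edge weight and `W_bound` the total weight of edges with exactly
#' one endpoint in `C`.
#'
#' @param graph a `protein_graph`.
#' @param members character vector of node ids.
#' @param penalty per-node penalty term.
#' @return the cohesiveness score.
#' @export
cohesiveness <- function(graph, members, penalty = 2.0) {
  W <- graph_matrix(graph)
  idx <- match(members, graph$nodes)
  if (anyNA(idx)) stop("unknown node id")
  w_in <- sum(W[idx, idx, drop = FALSE]) / 2
  w_bound <- sum(W[idx, -idx, drop = FALSE])
  w_in / (w_in + w_bound + penalty * length(idx))
}

#' Cohesiveness-greedy clustering (overlapping)
#'
#' Greedy growth of candidate clusters from seeds taken in decreasing order of
#' node total weight over nodes not yet in any cluster. At each step the
#' single best add-or-remove move that increases the cohesiveness score is
#' applied; growth stops when no move improves. Candidate clusters with
#' pairwise overlap score `|A∩B|² / (|A|·|B|)` at least `overlap_merge` are
#' merged; clusters smaller than `min_size` or with weighted density below
#' `min_density` are discarded. Ties between moves are broken
#' lexicographically by node id (additions preferred) for determinism.
#'
#' @param graph a `protein_graph`.
#' @param min_size minimum cluster size.
#' @param penalty per-node cohesiveness penalty.
#' @param min_density minimum weighted density `2·W_in / (|C|·(|C|−1))`.
#' @param overlap_merge overlap score at or above which clusters merge.
#' @return a `cluster_set` (possibly overlapping).
#' @export
cone_cluster <- function(graph, min_size = 2L, penalty = 2.0,
                         min_density = 0.3, overlap_merge = 0.8) {
  n <- length(graph$nodes)
  if (!n)
    return(new_cluster_set(list(), "cone",
                           list(penalty = penalty, min_density = min_density,
                                overlap_merge = overlap_merge),
                           n_nodes = 0L, min_size = min_size,
                           overlapping = TRUE))
  W <- graph_matrix(graph)
  deg <- Matrix::rowSums(W)
  in_any <- logical(n)
  seed_order <- order(-deg, graph$nodes)
  candidates <- list()
  for (s in seed_order) {
    if (in_any[s]) next
    members <- s
    w_in <- 0
    w_bound <- deg[s]
    f <- cohesive_score(w_in, w_bound, length(members), penalty)
    repeat {
      move <- best_move(W, deg, members, w_in, w_bound, penalty, f,
                        graph$nodes)
      if (is.null(move)) break
      members <- move$members; w_in <- move$w_in; w_bound <- move$w_bound
      f <- move$f
      if (!length(members)) break
    }
    if (!length(members)) next
    candidates[[length(candidates) + 1L]] <- sort(members)
    in_any[members] <- TRUE
  }
  merged <- merge_overlapping(candidates, overlap_merge)
  final <- list()
  for (cl in merged) {
    if (length(cl) < min_size) next
    w_in <- sum(W[cl, cl, drop = FALSE]) / 2
    dens <- 2 * w_in / (length(cl) * (length(cl) - 1L))
    if (dens < min_density) next
    final[[length(final) + 1L]] <- graph$nodes[cl]
  }
  new_cluster_set(final, "cone",
                  list(penalty = penalty, min_density = min_density,
                       overlap_merge = overlap_merge),
                  n_nodes = n, min_size = min_size, overlapping = TRUE)
}

cohesive_score <- function(w_in, w_bound, size, penalty) {
  denom <- w_in + w_bound + penalty * size
  if (denom <= 0) 0 else w_in / denom
}

# single best improving add/remove move, or NULL; ties: adds first, then
# lexicographically smallest node id
best_move <- function(W, deg, members, w_in, w_bound, penalty, f, node_ids) {
  memb_set <- logical(nrow(W))
  memb_set[members] <- TRUE
  nb <- Matrix::which(Matrix::rowSums(W[, members, drop = FALSE]) > 0)
  adds <- nb[!memb_set[nb]]
  best <- NULL
  consider <- function(kind, node, nf, nm, nwi, nwb) {
    if (nf <= f + 1e-12) return()
    if (!is.null(best)) {
      if (nf < best$f - 1e-12) return()
      if (abs(nf - best$f) <= 1e-12) {
        rank <- function(m) paste0(if (m$kind == "add") "0" else "1",
                                   node_ids[m$node])
        if (rank(list(kind = kind, node = node)) >= rank(best)) return()
      }
    }
    best <<- list(kind = kind, node = node, f = nf, members = nm,
                  w_in = nwi, w_bound = nwb)
  }
  for (v in adds) {
    w_vc <- sum(W[v, members])
    nwi <- w_in + w_vc
    nwb <- w_bound - w_vc + (deg[v] - w_vc)
    nf <- cohesive_score(nwi, nwb, length(members) + 1L, penalty)
    consider("add", v, nf, c(members, v), nwi, nwb)
  }
  if (length(members) > 1L) {
    for (u in members) {
      rest <- members[members != u]
      w_uc <- sum(W[u, rest])
      nwi <- w_in - w_uc
      nwb <- w_bound + w_uc - (deg[u] - w_uc)
      nf <- cohesive_score(nwi, nwb, length(rest), penalty)
      consider("remove", u, nf, rest, nwi, nwb)
    }
  }
  best
}

merge_overlapping <- function(candidates, threshold) {
  k <- length(candidates)
  if (k < 2L) return(candidates)
  repeat {
    merged_any <- FALSE
    for (i in seq_len(length(candidates) - 1L)) {
      for (j in seq((i + 1L), length(candidates))) {
        a <- candidates[[i]]; b <- candidates[[j]]
        ov <- length(intersect(a, b))^2 / (length(a) * length(b))
        if (ov >= threshold) {
          candidates[[i]] <- sort(union(a, b))
          candidates[[j]] <- NULL
          merged_any <- TRUE
          break
        }
      }
      if (merged_any) break
    }
    if (!merged_any) break
  }
  candidates
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table.
#'
#' @param a,b named label vectors over the same item names.
#' @return ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  common <- intersect(names(a), names(b))
  if (!length(common)) stop("no common items")
  a <- as.character(a[common]); b <- as.character(b[common])
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(common)
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# label vector over nodes assigned to exactly one cluster
unique_assignment <- function(cs) {
  memb <- cluster_membership(cs)
  counts <- table(memb$member_id)
  once <- names(counts)[counts == 1L]
  memb <- memb[memb$member_id %in% once, , drop = FALSE]
  setNames(memb$cluster_id, memb$member_id)
}

#' Compare two cluster sets over the same node set
#'
#' Reports cluster counts, size-rank vectors, mean/median sizes and the
#' adjusted Rand index restricted to nodes assigned to exactly one cluster in
#' both sets (overlapping assignments are excluded from the ARI).
#'
#' @param a,b `cluster_set` objects from the same node set.
#' @return list with `counts`, `sizes`, `summary` (data.frame) and `ari`.
#' @export
compare_clusterings <- function(a, b) {
  nodes_a <- unique(unlist(a$clusters))
  nodes_b <- unique(unlist(b$clusters))
  if (!length(intersect(nodes_a, nodes_b)))
    stop("cluster sets cover disjoint node sets")
  sizes_a <- sort(vapply(a$clusters, length, integer(1)), decreasing = TRUE)
  sizes_b <- sort(vapply(b$clusters, length, integer(1)), decreasing = TRUE)
  la <- unique_assignment(a); lb <- unique_assignment(b)
  ari <- if (length(intersect(names(la), names(lb))) >= 2L)
    adjusted_rand_index(la, lb) else NA_real_
  list(counts = c(a = length(a$clusters), b = length(b$clusters)),
       sizes = list(a = sizes_a, b = sizes_b),
       summary = data.frame(
         set = c("a", "b"),
         algorithm = c(a$algorithm, b$algorithm),
         n_clusters = c(length(a$clusters), length(b$clusters)),
         mean_size = c(mean(sizes_a), mean(sizes_b)),
         median_size = c(median(sizes_a), median(sizes_b)),
         singletons = c(a$singleton_count, b$singleton_count),
         stringsAsFactors = FALSE),
       ari = ari)
}
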