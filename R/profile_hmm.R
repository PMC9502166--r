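#' Amino-acid alphabet used by profile HMMs (alphabetical, 20 letters)
#' @export
AMINO_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Background amino-acid frequencies
#'
#' Fixed Swiss-Prot-style composition used as the null model for insert-state
#' emissions, pseudocount targets for wildcard residues, and log-odds
#' scoring. Normalized to sum exactly to 1.
#'
#' @return named numeric vector over [AMINO_ALPHABET].
#' @export
background_frequencies <- function() {
  f <- c(A = 0.0787945, C = 0.0151600, D = 0.0535222, E = 0.0668298,
         F = 0.0397062, G = 0.0695071, H = 0.0229198, I = 0.0590092,
         K = 0.0594422, L = 0.0963728, M = 0.0237718, N = 0.0414386,
         P = 0.0482904, Q = 0.0395639, R = 0.0540978, S = 0.0683364,
         T = 0.0540687, V = 0.0673417, W = 0.0114135, Y = 0.0304133)
  f / sum(f)
}

#' Assign alignment columns to match states
#'
#' A column becomes a match (consensus) column when its fraction of non-gap
#' symbols is at least `symfrac`; otherwise it is treated as insertions.
#'
#' @param msa an `msa` object.
#' @param symfrac match-column threshold (the standard default 0.5).
#' @return logical vector, one per column; at least one must be `TRUE` or the
#'   cluster is rejected as a degenerate all-gap alignment.
#' @export
assign_match_columns <- function(msa, symfrac = 0.5) {
  mat <- msa_matrix(msa)
  frac <- colMeans(mat != "-")
  match_cols <- frac >= symfrac
  if (!any(match_cols))
    stop("degenerate alignment [no_match_columns]: cluster ", msa$cluster_id)
  match_cols
}

msa_matrix <- function(msa) {
  matrix(unlist(strsplit(msa$rows, "")), nrow = length(msa$rows),
         byrow = TRUE)
}

#' Build a profile HMM from an aligned cluster
#'
#' Simplified profile construction: unweighted observed counts with Laplace
#' (+`pseudocount`) smoothing, in place of the sequence weighting and
#' Dirichlet mixture priors of full hmmbuild. Match emissions are
#' `(count + pseudocount) / (n_obs + 20 * pseudocount)` per match column;
#' insert emissions equal the background; transition probabilities are
#' counted from each row's match/insert/delete state path over the columns
#' and smoothed with +`pseudocount` per transition within each source-state
#' group. Non-standard residues (X, B, Z, ...) contribute
#' background-weighted fractional counts.
#'
#' @param msa an `msa` object.
#' @param match_cols logical per column, from [assign_match_columns()].
#' @param pseudocount Laplace smoothing constant.
#' @param name profile name; defaults to the alignment's cluster id.
#' @return object of class `profile_hmm` with elements `name`, `K`,
#'   `match_emissions` (K x 20), `insert_emissions` ((K+1) x 20),
#'   `transitions` ((K+1) x 7 : MM, MI, MD, IM, II, DM, DD; rows are nodes
#'   0..K), `background`, `n_seqs`.
#' @export
build_profile <- function(msa, match_cols = assign_match_columns(msa),
                          pseudocount = 1.0, name = msa$cluster_id) {
  bg <- background_frequencies()
  mat <- msa_matrix(msa)
  K <- sum(match_cols)
  if (K < 1L) stop("profile needs at least one match column")
  n_rows <- nrow(mat)
  # --- match emission counts (wildcards spread over the background) ---
  emiss <- matrix(0, nrow = K, ncol = 20L,
                  dimnames = list(NULL, AMINO_ALPHABET))
  n_wild <- 0L
  midx <- which(match_cols)
  for (k in seq_len(K)) {
    col <- mat[, midx[k]]
    res <- col[col != "-"]
    std <- res[res %in% AMINO_ALPHABET]
    if (length(std)) {
      tb <- table(factor(std, levels = AMINO_ALPHABET))
      emiss[k, ] <- emiss[k, ] + as.numeric(tb)
    }
    wild <- sum(!res %in% AMINO_ALPHABET)
    if (wild) {
      emiss[k, ] <- emiss[k, ] + wild * bg
      n_wild <- n_wild + wild
    }
  }
  if (n_wild)
    message(n_wild, " non-standard residue(s) mapped to ",
            "background-weighted wildcards")
  n_obs <- rowSums(emiss)
  match_emissions <- (emiss + pseudocount) / (n_obs + 20 * pseudocount)
  # --- transition counts from per-row state paths ---
  # states: 1..7 = MM MI MD IM II DM DD, rows are nodes 0..K (0 = begin)
  trans <- matrix(0, nrow = K + 1L, ncol = 7L,
                  dimnames = list(NULL,
                                  c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  node_of_col <- cumsum(match_cols)          # node index after this column
  for (r in seq_len(n_rows)) {
    state <- "M"; node <- 0L                 # begin state acts as M0
    for (j in seq_len(ncol(mat))) {
      ch <- mat[r, j]
      if (match_cols[j]) {
        to <- if (ch == "-") "D" else "M"
        # plan-7 has no I->D transition; such paths enter D uncounted
        if (!(state == "I" && to == "D"))
          trans[node + 1L, paste0(state, to)] <-
            trans[node + 1L, paste0(state, to)] + 1
        state <- to; node <- node_of_col[j]
      } else if (ch != "-") {
        # plan-7 has no D->I transition; a residue in an insert column
        # reached from a delete state enters I uncounted
        if (state != "D")
          trans[node + 1L, paste0(state, "I")] <-
            trans[node + 1L, paste0(state, "I")] + 1
        state <- "I"
      }
    }
    # exit to the end state counts as a *->M transition from node K
    trans[K + 1L, paste0(state, "M")] <- trans[K + 1L, paste0(state, "M")] + 1
  }
  transitions <- normalize_transitions(trans, K, pseudocount)
  structure(list(name = name, K = K,
                 match_emissions = match_emissions,
                 insert_emissions = matrix(rep(bg, K + 1L), nrow = K + 1L,
                                           byrow = TRUE,
                                           dimnames = list(NULL,
                                                           AMINO_ALPHABET)),
                 transitions = transitions,
                 background = bg, n_seqs = n_rows),
            class = "profile_hmm")
}

# smooth each source-state group (+pc) and renormalize; structural zeros:
# node 0 has no delete state (DM = 1); node K cannot go M->D or D->D
normalize_transitions <- function(trans, K, pc) {
  out <- matrix(0, nrow = K + 1L, ncol = 7L,
                dimnames = dimnames(trans))
  for (node in 0:K) {
    r <- node + 1L
    m <- trans[r, c("MM", "MI", "MD")] + pc
    i <- trans[r, c("IM", "II")] + pc
    d <- trans[r, c("DM", "DD")] + pc
    if (node == K) { m["MD"] <- 0; d["DD"] <- 0 }
    if (node == 0L) { d[] <- c(1, 0) }
    out[r, c("MM", "MI", "MD")] <- m / sum(m)
    out[r, c("IM", "II")] <- i / sum(i)
    out[r, c("DM", "DD")] <- d / sum(d)
  }
  out
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile HMM '", x$name, "': ", x$K, " match states, built from ",
      x$n_seqs, " sequence(s)\n", sep = "")
  invisible(x)
}

#' Validate a profile HMM object's invariants
#'
#' Checks that every emission row and every transition group sums to 1
#' within `tol` and that K >= 1.
#'
#' @param profile a `profile_hmm`.
#' @param tol numeric tolerance.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_profile <- function(profile, tol = 1e-9) {
  stopifnot(profile$K >= 1L)
  ok <- function(x) all(abs(x - 1) <= tol)
  if (!ok(rowSums(profile$match_emissions)))
    stop("match emission rows do not sum to 1")
  if (!ok(rowSums(profile$insert_emissions)))
    stop("insert emission rows do not sum to 1")
  tr <- profile$transitions
  if (!ok(rowSums(tr[, c("MM", "MI", "MD"), drop = FALSE])) ||
      !ok(rowSums(tr[, c("IM", "II"), drop = FALSE])) ||
      !ok(rowSums(tr[, c("DM", "DD"), drop = FALSE])))
    stop("transition groups do not sum to 1")
  invisible(TRUE)
}

#' Global Viterbi log-odds score of a sequence against a profile
#'
#' Plumbing scorer so profiles are testable without external search tools:
#' a global alignment Viterbi pass over the match/insert/delete lattice, with
#' emissions scored as `log2(e / background)` (insert states, whose emissions
#' equal the background, contribute 0 bits) and transitions as `log2(t)`.
#'
#' @param profile a `profile_hmm`.
#' @param seq amino-acid string (non-standard residues score 0 bits at any
#'   state).
#' @return log-odds score in bits.
#' @export
score_viterbi <- function(profile, seq) {
  if (is.null(profile$K) || profile$K < 1L) stop("empty profile")
  seq <- toupper(seq)
  if (!nchar(seq)) stop("empty sequence")
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  K <- profile$K
  bg <- profile$background
  # structurally impossible paths get a large finite penalty instead of -Inf
  # so the column recurrences stay NaN-free
  NEG <- -1e9
  l2 <- function(p) pmax(log2(pmax(p, 1e-300)), NEG)
  em <- matrix(0, nrow = K, ncol = max(n, 1L))
  known <- res %in% AMINO_ALPHABET
  if (any(known))
    em[, known] <- log2(profile$match_emissions[, res[known], drop = FALSE] /
                          rep(bg[res[known]], each = K))
  tr <- l2(profile$transitions)
  kk <- seq_len(K)
  # delete-state scan: vd[r] = P[r-1] + cummax(vm + t(M->D) - P)[r-1] where
  # P is the running sum of log t(D->D) (prefix-max form of the D chain)
  P <- cumsum(tr[kk, "DD"])
  delete_scan <- function(vm) {
    c(NEG, P + cummax(vm[kk] + tr[kk, "MD"] - P))
  }
  vm <- c(0, rep(NEG, K))              # nodes 0..K at residue prefix 0
  vi <- rep(NEG, K + 1L)
  vd <- delete_scan(vm)
  for (i in seq_len(n)) {
    new_vm <- c(NEG, em[, i] + pmax(vm[kk] + tr[kk, "MM"],
                                    vi[kk] + tr[kk, "IM"],
                                    vd[kk] + tr[kk, "DM"]))
    new_vi <- pmax(vm + tr[, "MI"], vi + tr[, "II"])
    vm <- new_vm
    vd <- delete_scan(vm)
    vi <- new_vi
  }
  last <- K + 1L
  max(vm[last] + tr[last, "MM"], vi[last] + tr[last, "IM"],
      vd[last] + tr[last, "DM"])
}
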