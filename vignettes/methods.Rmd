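---
title: "Methods: building viral protein family HMM databases with famforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building viral protein family HMM databases with famforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famforge)
```

# Scope and assumptions

famforge covers the computational middle of a viral protein family database
build: everything between the flat files written by external tools
(viral-contig predictors, CheckV-style contamination callers, gene callers,
pairwise aligners, annotation pipelines, proteomic search engines) and the
final searchable HMM flat file plus its companion metadata tables. The
external tools themselves are never executed; their output dialects are the
package's input contracts. This split keeps every stage deterministic,
testable and reproducible offline.

Three assumptions run through the design:

* **Consensus beats confidence.** Individual viral predictors disagree; a
  contig is only admitted when at least two of three independent tools call
  it viral at their strictest thresholds ("majority" tier), with a stricter
  "unanimous" tier nested inside. The unanimous set is a subset of the
  majority set on every input, by construction.
* **Contamination is handled at two levels.** Whole subregions typed as
  host are excised from contigs before gene-level work, and individual
  proteins with strong local identity to prokaryotic references are dropped
  afterwards, because prophage-bearing contigs contaminate databases both
  ways.
* **Similarity is e-value based.** Family structure is read off a weighted
  graph whose edge weights are capped negative-log e-values; clustering
  operates purely on this graph and never re-examines sequences.

# Stage-by-stage model

## Contig selection

Length thresholds are 5,000 bp for linear and 1,500 bp for circular contigs
(a complete circular genome is trustworthy at a shorter length). Topology is
an input flag, never inferred. Strict per-tool cut-offs: category 1
(VirSorter-like categorical output), score > 0.9 **and** p < 0.05
(score/p-value output), score > 0.90 (probability output); all inequalities
strict, so a score of exactly 0.9 fails. Contamination regions use 1-based
inclusive coordinates; viral spans become child contigs (topology linear,
since excision breaks a circle) and the length filter is re-applied to the
children — the source procedure leaves this order ambiguous, and we
re-filter so that sub-threshold fragments cannot reach clustering.
Conflicting duplicate score rows for one (contig, tool) resolve
most-permissively with a warning, favouring sensitivity at this stage since
later filters are stricter.

## Protein decontamination and dereplication

A protein is removed iff *any* reference hit exceeds 95% identity — no
coverage requirement, deliberately aggressive because even a
domain-length match to a prokaryotic protein can cause a family profile to
recruit host genes later. The exception list (tail, capsid, portal, virus,
virion, viral, phage, bacteriophage, terminase) is matched
case-insensitively as substrings of the *reference* hit's annotation: the
query proteins have no annotations of their own at this stage, so the
subject annotation is the only place keywords can live. Each disqualifying
hit must be excepted individually; one whitelisted and one non-whitelisted
strong hit still remove the protein. Dereplication is exact full-length
equality after normalization (uppercase, trailing stop stripped),
first-seen representative, global across the tier's protein set.

## The similarity graph

A hit becomes an edge iff e-value ≤ 1e-5, the alignment covers ≥ 70% of
*both* sequences, and both sequences are ≥ 50 residues (shorter sequences
are disproportionately mis-called or truncated genes). The printed
threshold in the source methodology reads "10e-5", which literally equals
1e-4; we adopt the conventional 1e-5 and expose the parameter. Weights are
w = −log₁₀(E) capped at 200, with E = 0 treated as capped rather than an
error; non-positive weights are dropped and duplicate/reciprocal pairs
collapse to the maximum weight (the aligner's two directions differ only by
rounding).

## Clustering

Two native algorithms are provided so their outputs can be compared on the
same graph.

**Cohesiveness-greedy (overlapping).** A candidate cluster C scores
f(C) = W_in / (W_in + W_bound + p·|C|), with W_in the internal weight,
W_bound the weight crossing the boundary and p = 2 a per-node penalty that
models unobserved edges. Seeds are taken in decreasing order of node total
weight among nodes not yet clustered; growth applies the single best
add-or-remove move while f improves; ties break lexicographically by node
id (additions preferred) so the run is deterministic. Candidates with
overlap score |A∩B|²/(|A|·|B|) ≥ 0.8 merge; clusters below size 2 or
weighted density 2·W_in/(|C|·(|C|−1)) < 0.3 are discarded. The defaults
(penalty 2, density 0.3, overlap 0.8) follow the published description of
the cohesiveness method, since the exact settings used upstream are not
restated; all are exposed.

**Markov clustering (non-overlapping).** The column-stochastic flow matrix
gets per-node self-loops equal to the node's maximum incident weight — on
weighted graphs this keeps the flow dynamics stable without letting the
loop dominate. Iterations alternate expansion (matrix squaring) and
inflation (entrywise power 2.0, column renormalization), pruning entries
below 1e-5, until the largest entry change is below 1e-6 or 100 iterations
(non-convergence returns the current interpretation with a warning flag).
Clusters are connected components of the limit matrix's nonzero pattern;
size-1 components are counted as singletons and not reported. The test
suite checks this implementation against an independent long-horizon dense
flow simulation on small random graphs.

Comparison of two cluster sets reports counts, size distributions and an
adjusted Rand index restricted to nodes assigned to exactly one cluster in
both sets, because ARI is only defined for partitions.

## Profile HMMs

Match columns are alignment columns with ≥ 50% non-gap symbols (symfrac
0.5, the standard default). Profile construction is a deliberate
simplification of full hmmbuild: unweighted observed counts with Laplace
(+1) pseudocounts for both emissions and transition groups, instead of
Henikoff sequence weighting and Dirichlet mixture priors. This makes every
number in a profile reproducible by hand at desk scale; users who need
bit-for-bit hmmbuild output can regenerate profiles from the same
alignments with the external tool. Insert emissions equal a fixed
Swiss-Prot-style background composition shipped with the package. The
plan-7 state graph has no D→I or I→D transitions; rows whose gap structure
implies one enter the target state uncounted. Node 0 has no delete state
(D→M fixed at 1) and the last node cannot go M→D or D→D.

Serialization is HMMER3/f ASCII: negative natural logs at 5 decimals, `*`
for probability zero, `//` terminators, statistical calibration lines
omitted (the database is valid but uncalibrated — E-value tau/lambda
fitting is out of scope). Round-trips through the package reader agree
within 1e-4, and the files parse with standard HMMER 3.4 tooling.

The builtin aligner is a center-star progressive aligner over global
pairwise alignments (BLOSUM62, affine gaps open −11 / extend −1): the
center maximizes the summed pairwise score, other rows merge under
once-a-gap-always-a-gap, and rows are sorted by id first so the result is
permutation-invariant. It trades alignment quality for determinism and
zero binary dependencies; the external adapter (default `muscle
-maxiters 4`) is preferred for production databases. A small global Viterbi
scorer (log₂-odds against the background) is included purely so profiles
are testable without external search tools.

## Annotation consolidation

Descriptions are *uninformative* when empty or containing
"uncharacterized", "hypothetical", "no annotation", or a DUF token (duf
followed by digits or a word boundary). *Structural* descriptions match a
virion-part vocabulary; `structur` is a prefix wildcard, and short or
ambiguous keywords (mu, gp23, gp9, head, neck, tail, coat) are matched at
word boundaries rather than as raw substrings — a plain substring search
would label "murein hydrolase" structural via "mu". This is a documented
divergence from the upstream plain string search, toggleable to pure
substring mode. Consensus annotations are normalized descriptions
(lowercase, punctuation stripped) supported by ≥ 2 distinct source
databases; the threshold is configurable because "agreed upon by different
databases" has no canonical operationalization. Cluster-size differences
between annotated and unannotated groups are tested with a two-sided
Mann–Whitney U test — the upstream analysis reports only a p-value without
naming a test, and a rank test is the natural choice for skewed size
distributions.

## Metaproteomic virion annotation

FDR(s) = #decoys(score ≥ s) / max(1, #targets(score ≥ s)) per independent
search; the cutoff keeps the largest target set with FDR ≤ 1%, and decoys
never survive. The alternative estimator 2D/(T+D) is available by
configuration. Peptides map to proteins by exact substring with I/L
equivalence on by default (the residues are isobaric and indistinguishable
to the mass spectrometer); matching runs against dereplicated
representatives and fans out to duplicate members so member sequences are
labeled too. Matched clusters become virion-associated; the statistics
separate de-novo annotations (no prior informative annotation) from
concordance checks (matched clusters whose prior annotation is not
structural).

## Benchmarking augmentation

Per-sample percent increase is 100·(n_aug − n_base)/n_base, undefined (and
reported absent) for empty baselines. Length bins default to
[1.5, 3, 5, 10, 20, ∞) kb — the source figures do not print their bins, so
we chose edges that straddle the 5 kb boundary where gene-content detectors
change behaviour; fully configurable. Transition tables introduce category
0 for "not detected" so that totals are conserved exactly
(sum of the 7×7 table = |union of contigs|, a property tested on random
runs). "Undetected or downgraded" counts moves to category 0 or into the
low-confidence categories {3, 5, 6} from elsewhere. Validation of newly
recovered contigs uses relaxed thresholds (score > 0.7 and p < 0.05, or
probability > 0.70) combined with OR — a contig confirmed by either
independent tool counts as validated.

# The synthetic world

The generators state one fixed world rather than a tunable benchmark:

* families descend from background-composition ancestors of 80–400
  residues, with per-site substitution probability 0.1 and single-residue
  indel rate 0.01 per site;
* within-family pairs get e-values log-uniform in [1e-180, 1e-20] and
  coverage ≥ 0.8 of both sequences; between-family pairs get spurious
  e-values ≥ 1e-3 at rate 0.01 — planted, not computed from alignments, so
  clustering tests isolate graph logic from alignment heuristics;
* contaminant decoys carry reference hits above 95% identity, 30% of them
  with whitelisted annotations;
* PSM scores are drawn from N(15, 2) for targets and N(8, 2) for decoys,
  2,000 PSMs per search, peptides cut fully tryptically (after K/R, never
  before P) from the planted proteins, decoys reversed;
* detection runs plant a 60%→category-2 / 40%→category-3 fate for baseline
  category-6 contigs and new-contig rates that decrease with length
  (0.5, 0.4, 0.3, 0.2, 0.1 per bin).

With substitution probability 0.1 *from the ancestor*, two family members
are ~0.81 identical to each other (0.9² plus small coincidence terms), and
the fixture tests assert that computed value. Everything is deterministic
under the seed, to the byte.

What a green suite does establish: the filters implement their thresholds
exactly; both clustering algorithms recover well-separated planted families
perfectly (ARI = 1); profiles are normalized, serializable and
discriminative against shuffled sequences; FDR control holds on the planted
score mixture; the reporting arithmetic reproduces printed bookkeeping
identities. What it does not establish: behaviour on real data where
family boundaries blur (paralogs, promiscuous domains, chimeric contigs),
where e-values correlate with alignment artifacts, or at the scale of
millions of proteins — the generators plant clean separation by design, and
no synthetic world exercises an aligner's pathologies.

# Numerical and degenerate-input choices

* Coverage is alignment columns / sequence length from the tabular hit,
  which can exceed 1 for gappy alignments; both directions must clear 0.7.
* E-value 0 caps at weight 200 instead of erroring.
* Viterbi scoring replaces −∞ with a −10⁹ penalty so structural zeros
  cannot produce NaNs in the vectorized recurrences; any path through a
  structural zero loses ~1,000 bits and cannot win when a legal path
  exists.
* All-gap (zero match column) alignments are rejected with a named error;
  single-sequence clusters cannot be aligned and are rejected upstream by
  the minimum cluster size of 2.
* Non-standard residues contribute background-weighted fractional counts
  to emissions and score 0 bits in Viterbi.
* Greedy moves, seed order, representative choice and serialization order
  are all tie-broken deterministically (lexicographic id, first-seen).

# Known limitations

* Profile construction is unweighted; deeply redundant clusters will
  over-count near-duplicate rows relative to hmmbuild's effective sequence
  number machinery (dereplication upstream removes exact duplicates only).
* Profiles are uncalibrated: no E-values from downstream HMM searches, only
  bit scores.
* The cohesiveness implementation is a faithful greedy procedure but not a
  byte-level reproduction of any specific external clustering binary.
* The center-star aligner is O(n²) in cluster size and optimizes no global
  objective; for large clusters use the external adapter.
* Markov clustering is run on dense-ish sparse matrices; graphs with
  hundreds of thousands of nodes want the dedicated external
  implementation.
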