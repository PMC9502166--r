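# famforge

famforge builds searchable profile-HMM databases of viral protein families
from metagenomic assemblies. It is aimed at viral ecologists who have contigs
from virome assemblies, predictions from several viral-identification tools,
and the standard flat-file outputs of gene callers, aligners and annotation
pipelines — and who want to turn those into a clean, decontaminated,
clustered and annotated family database that downstream HMM search tools can
consume directly.

The package implements the full database-construction methodology as
reusable, testable R code. It deliberately does **not** run any of the
external predictors, aligners or search engines — it consumes their standard
output formats (FASTA, BLAST outfmt-6 tabular, simple TSV tables) and covers
everything between them.

## The pipeline

1. **Contig selection** — contigs pass a length filter (≥ 5 kb linear,
   ≥ 1.5 kb circular) and per-tool strict cut-offs (VirSorter category 1;
   DeepVirFinder score > 0.9 and p < 0.05; MARVEL score > 90%). Contigs
   called by all three tools form the *unanimous* tier; by at least two, the
   *majority* tier. Host-typed contamination regions are excised and the
   length filter re-applied.
2. **Protein decontamination** — proteins with any reference hit at > 95%
   identity to bacterial/archaeal proteins are removed (no coverage
   requirement, all hits considered), unless the hit's annotation carries a
   viral keyword (tail, capsid, portal, virus, virion, viral, phage,
   bacteriophage, terminase). Survivors are dereplicated at 100% identity.
3. **Family clustering** — all-vs-all hits are filtered (e-value ≤ 1e-5,
   coverage ≥ 70% of both sequences, both ≥ 50 aa) and transformed into edge
   weights w = min(−log₁₀ E, 200). The graph is clustered by two native
   algorithms: a cohesiveness-greedy method with
   f(C) = W_in / (W_in + W_bound + p·|C|), and Markov clustering
   (expansion/inflation flow simulation).
4. **Profile HMMs** — each cluster is aligned (builtin deterministic
   center-star aligner, or an external tool), match columns are assigned at
   symfrac 0.5, and a match/insert/delete profile with Laplace-smoothed
   emissions and transitions is serialized to HMMER3/f ASCII (verified
   parseable by HMMER 3.4 tooling).
5. **Annotation consolidation** — per-protein annotations from KEGG,
   UniRef90, Pfam and VOGDB collapse to per-cluster detailed and consensus
   annotations, with informative/structural keyword logic and a
   Mann–Whitney test of cluster-size differences.
6. **Metaproteomic virion annotation** — PSMs are thresholded at 1% decoy
   FDR per search, surviving peptides are mapped to proteins by exact
   substring (I/L equivalent), and matched clusters are flagged
   virion-associated, with de-novo and concordance statistics.
7. **Benchmarking** — per-sample and length-binned gains of an augmented
   detection run over a baseline, 7×7 confidence-category transition tables
   (category 0 = undetected), and relaxed-threshold validation fractions.

A synthetic-fixture module (`fixture_config()`, `generate_families()`,
`generate_hits()`, `generate_contig_fixture()`, `generate_detection_runs()`,
`generate_psms()`, `generate_annotations()`) emits seeded inputs with
planted ground truth for every stage, so the entire workflow is testable
without external data.

## Worked example

```r
library(famforge)

cfg  <- fixture_config(seed = 42)          # a seeded synthetic world
fam  <- generate_families(cfg)             # 10 planted families + decoys
hits <- generate_hits(fam$proteins, fam$truth, cfg)

flt <- filter_proteins(fam$proteins, hits$reference)
#> removed 7 prokaryotic-like proteins; 64 unique proteins kept

g <- build_graph(hits$all_vs_all)
g
#> protein similarity graph: 61 nodes, 177 edges

cone <- cone_cluster(g)
mcl  <- mcl_cluster(g)
compare_clusterings(cone, mcl)$summary
#>   set algorithm n_clusters mean_size median_size singletons
#> 1   a      cone         10       6.1           7          0
#> 2   b       mcl         10       6.1           7          0
# adjusted Rand index (cone vs mcl): 1

profiles <- build_hmm_db(cluster_membership(mcl), fam$proteins, "families.hmm")
profiles[[1]]
#> profile HMM 'cluster_0001': 277 match states, built from 8 sequence(s)

psms <- generate_psms(cfg, proteins = fam$proteins)
surv <- fdr_threshold(psms$psms)$survivors
nrow(surv)
#> [1] 859      # of 2000 PSMs, at 1% decoy FDR
```

Both clustering algorithms recover the ten planted families exactly
(ARI = 1 against each other and against the planted labels); the seven
non-whitelisted contaminant decoys are the proteins removed; `families.hmm`
is a HMMER3 flat file that `hmmstat`/`hmmscan` accept after pressing.

## Command line

Every stage is exposed through `exec/famforge`:

```sh
famforge fixtures --seed 3 --out fx/
famforge select --contigs fx/contigs.fna --scores fx/tool_scores.tsv \
    --regions fx/regions.tsv --tier both --out sel/
famforge filter-proteins --proteins fx/proteins.faa \
    --ref-hits fx/ref_hits.tsv --out kept.faa --removed-report removed.tsv
famforge cluster --hits fx/all_vs_all.tsv --algorithm mcl --out clus/
famforge build-hmms --clusters clus/clusters.tsv --proteins fx/proteins.faa \
    --out families.hmm
famforge annotate --records fx/annotation_records.tsv \
    --clusters fx/true_clusters.tsv --out annot.tsv
famforge virion-map --psms fx/psms.tsv --proteins fx/proteins.faa \
    --clusters fx/true_clusters.tsv --records fx/annotation_records.tsv \
    --out vir/
famforge benchmark --baseline fx/run_baseline.tsv \
    --augmented fx/run_augmented.tsv --out bm/
```

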