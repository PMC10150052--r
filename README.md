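# clonediv

Clonal identification and diversity analysis of B-cell receptor (BCR)
repertoires.

## What problem this solves

Analyzing a B-cell repertoire starts with an unobservable quantity: which
sequences descend from the same founder cell, i.e. belong to the same
*clone*. Every diversity statistic computed afterwards — richness, Shannon
entropy, dominance, Chao estimators — depends on how clones were defined.
`clonediv` implements the three clone definitions in common use, makes
their calibration explicit and reproducible, and quantifies how strongly
diversity conclusions depend on the choice:

* **Junction-only** — clones are sets of identical junctions (CDR3s);
* **VJ & junction** — complete-linkage hierarchical clustering of the
  normalized Levenshtein distance
  `d(s1, s2) = 2·Lev(s1,s2) / (|s1| + |s2| + Lev(s1,s2))`
  between junctions, restricted to records sharing V and J gene calls;
* **Alignment-free** — tf-idf-weighted k-mer vectors (`k = 7`) of the
  3'-anchored last `L = 130` nt of each sequence, cosine distance,
  complete-linkage clustering with no use of gene calls at all.

Distance thresholds are calibrated from **negation sequences** (sequences
from unrelated individuals): the threshold is the lower δ-quantile of their
nearest-neighbor distances to the repertoire, giving specificity ≈ 1 − δ
(default δ = 1%). A bimodality-based calibration is available as a
fallback.

Diversity is quantified under Hill's unified framework,
`ᵅD = (Σ pᵢᵅ)^(1/(1−α))`, which recovers richness (α = 0), exp(Shannon)
(α → 1), inverse Simpson (α = 2) and inverse dominance (α = ∞), plus
diversity profiles over α ∈ [0, ∞], the bias-corrected Chao1 richness
estimator and the coverage-adjusted Chao–Shen Shannon estimator. Partitions
are compared with adjusted mutual information (AMI) using the *exact*
hypergeometric expected-MI, and sample rankings with Spearman correlation,
including a scan for the Hill order that maximizes cross-method rank
agreement.

Robustness utilities reproduce the standard sensitivity experiments:
sequencing-depth subsampling with fold-change analysis, 5' V-gene
truncation, V-call ambiguity/corruption injection, and potential
false-negative singleton detection. A ground-truth simulator (clonal
lineages with somatic hypermutation, unrelated singletons, negation sets)
makes the whole pipeline testable without any external data.

Intended users: immunology/AIRR bioinformaticians working with annotated
repertoire tables (AIRR Rearrangement TSV) who need defensible clone
definitions and diversity estimates.

## Worked example

```r
library(clonediv)

## a ground-truth repertoire: 50 clonal families, SHM rate 0.01/nt/edge,
## 30% unrelated singletons, plus 200 negation sequences
cfg <- simulation_config(n_clones = 50, shm_rate = 0.01, seed = 42)
sim <- simulate_repertoire(cfg)
neg <- simulate_negation_set(cfg, sim$repertoire)

## preprocess: productive records, alphabetical tie resolution,
## identical-junction collapse
rep <- collapse_identical_junctions(
  resolve_ambiguous_calls(filter_productive(sim$repertoire)), seed = 1)
rep
#> Repertoire: 224 records (junction-collapsed)
#>   total copy number: 281
#>   productive: 224 | distinct junctions: 224 | V genes: 15 | J genes: 6

## negation-calibrated threshold (specificity ~ 99%)
cal <- calibrate_threshold_negation(rep, neg, "normalized_levenshtein",
                                    delta = 0.01)
round(cal$threshold, 3)
#> [1] 0.373

clones <- cluster_vj_junction(rep, cal$threshold)
clones
#> ClonalPartition (vj_junction): 224 records in 134 clones
#>   singletons: 113 | largest clone: 12 | threshold: 0.3733333

ab <- abundance_from_partition(clones, rep)
round(diversity_indices(ab), 3)
#>     richness      shannon      simpson    dominance     evenness        chao1
#>      134.000        4.248        0.028        0.078        0.522      990.429
#> chao_shannon
#>        4.731
```

134 clones were found; the Shannon entropy of 4.25 nats corresponds to an
effective number of exp(4.25) ≈ 70 equally-abundant clones, and the largest
clone holds 7.8% of the reads (dominance). The Chao1 estimate is far above
the observed richness because 113 of the 134 clones are singletons — the
estimator extrapolates heavily from them, which is exactly the fragility
the subsampling analysis (`subsample_analysis()`) makes visible.

Because the repertoire is simulated, recovery can be scored against the
known clonal assignment (AMI, 1 = perfect):

```r
truth <- new_clonal_partition(sim$truth$assignment, "truth")
round(adjusted_mutual_information(expand_partition(clones, rep), truth), 3)
#> [1] 1
jo <- expand_partition(cluster_junction_only(rep), rep)
round(adjusted_mutual_information(jo, truth), 3)
#> [1] 0.245
```

The V/J + junction definition recovers the simulated clones essentially
perfectly here, while the junction-only definition fragments hypermutated
lineages (AMI 0.25).

A command-line interface wraps the same functions:

```sh
exec/clonediv simulate --n-clones 200 --seed 1 -o rep.tsv --truth truth.tsv --negation neg.tsv
exec/clonediv cluster  --method vjj --negation neg.tsv --seed 1 rep.tsv -o clones.tsv
exec/clonediv diversity clones.tsv -o div.tsv
exec/clonediv compare  clones.tsv truth.tsv -o ami.tsv
```

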