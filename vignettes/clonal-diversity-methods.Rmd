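---
title: "Clonal identification and diversity estimation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal identification and diversity estimation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonediv)
```

## The problem

B cells diversify their receptors (BCRs) in two stages: V(D)J recombination
creates a founder sequence, and somatic hypermutation (SHM) during affinity
maturation scatters point mutations over the whole rearrangement — not only
the junction (CDR3). Repertoire sequencing yields tens of thousands of such
sequences per sample, and nearly every downstream question (clonal
expansion, diversity, convergence) first requires grouping the reads into
*clones*: sets of cells descended from one founder. There is no observable
label for clonal identity in experimental data, so a clone definition is a
modeling choice, and diversity statistics inherit every bias of that choice.
This package implements three widely used clone definitions, keeps their
calibration explicit, and quantifies how much of a repertoire's diversity
profile depends on the definition rather than on the biology.

## Preprocessing model

`read_repertoire()` consumes tables that have already been annotated by a
germline aligner (AIRR Rearrangement TSV); germline alignment itself is out
of scope, which keeps the package deterministic and free of external
databases. The preprocessing chain is:

1. keep productive records (`filter_productive()`);
2. resolve top-score-tied gene calls alphabetically
   (`resolve_ambiguous_calls()`), the common deterministic convention;
3. merge records with byte-identical junctions into one representative with
   summed copy number (`collapse_identical_junctions()`). Identical
   junctions are taken as sufficient evidence of clonal identity, because a
   chance junction collision between unrelated founders is vanishingly
   unlikely; collapsing is purely computational and is undone by
   `expand_partition()` whenever partitions are compared at the sequence
   level.

The ordering — filter first, then collapse — is a genuine choice: collapsing
first can elect an unproductive representative and silently delete its whole
junction group on filtering. Filtering first avoids that failure mode, and
the two orders provably agree on the partition of the productive records
(this is asserted in the test suite).

Gene calls are compared at gene level by default (`collapse_alleles = TRUE`
strips `*01`-style suffixes), since clone definitions conventionally ignore
alleles; records with empty junctions are excluded with a message.

## The three clone definitions

**Junction-only** (`cluster_junction_only()`): clones are equivalence
classes of identical junctions. Parameter-free, but any SHM hit inside the
junction splits a lineage, inflating richness.

**VJ & junction** (`cluster_vj_junction()`): records are grouped by their
(V, J) gene pair; within a group, complete-linkage hierarchical
agglomerative clustering (HAC) of the normalized Levenshtein distance

$$d(s_1, s_2) = \frac{2\,\mathrm{Lev}(s_1, s_2)}{|s_1| + |s_2| + \mathrm{Lev}(s_1, s_2)}$$

between junctions is cut at a threshold. The normalization bounds the
distance in [0, 1] and tolerates the small length differences that indels
introduce. Note that thresholds here are *distances*: the conventional "90%
junction similarity" is `threshold = 0.1`.

**Alignment-free** (`cluster_alignment_free()`): every sequence is reduced
to its 3'-anchored window of `L` nucleotides, decomposed into overlapping
`k`-mers, and tf-idf weighted: $w(s, m) = tf(s, m)\cdot\log(|S|/df(m))$
with $df$ the number of corpus sequences containing k-mer $m$ (natural
log, no smoothing). Sequences are compared by cosine distance and clustered
by complete-linkage HAC over the whole repertoire, with no V/J grouping —
that is the method's point: it needs no germline calls at all, so it is
immune to V-gene misassignment. Defaults `k = 7`, `L = 130` follow the
published calibration of this vectorization for clonal identification. The
window is anchored at the 3' end so that 5'-truncated reads (a common
library-preparation artifact) lose only V-gene sequence, never the junction.

Two deliberate conventions in the tf-idf stage: the idf denominator is the
*document frequency* (sequences containing the k-mer), which is the standard
tf-idf reading — an occurrence-count variant is available via
`idf = "occurrence"` for sensitivity checks; and k-mers containing `N` are
skipped, since ambiguous bases carry no identity. A zero vector (possible
for very short or N-rich sequences) is assigned cosine distance 1 to
anything nonzero and 0 to another zero vector, so degenerate records cannot
inject NaNs into the clustering.

### Why an explicit HAC implementation

Complete-linkage merges are not unique when merge heights tie, and junction
edit distances tie constantly (they are ratios of small integers). The flat
partition at a cut height can genuinely differ between two valid merge
orders, so reproducibility requires pinning the tie rule. `hac_complete_cut()`
therefore implements the agglomeration directly with a documented
deterministic tie-break — among tied pairs, merge the one whose lowest
original member index is smallest — rather than delegating to a generic
dendrogram routine whose tie behavior is unspecified. On tie-free inputs it
agrees exactly with `stats::hclust(method = "complete")` + `cutree()`, which
the test suite uses as an independent cross-check; an O(n³) textbook
agglomerator serves as a second oracle on small random instances.

### Threshold calibration

The default calibration (`calibrate_threshold_negation()`) uses *negation
sequences*: sequences from unrelated individuals, which cannot be clonally
related to the repertoire. For each negation sequence we record the distance
to its nearest repertoire neighbor — restricted to same-V/J records for the
junction metric (distance 1 when no such record exists), unrestricted for
the cosine metric — and set the threshold to the lower empirical
$\delta$-quantile (order statistic at index $\lceil\delta N\rceil$) of those
distances. By construction at most a fraction $\approx \delta$ of unrelated
sequences falls below the threshold, i.e. specificity $\approx 1-\delta$;
the default tolerance is $\delta = 0.01$. Negation sequences are vectorized
against the repertoire's *fixed* tf-idf corpus so that the calibration set
cannot change the clustering itself.

The alternative (`calibrate_threshold_bimodal()`) exploits the expected
bimodality of within-repertoire nearest-neighbor distances (clonal relatives
near zero, unrelated sequences far): a Gaussian kernel density (Silverman's
bandwidth) is fitted and the threshold placed at the density minimum between
the two highest modes. It needs no external data but fails honestly — with a
pointer to the negation method — when the distribution is unimodal, and it
requires at least 50 distances.

## Diversity model

All diversity statistics operate on an abundance vector $p_1,\dots,p_S$ of
relative clone sizes. The Hill number

$${}^{\alpha}D = \Big(\sum_{i=1}^{S} p_i^{\alpha}\Big)^{1/(1-\alpha)}$$

is the common currency: $\alpha = 0$ is richness, $\alpha \to 1$ gives
$\exp(H)$ with $H$ the Shannon entropy (nats throughout; the exp/log
pairing forces a consistent base and we use the natural one), $\alpha = 2$
the inverse Simpson index, $\alpha = \infty$ the inverse dominance, and
$1 \le {}^{\alpha}D \le S$ always. Orders below 1 weigh rare clones, orders
above 1 the common ones. `hill_diversity()` handles $\alpha \in \{0, 1,
\infty\}$ by their closed-form limits and evaluates everything else in log
space (log-sum-exp), so large orders do not underflow.

`diversity_profile()` maps an even grid $A \in [-1, 1]$ through
$\alpha = \exp(\tan(A\pi/2))$, which compresses $\alpha \in [0, \infty]$
into a finite, symmetric axis; the endpoints are assigned their exact
limits (richness and inverse dominance) instead of evaluating
$\tan(\pm\pi/2)$.

Under incomplete sampling, `chao1_richness()` applies the bias-corrected
estimator $S_{obs} + f_1(f_1-1) / (2(f_2+1))$ and `chao_shannon()` the
coverage-adjusted entropy estimator with $C = 1 - f_1/n$ and
$\tilde p_i = C p_i$,

$$\hat H = -\sum_i \frac{\tilde p_i \log \tilde p_i}{1 - (1-\tilde p_i)^n}.$$

The coverage adjustment is sometimes written as a quotient $p_i / C$; that
variant is selectable (`adjust = "quotient"`) but the product form is the
default, being the standard coverage-shrinkage construction (the quotient
form can push $\tilde p$ above 1). An all-singleton sample has zero
estimated coverage and raises an error rather than returning a number.

Clone sizes can be counted per collapsed representative or per read
(`weight = "copy_counts"`, the default, which includes duplicate reads);
the choice matters for the Chao estimators, whose $f_1$, $f_2$ must be raw
observation counts. In `clonal_composition_summary()` a clone sitting at
exactly 1% abundance counts as *expanded* — the boundary needs a tie rule
and this one keeps "non-expanded" strictly below 1%.

## Comparing partitions and rankings

`adjusted_mutual_information()` computes
$(MI - E\{MI\}) / (\max(H_A, H_B) - E\{MI\})$ with the expected MI evaluated
*exactly* under the permutation model with fixed cluster sizes
(hypergeometric cell counts), grouped over unique size pairs so that
repertoires with thousands of singleton clones remain fast. Monte-Carlo
estimation is never used; the test suite checks the expectation against
exhaustive enumeration of all label permutations at $n = 6$. Two entropy-zero
partitions are identical and score 1 by convention.

`spearman_rank_agreement()` and `optimal_alpha_scan()` ask a different
question: do two clone definitions *rank samples* the same way, even when
their absolute diversity values differ? The scan evaluates the mean
pairwise Spearman correlation of per-sample Hill values over a grid of
orders (default 0 to 100 in steps of 0.01, the resolution at which the
curve is smooth) and reports the first argmax — a deterministic rule on flat
curves. Replicate samples are kept separate and correlated as-is;
correlations are averaged over method pairs only.

## Robustness experiments

`subsample_analysis()` emulates reduced sequencing depth by drawing reads
(representatives expanded by copy number) without replacement, re-running
clustering on every draw, and reporting fold changes of each index against
full depth. The threshold is calibrated once at full depth and held fixed —
the subsamples are the *same* sample at lower depth, so recalibrating would
conflate two effects. Expected behavior, asserted on the simulator:
rare-clone-sensitive orders ($\alpha < 1$) collapse at low depth while
dominance and other $\alpha > 1$ indices stay near 1; the Chao corrections
do not reliably reduce this sensitivity, since they lean on the singleton
count, which is exactly what clonal misidentification and subsampling
distort most.

`truncate_v_region()` removes the first `n_nt` nucleotides (default 70) to
emulate FR1-primer libraries. Re-annotation of truncated reads is outside
the package's scope (it would need an aligner), so the downstream
consequence — wrong V calls — is injected directly by
`inject_annotation_ambiguity()`: with a configurable probability the
primary V call is replaced by a different gene (truth demoted into the
alternatives), and tied candidate lists can be added at a second rate.
`false_negative_singletons()` then quantifies the damage: a singleton is a
*potential false negative* when one of its top-`top_n` alternative (V, J)
pairs (Cartesian product, capped per gene) would admit it into an existing
clone at the same distance threshold under the complete-linkage criterion.
An optional second partition reports the fraction of those flagged
singletons it "rescues" as non-singletons.

## The simulator

`simulate_repertoire()` generates the ground truth everything is validated
against. Layout per sequence: a per-gene random V stub (210 nt), a random
junction (27–60 nt, uniform per founder), and a J stub (40 nt) — ~300 nt
total, like a heavy-chain read, and long enough that the 130 nt 3' window
always retains the junction. Clonal families grow along random binary
(Yule-type) splitting trees, or stars; every tree edge mutates each position
independently with probability `shm_rate` (default 0.01), junction included.
Unrelated singleton founders are added so that they form 30% of records by
default, and `simulate_negation_set()` draws founder-style sequences from
the same germline pools under an independent seed stream, rejection-sampled
so no negation junction equals a repertoire junction.

Free parameters that the underlying study conditions do not pin down, fixed
here once: the clone-size distribution (power law with exponent 2 on sizes
1–50, a conventional heavy-tailed choice for clonal expansions), the
singleton fraction (0.3), the gene pool sizes (15 V, 6 J), and the stub
lengths. The simulator reproduces the *statistical structure* of simulated
benchmark repertoires — clonal families with variable sizes and junction
lengths, SHM divergence, unrelated singletons — not any particular
published dataset or learned tree topology.

What the simulator does **not** emulate: indels during SHM (off by default;
the normalized Levenshtein metric anticipates them, but substitution-only
lineages keep ground truth crisp), SHM hotspot motifs, selection, isotypes,
paired chains, and sequencing error as distinct from SHM. Passing tests on
this simulator therefore demonstrate correctness of the algorithms and the
direction of the method effects, not performance on any particular
experimental protocol.

## Numerical and scale choices

* Distances are symmetrized and clamped to [0, 1] after floating-point
  round trips; diagonals forced to zero.
* The negation quantile uses the lower order statistic, never
  interpolation — specificity guarantees are about order statistics.
* HAC ties: lowest member index, as above. Junction-collapse
  representatives are drawn with an explicit seed and the global RNG state
  is restored afterwards.
* Test and validation problem sizes (a few hundred clones, hundreds of
  negation sequences, 100 subsampling repetitions, 10 simulation seeds)
  were chosen so the whole validation suite completes in minutes on one
  core while keeping the statistical assertions well-powered; they are
  smaller than the tens-of-thousands-of-reads scale of real repertoires,
  which the algorithms handle but the test suite does not exercise.

## Known limitations

* The alignment-free partition depends on the idf corpus: adding unrelated
  sequences changes weights and can change clusters. This is inherent to
  corpus-dependent embeddings and is surfaced, not hidden (see
  `extra_corpus`).
* Probabilistic clone inference via lineage reconstruction (unmutated
  common ancestor models) is out of scope, as are learned sequence
  embeddings.
* `calibrate_threshold_bimodal()` is a fallback, not the default: kernel
  density valleys are sensitive to bandwidth on small samples.
* AMI between methods is computed on the same preprocessed record set;
  disagreements caused by preprocessing itself (e.g. productivity calls)
  are not measured.
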