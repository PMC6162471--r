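---
title: "Ranking miRNAs by network topology: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking miRNAs by network topology: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnetmapper)
```

## The model

miRNAs act canonically by binding target mRNAs and repressing them, mostly
through transcript degradation, so in a paired differential-expression
experiment an upregulated miRNA is expected to leave a footprint of
downregulated targets (and vice versa). The package takes that footprint —
a predicted miRNA–target edge list already restricted to DE molecules — as
its raw material and treats it as a bipartite network. Five assumptions
underlie everything downstream:

1. miRNA regulation is inversely correlated with target expression
   (canonical silencing);
2. the effect of a miRNA depends on the cellular context, so only
   interactions observed among this experiment's DE molecules matter;
3. a miRNA regulating many targets matters more for the phenotype than one
   regulating few (miRNA centrality);
4. two miRNAs with many common targets act similarly regardless of
   sequence family (structural equivalence); and
5. a gene targeted by many miRNAs is likely a key gene of the system (gene
   centrality).

Assumption 1 is operational, not computed: the package accepts **one
sign-stratum per run** (e.g. upregulated miRNAs against downregulated
genes). An experiment with both strata is analyzed in two runs; enforcing
the sign pairing is the caller's responsibility because the edge list
carries no expression values.

From the edge list we build the binary gene × miRNA incidence matrix. Row
sums are gene degrees of centrality. For a miRNA with $t$ distinct
targets, impact is reported as $100\,t/T$ (share of the $T$ genes targeted
by at least one miRNA — the miRNA's centrality within the network) and
$100\,t/G$ (share of the $G$ DE genes — its impact on the experiment as a
whole). Structural equivalence uses the Jaccard distance
$D_{ij} = 1 - |t_i \cap t_j|/|t_i \cup t_j|$ on target sets, clustered
agglomeratively.

### Why Jaccard?

In networks where target lists are large and mostly non-overlapping, a
similarity measure must count only the **mutual presence** of targets.
Simple-matching-style coefficients (and chi-square statistics on the 2×2
incidence table) would score two miRNAs as similar merely because both
fail to target thousands of the same genes; the Jaccard coefficient
ignores joint absences entirely and is a proper metric on finite sets,
which the test suite verifies (symmetry, zero diagonal, unit range,
triangle inequality) on every generated instance.

## Operational definitions

Two quantities the impact formulas need are not self-evident from an edge
list, and we fix them as follows:

* **T** is the number of *distinct* genes targeted by at least one miRNA
  in the (post-intersection) interaction table — equivalently the number
  of rows of the adjacency matrix. This is the only reading under which a
  single $(T, G)$ pair reproduces both percentage columns consistently
  across all miRNAs, and it makes $t \le T$ automatic.
* **G** is the number of distinct genes in the DE list. The DE list is
  optional; when absent, $G$ falls back to $T$, the two percentage columns
  coincide, and the written table renames the DE column
  `Percentage_of_DE_Genes(derived:G=T)` so the fallback is never silent.

Interaction lists pulled straight from prediction repositories may contain
genes outside the experiment's DE universe. `validate_universe()`
implements the intersection rule: policy `strict` drops such edges (and
aborts if nothing survives), policy `warn` — the default, since users who
prepared their input correctly should not have rows silently removed —
keeps them but reports the stray genes.

## Numerical and determinism choices

* **Percentages** are stored at full double precision; rounding is applied
  only at rendering time, using base R's round-half-to-even, with 1
  decimal as the tabular default. Whether half-even or half-up is "right"
  is undecidable at one decimal for realistic values; half-even is R's
  native behavior and is documented rather than configurable.
* **Linkage** defaults to `complete`, the default of `stats::hclust`'s
  ecosystem for this kind of analysis; `average` (UPGMA) and `single` are
  selectable. The dendrogram's shape depends on this choice, so it is
  recorded in the run manifest.
* **Tie-breaking.** Agglomeration order is ambiguous when two candidate
  merges share the minimal linkage value (common with Jaccard distances,
  which are ratios of small integers). We merge the pair whose
  concatenated sorted leaf names are lexicographically smallest. This
  makes the tree a pure function of the distance matrix, independent of
  input row order — a property the suite tests directly. The clustering is
  implemented in the package (Lance–Williams updates) precisely so the tie
  rule is under our control; on tie-free matrices its merge heights equal
  `stats::hclust`'s, and the tests also check them against a naive
  agglomerative re-implementation that recomputes every linkage value from
  the original distances.
* **Row/column order** of the written adjacency matrix is decreasing
  degree, then identifier — the layout a reader scans for hubs. Ties at
  equal degree are resolved lexicographically for byte-for-byte
  reproducible outputs.
* **Degenerate inputs.** Zero-target miRNA columns (possible after strict
  intersection) are dropped with a warning before the distance
  computation, because $0/0$ leaves the Jaccard distance undefined;
  assigning such miRNAs distance 1 to everything would fabricate
  structure. If the caller supplies the full DE miRNA cohort via
  `mirna_list`, members without surviving targets are reported in a
  dedicated `zero_impact_mirnas` field (and in the run manifest) rather
  than as zero rows of the impact table, mirroring how such miRNAs are
  normally absent from published impact tables while still deserving
  explicit mention. Fewer than two miRNAs is a hard "nothing to cluster"
  error.
* **Identity heatmap.** The heatmap renders Jaccard *similarity*
  ($1 - D$), so the diagonal is identically 1 — that is what "identity"
  promises — while the file written to disk is the distance matrix itself,
  the quantity downstream tools want. Rows and columns follow the
  dendrogram's leaf order.
* **Newick export** assigns branch lengths by splitting each merge height
  at its midpoint (two leaves merged at height $h$ each get a branch of
  $h/2$), the standard ultrametric rendering.

## What the generator simulates — and what it does not

`simulate_network()` produces the structures the method is designed to
detect: planted **hub genes** (each targeted by a chosen number of
miRNAs) and planted **miRNA clusters**, groups whose members share a
common core comprising a fraction `within_cluster_overlap` of their
target budget, with cluster gene pools kept disjoint so between-cluster
target sets do not overlap. A `decoy_frac` of never-targeted genes is
appended to the DE list so that $G > T$, as in real experiments. One
integer seed drives all sampling (the global RNG stream is saved and
restored), and `write_network()` emits the exact input formats the
readers consume plus a sidecar JSON of the generator arguments.

Defaults are sized to a typical single-stratum experiment: low tens of
miRNAs against a DE universe of order $10^3$ genes, with each miRNA
targeting a quarter of the gene pool. Validation runs use deliberately
small instances — networks of up to 20 miRNAs × 50 genes for the
distance-matrix oracles, 6–10 leaves for the clustering oracles, and 10
miRNAs × 120 genes over 20 seeds for recovery — because every check there
is exact or combinatorial and gains nothing from scale.

The generator does **not** simulate expression values, fold changes,
p-values, prediction-score noise, or overlapping cluster membership. A
passing recovery test therefore shows that the pipeline turns clean
set-overlap structure into the correct partition and ranking; it does not
show that target-prediction noise or soft cluster boundaries in real data
will be resolved, and with `within_cluster_overlap` near the background
density there is genuinely no separation to find (the recovery report
then says so instead of asserting).

## Scope and limitations

* Everything upstream is out of scope: differential-expression testing,
  target-prediction retrieval and filtering, and sign-stratum assembly all
  happen before the edge list reaches this package.
* The adjacency is strictly binary; prediction confidence scores and
  fold-change weighting are deliberately not modeled — impact here is a
  count-based centrality, which is the point of the method.
* Dendrogram leaf order is deterministic given the linkage and tie rule
  but is not unique across implementations; comparisons with trees from
  other software should be made on merge heights and induced partitions,
  not on leaf order.
* Only canonical (repressive) miRNA action is represented; noncanonical
  modes fall outside the model.
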