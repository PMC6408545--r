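---
title: "Methods: rank signatures, network overlap, and qPCR rank products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank signatures, network overlap, and qPCR rank products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sig2net)
```

`sig2net` turns one expression dataset containing two crossed disease
phenotypes into a pair of disease-specific gene networks and their
overlap, plus a qPCR validation branch. This vignette is the package's
account of the underlying methods: the models and their assumptions,
the parameters that matter, the numerical conventions, and what the
synthetic-data validation does and does not establish.

## The signature model

A sample's transcriptional state is summarized not by absolute levels
but by *which features are most extreme relative to the cohort*. The
reference profile is the genewise average across the whole dataset;
each sample is divided by it (`fold_change_profiles`). On log2 data the
same operation is a subtraction; the scale is an explicit flag
(`scale = "linear"` or `"log2"`), never auto-detected — a silent
heuristic would be untestable and wrong exactly when it matters.

Ranking raw fold changes mixes disease signal with age, sex and other
nuisance structure, so a feature-selection step precedes signatures:
per feature and per configured group contrast, a two-sample Student's
t-test with pooled variance, two-sided, on the fold-change values; the
selected set is the union over contrasts of features with p below
`alpha` (default 0.01). The classical pooled two-sided test is used
because it is the standard reading of an unqualified pairwise t-test;
features with zero pooled variance and equal means are excluded as
informationless (zero variance with unequal means is kept — the
evidence for separation is infinite, not absent). The default
contrasts compare the two phenotype-positive groups with their matched
controls within each cohort, which is the design under which a few
hundred of 20000 features survive at `alpha = 0.01`.

Each sample's signature is the first `n1` and last `n2` features of
its fold-change ranking (defaults `n1 = n2 = 100`). All rankings use
one deterministic tie rule — value descending, then feature id
ascending — so results are identical across platforms.

## The enrichment-score distance

Two samples are compared by scoring each one's signature lists against
the other's *full* ranking. For a set $S$ and ranking $R$ over $G$
features, walk $R$ accumulating $+1/|S|$ at members of $S$ and
$-1/(G-|S|)$ elsewhere; $ES(S,R)$ is the signed value of the running
sum at its largest absolute excursion (the classic unweighted
Kolmogorov–Smirnov enrichment score; we deliberately use unweighted
increments rather than value-weighted ones, as only ranks are
available once signatures are extracted). The symmetrized similarity

$$\mathrm{sim}(A,B) = \tfrac14\left[ES(up_A,R_B) - ES(down_A,R_B) +
ES(up_B,R_A) - ES(down_B,R_A)\right] \in [-1,1]$$

gives $d(A,B) = 1 - \mathrm{sim}(A,B) \in [0,2]$. The signed-extremum
form is the one convention under which the two boundary cases behave
correctly: identical signatures and rankings give distance 0, and
perfectly reversed profiles give distance 2 (a "maximum of the running
sum" convention would bound the distance at 1 and lose the reversed
case). When the positive and negative excursions tie in magnitude, the
first one encountered wins — an arbitrary but fixed rule that keeps
the distance deterministic.

The sample map connects pairs whose distance falls in the bottom `k`%
(default 10) of the strictly-upper-triangle distances; the threshold is
the k-th percentile under linear interpolation (R's default quantile
definition, type 7), with ties at the threshold included. No convention
for the percentile is canonical; this one is simply fixed and
documented.

## Consensus signatures

Group-level signatures aggregate by *popularity*: for each feature,
the number of subject up-lists (resp. down-lists) containing it. The
consensus up-list is the `n1` most popular up features — ties broken
by smaller mean position within the up-lists, then feature id — and
the down-list symmetrically (`n2` features, ties by mean position
closer to the bottom extreme). Both full popularity tables are kept in
the result.

One subtlety is resolved here as a design choice: with a few hundred
selected features and 200-long subject signatures, a mid-ranked
feature can fall in some subjects' up-lists and other subjects'
down-lists and qualify for both consensus lists. Since a consensus
must name `n1 + n2` *distinct* probes to be a usable seed list, such a
feature is assigned to the direction where its popularity is higher
(ties go up) and the other list back-fills from its next candidates. A
single-subject group therefore reproduces that subject's signature
exactly.

## Networks and overlap

The interactome is built from BioGRID-style records by keeping
physical, within-taxon (default 9606) interactions and collapsing them
to unique unordered symbol pairs; self-interactions are dropped (they
never change 1-step reachability and distort edge counts). Disease
networks are the *seed-incident* edges — the seeds' direct 1-step
interactions, not the induced subgraph on seeds plus neighbours, which
would add neighbour–neighbour edges the seed list never asked for.
Seeds absent from the interactome are reported as unmapped rather than
kept as isolated nodes: they carry no interaction evidence, but hiding
them silently would bias the seed accounting. The cross-disease module
is the plain node and edge intersection of the two networks,
commutative and monotone by construction.

## Over-representation

Gene lists are tested against GMT collections with the upper-tail
hypergeometric test (`P(X \ge k)`; depletion is out of scope) within
an explicit universe. The universe is a flag — all annotated platform
genes (default) or all interactome nodes — because the choice changes
p-values materially and should never be implicit. Sets are filtered to
5–2000 members within the universe before testing (configurable), a
standard guard against degenerate tails that is an addition of this
implementation. Benjamini–Hochberg adjustment spans every size-passing
set, including zero-overlap sets (excluding them would bias the FDR),
though only overlapping sets are reported.

## qPCR branch

ΔΔCt uses, per animal, the arithmetic mean of the reference-gene Ct
values — equivalent to normalizing expression by the geometric average
of the references' $2^{-Ct}$ levels — then subtracts the control-group
mean ΔCt per gene and reports $2^{-\Delta\Delta Ct}$.

The rank-product test forms all $|A| \times |B|$ between-group
pairwise ratio comparisons (the original unpaired two-class
formulation), ranks genes within each comparison (ascending ratio for
the down direction, descending for up; ties get average ranks — the
test operates on log-ratios internally, which changes nothing under
ranks), and reports the geometric mean of ranks so values are
comparable across comparison counts. Significance comes from a
sampled null: `n_perm` draws of independent uniform ranks per
comparison, with smoothed p-values $(\#\{RP_{null} \le RP\} + 1) /
(n_{perm} + 1)$ — under the null a fixed gene's ranks are exactly
independent uniforms, so a single null sample serves both directions.
An estimated false-positive proportion ($p \cdot G / \mathrm{rank}(RP)$)
accompanies each direction, and the pipeline additionally reports
BH-adjusted p-values, since the appropriate multiplicity correction
for small panels is a judgement call left to the analyst.

## Synthetic data: what it emulates and what it does not

The generators reproduce the statistical structure the analysis
assumes, at the study's own scale:

* **Expression**: four groups of 20/12/6/19 samples, 20000 features,
  Normal noise (SD 1) on the log2 scale around a baseline of 8, with
  10 up- and 10 down-planted features per group shifted by 2 SD. At
  these settings the p < 0.01 union selection passes a few hundred
  features, matching the regime the signature method was designed for.
* **Interactome**: uniform random distinct pairs (default 30000 edges
  over the platform's symbols) plus a planted path module through the
  disease groups' planted genes, guaranteeing a non-empty cross-disease
  overlap with known membership.
* **Gene sets**: uniform decoys plus one planted set with fixed overlap
  to a known query, sized so the closed-form hypergeometric p is far
  below any reasonable threshold.
* **qPCR**: 3 reference genes at Ct ≈ 20 and 80 targets at Ct ≈ 25
  (configurable baselines in plausible assay ranges), noise SD 0.25
  cycles, 6 animals per group, and 2-fold planted changes implemented
  as −1 cycle shifts.

Deliberately absent: probe-level effects, batch structure, missing
values, correlated co-expression modules, hub-dominated (scale-free)
interactome topology, and amplification-efficiency drift. Passing
recovery tests on this data therefore shows the pipeline's machinery
is correct and well-calibrated under its own assumptions — not that
the method is robust to the artefacts of any particular platform.

Every generator is a pure function of parameters + seed;
`simulate_dataset` writes the complete input directory along with a
`truth.json` recording all planted structure.

## Numerical and reproducibility choices

* Gene symbols are uppercased at every boundary, so expression,
  interactome and gene-set sources match case-insensitively.
* Unannotated probes are dropped at translation (networks and gene
  sets are symbol-keyed); probes sharing a symbol collapse to one.
* The geometric mean of ranks is clamped into its mathematical range
  $[1, G]$ (exp/log round-trips can overshoot by one ulp), and the
  permutation-count comparison uses a relative $10^{-9}$ tolerance so
  exact rank ties are counted as ties.
* The run manifest omits wall-clock timestamps unless
  `include_timestamps = TRUE`, so a fixed config + seed reproduces the
  output tree byte for byte; stage record counts are always included,
  and the manifest is written on failure too, tagged with the failing
  stage.
* Validation problem sizes: unit tests run on reduced datasets (2000
  features, 8 samples/group); end-to-end checks use the full default
  scale above, which completes in seconds on one core.

## Known limitations

* The enrichment-score distance is one fixed convention among several
  plausible ones (weighted increments, max-only extremum); rankings
  produced by other conventions are not comparable.
* Over-representation ignores gene-set structure (no ontology
  propagation or term-similarity reduction); closely related sets will
  co-flag.
* The rank-product permutation null assumes exchangeable genes within
  a comparison; strong inter-gene correlation makes the p-values
  anti-conservative, as with any gene-wise permutation scheme.
* One-step network expansion inherits study bias from the interaction
  database: heavily studied genes acquire neighbours more easily, and
  overlap counts are not comparable across database releases.
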