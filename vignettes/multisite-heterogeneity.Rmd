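---
title: "Quantifying multisite tumor heterogeneity with bcchet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multisite tumor heterogeneity with bcchet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcchet)
```

## The problem

When a tumor is excised and profiled as a single bulk sample, the result
is an average over whatever cell populations happened to be in that
piece. Sampling the same lesion at several locations and profiling each
piece separately turns heterogeneity into a measurable quantity: if the
pieces of one tumor differ from each other almost as much as tumors from
different patients differ, single-site biopsies cannot represent the
lesion. `bcchet` implements four complementary ways of asking that
question on multisite cohorts — correlation structure, presence/absence
intersections, per-gene fold-change screening, and per-position
expressed-allele divergence — together with a synthetic cohort generator
used to validate all of them.

The cohort design the package emulates is 3 histological subtypes
(infiltrative, superficial, nodular) × 3 patients per subtype × 3
sampled locations per lesion for proteomics (27 samples), a 3-patient ×
3-location subset for RNA-seq (9 samples), and a 5-replicate
noise-control group of repeated LC-MS measurements of one unrelated
sample.

## Correlation groups and the misclassification probability

Every unordered pair of samples gets a Spearman and a Pearson
correlation and a group label derived from the annotation:

* **Group 2** — both samples from the same patient (intra-tumor),
* **Group 1 intra-subtype** — different patients, same subtype,
* **Group 1 inter-subtype** — different subtypes,
* **Group 3** — noise-control replicate pairs.

For a 27-sample cohort these partition the `choose(27, 2) = 351` pairs
into 27 / 81 / 243, and the 5 noise replicates add `choose(5, 2) = 10`
Group 3 pairs. Low Group 2 values — comparable to Group 1 — indicate
high intra-tumor heterogeneity.

Two missing-value policies are offered, because LFQ missingness is
informative (a missing protein was not observed): the default treats
absent intensities as 0 over the union of features observed in either
sample of the pair; `missing_policy = "pairwise"` restricts to complete
features. Pearson is computed on raw intensities by default, with a
`log2_transform` flag.

Distribution overlap is summarized by a binned Bayes error: with equal
priors and per-bin masses $d_1(b), d_2(b)$,

$$P(\text{misclassify}) = \sum_b d_2(b)\,\frac{d_1(b)}{d_1(b) + d_2(b)},$$

totaled over the Group 2 mass. This is 0.5 exactly when the binned
densities coincide and 0 when supports are disjoint, and it can never
exceed the 0.5 prior. The default bin width is 0.01 over the observed
range, configurable — note that with few pairs per group a narrow bin
width underestimates overlap (empirical histograms become sparse), so
for small cohorts a wider bin (0.05) is the more honest choice.
One-sided Wilcoxon rank-sum tests compare ordered group pairs
(G2 > G1, G3 > G2, G3 > G1); the exact null distribution is used for
combined *n* ≤ 12 without ties, the normal approximation with
continuity correction and mid-ranks otherwise (the two agree to better
than 0.01 at the crossover).

## The intersection decomposition

Presence is strictly `value > 0` with missing treated as absent. The
decomposition reports, per level of the subtype → patient → location
hierarchy, the number of features present in *every* sample of the level
(cumulative) and the increment over the enclosing level (additional).
Per location, the unique count (present there, absent in the patient's
other locations) and the location total close the arithmetic:

```
patient_shared + Σ pairwise_additional(L, ·) + unique(L) = total(L)
```

for three-location patients. `build_presence_fixture()` inverts the
decomposition: given additive slice sizes it constructs a boolean matrix
realizing them exactly, assigning features to membership patterns in
deterministic feature-id order (no randomness). The bundled
`proteome_venn_reference()` and `transcriptome_venn_reference()` encode
published per-patient slice tables for the 27-sample proteome and
9-sample transcriptome; slices not printed in those tables (the L1/L3
pair increments) are closed from the location totals, and the
decomposition recovers every input cardinality exactly:

```{r venn}
ref <- proteome_venn_reference()
dec <- decompose_presence(build_presence_fixture(ref$spec, ref$annotation),
                          ref$annotation)
dec$subtypes
dec$locations[dec$locations$patient == "P1", ]
```

Two further summaries follow the same presence logic. The
partial-multisite count of a subtype reports features present in all
locations of every patient, in at least one location of every patient,
and — the heterogeneity signal — in at least one location of every
patient while complete in none ("1 or 2 locations only"; the plain
difference of the first two counts is emitted alongside, since the two
readings differ). Subtype markers are features present in at least one
location of every patient of one subtype and absent from all samples of
another (or of all others).

The expected number of location-unique features under randomness uses an
occurrence-preserving null: each feature keeps its number of occurrences
$k$ but is re-placed uniformly among all $N$ samples. The closed form
per location is $\sum_f \binom{N-m}{k_f-1}/\binom{N}{k_f}$ ($m$ =
locations of the patient), reported alongside a Monte-Carlo estimate
whose agreement is itself a test of the implementation.

## Heterogeneous-gene screening

Counts are normalized to counts per million (plain column scaling — no
compositional correction, matching standard practice for this screen)
and genes with CPM < 0.5 in *all* samples are removed (a gene reaching
0.5 anywhere is kept). The per-gene, per-patient heterogeneity score is
the maximum $|\log_2$ fold change$|$ over all pairs of the patient's
samples, with a 1-CPM pseudocount by default (0 allowed for strictly
positive matrices). Genes scoring at or above `fc_threshold` (default 2,
i.e. 4-fold — the screen's one free knob, deliberately exposed) in at
least `min_patients = 2` patients are selected, and ranked exports
(gene-only and gene + score) are written for downstream GO-enrichment
tools.

The significance of the cross-patient overlap is assessed by
permutation: each patient's list is redrawn uniformly from the filtered
gene universe, the overlap statistic is recomputed, and
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{\text{perm}})$. An
exhaustive-enumeration path (`overlap_significance_exact()`) exists for
small universes and anchors the permutation estimate in the tests.

## Jensen–Shannon allelic heterogeneity

Per position and intra-patient sample pair, expressed-allele
distributions over {A, C, G, T} (no pseudocount; strand-collapsed,
1-based positions) are compared with the Jensen–Shannon *distance* — the
square root of the base-2 JS divergence, a symmetric metric bounded in
[0, 1], so the 0.6 call threshold is on a fixed scale. For example, a
pure-reference site against a balanced heterozygous site gives
$\sqrt{H(0.75, 0.25) - \tfrac12} \approx 0.558$ (below threshold), while
a 1.0-vs-0.4/0.6 split gives ≈ 0.63 (above). Pairs need `min_cov = 10`
reads on both sides (explicit and configurable; failing pairs are
reported as skipped, not silently dropped), and a per-position,
per-patient summary takes the *maximum* pairwise distance — the natural
aggregation when any divergent location pair flags the position.

## The synthetic generator: what it does and does not emulate

Log-scale expression is a sum of independent Gaussian effects — a global
per-feature mean (SD 1.5), subtype (0.4), patient (0.4), location (0.25)
and measurement noise (0.05) — exponentiated to intensities, with
hierarchical presence dropout (whole subtype 2%, whole patient 3%,
single location 5%). Samples of one patient share more terms than
samples of different patients, which yields the empirical ordering
noise replicates > intra-patient > intra-subtype > inter-subtype, and
the misclassification probability between Groups 1 and 2 falls as the
patient-effect variance grows. These defaults were set once as a
realistic rendering of the cohort design; note that with many features
the pairwise correlations concentrate tightly around their
group-specific expectations, so at the defaults Groups 1 and 2 separate
completely — real lesions, where per-tumor heterogeneity itself varies,
show broader and overlapping distributions. The generator makes no
attempt to emulate intensity-dependent missingness, batch effects, or
compositional library artifacts.

RNA counts are negative binomial (dispersion 0.1) around lognormal gene
means (mean depth 500); injected heterogeneous genes receive an 8-fold
location-specific change in two of three patients. Allele pileups are
multinomial draws at coverage 500 from per-patient frequency vectors
(homozygous, or heterozygous with probability 0.2); injected positions
keep the pure reference allele in the first location and a 0.4/0.6 split
elsewhere. Under these conditions the screens recover ≥ 90% of injected
genes (with ≥ 90% specificity) and ≥ 90% of injected positions with at
most 1% of null positions called — passing these tests demonstrates
correct mechanics at the stated effect sizes, not performance on real
tissue, where effect sizes, dispersions and coverages vary widely.

## Numerical choices and degenerate inputs

* Correlation pairs need ≥ 3 usable features and non-constant profiles;
  violations name the offending pair.
* Histogram bins are left-closed with the last bin closed on both
  sides; empty-in-both bins contribute 0 to the Bayes error.
* PCA standardizes the `log2(x+1)` matrix per feature (zero-variance
  features dropped, missing treated as 0) and fixes each component's
  sign by making its largest-magnitude loading positive, so embeddings
  are reproducible across runs and platforms.
* JS distance clamps tiny negative rounding of the divergence to 0 and
  rejects inputs whose sums deviate from 1 by more than 1e-9.
* Gene-list ranking breaks ties by patient count, then score, then gene
  id — stable under input permutation.
* Fixture construction is seedless and deterministic; all generators
  take an explicit integer seed, and the pipeline splits one root seed
  across stages.
* Mixed pairs (noise-control vs tumor sample) fall through to the
  inter-subtype label so group counts always partition the pair set;
  reports use only noise–noise pairs for Group 3.

Problem sizes in the test suite (cohorts of 120–200 features, universes
of 4–6 genes for exact enumeration, 40–60 positions at coverage 500, 5–10
generator seeds per recovery check) were chosen so every statistical
check rests on either an exact oracle or a comfortably powered
Monte-Carlo margin.

## Known limitations

* The decomposition assumes the subtype → patient → location hierarchy;
  patients with a single location get empty pairwise/unique slices and a
  warning rather than an error.
* The overlap permutation null treats per-patient lists as uniform
  draws, ignoring expression-dependent selection biases.
* The allelic caller does not distinguish somatic variants from
  copy-number imbalance or allele-specific expression — it flags
  divergence, not mechanism.
* GO-term enrichment is out of scope: the package produces the ranked
  inputs for external enrichment tools but does not re-implement their
  statistics.
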