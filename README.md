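# bcchet — multisite tumor heterogeneity analysis

`bcchet` quantifies intra- and inter-tumor molecular heterogeneity from
multisite profiles of the same lesion — the setting in which a tumor
(here, basal cell carcinoma, BCC) is sampled at several locations and
each piece is profiled by label-free quantitation (LFQ) proteomics and/or
bulk RNA-seq. It is aimed at computational biologists who have a
feature × sample quantification matrix, a sample → patient → subtype →
location annotation, and (optionally) per-position expressed-allele
counts, and who want to ask: *how different are pieces of the same tumor,
compared to tumors from different patients?*

## What it computes

**Correlation groups.** All pairwise sample correlations (Spearman and
Pearson) are labeled by group: intra-patient pairs (Group 2),
inter-patient pairs of the same subtype (Group 1 intra-subtype) or of
different subtypes (Group 1 inter-subtype), and technical noise-control
replicate pairs (Group 3). Groups are compared with one-sided Wilcoxon
rank-sum tests, and the overlap of the Group 1/Group 2 distributions is
summarized by a binned Bayesian misclassification probability: with equal
priors and per-bin probability masses `d1`, `d2`,

```
P(misclassify G2 as G1) = Σ_b  d2(b) · d1(b) / (d1(b) + d2(b))
```

which is 0.5 for identical distributions and 0 for disjoint ones.

**Intersection (Venn slice) decomposition.** Presence is called as
"observed with a positive intensity". The nested decomposition counts
features present in *every* sample (global), in every sample of a subtype,
in all locations of a patient, in a location pair, or unique to one
location — each reported cumulatively and as the increment ("additional")
over the enclosing level. Marker extraction (present in at least one
location of every patient of subtype A, absent from all samples of
subtype B) and a permutation/closed-form expectation of location-unique
features under an occurrence-preserving random null are included.

**Heterogeneous-gene screening.** Counts are CPM-normalized, genes below
0.5 CPM in all samples are dropped, and each gene gets a per-patient
score `max over sample pairs |log2((x_i + c)/(x_j + c))|`. Genes scoring
above a threshold in at least two patients are selected; the size of that
cross-patient overlap is tested against a uniform-draw permutation null
(with an exact enumeration path for small universes).

**Allelic heterogeneity.** Per genome position, expressed-allele
distributions of intra-patient sample pairs are compared with the
Jensen–Shannon distance (square root of the base-2 JS divergence, a
metric in [0, 1]); positions with distance above 0.6 between locations of
the same patient indicate possible somatic variants or allele-specific
expression.

A hierarchical synthetic-data generator (3 subtypes × 3 patients × 3
locations, log-scale Gaussian effects per level, negative-binomial
counts, multinomial pileups) provides validated inputs for all of the
above.

## Worked example

Reconstruct a published per-patient intersection table from its additive
slice sizes, then decompose it:

```r
library(bcchet)
ref <- proteome_venn_reference()        # 27 samples, 9 patients, 3 subtypes
pres <- build_presence_fixture(ref$spec, ref$annotation)
dec <- decompose_presence(pres, ref$annotation)
tbl <- venn_tables(dec)
tbl[tbl$patient == "P1", c("global_shared", "subtype_shared", "patient_shared",
                           "pair_L1_L2_shared", "unique_L1", "total_L1")]
#>   global_shared subtype_shared patient_shared pair_L1_L2_shared unique_L1 total_L1
#> 1          1760           2509           3200              3318        85     3656
```

Reading the row: 1760 proteins are shared by all 27 samples; 2509 by all
9 infiltrative samples; 3200 by all three locations of Patient 1; 3318 by
its locations 1 and 2; 85 proteins are seen only in location 1, which
carries 3656 proteins in total (2.3% unique).

Correlation-group analysis on a synthetic cohort:

```r
gen <- generate_expression(cohort_config(seed = 1))
pairs <- assign_groups(pairwise_correlations(gen$matrix, method = "spearman"),
                       gen$annotation)
rep <- heterogeneity_report(pairs, bin_width = 0.05)
round(rep$spearman$medians, 3)
#>    G1    G2    G3
#> 0.571 0.791    NA
signif(rep$spearman$wilcoxon[["G2_gt_G1"]], 3)
#> [1] 2.97e-18
rep$spearman$misclassification
#> [1] 0
```

Intra-patient correlations (median 0.791) sit above inter-patient ones
(0.571) and the Wilcoxon test confirms the ordering. At the generator's
default noise settings the two distributions separate completely, so the
estimated misclassification probability is 0; raising the location-level
variance toward the patient-level variance makes the groups overlap and
the probability grow toward 0.5 (real lesions show substantial overlap).

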