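---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsisimmune)
```

This vignette is the package's own account of its methods: the statistical
models behind each stage, the parameters that matter and why their defaults
are what they are, and the choices made where the design was genuinely open.

## The analysis model

The pipeline treats a cytometry study as a hierarchy:

* **events** — single cells with ~30 marker intensities on a raw,
  non-negative scale;
* **subsets** — groups of phenotypically similar events, found without
  supervision by a self-organising map (SOM) plus hierarchical merging;
* **subjects** — characterised by the vector of subset frequencies
  (percent of CD45+ events);
* **groups** — sepsis versus healthy, compared through subset frequencies
  (differential abundance), through the correlation structure *between*
  subsets (network analysis), and through subset-based classifiers.

### Preprocessing

All clustering and embedding operates on `asinh(x / c)` with cofactor
`c = 5`, the standard variance-stabilising transform for mass cytometry
(`c = 150` would be typical for fluorescence data; the cofactor is a
parameter of `asinh_transform()`). The transform is monotone and invertible
(`asinh_inverse()` recovers raw values to 1e-9 in the tests), and the
`event_matrix` scale flag prevents accidental double transformation.

Per-subject downsampling to a common event count (default 50,000) is
uniform *without* replacement: sampling with replacement would duplicate
events and artificially tighten clusters. Subjects with fewer events than
the target are kept in full with a warning rather than dropped — dropping
would silently change the cohort size — and all downstream frequencies use
each subject's retained event count as the denominator, so unequal
retention cannot bias percentages.

### SOM clustering and metaclustering

`som_fit()` is a batch SOM on a rectangular grid (default 10×10 = 100
nodes). Codebook vectors are initialised from a seeded sample of events and
updated for 14 epochs as Gaussian-neighbourhood weighted means, the radius
decaying linearly from half the grid diagonal to 0.2. The late near-zero
radius makes the final epochs behave like per-node refinement, which keeps
codebook vectors at population modes instead of halfway between populations
(bridge nodes); that mattered empirically for keeping rare, tight
populations in single metaclusters. Event assignment is nearest codebook by
Euclidean distance with ties broken to the lowest node index, so the whole
fit is a deterministic function of the seed.

Nodes are merged into metaclusters (default 47) by average-linkage
hierarchical clustering of the codebook vectors. The linkage is exposed
(`average`, `ward`, `complete`); average linkage is the conventional
codebook-merging choice and is deterministic. Only *populated* nodes enter
the merge; a node that captured no events inherits the metacluster of its
nearest populated node, which guarantees every metacluster has events and
keeps the node→metacluster map total.

Mixed-population (doublet-like) metaclusters are excluded by rule rather
than by eye: a metacluster is flagged when its scaled median expression
exceeds 0.5 on both markers of a mutually exclusive lineage pair (defaults
CD3/CD19, CD3/CD14, CD14/CD56). Scaled medians are per-marker min–max
scaled across metaclusters, exactly the values a dendrogram heatmap
displays. Two guards make the rule robust: a constant marker (no scale) is
emitted as 0 with a warning, and metaclusters below `min_frac = 0.001` of
pooled events are ineligible for exclusion, because a median over a handful
of cells is too unstable to support a phenotype call. With the default
synthetic scenario this chain yields 100 nodes → 47 metaclusters → exactly
one exclusion → 46 retained subsets.

Frequencies are percentages of *all* of a subject's events — excluded
metaclusters leave the columns but stay in the denominator — because subset
abundance is reported as a share of CD45+ PBMC, not of retained events.
Pre-exclusion frequencies therefore sum to exactly 100 per subject.

### Differential abundance

Each subset is tested with a two-sided Mann–Whitney U test: exact when both
groups have ≤ 8 subjects and no ties, otherwise the normal approximation
with tie and continuity correction (the behaviour of `wilcox.test`).
Multiplicity is controlled by Bonferroni over the number of subsets tested,
and the significance flag applies to the *adjusted* p at α = 0.1. The
α = 0.1 threshold is interpreted as paired with the correction (an adjusted
p below 0.1 is roughly a raw p below 0.002 at m = 46); the raw-p flag is
reported alongside for sensitivity analyses, and α is a parameter.

Effect sizes are classical pooled-SD Cohen's d (positive = higher in
sepsis) with the standard large-sample CI,
`var(d) = (n1+n2)/(n1 n2) + d² / (2(n1+n2))`; Hedges' small-sample
correction is available by flag but off by default so that d means the same
thing at every n. A zero pooled SD yields a flagged `NA` rather than an
invented value.

The age-stratified sensitivity analysis cuts at one year — immune
development in infancy is rapid enough that subset frequencies can differ
by age alone — and skips (with a warning) any stratum with fewer than two
subjects per group. Clinical correlations use Pearson for continuous
laboratory values (CRP, procalcitonin, lactate, WBC) and Spearman for
ordinal severity scores (pSOFA, PELOD-2, PIM-3); the assignment is a
documented default, exposed per variable.

### Network analysis

For each group separately, pairwise correlations of subset frequencies
across subjects define a signed graph: subsets are connected when
|r| strictly exceeds 0.6 *and* the two-sided p-value is below 0.05, so
every represented edge is statistically significant. Pearson is the default
coefficient; Spearman is a flag. Edges keep the correlation's sign — a
negative edge is read as a regulatory/inhibitory relationship.

Summary statistics:

* **density** `D = 2E / (n(n−1))` over *all* retained subsets, isolated
  nodes included — a subset with no suprathreshold correlations is still
  part of the immunome, and counting it keeps densities comparable across
  groups;
* **negative edges** — count and fraction of E (0 with a flag on an empty
  graph);
* **modularity** — Newman's Q on the unweighted, sign-stripped graph. The
  maximising partition is found exactly (exhaustive search over set
  partitions) when at most 8 nodes carry edges, and by deterministic greedy
  agglomeration (fast-greedy) otherwise; the cross-over bound is a
  parameter. Stochastic community detection (e.g. Louvain) was rejected for
  reproducibility.

Both statistics are checked in the tests against brute-force oracles
(explicit double loops; exhaustive partition enumeration on small graphs).
Layouts are seeded Fruchterman–Reingold with isolated nodes placed on a
deterministic surrounding ring; GraphML export is provided for external
tools.

One caveat is inherited from the procedure itself: subset frequencies are
compositional (they sum to 100%), and marginal correlations of compositions
carry a negative closure bias. The package implements the literal
marginal-correlation procedure and keeps baseline subset shares moderate in
the generator (largest ≈ 15%), where the closure bias (≈ −0.1 to −0.2
between the largest pairs) stays far from the 0.6 edge threshold. No
log-ratio or partial-correlation correction is applied; that would be a
different estimand.

### Classification

Diagnostic/prognostic models are logistic regressions on subset frequencies
with age in years as an optional covariate ("adjusted for age" is taken as
age-as-covariate, not stratification). Perfect separation — likely at
n = 58 with strong subsets — is detected and handled by a ridge-penalised
IRLS fallback (λ = 0.01 on non-intercept terms) so scores are always
produced; the flag is carried on the fit.

`roc_metrics()` computes the AUC by the trapezoidal rule over all score
thresholds, which coincides with the Mann–Whitney rank estimator (asserted
to 1e-12 in the tests), a DeLong-style asymptotic CI from the paired
placement variances, and a Youden-J cutoff (ties resolve to the highest
threshold) from which sensitivity, specificity, PPV and NPV are derived.
PPV/NPV always come from the integer confusion matrix, so the four rates
are internally consistent by construction. Comparator models are
single-variable ROCs for the clinical severity scores and laboratory
markers under the same contract.

## The synthetic-cohort generator

The generator's defaults *are* the study conditions the rest of the package
is tested under: a discovery cohort of 39 sepsis and 19 healthy children
(validation: 20 + 15), ~60,000 events per subject before downsampling, and
twenty population archetypes — the eleven differential subsets (four
enriched, seven depleted) plus nine fillers including one doublet-like
mixed population.

**Abundance model.** Subject subset frequencies follow a logistic-normal
model: a log-abundance vector is drawn from a group-specific multivariate
normal and closed through a softmax. A Dirichlet cannot encode negative
inter-subset correlation beyond the closure itself, and planted covariance
is exactly what the network stage must recover, so the logistic-normal is
the minimal adequate choice. The log-scale standard deviation is 0.35
throughout, giving subject-level frequency CVs around 35%, a realistic
order for immune subset frequencies.

**Planted effects.** Enriched subsets carry standardised effect sizes
(Cohen's d on the percent scale) of 1.5 (CD15+CD14+ monocytes, the largest),
1.4, 1.3 and 1.2 (the memory Th17 subset); depleted subsets −0.8 to −1.2.
Because the softmax closure attenuates log-scale shifts by roughly 15% in a
composition-dependent way, the log shifts are calibrated by fixed-seed
Monte Carlo (20,000 subjects per group, four iterations) at scenario build
time so the planted d is exact on the scale the analysis measures. The
upper half of the plausible 0.8–1.5 range is used because, at n = 39/19
with Bonferroni control at adjusted p < 0.1, the normal-approximation power
at d = 0.8 is only ≈ 50%, while d ≥ 1.2 gives ≥ 90% — and the generator is
required to yield ≥ 80% recovery of every enriched subset. That power
computation was done analytically before the recovery tests were written.

**Covariance structure.** Correlations are built from factor loadings
(guaranteeing positive semi-definiteness). In health, one cross-lineage
factor loads positively (0.88) on eight subsets spanning T, B, NK and
myeloid lineages and negatively (−0.82) on the two regulatory subsets
(naive Treg, PD1+CTLA4+TIGIT+ effector-memory CD4), producing a dense web
with planted negative edges. In sepsis, two disjoint all-positive factors
(0.9) cover a CD4 module and a CD8 module — sparse, modular, no negative
edges. Thresholded at |r| > 0.6 these imply a denser, low-modularity
healthy network and a sparse, high-modularity sepsis network, the contrast
the comparison stage must reproduce qualitatively.

**Events.** Each event draws its population from the subject's composition
(multinomial) and its raw intensities from the population archetype: per
marker a zero-inflated lognormal, with expression levels 0–4 mapping to
(dropout, median, log-sd) triples. Zero inflation mimics mass-cytometry
dropout without modelling instrument physics. The doublet-like archetype is
special-cased: its positive markers (CD3, CD4, CD19, HLA-DR) have no
dropout and its dispersion is low, because a doublet is the superposition
of two intact cells — and because dropout sub-modes would let the SOM split
it into several metaclusters, which defeats the purpose of a single planted
mixed population.

**Clinical records.** Laboratory values for sepsis subjects are linear in
the standardised frequency of their coupled subset plus Gaussian noise,
with the noise share set so the population Pearson correlation equals the
coupling target (defaults: monocyte–procalcitonin 0.68, Th17–lactate 0.57);
frequency standardisation uses the fixed-seed calibration moments, so the
coupling is exact in population and recovered within sampling error
(±0.06 at n = 1000 in the acceptance checks). Outcomes (severe sepsis,
septic shock, multiorgan dysfunction, PICU mortality) are Bernoulli draws
from a logistic link on the four enriched subsets with intercepts
calibrated to prevalences of 74.6%, 72.9%, 69.5% and 13.6%. Severity scores
are discretised Gaussians matched to plausible medians/IQRs (pSOFA 8 (5, 11),
PELOD-2 6 (3, 8), PIM-3 lognormal about 3.4) sharing a latent severity axis
(ρ = 0.5) with the mortality linear predictor — only their rank structure is
used downstream. Every sepsis subject's pSOFA is at least 2, the
organ-dysfunction rise that defines sepsis; healthy subjects carry no
severity scores, laboratory values or infection site. Ages are drawn from
bracket distributions giving ≈ 74% of sepsis subjects above one year.

**What the generator does *not* emulate.** Staining chemistry, barcoding,
bead normalisation, acquisition drift, debris and true doublet kinetics are
all out of scope; the marker panel is reconstructed from subset phenotype
names and is approximate; and no attempt is made to match any real cohort's
measured subset frequencies. Passing the recovery tests therefore shows the
*pipeline* is correct and well-calibrated under a known truth — it does not
certify performance on real instrument data, where batch effects and
population overlap are harsher.

## Numerical choices and degenerate inputs

* Seeds: every stochastic function takes an explicit seed evaluated under
  `withr::with_seed`, leaving the caller's RNG untouched; `derive_seed()`
  hashes a master seed with a stage label so one integer reproduces an
  entire `run_pipeline()` run. Scenario calibration uses its own fixed
  internal seed, independent of the user seed.
* Ties: SOM assignment and Youden cutoff selection resolve ties to the
  lowest index / highest threshold; metacluster merging inherits `hclust`'s
  deterministic behaviour.
* Compositions are validated to sum to 1 within 1e-9; covariances must be
  symmetric PSD within an eigenvalue tolerance of 1e-8 relative.
* Degenerate cases are errors or flagged values, never silent: negative raw
  intensities, double asinh transforms, mixed scales in concatenation,
  empty archetype lists, single-class ROC inputs, zero-variance subsets
  (absent network edges with a warning), zero pooled SD (flagged `NA`
  effect size), sub-minimum strata (skipped with a warning).

## Problem sizes used by the tests

The test and acceptance suites run the full event-level chain at 1,200
events per subject (58 subjects, ~70k pooled events) and the
composition-level studies at their native sizes (200 cohorts for effect-size
recovery, 500 null cohorts for error control, n = 1000 subjects for the
coupling calibration, n = 200 for network edge recovery). These sizes were
chosen so the planted structure is comfortably recoverable — the event count
enters only through the binomial noise on frequencies, which at 1,200
events is already an order of magnitude below the between-subject
variability being measured.

## Known limitations

* Marginal correlations of compositional frequencies carry closure bias
  (documented above); interpretations of individual weak edges should be
  conservative.
* The exact modularity search is exponential and capped at 8 active nodes;
  beyond that the greedy partition is a lower bound on the optimal Q.
* The t-SNE implementation is exact (quadratic cost) and intended for
  downsampled event sets of a few thousand cells, as a seeded visual check
  only; no quantitative conclusion in the package depends on embedding
  coordinates.
* The ridge fallback under separation biases coefficients toward zero by
  design; its scores are used for ranking (ROC), where the bias is
  immaterial.
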