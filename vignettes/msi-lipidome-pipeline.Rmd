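---
title: "Methods: spatiotemporal MSI lipidome analysis with lipidmsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal MSI lipidome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmsi)
```

## Scope

`lipidmsi` implements a complete analysis chain for two-arm developmental
MALDI-MSI lipidomics studies: a ground-truthed study simulator, global
maximum-pixel normalization, ROI aggregation, winsorized z-score
preprocessing, per-feature linear models with decile-stratified selection of
supplement-elevated peaks, accurate-mass lipid annotation with
knowledge-based filtering, class/pathway over-representation, and PCA/HCA
exploration. This vignette is the package's account of the underlying
models, the tunable parameters, and the design decisions taken where the
methodology was genuinely open.

## The generative model behind the simulator

The simulator emulates the statistical structure such a study imposes on the
data, not the physics of the measurement. The log intensity of tissue pixel
$(x, y)$ in region $r$, feature $f$, animal $u$, age $a$, treatment $T$ is

$$\log I = b_f + a_f(a) + r_{f,r} + \delta_f\,[T = \mathrm{suppl.}]
          + u_{f,\mathrm{animal}} + \varepsilon_{\mathrm{pixel}}$$

* $b_f \sim N(4, 1)$: feature baseline abundance (log scale). The absolute
  level is arbitrary because the pipeline normalizes and z-scores.
* $a_f(a)$: developmental trend. Each feature belongs to one of three
  clusters — increasing, flat, decreasing — with default probabilities
  0.46 / 0.28 / 0.26, the approximate proportions observed in developing rat
  brain. The trend is linear in $\log(\text{age})$ and spans
  `age_amplitude` (default 1.0 log unit) over the sampled range, so an
  "increasing" feature roughly e-folds between the first and last age.
* $r_{f,r}$: a spatial profile per feature, one of four types — rostral
  gradient (+0.3 in telencephalic regions, −0.3 elsewhere), caudal gradient
  (reverse), fiber-tract enrichment (+0.5 in arbor vitae / fornix / corpus
  callosum, −0.1 elsewhere), or uniform. Exponentiating keeps all region
  multipliers positive.
* $\delta_f$: the treatment effect, nonzero for exactly
  `round(effect_fraction * n)` features per mode (default 10%), with default
  size 0.30 on the log scale.
* $u \sim N(0, \texttt{animal\_sd}^2)$, default 0.2: a per-animal random
  intercept per feature. The study is cross-sectional (different animals at
  each age), so one intercept per section is drawn.
* $\varepsilon \sim N(0, \texttt{noise\_sd}^2)$, default 0.3: pixel-level
  log-normal noise.

The defaults make the planted effect 1.5 animal-level standard deviations
($0.30 / 0.20$), which is the regime the selection step is designed for:
with 16 animals per arm the one-sided test has high power while null
features stay near the nominal 5% positive rate. The variance split between
`animal_sd` and `noise_sd` is a modelling choice, not an estimate — the kind
of study simulated here does not report within- vs between-animal
components — so both are plain configurable parameters.

With `noise_sd = 0` and `animal_sd = 0` the ROI means recover the generative
equation exactly (the tests exploit this closed form). The default species
panel weights lipid classes by the composition of a milk polar-lipid extract
(sphingomyelin and phosphatidylcholine dominate, then
phosphatidylethanolamine, -serine and -inositol), so the annotation stage is
exercised on the classes such a supplement actually contains; the remaining
features are identity-free decoys kept >10 ppm from every panel mass.

What the simulator does **not** emulate: isotope envelopes at pixel level,
matrix and ionization suppression effects, instrument drift, mass-accuracy
drift, section-to-section registration error, or anatomically realistic
region shapes (the atlas is a banded ellipse — regions are contiguous,
disjoint and ordered rostral–caudal, which is all the aggregation stage
needs). Passing recovery tests on simulated data therefore demonstrates the
statistical machinery, not robustness to those instrumental artifacts.

## Normalization and aggregation

All sections of one ionization mode are divided by the single maximum pixel
intensity across the whole mode, making images comparable on a common [0, 1]
scale. Modes are normalized separately because positive- and negative-mode
acquisitions are separate experiments with incomparable scales. Since ROI
aggregation is a linear average, normalizing before or after aggregation
differs only by that scalar — the order is immaterial for every downstream
statistic (z-scores remove the scalar entirely), which is why the pipeline
fixes normalize-then-aggregate without loss of generality.

Pixel coordinates are 0-based $(x, y)$ with $y$ increasing downward, stated
in the file headers to avoid atlas misregistration. An atlas region with no
pixels is an explicit error by default (`na_empty = TRUE` emits NA rows
instead) — silently dropping a region corrupts the balanced design that the
GLM stage assumes.

## Preprocessing

The fixed order is log → z-score → winsorize.

* **Log transform.** Natural log; the base is immaterial because z-scoring
  absorbs constant factors. Zeros are handled per feature: offset = half the
  smallest positive value of that feature (an all-zero feature gets offset 1
  and is flagged). This avoids $-\infty$ without imposing one global
  pseudo-count across features whose scales differ by orders of magnitude.
* **Z-scores.** Per feature, mean 0 and sample SD 1 (denominator $n-1$).
  Constant features map to all-zero and are flagged rather than NaN.
* **Winsorization.** "5% winsorized" is read as 5% *per tail* (the usual
  convention for winsorization limits); the fraction is a parameter because
  the phrase is ambiguous. Per feature, the lowest
  $\lfloor 0.05\,n \rfloor$ values are replaced by the smallest unreplaced
  value, symmetrically at the top. Winsorization is applied per feature, not
  globally, consistent with the per-peak logic of the two previous steps.

All recorded parameters (offsets, means, SDs, winsor bounds) are written to
a JSON sidecar so a preprocessing run can be reproduced exactly.

## Per-feature models and decile-stratified selection

"GLM" is realized as ordinary least squares with Gaussian errors and
identity link: the response is already a z-score, and the questions —
main effects of treatment and age, their interaction — are classical
ANOVA questions. Per feature the package fits
`z ~ treatment + age + treatment:age` (ages as a 4-level factor) and reports
sequential-SS F tests against the full-model mean square; in the balanced
designs this pipeline produces these coincide with the standard two-way
ANOVA tests. The treatment p-value is **one-sided** (supplemented greater
than control) from the t statistic of the supplemented-arm coefficient in
the main-effects model, because the selection targets supplement-*elevated*
peaks; `two_sided = TRUE` is exposed. Degenerate (constant) features get
effect 0 and p = 1 by convention. Because the design matrix is shared across
features, all features are fitted through one QR decomposition per nested
model; the tests validate this fast path against `lm`/`anova` and against a
permutation oracle.

Selection: features with one-sided p < α (default 0.05) are ranked by m/z
and split into `n_deciles` (default 10) rank-based strata **computed on the
significant set** — the stratification is meant to spread the retained set
over the observed mass range of the significant pool, so stratifying the
full feature list would defeat its purpose. Within each stratum the
$\lceil 0.6\,n_d \rceil$ smallest p are kept; the ceiling guarantees
non-empty retention in non-empty strata, and p ties break toward smaller
m/z for determinism. Rank-based strata make the selection invariant to any
monotone rescaling of m/z. No multiplicity correction is applied at this
stage (the selection is a screening step); Holm is available downstream in
the enrichment stage. On significant sets not divisible by the number of
deciles, the ceiling makes the realized retained fraction slightly exceed
the nominal 60%.

The per-ROI variant adds region (13 levels) as a main-effect factor and
reports its F test. A caveat the package states rather than hides: the 13
region rows of one section share that animal's random intercept, so the
fixed-effects treatment test on region rows is anti-conservative when
`animal_sd > 0`. The whole-section model is the primary inferential surface;
the ROI model is descriptive (which regions differ), matching how such
analyses are used in practice. A mixed model with an animal random effect is
deliberately out of scope.

## Annotation

Matching accepts every reference entry of the same ionization mode within
10 ppm relative error (binary search over the sorted reference). The
knowledge-based filters then run in a fixed order, and every rejection is
recorded with the rule that fired:

1. **Adduct–class consistency.** Choline-bearing classes (PC, LPC, SM, plus
   CAR and WE) are expected in positive mode; acidic classes (FA, PA, PG,
   PI, PS, LPA, ST, HexCer, CDP-DG, PE-Cer, PE, FMC) in negative mode. The
   table is configurable because adduct formation varies between lipids and
   matrices.
2. **Isotope plausibility** (only when an (M+1)/M envelope is supplied):
   observed ratio within ±30% (relative) of $0.0107\,n_C + 0.0037\,n_N$,
   the first-order ¹³C/¹⁵N expansion. The tolerance is generous because
   MALDI intensity ratios are noisy; it is a parameter.
3. **Chain plausibility.** Total-carbon windows per structural category:
   diacyl 26–48, lyso/free fatty acyl 12–26, sphingoid-containing 30–48.
4. **Tie resolution.** Candidates with identical molecular formulas (O-
   ether vs P- plasmalogen isomers) merge into one ambiguous `A|B`
   annotation — without MS/MS they cannot be discriminated, and the honest
   output is the ambiguity. Among the rest, even total carbon counts are
   preferred (mammalian fatty-acyl chains are overwhelmingly
   even-numbered), then the smallest |ppm error|. A lone odd-chain
   candidate is retained but flagged `parity_preferred = FALSE`: odd chains
   occur (dietary origin), so discarding them outright would be wrong, but
   they should never win a tie against an even-chain alternative.

Molecular formulas come from closed-form per-class rules in total carbons
$C$ and double bonds $D$ (e.g. PC($C{:}D$) = C$_{C+8}$H$_{2C-2D+16}$NO$_8$P;
the O- variant is the diacyl formula −O +H₂ and the P- variant −O); classes
without a safe closed form (CDP-DG, ST, HexCer, FMC, PE-Cer, WE) resolve
against a bundled lookup table. The FMC-6 entry is provisional — its
structure is not fully characterized — and is marked as such in the table.
Masses use principal-isotope masses, and adduct m/z includes the electron
mass. The bundled reference and pathway tables replace live database
queries; determinism and offline operation are requirements here, and the
tables are small enough to audit.

## Enrichment

Over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ (equivalently the one-tailed Fisher exact test), with the
universe defined as the *annotated detected* lipids — enrichment against all
detected peaks would conflate annotatability with biology. The familywise
correction is **Holm** step-down; Benjamini–Hochberg is available behind
`method = "BH"`. (Method naming in this literature is sometimes
inconsistent; the package implements both and defaults to the step-down
procedure it names.) Pathway impact is the summed relative betweenness
centrality of hit nodes in a small class-level pathway graph — a topology
measure in [0, 1] where hitting the hub of a linear pathway scores higher
than hitting its ends.

## Exploration

PCA is a singular value decomposition of the preprocessed matrix without
re-centering (columns are already z-scored, hence centered); variance
fractions are $d_i^2 / \sum d^2$. Scores are additionally averaged within
treatment × age (× ROI) conditions for biplot display. Signs follow the
convention that each component's largest-magnitude loading is positive,
making outputs reproducible across platforms. Constant matrices are a
degenerate-input error.

HCA uses distance $1 - r$ (Pearson) between item profiles and
furthest-neighbor (complete) linkage; the k-cut labels, dendrogram leaf
order and the reordered correlation matrix are exported as numbers — figures
are a convenience, the numeric outputs are the test surface. Zero-variance
items have no defined correlation: they are flagged, excluded from the tree,
and assigned to the cluster of the nearest valid neighbor (Euclidean) with a
warning.

## Orchestration and reproducibility

`msi_config()` collects every parameter; `msi_run_all()` executes the stages
in acquisition order, writes every intermediate as TSV/JSON, and aborts with
the stage name on failure. All randomness flows from one master seed through
deterministic per-stage sub-seeds, so a rerun with the same config is
bit-identical. When ground truth is present the report includes recovery
metrics: sensitivity and null positive rate of the significance step,
selection FDR, and annotation accuracy. The package's interface is R
functions plus `scripts/acceptance.R`; no shell subcommand layer is shipped,
as users of this kind of pipeline drive it from R.

## Problem sizes

Default scale is 500 features per mode on a 64 × 40 px atlas — scaled down
by roughly a factor of six from the feature counts a full-scan FTICR
acquisition produces, chosen so that a complete two-mode run finishes in
well under a minute on one core while keeping ≥ 50 planted effect features
per mode for stable recovery estimates. The test suite uses 40–60 features
and a 48 × 32 px atlas for unit-level checks and the full default scale for
the recovery and end-to-end checks.

## Known limitations

* The ROI-level fixed-effects model ignores within-section correlation (see
  above); interpret its treatment test descriptively.
* Winsorization slightly shortens the tails the t test sees, so realized
  null positive rates can run marginally above nominal; at the default 5%
  per tail the effect is small.
* Annotation is sum-composition only: no sn-position, no double-bond
  location, no MS/MS evidence — `A|B` ambiguity is reported, never resolved
  by guessing.
* The bundled reference, class→pathway map and pathway graphs are miniature
  curated tables for deterministic operation, not a substitute for a full
  database in a real annotation campaign.
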