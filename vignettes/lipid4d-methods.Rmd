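---
title: "4D lipidomics with lipid4d: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{4D lipidomics with lipid4d: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipid4d)
```

## The problem

Trapped ion mobility mass spectrometry coupled to liquid chromatography
describes every detected lipid ion by four descriptors: mass-to-charge
(m/z, Da), retention time (RT, min), collision cross section (CCS, A^2)
and a fragmentation spectrum. Profiling blood specimens at clinical
throughput with this data requires four computational pieces, all of which
this package implements on plain-text feature tables:

1. **Feature selection** — aligning replicate runs into a *bucket table*,
   gap-filling at a lowered detection threshold, and keeping only features
   that recur across the batch, are absent from solvent blanks, and track
   the amount of matrix loaded on column (dilution response).
2. **Annotation** — matching buckets against a 4D reference library with
   banded confidence scoring per descriptor.
3. **Quantification** — converting peak areas to molar concentrations via
   class-specific internal standards, with back-calculated accuracies and
   detection limits.
4. **Pheno-mapping statistics** — paired nonparametric comparisons of blood
   matrices, time-point stability tests, person-held-out classification,
   PCA, pooled class variability and cardiovascular marker ratios.

A seeded synthetic-data module generates every input with exported ground
truth, so each stage is testable without instrument data.

## Matching model

All coordinate matching uses a per-dimension (Chebyshev) tolerance box, not
a Euclidean ball, because the platform's matching rules are stated per
dimension: |dm/z| < 0.002 Da, |dRT| <= 0.1 min, |dCCS| <= 0.2 A^2
(`tolerance_set()`). Alignment (`align_buckets()`) is greedy centroid
clustering: features pooled across runs are sorted by descending peak area
(ties broken lexicographically by m/z, RT, CCS, sample id); the highest
unassigned feature seeds a bucket and every unassigned feature in its box
joins, at most one per sample — the nearest by normalized Chebyshev
distance, ties to the lower m/z. This is deterministic and invariant to
input order.

Two consequences worth knowing:

* The bucket's *box* is centered on the seed feature. The consensus
  coordinate (area-weighted member mean) always lies in the seed's box, and
  every member lies in the seed's box, but two members may sit up to twice
  the tolerance apart — no clustering rule with a finite box can promise
  less.
* Presence filtering uses the two-threshold occurrence rule: gap filling
  (`recursive_fill()`, provenance `recursive`) is attempted for buckets with
  primary presence of at least 17 of 32 analyses, and a bucket is retained
  only at full presence (32 of 32) after filling. Recursive values are
  flagged and *never* used for quantification.

The dilution-response filter keeps a bucket iff the Pearson correlation of
its per-level mean areas with the dilution volumes is at least 0.9 and the
SD of the normalized level means exceeds 0.1. The SD criterion has no
stated scale on raw areas (where it would be vacuous), so level means are
scaled to max = 1 by default; the normalization is configurable and
recorded in the diagnostics. The SD is the sample SD; on a noise-free
six-level 1:2 ladder the normalized means are (1, 1/2, ..., 1/32) and the
sample SD is 0.37, comfortably above the 0.1 threshold either way. Missing
cells count as zero signal in the level means (absence of a response *is*
evidence against a dilution response). Volumes, not dilution-step indices,
are the correlation x-variable; this too is configurable at the design
level by what is written into `dilution_volume`.

## Annotation scoring

Per dimension the confidence bands are 1–3 ppm mass accuracy, 0.1–0.5 min
RT, 0.2–1.5 A^2 CCS: a deviation at or below the tight bound scores 1,
decays *linearly* to 0 at the loose bound and is rejected beyond it. The
source platform states the ranges but not a functional form; linear decay is
the minimal assumption and makes band edges testable (a 2 ppm deviation
scores exactly 0.5).

The spectral match pairs peaks greedily by nearest m/z within 0.01 Da and
compounds three components on a 0–1000 scale: *fit* (cosine over the union
of peaks on square-root intensities), *reverse fit* (the same cosine
restricted to reference peaks) and *purity* (matched fraction of query
intensity), weighted 0.5/0.3/0.2. The vendor's exact formulas are
unpublished; these definitions are this package's own, the weights are
exposed in `spectral_score()` and echoed in its output. Scores of 900 and
500 mark the good-confidence and acceptance thresholds; the MS/MS sub-score
rescales `[500, 1000]` to `[0, 1]`.

The composite is the unweighted mean of the *available* sub-scores; absent
dimensions (no spectrum, no isotope peaks) are omitted rather than zeroed,
with the tier (`full_4D` / `no_MS2` / `rejected`) carrying the penalty.
ppm deviations are computed against the library's empirical `expected_mz`,
not a theoretical adduct mass, because library coordinates are measured.
The isotope-pattern score compares observed M+1/M (and optionally M+2/M)
ratios with an elementwise convolution of natural isotope abundances and
scores `max(0, 1 - mean relative deviation)`; how the source software
quantified "isotopic pattern quality" is unknown, so this is a documented
stand-in.

## Quantification model

The calibration model is `areaRatio = c1 * concRatio^(1/c2)` with
`areaRatio = A_ES/A_IS` and `concRatio = C_ES/C_IS`. It is fitted by
ordinary least squares in log–log space (slope maps to 1/c2, intercept to
log c1); the named coefficients are published, the fitting procedure is
not, and the log–log OLS is the canonical choice for a power law with
multiplicative noise. Concentrations follow

* `A = ((area_analyte/area_istd)/c1)^c2 * C_IS` (ng/mL on column),
* `B = A * final_volume / sample_volume` (ng/mL in sample; defaults 360 uL
  reconstitution over 20 uL extracted),
* `C = B / adduct_mass` (nmol/mL).

One-point quantification replaces the fitted curve by a single calibrant's
response factor `m`; on noise-free linear data the two strategies agree to
machine precision for every calibrant choice. Back-calculated per-point
accuracies are flagged outside the 80–120 % band but *not* dropped — the
acceptance criterion is published, a refit policy is not; an explicit
re-fit after manual exclusion remains the caller's decision.
Detection limits are `LLOD = 3.3 sigma/s` and `LLOQ = 10 sigma/s`. The
source only says sigma and s come from an ANOVA of the calibration; here
sigma is the residual SD and s the slope of an ordinary linear regression
of response on concentration ratio (the standard ICH reading), and both are
reported so an alternative convention can be substituted.

## Statistics

* **Wilcoxon dissimilarity.** For each matrix pair, samples pair by
  (individual, time point); per lipid a two-sided signed-rank test,
  Benjamini–Hochberg across lipids within the pair, and the dissimilarity
  entry counts q < 0.05. Zero differences follow the Pratt convention by
  default (kept in the ranking, normal approximation with zero and tie
  corrections); `zero_method = "wilcoxon"` drops them and uses the exact
  distribution where available. The source is silent on the convention;
  Pratt is the conservative choice when many paired values tie exactly.
* **Friedman test** across time points with (individual x matrix) blocks,
  BH-corrected across lipids.
* **Random forest.** "3 x 4 cross-validation" is read as 3 repeats x one
  fold per individual (4 individuals): each fold holds out every sample of
  one person, which is the only split that prevents person-level leakage.
  Repeats differ only in the classifier seed. The multiclass AUROC is the
  macro-averaged one-vs-rest AUROC over pooled held-out probabilities (the
  averaging convention is unstated in the source; macro is insensitive to
  class imbalance). Because no tree-ensemble package is available in the
  supported environment, the forest itself is a compact in-package
  implementation: bagged, fully grown CART trees, Gini splitting,
  `floor(sqrt(p))` random candidate features per node, leaf class
  proportions averaged across trees.
* **PCA** log10-transforms concentrations (zeros imputed to half the
  smallest positive value) and standardizes columns; the source states only
  that molar concentrations were used, and the transform reflects the
  log-normal spread of lipid concentrations across four decades.
* **Pooled class SD**: per matrix and lipid, the variance across that
  matrix's samples over the time course; variances pooled across the
  lipids of a class by degrees of freedom, square root reported.
* **Marker ratios**: the three ceramide/phosphatidylcholine molar ratios
  and one concentration that feed the published CERT2 cardiovascular risk
  score. The score itself is *not* computed — its coefficients are
  published elsewhere and are not part of this artifact.

## The synthetic world

The generators state one fixed world rather than free dials:

* Library entries lie on per-class CCS-vs-m/z linear trends with scatter,
  emulating the class-wise banding of real lipidomes in the
  (m/z, CCS, RT) cube; five classes (PC, PE, SM, Cer, TG), ten entries
  each by default.
* Coordinate noise is *within-batch repeatability*: 0.5 ppm m/z, 0.01 min
  RT, 0.05 A^2 CCS. Published inter-day CVs (about 0.1–0.2 % CCS, i.e.
  0.3–0.5 A^2) describe remeasurement weeks apart; a within-batch scatter
  of that size would contradict the platform's own workflow, whose 0.2 A^2
  matching box plus a 32-of-32 presence requirement only function when
  batch scatter sits well inside the box. Area noise is multiplicative
  log-normal at 10 % CV (areas are positive and right-skewed; most
  published replicate CVs are below 10 %).
* The dilution ladder is 2, 1, 0.5, 0.25, 0.125, 0.0625 uL matrix on
  column in triplicate; true lipid areas scale with volume before noise,
  planted artifact features stay flat.
* Calibration series have 7 points spanning a 64-fold range with truth
  (c1 = 1.2, c2 = 1.1, C_IS = 100 ng/mL) and 2 % log-normal noise.
* The study is 4 individuals x 5 blood matrices (plasma, serum, whole
  blood, venous and finger-prick dried blood spots) x 3 time points.
  Serum differs from plasma by tiny per-lipid offsets (log-SD 0.05), the
  finger-prick spot from the venous spot likewise; whole blood is strongly
  displaced (log-SD 0.5). Time points are stable except triglycerides,
  which carry 25 % multidien variation, mirroring their known dynamic
  turnover.

What a green test does and does not establish: the synthetic world has no
chromatographic drift, no co-eluting isomers sharing fragmentation
patterns, no intensity-dependent mass error, no batch effects and no
missing-not-at-random structure. Ground-truth recovery here validates the
*algorithms* against their contracts, not the platform's real-data
performance figures (funnel counts, annotation totals, classification
AUROCs), which depend on the original measurements and are deliberately
not reproduced.

## Numerical choices and degenerate inputs

* Constant dilution-level means make the Pearson correlation undefined;
  such buckets are removed with reason `"constant"`.
* Spectra with duplicate m/z values are aggregated by summing intensities
  so stored peak lists are strictly increasing.
* Alignment ties (equal areas, equal distances) are broken
  lexicographically and toward the lower m/z; the procedure is reproducible
  across platforms to the limits of IEEE arithmetic.
* Zero ISTD areas, non-positive calibration values, empty spectra, empty
  libraries, unpaired samples and incomplete Friedman blocks are all hard
  errors naming the offending record, never silent drops.

## Known limitations

No vendor raw formats or mzML are read — the package consumes feature
tables, spectra (MSP/MGF) and designs as delimited text. There is no
de novo identification of unknown features, no sn-position or double-bond
localization, and no drift correction for the hydrophobic precipitation of
triglycerides and cholesteryl esters over long batches (the phenomenon is
real but no correction algorithm is defined in the source material).

## A worked run

```{r pipeline}
res <- run_pipeline(list(
  seed = 1,
  stages = list(list(name = "simulate",
                     params = list(n_replicates = 6L, with_dilution = TRUE)),
                "align", "filter_presence", "subtract_blank",
                "filter_dilution", "annotate", "quantify")))
vapply(res$manifest$stages, function(s) s$n_out, numeric(1))
```

The funnel never grows after alignment. With the default 50-entry world
the survivors of presence, blank and dilution filtering are the true
lipids (a seed-dependent one or two sit at the stochastic edge of the
matching box and drop out of full presence — at zero noise the recovery is
exactly 50 of 50, which is what the acceptance suite asserts); all
survivors are annotated against the generating library and quantified
against the fitted calibration.
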