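# lipid4d

Computational core of a four-dimensional (4D) ion-mobility lipidomics
platform for clinical blood profiling. Every detected lipid ion carries four
descriptors — m/z (Da), retention time (RT, min), collision cross section
(CCS, Å²) and an MS/MS spectrum — and `lipid4d` implements the full desk
side of such a platform on plain-text inputs:

* **Feature selection**: alignment of replicate runs into a bucket table
  (per-dimension tolerance box: |Δm/z| < 0.002 Da, |ΔRT| ≤ 0.1 min,
  |ΔCCS| ≤ 0.2 Å²), recursive gap-filling, the 17-of-32 / 32-of-32
  presence rule, solvent-blank subtraction, cross-experiment overlap
  matching and the dilution-response filter (Pearson r ≥ 0.9 with the
  volume ladder, normalized-mean SD > 0.1).
* **4D annotation**: library matching with banded confidence scores
  (mass accuracy 1–3 ppm, RT 0.1–0.5 min, CCS 0.2–1.5 Å², MS/MS 900–500 on
  a 0–1000 fit / reverse-fit / purity scale) and isotope-pattern scoring.
* **Quantification**: internal-standard calibration
  `areaRatio = c1·concRatio^(1/c2)` fitted in log–log space;
  `A = ((a_analyte/a_ISTD)/c1)^c2·C_IS` ng/mL on column,
  `B = A·V_final/V_sample` (360/20 µL), `C = B/adduct mass` nmol/mL;
  one-point quantification, ±20 % back-calculated accuracy flags,
  `LLOD = 3.3 σ/s`, `LLOQ = 10 σ/s`, recovery/matrix-effect arithmetic and
  batch-layout validation.
* **Pheno-mapping statistics**: paired Wilcoxon dissimilarity counts with
  Benjamini–Hochberg correction, Friedman time-point tests, random-forest
  classification with person-held-out folds and AUROC, PCA, pooled class
  SDs and the CERT2 cardiovascular marker-ratio inputs.
* **Synthetic data**: seeded generators for libraries, replicate batches
  with background features, dilution ladders, calibration series and a
  4-individual × 5-blood-matrix × 3-time-point study, all with exported
  ground truth.

## Worked example

```r
library(lipid4d)

## calibrate and quantify -----------------------------------------------
cal   <- gen_calibration(simulation_config(seed = 42))  # 7 points, 2% noise
model <- fit_calibration(cal$points)
model
#> <calibration_model: c1 = 1.231, c2 = 1.091, r2 = 0.9998, LLOD = 0.1155, LLOQ = 0.35>
round(model$accuracy, 1)    # back-calculated accuracy per point, %
#> [1]  98.5 104.6  98.8  97.2  99.8 100.3 100.9

quantify_multipoint(2.4e5, 1.0e5, model, quant_context(), adduct_mass = 803.58)
#>        A        B        C
#>  207.280 3731.046    4.643
```

The analyte at an area ratio of 2.4 corresponds to 207 ng/mL on column
(`A`), 3731 ng/mL in the original 20 µL specimen after the 360 µL
reconstitution (`B`), i.e. 4.64 nmol/mL at an adduct mass of 803.58 Da
(`C`). All seven calibration points back-calculate within the ±20 %
acceptance band.

```r
## blood-matrix dissimilarity -------------------------------------------
st <- gen_study(simulation_config(seed = 42))   # 60 samples x 100 lipids
pairwise_wilcoxon(st$conc, st$design)$dissimilarity
#>            blood DBS_finger DBS_venous plasma serum
#> blood          0         86         89     86    84
#> DBS_finger    86          0          0     78    85
#> DBS_venous    89          0          0     84    82
#> plasma        86         78         84      0     0
#> serum         84         85         82      0     0
```

Each entry counts the lipids whose paired signed-rank test rejects after
Benjamini–Hochberg correction: 0 means the two matrices are
indistinguishable. The simulated world reproduces the expected biology —
plasma ≈ serum and venous ≈ finger-prick dried blood spots, while whole
blood and the dried spots differ from plasma in most lipids.

A full pipeline (simulate → align → presence → blank → dilution →
annotate → quantify) with a JSON manifest:

```r
res <- run_pipeline(list(seed = 1, stages = list(
  list(name = "simulate", params = list(n_replicates = 6L, with_dilution = TRUE)),
  "align", "filter_presence", "subtract_blank", "filter_dilution",
  "annotate", "quantify")))
vapply(res$manifest$stages, function(s) s$n_out, numeric(1))
#> [1] 1500 1252   48   48   48   48   48
```

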