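# macroGP

Three-way macrophage phenotyping (M0 / M1 / M2) as a tested R pipeline:
ratiometric **generalized-polarization (GP) membrane-order imaging** with
LUV-based calibration, **2^−ΔΔCq relative expression** quantification,
**surface-marker MFI profiling**, a shared **two-group statistical
engine**, and **marker-based phenotype classification** — all exercisable
offline on a seeded synthetic-data module that emulates the three-group
study design.

It is written for quantitative cell biologists and image analysts who
work with environment-sensitive membrane dyes (Di-4-ANEPPDHQ, Laurdan)
and need the full chain from dual-channel intensities to per-cell
membrane-order statistics, alongside the standard expression and
cytometry readouts used to benchmark them.

## The model

Membrane lipid order is quantified pixel-wise from an "ordered"
(500–580 nm) and a "disordered" (620–750 nm) emission channel:

```
GP = (I_ordered − G · I_disordered) / (I_ordered + G · I_disordered)
```

with the instrument calibration factor derived from a reference standard
of known GP (measured raw on the instrument as GPmes):

```
G = (1 − GPref)(1 + GPmes) / ((1 − GPmes)(1 + GPref))
```

so that a pair whose raw GP equals GPmes maps back to GPref exactly (the
round-trip identity, tested to 1e−9). Per-cell summaries are reported
both on the internal [−1, 1] scale and on the ×100 reporting scale used
for group statistics. Expression fold changes follow RQ = 2^−ΔΔCq
against the 18S reference gene and an M0 calibrator; every pairwise
group contrast (t, df, p, 95% CI, F variance test) carries the η²/R²
effect size R² = t²/(t² + df).

## Worked example

Calibrate from synthetic reference vesicles, image a field of M2-like
cells, segment membranes automatically, and classify by GP:

```r
library(macroGP)

cal <- estimateCalibration(
  simCalibrationSet(gpRef = 0.6, gpMes = 0.4, nVesicles = 50,
                    noiseSd = 0.02, seed = 1),
  gpRef = 0.6)
cal
#> CalibrationReference: GPref = 0.6000, GPmes = 0.4020, G = 0.586133

field <- simMembraneImages(SyntheticImageSpec(
  imageSize = c(200, 200), nCells = 6, gpTrue = 0.6999,
  photonBudget = 2000, seed = 7))
map  <- gpMap(field$channels, gFactor = 1, intensityFloor = 100)
summ <- summarizeROIs(map, segmentMembranes(field$channels),
                      phenotype = "M2")
summ
#>    cell_id phenotype n_pixels mean_gp_internal mean_gp_reported
#> 1 auto_001        M2      160           0.6997            69.97
#> 2 auto_002        M2      157           0.6987            69.87
#> ...
classifyByGP(summ)$gp_call
#> [1] "M2" "M2" "M2" "M2" "M2" "M2"
```

Each ring-shaped cell is recovered with ~160 membrane pixels and a mean
reported GP within a fraction of a unit of the ground-truth 69.99, so
every cell lands above the M1/M2 threshold (66.78).

The statistical engine accepts summary statistics directly, which lets
printed tables be re-analysed without raw data:

```r
compareGroups(groupStats("M0", 9, 1, 7.775),
              groupStats("M1", 9, 371.9, 136.37), "pooled")
#> ComparisonResult: M0 vs M1 (pooled)
#>   mean diff (b-a) = 370.9 +/- 45.53 (SEM), 95% CI 274.4 to 467.4
#>   t = 8.146, df = 16, p = 4.381e-07, R^2 = 0.8057
#>   F = 307.6 (df 8, 8), p = 7.655e-09
```

The full synthetic study — imaging, expression, markers, and the
combined phenotype report — runs end to end with
`runPipeline(pipelineConfig(seed = 1))`.

See the methods vignette
(`vignettes/membrane-order-phenotyping.Rmd`) for the model details,
generator design, numerical choices, and known limitations.

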