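# grapenir

Vis–NIR chemometrics for non-destructive prediction of wine-grape internal
quality during on-vine ripening.

Deciding when to harvest requires tracking soluble solids (°Brix), reducing
sugars, pH, titratable acidity, tartaric and malic acid, and potassium in
the berries. Wet chemistry is slow and destructive; diode-array Vis–NIR
spectroscopy (380–1,700 nm, log(1/R)) of intact bunches or pressed must can
predict all of these at once. `grapenir` implements the complete calibration
workflow a spectroscopist runs on such data, for R users who want each stage
as a tested, composable function:

- **Data model and I/O** — replicate spectra with metadata plus a
  reference-chemistry table, in a documented CSV dialect; replicate
  averaging; spectral-window slicing.
- **Pretreatment** — standard normal variate (SNV) and second-degree
  detrending per spectrum; WinISI-style gap–segment derivatives coded
  `"order,gap,smooth1,smooth2"` (e.g. `"2,5,5,1"`).
- **Population structuring (CENTER-style)** — PCA of pretreated spectra,
  the standardized Mahalanobis distance GH = D²/n_PC (outlier rule GH > 3),
  and a deterministic spectral-only calibration/validation split along the
  GH ranking with boundary samples protected into calibration.
- **Global calibration** — PLS1 and modified PLS (MPLS: per-wavelength
  rescaling of spectral residuals by their SD after each factor,
  Shenk–Westerhaus), with seeded 4-group cross-validation and a
  parsimonious SECV-based factor choice.
- **LOCAL memory-based regression** — per query, select the k library
  spectra with the highest Pearson correlation to the query, fit a local
  (M)PLS model with l factors, discard the first 4 factor predictions and
  combine the rest with reciprocal residual×coefficient-norm weights; tune
  (k, l) on a grid (k ∈ {25, 50, 75, 100, 110, 125, 150}, l ∈ {14, 15, 16}
  for the main design).
- **Diagnostics** — bias, SEP = √(Σe²/n), SEP(c) = √(Σ(e−bias)²/(n−1)),
  SEC, SECV, r², slope, RPD = SD/SECV, CV% = 100·SECV/mean, and
  model-comparison improvement percentages.
- **Synthetic study generator** — grape-like reference chemistry over three
  seasons (108/120/135 samples, 25 varieties, 8 replicate spectra per
  sample) and stylized Gaussian-band spectra with scatter, noise, and a
  mild sugar-regime-dependent nonlinearity, so the whole workflow is
  testable end to end.

## Worked example

```r
library(grapenir)

study <- generate_study(synthetic_config(seed = 42, presentations = "bunch"),
                        file.path(tempdir(), "demo"))
ds      <- load_dataset(study$spectra, study$reference)
spectra <- average_replicates(ds$spectra)
pre     <- apply_pretreatment(spectra,
             pretreatment_spec("snv_detrend", "2,5,5,1", c(380, 1650)))
pre
#> SpectraSet: 363 spectra x 622 wavelengths (394-1636 nm)
#>   presentation: bunch=363

ssc <- ds$reference$ssc_brix[match(pre$meta$sample_id, ds$reference$sample_id)]
cv  <- cross_validate(pre$x, ssc, max_factors = 16, n_groups = 4,
                      seed = 42, mode = "mpls")
sprintf("SSC: %d factors, SECV = %.2f, r2_cv = %.3f, RPD = %.1f",
        cv$chosen_factors, cv$secv, cv$r2_cv, rpd(sd(ssc), cv$secv))
#> "SSC: 8 factors, SECV = 0.43, r2_cv = 0.992, RPD = 11.1"
```

The cross-validation picked 8 latent factors; the 0.43 °Brix SECV is the
pooled out-of-group error, and an RPD (reference SD over SECV) above 3
indicates excellent quantitative ability. Splitting on spectral structure
only, validating the global model externally, and predicting one validation
bunch with LOCAL:

```r
s08   <- subset_rows(pre, pre$meta$season == 2008)
split <- split_by_center(s08, fit_center(s08), validation_fraction = 0.27)
is_val <- pre$meta$sample_id %in% split$validation_ids

glob <- fit_pls1(pre$x[!is_val, ], ssc[!is_val], 16, "mpls")
eval_stats(ssc[is_val], predict_pls(glob, pre$x[is_val, ], 16))
#> EvalStats (n=33): bias=0.03032 SEP=0.4748 SEP(c)=0.4812 r2=0.988 slope=1.012

lp <- local_predict(subset_rows(pre, !is_val), ssc[!is_val],
                    pre$x[which(is_val)[1], ], local_config(k = 75, l_max = 16))
sprintf("LOCAL: %.2f °Brix (GH %.2f, NH %.2f)", lp$value, lp$gh, lp$nh)
#> "LOCAL: 16.01 °Brix (GH 0.45, NH 0.16)"
```

GH and NH are the Mahalanobis distances of the query to the whole library
and to its selected neighbors; values near 1 are typical, above 3 suspect.
`run_study()` chains all of this — best-pretreatment scan per analyte,
external validation, the 21-cell LOCAL grid, and MPLS-vs-LOCAL comparison
tables — from a single `study_config()`.

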