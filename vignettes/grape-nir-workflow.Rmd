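---
title: "Vis–NIR calibration of grape internal quality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vis–NIR calibration of grape internal quality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grapenir)
```

`grapenir` implements the calibration workflow used to predict internal
quality of wine grapes from visible/near-infrared reflectance spectra
collected non-destructively during on-vine ripening. This vignette explains
the statistical machinery, the conventions adopted where the field leaves
choices open, what the synthetic data generator does and does not emulate,
and the package's known limitations.

## The data and its pretreatment

A field campaign produces, per sample, several replicate spectra (eight in
the standard protocol) of intact bunches and/or pressed must on a 2 nm grid
from 380 to 1,700 nm, stored as log(1/R) absorbance, plus wet-chemistry
reference values: soluble solids (°Brix), reducing sugars (g/L), pH,
titratable acidity (g/L tartaric-acid equivalents), tartaric and malic acid
(g/L), and potassium (mg/L). Replicates are arithmetically averaged per
sample and presentation before any modeling; averaging eight replicates
reduces uncorrelated noise variance about eight-fold.

Raw bunch spectra are dominated by scatter: berry size, packing and surface
effects shift and scale the whole spectrum. Three candidate windows are
scanned (380–1,650 Vis+NIR, 780–1,650 NIR, 1,100–1,650 nm strict NIR; the
noisy 1,650–1,700 nm detector edge is always discarded; windows are closed
intervals, so 380–1,650 keeps exactly 636 of the 661 grid points).
Within a window, each spectrum is corrected by the standard normal variate
(subtract its mean, divide by its sample SD) plus detrending (subtract the
least-squares second-degree polynomial in wavelength), then differentiated
by a gap–segment derivative coded as four integers `d,g,s1,s2`: first
derivative `x[i+g] − x[i−g]` or second derivative
`x[i+g] − 2·x[i] + x[i−g]` with gap `g`, followed by centered running means
of widths `s1` and `s2` (width 1 = none). Edges are truncated rather than
padded, so a treatment loses `2g + (s1−1) + (s2−1)` points. The four codes
scanned by default are `1,5,5,1`, `2,5,5,1`, `1,10,5,1` and `2,10,5,1`.

Conventions adopted where practice varies, all configurable:

- all four code numbers are data points (2 nm per point on the default
  grid), the WinISI reading; treating the gap as nanometers would only
  rescale it by a constant factor;
- pipeline order is window → scatter correction → derivative;
- SNV divides by the sample (n−1) standard deviation;
- detrending uses degree 2, the usual convention for this correction;
- derivatives are symmetric gap differences with boxcar smoothing (widths
  must be odd so the output grid stays aligned), not Savitzky–Golay, which
  matches the running-average description of the treatment codes.

## Population structuring and the spectral split

Calibration/validation assignment uses spectral information only, so the
split cannot leak reference values. A PCA of the pretreated spectra retains
the smallest number of components reaching 99% cumulative variance (capped
at 15). The standardized Mahalanobis statistic of a spectrum is
GH = D²/n_PC, with D² computed on PC scores scaled by their eigenvalues;
under this normalization the training mean GH is (n−1)/n ≈ 1 and GH > 3 is
the conventional outlier flag (flagged samples are reported, never removed
automatically).

The split orders one season's samples by GH (descending, ties broken by
sample id), walks the ranking, and assigns every `round(1/f)`-th sample to
validation, starting mid-stride. Samples marking the boundary of the
population — the top and bottom of the GH ranking and the outer ~2% of the
score range on each retained PC (protection capped at half the population)
— always stay in calibration; a protected pick is replaced by the adjacent
rank so the validation count is preserved. The intent is the classic
set-selection property that validation reference ranges nest inside
calibration ranges. On spectrally expressed chemistry this holds reliably,
but it is a statistical tendency, not a theorem: a sample can be extreme on
one analyte while sitting on a diagonal of the composition space where its
eigenvalue-scaled GH looks unremarkable, so occasional single-analyte
violations by small margins are possible on unfavorable random draws.

The multi-season protocol mirrors field practice: the split is computed on
the most recent season; validation comes from that season only, and all
earlier-season samples join the calibration set. Potassium is modeled from
the single season carrying potassium chemistry.

## Global calibration: PLS1 and MPLS

Calibrations are univariate partial least squares fitted by NIPALS on
column-centered spectra. In the modified-PLS (MPLS) variant, after each
factor is deflated every wavelength's residual column is rescaled by its
standard deviation, so later factors see all wavelengths' remaining
information on a common scale. The model stores a regression vector for
every factor count j (obtained by unwinding the scaling and deflation
maps), so predictions at reduced rank need no refitting, and
`ŷ = y_mean + (x − x_mean)·b_j` exactly reproduces the sequential
deflation-path prediction. Plain PLS1 is retained both as a user option and
because it admits an independent oracle: with no rescaling, full-factor PLS
equals ordinary least squares, and the test suite also cross-checks
predictions against an independent NIPALS implementation (`mixOmics::pls`)
to 10⁻⁶.

Factor counts are chosen by grouped cross-validation: a seeded shuffle cuts
the calibration set into 4 contiguous blocks; SECV(j) pools out-of-group
residuals (root mean square, denominator n); the chosen count is the
smallest j within 2% of the SECV minimum. The 2% parsimony rule guards
against buying negligible error reductions with extra factors; the maximum
is 16 factors by default. A constant response is handled as a special case
(SECV 0, one factor) since the factor extraction itself requires response
variance.

## The LOCAL algorithm

Global models average over the whole ripening trajectory; matrix effects
make the spectra–composition relationship mildly regime-dependent, which a
single linear model cannot fully capture. LOCAL builds a fresh calibration
per query: (1) rank all library spectra by Pearson correlation with the
query spectrum (computed on pretreated spectra, ties broken by sample id);
(2) fit (M)PLS with l factors on the top k; (3) predict with every factor
count from 5 to l (the first 4 are discarded — low-rank local models are
dominated by scatter artifacts); (4) combine the per-factor predictions by
weights proportional to 1/(RMS spectral residual after j factors × norm of
the j-factor regression vector), normalized to sum to one (uniform
weighting is available for ablation). Queries also receive GH against the
whole library and NH, the same statistic computed in the PC space of the
selected neighbors only, since no closed formula for the neighborhood
statistic is standard.

Tuning scans k ∈ {25, 50, 75, 100, 110, 125, 150} × l ∈ {14, 15, 16} (21
cells; k ∈ {25, 50, 75} for the single-season potassium library, 9 cells)
and selects the cell minimizing SEP(c) (SEP selection is a toggle). Two
caveats are inherent to the protocol and printed with the results: the grid
is tuned on the validation set, which favors LOCAL over the global model
chosen on cross-validation statistics alone, and cells with k below the
minimum usable library (15) are skipped. With k equal to the library size,
LOCAL degenerates to the global model factor-for-factor, which the tests
verify numerically. Within the full study pipeline, LOCAL runs at each
analyte's best global pretreatment rather than re-scanning all twelve
treatment×window combinations; `optimize_local_grid()` accepts any
pretreated library for users who want the wider scan.

## Diagnostics

With residuals e = ŷ − y: bias = mean(e), SEP = √(Σe²/n),
SEP(c) = √(Σ(e−bias)²/(n−1)), r² the squared Pearson correlation, slope
from regressing reference on prediction, RPD = SD_ref/SECV and
CV% = 100·SECV/mean_ref. These denominators satisfy
n·SEP² = (n−1)·SEP(c)² + n·bias², are the unique common convention
consistent with published (n, SEP, SEP(c), bias) validation quadruples, and
legitimately allow SEP(c) > SEP at small bias. SECV uses denominator n;
SEC uses n − factors − 1. Model comparisons report error reductions
relative to the baseline model and r² gains relative to the improved model,
in percent. Report tables round half-up to two decimals.

## The synthetic study generator

No grape spectra are publicly deposited with reference chemistry at this
design, so the package ships a generator that emulates the statistical
structure the workflow assumes, and the test suite exercises everything end
to end on it.

**Chemistry.** Each sample gets a latent ripeness r ~ U(0,1) within its
season (default 108/120/135 samples across three seasons, 25 varieties,
both presentations). Soluble solids rise with r (11 + 16r ± season shift ±
1.5 noise), reducing sugars track soluble solids at 9.7 g/L per °Brix (the
ratio of their typical calibration means), pH rises, titratable and
tartaric acid fall linearly, malic acid falls quadratically (it is
metabolized during ripening), and potassium rises weakly with a coupling to
acidity. All values are clipped to the calibration ranges of a three-season
ripening campaign, so generated chemistry respects those ranges by
construction, and sugar–acidity correlations are negative as in real
ripening.

**Spectra.** A clean spectrum is a sloping baseline plus water bands
(970/1,190/1,450 nm), chlorophyll (678 nm, scaled by unripeness), red-variety
pigment bands (530/640 nm), and one Gaussian band set per analyte weighted
by concentration. Band positions and absorptivities are stylized: they are
chosen so each analyte's full-range contribution (~0.1–0.2 AU) is
comparable to the background structure — the regime in which NIR
calibration of grape chemistry is known to work — not as vibrational
assignments. Two mild nonlinearities driven by the saturating regime term
tanh((SSC−20)/8) distort the linear mixture: a path-length factor applied
to the NIR side only (sigmoid onset near 950 nm) and a drift of the sugar
band centers (strength 0.15 by default; 0 gives fully linear mixing). A
flat multiplicative factor would be annihilated by SNV, which is why the
nonlinearity is wavelength-dependent. Each replicate then receives
multiplicative scatter, an additive offset, a linear tilt and white noise;
bunch presentation carries 1.8× the scatter of must. All randomness flows
from one root seed (chemistry and replicate substreams), so studies
regenerate byte-identically.

**What passing tests do and do not show.** On this generator, the linear
regime is recovered by global MPLS with cross-validated r² ≥ 0.95 for
soluble solids, and under the default nonlinearity the best LOCAL cell
beats the global model's SEP on held-out samples — the qualitative
direction expected of memory-based calibration. The generator does not
emulate instrument drift, temperature effects, water-band saturation,
variety-specific band shapes, or reference-method error structure, so
passing tests demonstrate correctness of the algorithms and the expected
direction of effects, not field-level accuracy figures. Problem sizes used
by the tests and the acceptance script (363 samples, 622–636 pretreated
wavelengths, 21-cell LOCAL grids) were chosen to mirror the emulated
campaign while keeping a full run in minutes on one CPU.

## Numerical choices and degenerate inputs

- Zero-variance spectra are rejected by SNV and by neighbor correlation;
  zero-variance responses are rejected by the PLS fit and special-cased in
  cross-validation; a LOCAL neighborhood whose references are all equal
  predicts that value exactly.
- A vanishing weight vector during NIPALS (response fully explained) yields
  zero factors from that point on; MPLS residual SDs below 10⁻¹² are
  replaced by 1 before rescaling.
- Neighbor selection and the spectral split break ties by sample id, so all
  set selections are deterministic.
- Smoothing widths must be odd; derivative supports are truncated, never
  padded.
- `j = 0` is allowed in prediction as the intercept-only baseline.

## Limitations

- MPLS rescaling follows the Shenk–Westerhaus description; proprietary
  implementations may differ in unpublished details, so exact numerical
  agreement with WinISI output is not claimed.
- The SECV denominator (n) and the slope convention (reference on
  prediction) are documented defaults; both have common alternatives.
- The spectral split guarantees determinism and boundary protection but not
  strict per-analyte range nesting (see above).
- LOCAL is O(library × wavelengths) per query with a fresh PLS fit per
  grid cell; libraries beyond a few thousand spectra would want indexing
  that this package deliberately omits.
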