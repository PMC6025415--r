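---
title: "CDOM optics, FRI and phthalate risk: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CDOM optics, FRI and phthalate risk: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdomPAE)
```

`cdomPAE` analyses two-season lake surveys in which every water sample
carries an excitation–emission fluorescence matrix (EEM), a UV–Vis
absorbance spectrum, water-quality covariates and concentrations of the
three priority phthalate esters (DMP, DEP, DBP). This vignette is the
package's account of the science: the models, their assumptions, the
tunable parameters, the numerical choices, and what the synthetic
test-bed does and does not establish about real data.

## EEM preprocessing

Three corrections precede any integration, applied in the order
blank → inner-filter → scatter. The order in which field
laboratories apply blank subtraction and inner-filter correction
varies between instruments and protocols; this default was chosen
because the blank is acquired in the same cell geometry (so the
inner-filter factor applies to the blank-free signal) and every
correction is logged on the object, so the order is auditable and
each step can be invoked separately in any order if a lab's protocol
differs.

**Blank subtraction** (`subtractBlank`) removes the Milli-Q water
spectrum cell-wise. Differences driven below zero by instrument noise
are floored at zero and counted (attribute `flooredCells`): regional
volumes are Riemann sums, and negative noise must not erode them.

**Scatter excision** (`removeScatter`) removes the first-order
(λ_em ≈ λ_ex) and second-order (λ_em ≈ 2 λ_ex) Rayleigh ridges. A cell
is excised exactly when |λ_em − λ_ex| ≤ w₁ or |λ_em − 2 λ_ex| ≤ w₂;
both half-widths default to 15 nm, a common choice for 5 nm excitation
steps, and are configurable. Excised cells are either zeroed (and
flagged in the object's mask) or re-filled by linear interpolation
*along the emission axis only* between the nearest retained
neighbours, with a zero anchor when the excised run touches a spectrum
edge. One-dimensional interpolation was chosen over 2-D inpainting
because it is exactly reproducible and checkable against a brute-force
oracle; the cost is a small bias inside wide bands, which matters
little here because all five FRI regions sit away from the ridges.

**Inner-filter correction** (`innerFilterCorrect`) multiplies each cell
by 10^((A(λ_ex)+A(λ_em))/2), where A is the decadic optical density as
measured. No path-length renormalisation is applied because
fluorescence and absorbance are both acquired in 1 cm cells. The
absorbance spectrum must cover every EEM wavelength — the function
refuses to extrapolate.

## Fluorescence regional integration

Each regional volume is the Riemann sum Φᵢ = Σ I(λ_ex, λ_em) Δλ_ex
Δλ_em over the grid points inside the region; wavelength steps are
inferred from the (regular) axes — 5 nm and 1 nm on the standard grid.
Three conventions are worth stating because the classical region table
leaves them ambiguous:

* **Half-open boundaries.** The published region bounds share the
  250/330/380 nm edges. Membership here is `low ≤ λ < high` on both
  axes, which makes the five regions a partition: every grid cell
  belongs to at most one region, and ΣPᵢ = 1 whenever Φ_T > 0. The
  tests verify this exhaustively on the default grid.
* **Clipping.** R1–R3 nominally start at excitation 200 nm but the
  standard acquisition starts at 220 nm; region parts outside the
  measured axes contribute nothing. No intensity is extrapolated.
* **Unassigned volume.** Emission 550–600 nm and excitation ≥ 400 nm
  belong to no region. That volume is computed and reported
  (`unassignedVolume`) so the partition is transparent, but it is not
  part of Φ_T.

Area-normalisation multiplication factors (which rescale each Φᵢ by
the inverse of its fractional region area) are **off by default** —
the integral as defined is a raw volume — and available behind
`multiplicationFactors = TRUE` for comparability with studies that
apply them. Volumes are reported in intensity·nm²; intensity units are
instrument-dependent and carried through unchanged (no Raman
normalisation), so only ratios and correlations are comparable across
instruments.

`friComponents` refuses an EEM whose correction log lacks blank and
scatter treatment unless `force = TRUE`: integrating a raw EEM silently
is the most common way to corrupt FRI shares.

The fluorescence indices are plain intensity ratios on the grid —
FI370 = I(370,450)/I(370,500), FI310 = I(310,380)/I(310,430) — with
thresholds 1.4/1.9 (terrestrial/microbial) and 0.7/0.8 (autochthonous
level); threshold values themselves classify as "intermediate"
(inclusive bounds). A non-positive denominator yields NA with a
warning; an excised cell is an error directing the user to
interpolation mode.

## CDOM absorption metrics

`napierianAbsorption` converts optical density with
a(λ) = 2.303·OD(λ)/γ, γ = 0.01 m. No long-wavelength null-point offset
is subtracted by default (the conversion formula has none); a window
such as 700–800 nm can be supplied. SUVA₂₅₄ is a(254)/DOC using the
Napierian coefficient — with the survey's own means (a(254) =
16.06 m⁻¹, DOC = 26.08 mg L⁻¹) this gives 0.62 L mg C⁻¹ m⁻¹, which is
how the two quantities reconcile.

The spectral slope S is estimated by ordinary least squares on
ln a(λ) vs λ over the closed window (default 275–295 nm). A log-linear
fit rather than a nonlinear exponential fit is deliberate: over a 20 nm
window the two agree closely, and the OLS estimate is deterministic,
scale-invariant and exactly recovers the generating slope on noiseless
exponentials — properties the tests rely on. Non-positive coefficients
are dropped; fewer than 5 usable points gives NA with a warning.

The slope ratio S_R is defined here as S₂₇₅₋₂₉₅/S₃₅₀₋₄₀₀ (the common
window pair). A flat spectrum gives NA rather than 0/0.

Published per-survey S₂₇₅₋₂₉₅ magnitudes vary by an order of magnitude
across reports depending on unit conventions; this package reports S in
nm⁻¹ from the fit and makes no attempt to match any particular survey's
absolute slope values.

## Risk screening

The exposure chain is ADD = (C·DR·EF·ED)/(BW·AT), HQ = ADD/RfD,
HI = ΣHQ, with CR = ADD·CSF and RI = ΣCR when slope factors are
configured. Defaults (`riskParams()`): DR 2 L/d, EF 350 d/yr, ED 30 yr,
BW 60 kg, AT 26,280 d, RfD DMP 1.0, DEP 0.8, DBP 0.1 mg kg⁻¹ d⁻¹, no
CSFs (the three congeners are treated as non-cancer compounds, so the
carcinogenic branch reports "not-evaluated").

Two parameter subtleties:

* AT = 26,280 d equals 72 years, not ED·365 = 10,950 d. The default
  reproduces the published parameterisation verbatim;
  `strictAveragingTime = TRUE` recomputes AT = ED·365 for sensitivity
  (it raises every HQ by ×2.4, which does not change the HI < 1
  conclusion at the observed concentration range).
* Concentrations are mg/L and reference doses mg kg⁻¹ d⁻¹ throughout;
  the µg-valued published RfDs are converted once at construction.
  The Chinese surface-water DBP limit of 3 µg/L sometimes quoted as an
  "RfD" is a water-quality screening limit, not a dose, and is not
  used as one here.

With these defaults, HQ = C × 0.01332/RfD, so any concentration below
1 mg/L with RfD ≥ 0.1 keeps HQ below 0.14 — the HI < 1 finding is
structural at surveyed concentrations, and the tests assert it both for
the seasonal means and per site on synthetic surveys.

Composition statistics (`paeComposition`) report per-congener
mean/median/max and percentage shares of the summed mean per season and
overall; overall means are sample-size-weighted across seasons, which
equals the pooled-sample mean.

## Association layer

`pearsonMatrix` computes pairwise-complete Pearson correlations with
two-tailed p-values from the t-transform on n−2 df. Both r and r² are
always emitted: survey reports in this field often label Pearson tables
"R²", and emitting both sidesteps the ambiguity instead of resolving
it. Missing values are deleted pairwise (no imputation). No
multiple-testing correction is applied by default; Benjamini–Hochberg
is available via `adjust = "BH"`. `regressSimple` is ordinary least
squares with an exposed prediction function — the "optical surrogate"
use — and requires at least three complete pairs. `anovaOneway` is the
classical F-test, with the all-values-identical degenerate case mapped
to F = 0, p = 1.

## The synthetic survey: what it emulates

`cohortConfig()`/`generateCohort()` define the test-bed conditions:

* **Design.** 25 June + 20 October samples on the standard grid.
* **Latents.** Terrestrial input T and autochthonous production A are
  lognormal (log-sd 0.35 and 0.30) with log-scale correlation 0.6;
  October raises the T median ×1.5 and lowers A (1.2 → 0.8 linear
  median), mirroring a dry-season terrestrial shift. Lognormal latents
  keep all quantities positive and right-skewed like field data.
* **Fluorophores.** One 2-D Gaussian per region, centred near its
  region's midpoint, with widths chosen so roughly ±2 sd fit inside
  the home region (≥95% of a lone fluorophore's measured volume
  integrates into its own region). Amplitudes load R1/R2 on A, R3/R5
  on T, R4 on T^0.7·A^0.3, each with its own lognormal jitter (R3
  small, 0.05; R5 large, 0.4) — the jitter ladder is what makes the
  observed correlation strength decay in the order R3 ≥ R4 > R5.
* **FI370 calibration.** The humic-like emission-peak centre is solved
  in closed form from the seasonal FI370 targets (1.39 June, 1.14
  October) given the peak width — a red-shift of about 6 nm reproduces
  the seasonal contrast. FI310 levels are *not* targeted: matching
  both indices simultaneously would require a second simultaneous
  calibration of the protein-like peak, and no test depends on FI310
  cohort means.
* **DEP link.** DEP = β·T + ε with β = 0.28 mg/L per unit T. The noise
  sd is solved in closed form from pooled lognormal moments so that
  the population r² between the fulvic-like *amplitude* and DEP equals
  the 0.78 target. Crucially DEP is tied to the latent T, not to the
  fluorescence itself, so the observed Φ₃–DEP correlation is an
  emergent, pipeline-mediated property — blank subtraction,
  inner-filter correction, scatter interpolation and Riemann
  integration all sit between the latent and the measured r².
* **Optics.** a(λ) = 2.1·T·e^(−S(λ−350)) m⁻¹ with S = 0.020 (June)
  and 0.018 nm⁻¹ (October) and 0.5% multiplicative OD noise; the EEM
  is attenuated by the sample's own inner-filter factor (which the
  pipeline later undoes), carries deterministic Rayleigh ridges
  (amplitude 300, width 4 nm; the blank carries the same ridges) and
  additive Gaussian noise (sd 1 instrument unit against peak
  amplitudes of order 150–600).

What passing tests on this generator show: the preprocessing chain is
self-consistent (it inverts the generator's attenuation and ridges),
FRI recovers analytic fluorophore masses within discretisation error,
the slope fit recovers the generating S, and the correlation/regression
layer recovers the calibrated association through the full pipeline.
What they do not show: absolute fluorescence magnitudes (instrument
units are arbitrary and no Raman normalisation is applied), FI310
levels, real scatter-band shapes (real ridges have wavelength-dependent
width and Raman structure), non-Gaussian fluorophore line shapes, or
spatial site-to-site structure — sites are exchangeable draws here.

## Problem sizes and tolerances in the test suite

The suite runs on full-size cohorts (45 samples, 47×351 grids). The
end-to-end correlation recovery uses 50 seeded cohorts and checks the
median realised r²(Φ₃, DEP) within ±0.1 of the 0.78 target; slope
recovery uses 50 seeded spectra at 1% noise (mean within 0.0005 nm⁻¹);
Gaussian-mass agreement is checked at 2%, the size of the left-endpoint
Riemann error at a 5 nm excitation step. Brute-force double-loop
oracles (cell classification, region volumes, Pearson sums, ANOVA sums
of squares) are implemented independently in the test helpers.

## Known limitations

* No Raman normalisation or lamp-drift correction; volumes are in raw
  instrument units.
* Scatter interpolation is 1-D along emission; wide excised bands near
  strong peaks will be biased toward their flanks.
* The slope ratio S_R uses fixed windows (275–295/350–400 nm).
* Risk screening covers the drinking-water ingestion route only — no
  dermal or inhalation models, and no Monte-Carlo exposure
  uncertainty.
* PCA ordination and spatial mapping of per-site risk are out of
  scope; per-site HQ/HI tables are produced for external mapping
  tools.
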