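# cdomPAE

Lake surveys increasingly pair optical measurements of chromophoric
dissolved organic matter (CDOM) with chemical monitoring of plasticizer
pollution. `cdomPAE` implements that joint analysis for the three
priority phthalate acid esters — dimethyl (DMP), diethyl (DEP) and
dibutyl (DBP) phthalate — in a two-season drinking-water-source survey:
it preprocesses excitation–emission matrices (EEMs), decomposes them by
fluorescence regional integration (FRI), derives CDOM absorption
indices, screens human-health risk for the dietary (drinking water)
route, and quantifies how well the FRI components predict PAE
concentrations, so that a fluorometer can serve as a fast optical
surrogate for chemical PAE quantification.

## Methods at a glance

**EEM preprocessing.** Blank subtraction (negatives floored at zero),
Rayleigh scatter excision around |λ_em − λ_ex| ≤ w₁ and
|λ_em − 2λ_ex| ≤ w₂ (excised cells re-filled by linear interpolation
along the emission axis, or zeroed), and the inner-filter correction
I_corr = I · 10^((A(λ_ex)+A(λ_em))/2) with A the decadic optical
density in a 1 cm cell.

**Fluorescence regional integration.** The EEM plane is partitioned
into five regions — tyrosine-like R1, tryptophan-like R2, fulvic-like
R3, microbial protein-like R4 and humic-like R5 — and each volume is
the Riemann sum

    Φᵢ = Σ_ex Σ_em I(λ_ex, λ_em) Δλ_ex Δλ_em

with Δλ_ex = 5 nm and Δλ_em = 1 nm on the standard acquisition grid
(Ex 220–450 nm / Em 250–600 nm). Φ_T = ΣΦᵢ, shares Pᵢ = Φᵢ/Φ_T, and
the allochthonous vs autochthonous split is F_R(3+5) vs F_R(1+2+4).
Region boundaries are half-open so the five regions form a true
partition. The fluorescence indices FI370 = I(370,450)/I(370,500) and
FI310 = I(310,380)/I(310,430) classify the CDOM source (terrestrial
below 1.4, microbial above 1.9; autochthonous contribution low below
0.7, high above 0.8).

**CDOM absorption.** Napierian coefficients a(λ) = 2.303·OD(λ)/γ
(γ = cuvette path, 0.01 m), the spectral slope S₂₇₅₋₂₉₅ from a
log-linear OLS fit, E₂₅₀:₃₆₅ = a(250)/a(365), SUVA₂₅₄ = a(254)/DOC and
the slope ratio S_R = S₂₇₅₋₂₉₅/S₃₅₀₋₄₀₀.

**Risk screening (USEPA scheme).** ADD = (C·DR·EF·ED)/(BW·AT),
HQ = ADD/RfD, HI = ΣHQ (HI < 1 ⇒ low non-cancer risk), and the
carcinogenic branch CR = ADD·CSF, RI = ΣCR, for the adult scenario
DR 2 L/d, EF 350 d/yr, ED 30 yr, BW 60 kg, AT 26,280 d with oral
reference doses DMP 1.0, DEP 0.8, DBP 0.1 mg kg⁻¹ d⁻¹.

**Association layer.** Pairwise-complete Pearson correlations (r, r²
and two-tailed p), simple OLS regression of PAE concentration on an FRI
volume, and classical one-way ANOVA for the seasonal contrasts.

**Synthetic survey generator.** A seeded generator emulates the study
conditions — 25 June + 20 October samples, five Gaussian fluorophores
driven by correlated terrestrial/autochthonous latent factors,
exponential CDOM absorption, and DEP linked to the terrestrial latent
and calibrated so the population r² between the fulvic-like volume and
DEP is 0.78 — so the whole pipeline is testable without field data.

## Worked example

```r
library(cdomPAE)

bundle <- generateCohort(cohortConfig(), seed = 1)   # synthetic survey
res    <- analyzeCohort(bundle)                      # preprocess + FRI + CDOM

aggregate(cbind(p_allo, fi370, s275_295_per_nm, suva254, dep_mg_per_l)
          ~ season, res, function(x) round(mean(x), 3))
#>   season p_allo fi370 s275_295_per_nm suva254 dep_mg_per_l
#> 1    JUN  0.770 1.379           0.020   0.599        0.304
#> 2    OCT  0.806 1.134           0.018   0.924        0.482

fit <- regressSimple(res$phi3, res$dep_mg_per_l)
sprintf("r2 = %.3f, p = %.3g", fit$r.squared, fit$p.value)
#> "r2 = 0.810, p = 4.24e-17"

assessRisk(c(DMP = 0.01, DEP = 0.403, DBP = 0.007))
#> RiskResult
#>   ADD (mg/kg/day):
#>       DMP       DEP       DBP
#> 1.332e-04 5.367e-03 9.323e-05
#>   HQ:
#>       DMP       DEP       DBP
#> 0.0001332 0.0067090 0.0009323
#>   HI = 0.007774 (low non-cancer risk); carcinogenic: not-evaluated
```

Reading the output: the allochthonous share `p_allo` and SUVA₂₅₄ rise
from June to October (more terrestrial input in the dry season) while
FI370 falls below 1.4 (terrestrial source); the fulvic-like volume Φ₃
explains ~80% of the DEP variance in this cohort; and the hazard index
for the pooled seasonal-average concentrations is ~0.008, far below the
HI = 1 risk threshold.

A YAML-configured end-to-end run over files on disk is available via
`runPipeline()` (see `inst/scripts/run_pipeline.R` for a shell
wrapper), producing per-sample indices, composition, risk and
correlation tables plus a run manifest.

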