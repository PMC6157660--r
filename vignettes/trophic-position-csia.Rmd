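---
title: "Estimating trophic position from amino-acid delta15N: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating trophic position from amino-acid delta15N}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csiaTP)
```

## The problem

The trophic position (TP) of a consumer — producer = 1, herbivore = 2, and
fractional values in between for mixed feeders — is classically estimated
from bulk-tissue delta15N, which rises by about 3.4 per mil per trophic
level. That estimate needs the delta15N of the local primary producers,
which is rarely known for historical material and varies in space and time.
Compound-specific isotope analysis of amino acids (CSIA-AA) removes that
requirement by reading both signals from the same tissue: phenylalanine
(Phe) is a "source" amino acid whose delta15N barely changes up the food
chain and so preserves the baseline, while glutamic acid (Glu) is a
"trophic" amino acid enriched at every transfer. Their spacing,
delta15N(Glu) − delta15N(Phe), therefore encodes the number of trophic
steps without any external baseline.

This package implements the Glu/Phe estimators, the surrounding
corrections (body-size adjustment, prey inference from bulk offsets,
two-prey diet mixing), per-amino-acid enrichment factors with a Suess
correction for delta13C, aggregation of dated specimens into climate
periods, and uncertainty propagation — plus a synthetic food-chain
generator with known true TPs so every estimator can be validated end to
end. The packaged example data are bone-collagen measurements of ancient
tropical seabirds (1020–1913 AD) and modern flying fish from the South
China Sea.

## The estimators

With spacing $S = \delta^{15}N_{Glu} - \delta^{15}N_{Phe}$, producer
spacing $\beta$ and trophic discrimination factors (TDFs) per step:

* **Single-TDF** (aquatic consumers, every step plankton-like):
  $TP_1 = 1 + (S - \beta)\,/\,TDF_{plankton}$
* **Multi-TDF** (birds): the chain is modelled as one plankton-type level
  (TP 1 to 2) followed by avian enrichment at the lower avian-specific
  TDF: $TP_2 = 2 + (S - TDF_{plankton} - \beta)\,/\,TDF_{bird}$
* **Size correction**: when the measured individuals differ in size from
  the population of interest, the TP is shifted by the bulk delta15N
  offset over the per-level bulk enrichment,
  $TP' = TP + (\delta^{15}N_{ref} - \delta^{15}N_{sample})\,/\,b$.
* **Bulk-offset inference**: a second prey's TP is placed relative to a
  known one, $TP_t = TP_b + (\delta^{15}N_t - \delta^{15}N_b)\,/\,b$.
* **Diet mass balance**: a consumer eating two prey in mass proportions
  $f$ and $1-f$ sits one level above their weighted mean,
  $TP_{diet} = f\,TP_1 + (1-f)\,TP_2 + 1$ — affine in $f$ with slope
  $TP_1 - TP_2$.

The two Glu/Phe estimators are linked by the exact identity
$TP_2 = 2 + (TDF_{plankton}/TDF_{bird})(TP_1 - 2)$, which the test suite
verifies to 1e-12; on marine birds the single-TDF model is biased low by
$(TDF_{plankton}-TDF_{bird})\,\Delta tp/TDF_{plankton}$ per avian step.

## Parameters

All constants live in a `tdf_model()` and are configurable (YAML keys in
parentheses); defaults are the established marine values:

| parameter | default | units | meaning |
|---|---|---|---|
| `beta` | 3.4 | per mil | Glu–Phe spacing of aquatic producers (`beta`) |
| `tdf_plankton` | 7.6 | per mil / level | spacing growth through plankton-type consumers (`tdf_plankton`) |
| `tdf_bird` | 3.5 | per mil / level | avian-specific spacing growth (`tdf_bird`) |
| `bulk_step` | 3.4 | per mil / level | bulk-tissue delta15N enrichment (`bulk_step`) |
| `suess_offset` | −1.8 | per mil | post-1850 regional delta13C decline (`suess_offset`) |

No default `beta` is provided for C3/C4 terrestrial webs: users working
on terrestrial systems must supply their own value, since the aquatic
default would be silently wrong.

## Conventions that matter for reproduction

* **Rounding.** All arithmetic is full precision; rounding happens only
  at presentation, and is half-away-from-zero (`round_half_up()`), which
  is how isotope tables are conventionally printed (2.625 prints 2.63).
* **Reporting precision of reference means.** Bulk summary values enter
  corrections at the 1-decimal precision at which such tables report them
  (consistent with the ±0.2 per mil analytical precision of delta15N),
  and prey TPs enter the diet mass balance at 2 decimals — the published
  mixing line $3.67 - 0.29f$ is itself stated at that precision. Using
  full-precision intermediates instead moves the size-corrected fish TP
  from 2.38 to 2.37 and the LIA diet TP from 3.56 to 3.57.
* **Dispersion.** Published ± values in this literature mix conventions
  (the fish TP ±0.10 matches a population SD, the Glu–Phe spacing ±0.9 a
  sample SD), so the convention is explicit everywhere
  (`sd_convention`, default `"sample"`, n−1 divisor).
* **Closed intervals.** The collagen C/N preservation range 2.9–3.6 and
  the period definitions (MWP 850–1200 AD, LIA 1400–1850 AD) are treated
  as closed at both ends; a 1341 AD specimen belongs to neither named
  period but does enter the whole-record summary. Specimens failing QC
  are flagged, never silently dropped.

## Uncertainty propagation

`propagate()` draws each `uncertain_input()` independently (Gaussian or
fixed), evaluates the estimator per draw, and reports the Monte-Carlo
mean and SD; `propagate_analytic()` gives the exact affine result
$\sigma = \sqrt{\sum (c_i\,\sigma_i)^2}$ and refuses non-affine
estimators via a second-difference check. Every TP formula above is
affine, so the two routes must agree — the suite checks
$|\sigma_{MC}-\sigma_{exact}| < 3\sigma_{exact}/\sqrt{2(n-1)}$ at
$n = 10^5$ draws.

Diet fractions are physically confined to $[0,1]$; out-of-range draws
are resampled into the interval (default `clip_fractions: true`), the
count of resampled draws is reported, and the resulting mean shift is
visible rather than hidden: a wide fraction such as the Little Ice Age
0.37 ± 0.30 necessarily truncates, which is why Monte-Carlo means are
reported next to the deterministic mass-balance values. Defaults:
100,000 draws, seed recorded in every result. Inputs are treated as
independent (no covariances are available for these data), and published
± values are matched only loosely, since their propagation rule is not
stated.

## The synthetic generator and what it does (not) show

`generate_food_chain()` draws specimens from an idealised chain: Phe
carries the baseline, the Glu–Phe spacing at a level is
$\beta + \sum_{steps} TDF(type)\,\Delta tp$, bulk delta15N rises by
`bulk_step` per level, and independent Gaussian noise (default 0.2 per
mil, the typical analytical precision) is added per measurement.
Fractional steps are allowed. The nine other amino acids get
level-constant offsets (drawn once per configuration) so enrichment code
paths see realistic-shaped data, but carry no truth claims; delta13C
values sit at per-amino-acid offsets from a baseline and can drift
post-1850 (`suess_trend`), letting the Suess adjustment be exercised end
to end against a known answer.

One modelling point deserves emphasis: under this spacing law the
multi-TDF estimator is the *exact* inverse only for chains whose
plankton-type regime spans exactly TP 1 to 2 (which is the multi-TDF
formula's own assumption). For a bird one avian step above a fish at TP
2.4, the estimator is not the generator's inverse — the residual is the
model-mismatch the estimator family inherently carries, not a bug. The
round-trip tests therefore use chains on each estimator's valid domain,
and the misspecification tests quantify the bias off it.

Passing on synthetic chains shows the estimators invert the assumed
propagation model under Gaussian noise; it cannot show that real
collagen obeys that model (tissue-specific fractionation, diet quality
effects and diagenesis are all outside the generator).

## Problem sizes and numerical choices

The packaged analyses are desk-scale: 3 fish and 7 birds, so the full
reproduction (`reproduce_paper()`, including three 100,000-draw
Monte-Carlo runs) completes in about a second. Validation simulations
use 200 specimens per level, at which the standard error of a recovered
level mean, $(\sigma\sqrt{2}/TDF)/\sqrt{n}$, separates the tested biases
from noise at 3 SE. Degenerate inputs are handled by convention rather
than error where a convention is defensible (zero-variance group
comparisons; `sd` absent for n = 1), and by informative errors
otherwise (missing Glu/Phe names the specimen; overlapping periods and
invalid chain configurations list every violation).

## Known limitations and recorded discrepancies

* The published per-specimen multi-TDF TPs of the seabird table were
  evidently computed from unrounded instrument data: recomputation from
  the printed delta15N values differs by up to 0.05. The discrepancy
  report compares at a documented ±0.06 and flags nothing there.
* The published Little Ice Age multi-TDF period mean (3.40) cannot be
  recomputed from the three LIA-dated specimens (3.51 from printed
  inputs; 3.49 even averaging the printed per-specimen TPs); the sample
  membership behind it is unstated. `reproduce_paper()` flags this cell
  and makes no attempt to force agreement.
* Per-amino-acid delta13C enrichment values were published only as
  figures, so no numeric fixture exists for them; the Suess-adjustment
  behaviour is validated on synthetic data instead.
* Enrichment offsets between the packaged groups compare ancient bird
  bone with modern fish bone; they are labelled trophic *enrichment*
  factors and deliberately not discrimination factors.
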