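---
title: "Estimating and scaling marine N2-fixation rates with diazofix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and scaling marine N2-fixation rates with diazofix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diazofix)
library(dplyr)
```

## The measurement problem

Biological N~2~ fixation is measured at sea by spiking an incubation
bottle with ^15^N~2~-enriched seawater and tracking the heavy-isotope
enrichment of particulate nitrogen (PN) over the incubation. The same
mass balance applies at two scales:

* **bulk**: the whole-community rate from the atom% ^15^N of filtered
  PN before and after incubation, and
* **single cell**: the per-cell rate of an individual
  UCYN-A/haptophyte symbiosis, from nanoSIMS ion-count images of one
  region of interest (ROI) and a biovolume-derived cell N quota.

In both cases

$$
\mathrm{NFR} \;=\;
\frac{A_{PN}^{final} - A_{PN}^{t0}}{A_{N_2} - A_{PN}^{t0}}
\cdot \frac{[PN]}{\Delta t},
$$

where $A$ denotes atom% ^15^N, $A_{N_2}$ is the enrichment of the
dissolved-N~2~ source pool after tracer addition, $[PN]$ is the PN
pool (µmol N l^−1^ for bulk, fmol N cell^−1^ for a cell), and
$\Delta t$ the incubation length. `diazofix` implements this chain end
to end, together with the scaling of per-cell rates to volumetric
rates through *nifH* gene-copy abundances, derived hydrochemical
quantities, and a synthetic-survey generator that makes the whole
pipeline testable without any cruise data.

### Assumptions worth stating

* The source pool mixes linearly by volume
  (`mix_source_pool()`), assuming equal dissolved-N~2~ concentration
  per litre of enriched and ambient seawater. No gas-solubility
  correction is applied; the atom% of the enriched seawater is an
  input, as it is measured directly in practice.
* Isotope assimilation is linear over the incubation (no label
  recycling within 24 h).
* Ambient dissolved N~2~ is at natural abundance, 0.3663 atom%
  (configurable; `diazofix_constants()`).

## Detection limits

The rate detection limit (LOD) and minimum quantifiable rate (MQR)
are the rates that would be observed if the final atom% sat `k_lod`
(default 3) or `k_mqr` (default 10) reference-measurement standard
deviations above the t0 atom%. Both scale linearly with the reference
SD and with the PN pool, so N-rich, noisy samples have high limits. A
computed rate below the LOD is reported `BDL` (below detection limit,
rate clamped to zero, signed raw value retained for diagnostics);
between LOD and MQR it is `DNQ` (detected, not quantified). The same
rule, applied to reference (unenriched) cell ROIs, gives the
single-cell detection limit.

With an IRMS reference SD of 5×10^−4^ atom%, a 1 µmol l^−1^ PN pool
and a source pool near 2.4 atom%, the bulk LOD is:

```{r}
nfr_detection_limits(0.3663, 2.3941, 1, 1, sd_a_pn_ref = 5e-4)$lod
```

i.e. a fraction of a nmol N l^−1^ d^−1^, consistent with the
0.2–5.4 nmol N l^−1^ d^−1^ limits typical of field surveys.

## Single cells, quotas and isotope dilution

A symbiosis is measured as two ROIs — symbiont and host — each with
its own biovolume $V$ (µm^3^). Cellular carbon follows the allometric
scaling $\mathrm{pg\,C} = a V^b$ with defaults $a = 0.216$,
$b = 0.939$ (a protist carbon-to-volume relation), converted to
nitrogen with molar C:N $= 106/16$. These constants are a **surrogate
calibration**: the studies this workflow follows cite
biovolume-to-carbon and C:N conversions without printing the
constants, so the defaults were chosen once such that symbiosis N
quotas land in the observed ranges (2.6–27.7 fmol N cell^−1^ for the
UCYN-A1 symbiosis at partner biovolumes of roughly 1–12 µm^3^;
49.3–159.8 fmol N cell^−1^ for the larger UCYN-A2 symbiosis at
22–77 µm^3^). All three constants are exposed in `quota_model()`.

Partner rates are computed independently and summed per association
(`symbiosis_nfr()`); station means use the sample SD over
associations. An association whose partners are both below the
single-cell detection limit enters the station mean as zero by
default (`bdl_policy = "zero"`; `"exclude"` drops it) — the
conservative choice when below-detection cells are plausibly inactive
rather than unmeasured.

Chemical fixation and sample processing dilute the ^15^N label.
With the standard dilution fraction of 0.75, the corrected
("maximum") rate is exactly 4× the measured rate:

```{r}
dilution_correct(c(3.6, 279.9))
```

## Scaling to the community: the contribution engine

qPCR *nifH* abundances are censored against assay limits
(`censor_qpcr()`: ≤LOD is BDL, below LOQ is DNQ), converted to cells
under a copy-number convention (1 copy cell^−1^ for UCYN-A1, 10 for
UCYN-A2 — the high end of the reported polyploidy range, making
UCYN-A2 contributions conservative), and multiplied by the per-cell
rate:

$$
\mathrm{NFR}_{group} = \mathrm{NFR}_{cell} \times
\frac{\mathrm{copies\,l^{-1}}}{\mathrm{copies\,cell^{-1}}} \times
10^{-6}\ \mathrm{nmol\,N\,l^{-1}\,d^{-1}}.
$$

The percent contribution divides by the bulk rate; when the bulk rate
is below detection its LOD stands in for the denominator and the row
is flagged (`bulk_is_lod`). Contributions can legitimately exceed
100%: bulk and single-cell measurements carry independent errors, and
the copy-number convention biases abundances low. DNQ abundances are
excluded by default (`dnq_policy = "loq_half"` imputes LOQ/2
instead). Reported SDs use first-order product/quotient propagation
(relative SDs add in quadrature); the parenthetical errors printed in
survey reports follow conventions that are rarely stated, so the
package reports its own propagated SDs and does not attempt to match
published ones.

The packaged example `sccs_ucyna_survey()` carries the measured
inputs of a Southern California Current System survey, and
`sccs_contributions()` rebuilds the derived columns:

```{r}
sccs_contributions() |>
  select(station, group, volumetric_nfr, contribution_pct,
         max_single_cell_nfr, max_contribution_pct) |>
  mutate(across(where(is.numeric), \(x) round(x, 2)))
```

## Hydrochemistry

* `p_star()` computes the excess-phosphate index
  $P^* = \mathrm{PO_4^{3-}} - (\mathrm{NO_3^-+NO_2^-})/16$; positive
  values mark water with P left over after Redfield drawdown of N,
  conditions conducive to N~2~ fixation.
* `depth_integrate()` integrates a profile trapezoidally, extending
  the shallowest sample as a constant to 0 m (mixed surface layer
  assumption) and, by default, stopping at the deepest sample. A
  per-litre rate in nmol integrates directly to µmol m^−2^.
* `mixed_layer_depth()` uses the conventional density threshold
  Δσ~θ~ = 0.125 kg m^−3^ against the shallowest sample (ΔT = 0.2 °C
  selectable), interpolating linearly between the bracketing samples;
  an unstratified profile returns the deepest depth, flagged.
* `redfield_c_equivalent()` converts areal N supply to supported C
  production (×106/16).
* Values below analyte detection keep their raw value plus a `BDL`
  flag; nothing is silently zeroed.

## The association screen

Field surveys relate abundances, rates and environmental variables
with Spearman's rank correlation and compare seasons with the
Mann–Whitney U test. Both are implemented on mid-ranks (average ranks
for ties). For small samples (n ≤ 8 pairs for ρ, pooled n ≤ 12 for U)
the two-sided p-value is computed from the exhaustive permutation
null — exact by construction — and otherwise from the t (ρ) or
tie-corrected normal (U) approximation. The test suite checks both
statistics against brute-force enumeration oracles and against
`stats::cor.test()` / `stats::wilcox.test()`.

```{r}
spearman_screen(1:4, c(2, 1, 4, 3))
```

## The synthetic survey generator

`survey_design()` + `generate_survey()` emit the four input tables
(`hydro`, `incubations`, `nanosims_rois`, `qpcr`) plus a `truth`
table. The defaults are fixed at survey-like magnitudes and are not
tuning knobs:

| feature | default | emulates |
|---|---|---|
| surface bulk rate | 8.5 nmol N l^−1^ d^−1^, e-folding 40 m | observed surface means, euphotic decay |
| single-cell rates | 6.6 / 151.1 fmol N cell^−1^ d^−1^ | UCYN-A1 / UCYN-A2 group means |
| abundances | lognormal, ~10^5^–10^6^ copies l^−1^, e-folding 15 m | surface-concentrated populations; deep samples approach assay limits (~10–30% BDL/DNQ) |
| abundance correlation | Spearman ρ = 0.71 via Gaussian copula | co-occurrence of the two sublineages |
| IRMS noise | SD 5×10^−4^ atom% | replicate reference filters |
| nanoSIMS noise | binomial at 10^5^ ions per ROI | ion-counting statistics |
| qPCR noise | 10% CV, LOD 28 / LOQ 225 copies l^−1^ | assay precision and limits |
| tracer addition | 0.1 l into 1.1 l, 2–24.7 atom% enriched water | the incubation protocol |

The copula uses the normal-score relation $r = 2\sin(\pi\rho_s/6)$ to
hit the target rank correlation; at n = 500 the sample ρ lands within
±0.05 of the target. Incubation atom% values are produced by
*forward-running* the same mass balance the estimator inverts — so a
noiseless design round-trips exactly, and recovery tests measure only
the effect of injected noise. Each output table draws from its own
RNG substream split off the master seed, so adding a table never
perturbs the others.

What the generator does **not** emulate: advection and patchiness,
gas-equilibration kinetics of the tracer, qPCR inhibition or
extraction efficiency, ROI segmentation error, and host/symbiont
rate partitioning beyond quota proportionality. Passing recovery
tests therefore demonstrate correctness of the estimators under the
stated noise model, not field accuracy.

## Numerical and design choices

* Atom% is carried in percent everywhere (never as a fraction); rates
  in nmol N l^−1^ d^−1^ (bulk/volumetric) and fmol N cell^−1^ d^−1^
  (per cell).
* Negative enrichment is clamped to a zero rate with status BDL; the
  signed raw rate is kept in `rate_raw`.
* Boundary censoring: a value equal to the LOD is BDL; equal to the
  LOQ is quantified.
* `depth_integrate()` refuses single-depth profiles and extrapolation
  beyond the deepest sample unless explicitly enabled.
* Permutation p-values use a 10^−12^ slack when comparing statistics,
  so ties at the observed value count as at-least-as-extreme.
* Pipeline outputs carry a configuration hash per row; identical
  inputs and config give byte-identical outputs.

Problem sizes in the test suite are deliberately modest — recovery
runs use 200 replicate one-station surveys with two depths, six
associations and five reference ROIs per group — chosen as the
smallest sizes at which the Monte-Carlo medians are stable.

## Known limitations

* The quota constants are surrogate values calibrated to published
  quota ranges, not measured conversions; per-study constants should
  be supplied via `quota_model()` when available.
* The UCYN-A2 qPCR assay cross-reacts with the rarer UCYN-A3/A4
  sublineages; abundances scaled with it inherit that ambiguity.
* Contributions computed against a bulk LOD are lower bounds relative
  to a detectable rate, not point estimates.
* The exact formula variant behind published rate LOD/MQRs differs
  between groups; the k·SD substitution rule used here reproduces the
  conventional magnitudes but is one of several defensible choices.
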