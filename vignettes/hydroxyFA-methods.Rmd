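---
title: "Models and methods behind hydroxyFA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hydroxyFA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroxyFA)
```

## The scientific problem

Gram-negative bacteria keep their membranes fluid under changing
temperature and pH by re-balancing the branching pattern of their fatty
acids (homeoviscous adaptation). The 3-hydroxy fatty acids (3-OH FAs,
C10–C18) anchored in lipid A come in three branching classes — *normal*
(straight chain), *iso* (methyl on the penultimate carbon) and *anteiso*
(methyl on the antepenultimate carbon) — and because *anteiso* chains have
the lowest melting point, their share rises as growth temperature falls.
Ratios of these classes have therefore been proposed as soil temperature
and pH (paleo)proxies:

$$\mathrm{RIAN} = -\log_{10}\frac{I + A}{N}, \qquad
  \mathrm{RAN}_{15} = \frac{ai\text{-}C_{15}}{n\text{-}C_{15}}, \qquad
  \mathrm{RAN}_{17} = \frac{ai\text{-}C_{17}}{n\text{-}C_{17}},$$

where $I$, $A$ and $N$ are the summed relative abundances of all *iso*,
*anteiso* and *normal* 3-OH FAs in the C10–C18 range. hydroxyFA implements
the full chain from GC-MS peak areas to these indices and their trend
statistics, together with packaged reference tables from triplicate culture
experiments on three soil *Bacteroidetes* strains (strain A ≈
*Flavobacterium pectinovorum*, strains B/C ≈ *Pedobacter* spp.) grown at
5–25 °C and pH 5–8.

## Compositional model

Measurements live on a stated normalization basis and the two bases are
never mixed: non-hydroxy tables are percent of **total FAs**, index
arithmetic runs on percent of **total 3-OH FAs**. `normalize_profile()`
closes detected peak areas to exactly 100 %; the operation is idempotent
and invariant to rescaling all areas, and since every index is a ratio, the
closure constant cancels — indices computed from raw areas equal those from
the closed composition (`test-indices.R` asserts this).

"n.d." (not detected) is stored as *missing*, never as zero by fiat. In
class totals an undetected homologue contributes 0 (the sum runs over what
was seen); in ratio denominators it leaves the index **undefined**, which
reproduces how reference tables print "n.d." for RAN~15~ when *n*-C~15~ is
absent (strain B at every condition). The detection floor uses a
strict-less rule: a value exactly at the floor stays detected.

The logarithm in RIAN is base 10. The choice is validated, not assumed:
with the printed strain-A 5 °C class totals,
$-\log_{10}((80.69+8.55)/10.77) = -0.92$ reproduces the printed index
exactly, while a natural log gives −2.11.

## Mean-of-ratios versus ratio-of-means

Printed index rows are means of per-replicate indices (hence their ± sd).
`index_table()` defaults to this `per_replicate` mode and offers
`ratio_of_means` (indices of the aggregated mean composition) for
table-level checks. The two agree exactly in the zero-noise limit and
within one printed sd on the reference tables, but not to printed
precision everywhere: for convex ratios Jensen's inequality makes the mean
of ratios exceed the ratio of means. The largest instance in the packaged
tables is strain C at 5 °C, where anteiso/normal is printed 22.46 (mean of
replicate ratios) while the printed class totals give 72.00/3.28 = 21.95.
The acceptance tests therefore assert RIAN and iso/anteiso to two decimals
and anteiso/normal within one printed sd.

Near-zero denominators are flagged rather than hidden: a normal homologue
below 0.1 % (e.g. *n*-C~17~ = 0.07 ± 0.06 in strain A at 5 °C) makes
RAN~17~ numerically unstable, and `index_set()` marks such values with
`ran17_small_denom`.

## Semi-quantification

Amounts are single-point estimates against a deuterated injection standard
(0.5 mg/mL, 3 µL per 100 µL of sample, i.e. 1.5 µg injected):
`amount = 1.5 µg × area / standard_area`. No per-compound response factors
are described for this kind of assay, so the factor defaults to 1 and is
exposed as an optional multiplier. The deuterated fragment (m/z 178 vs 175)
is metadata; no spectra are modelled.

## Trend statistics

Regressions are ordinary least squares on *replicate-level* points (5
temperatures × 3 replicates = 15 points), not on level means. The printed
p-values force this reading: a p of 6.8 × 10⁻¹³ is unreachable with n = 5.
The slope test is two-sided on n − 2 df with significance at 0.05
throughout; no multiple-testing correction is applied across responses
(matching the source analyses). Spearman correlations use average ranks and
the t approximation for p. ANOVA with Tukey HSD post-hoc (studentized
range, pooled variance) compares condition levels; all-zero within-group
variance is flagged degenerate instead of producing an infinite F.
Undefined replicate index values are dropped pairwise with the contributing
n reported, and a response missing in more than half the replicates is
skipped with a warning.

`invert_calibration()` does inverse prediction
$\hat{x} = (y_0 - b_0)/b_1$ with a first-order (delta-method) interval
propagating the coefficient covariance, and *refuses* a fit that is not
significant at the chosen level: a slope indistinguishable from zero has no
usable inverse.

## The synthetic generator: what it emulates and what it does not

`generate_series()` draws, for each condition level $L$ and replicate,

$$\text{composition} = \mathrm{closure}\!\left(\exp\big(\log b + s\,(L -
L_\mathrm{ref}) + o + \varepsilon\big)\right), \qquad
\varepsilon \sim N(0, \sigma^2),$$

with baseline $b$, per-class slopes $s$ (plus optional per-homologue
deviations), constant offsets $o$, and iid Gaussian noise in log space.
Log-space noise keeps parts positive and mimics multiplicative measurement
error; re-closure makes only slope *differences* between classes
identifiable, which is exactly what the class-ratio regressions estimate.
Defaults encode the stated experimental world: 5 temperature levels
(5–25 °C), 3 replicates, `noise_sd = 0.05` (≈ 5 % relative scatter, the
magnitude of the printed ± values, which run ≈ 2–10 %), detection floor
0.02 % (just below the smallest printed abundance, 0.03 %). Noise is drawn
per homologue; the printed sds cannot distinguish per-homologue from
per-class error, so the finer-grained choice is the default.

Presets `strainA`–`strainC` anchor the baseline at the 25 °C column of the
corresponding reference table and fit per-homologue log-linear slopes to
the printed level means (homologues undetected at 25 °C are omitted). A
green preset test establishes that the generator reproduces each strain's
*qualitative* adaptation — anteiso/normal falling and iso/anteiso rising
with temperature, significantly, and level means tracking the printed
means on the log scale (r > 0.95). It does **not** establish cell-level
quantitative agreement: the model is log-linear in the condition, while
several real homologue trajectories are non-monotone (strain A *i*-C~15~
runs 46 → 56 → 49 % across 5–25 °C) and some printed sds are as small as
0.006, so a moment-matching criterion at 2 sd/√3 per cell is not attainable
under this model class (measured ≈ 60 % of cells). Capturing curvature
would require a quadratic or mechanistic membrane model, which is out of
scope; trends here are phenomenological.

`recover_parameters()` closes the loop: regressing log class ratios on the
condition recovers injected slope differences exactly at zero noise, with
~95 % CI coverage at the default noise (500-seed check in the acceptance
suite), and with ~5 % false-positive rate under null slopes.

## Numerical and design choices

* Closure tolerance on stated relative abundances is 0.5 percentage points
  (printed cells are rounded to 2 decimals); re-closing a printed column
  reproduces 100 within 0.01–0.5.
* Replicate aggregation uses the sample sd (n − 1), consistent with
  triplicate "mean ± sd" magnitudes; a single replicate reports sd = NA.
* The C10–C18 scope filter is applied unconditionally to class totals and
  indices, even though no packaged homologue falls outside it.
* The descriptor universe is open (C2–C40) so non-hydroxy profiles parse
  freely; only 3-OH compounds in scope enter index arithmetic.
* Fixture CSVs keep the printed numbers verbatim (wide mean/sd layout, one
  file per table and condition block) and are md5-verified at load time.
  The non-hydroxy tables report "% vs. total FAs" with totals below 100 —
  the denominator evidently includes the 3-OH FAs; the packaged numbers are
  kept as printed and no re-closure is attempted for those tables.
* The pipeline is a pure function of (input, config, seed); re-running
  yields byte-identical CSVs.

## Known limitations

* Raw replicate-level culture data were never published; regression
  criteria run on stochastic surrogates drawn from printed mean ± sd cells,
  so printed R²/p values are targets in distribution, not exactly.
* The generator cannot produce non-monotone homologue trajectories or
  replicate correlation structure induced by closure (homologue draws are
  independent before re-closing).
* No global soil calibration transfer functions (random-forest MAAT/pH
  models) and no chromatogram processing: inputs begin at peak areas.
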