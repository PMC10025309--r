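# hydroxyFA

Analysis of bacterial **3-hydroxy fatty acid (3-OH FA)** distributions and
the branching-ratio indices proposed as soil temperature and pH
(paleo)proxies.

Gram-negative bacteria adjust the branching of their membrane lipids —
including the 3-OH FAs of lipopolysaccharide lipid A — to growth conditions
(homeoviscous adaptation): *anteiso* chains melt lowest, so their share
rises as temperature falls. With `I`, `A`, `N` the summed *iso*, *anteiso*
and *normal* 3-OH FAs in the C10–C18 range, the package computes

```
RIAN  = -log10((I + A) / N)
RAN15 = anteiso-C15 / normal-C15
RAN17 = anteiso-C17 / normal-C17
```

plus class totals and branching ratios, per replicate and aggregated.

For whom: lipid biogeochemists and microbiologists working with GC-MS
fatty-acid tables from culture experiments or environmental samples, who
need reproducible index bookkeeping and the accompanying statistics.

What's inside:

* a parser for the common FA naming dialects (`"iso C_15"`, `"ai-C17"`,
  `"16:1"`, `"3-OH ai-C17"`, …) and a strict compositional data model with
  two normalization bases (% of total FAs vs % of total 3-OH FAs);
* semi-quantification against a deuterated injection standard and a
  detection floor that turns trace peaks into "n.d." (stored as missing,
  never zero);
* replicate-level trend statistics: OLS regressions, Spearman
  correlations, one-way ANOVA + Tukey HSD, and inverse calibration with
  delta-method intervals;
* a synthetic culture-series generator (log-linear compositional model with
  injected class slopes) for end-to-end validation, with presets matched to
  the packaged reference strains;
* transcribed reference tables from triplicate cultures of three soil
  *Bacteroidetes* strains grown at 5–25 °C and pH 5–8 (md5-verified
  fixtures);
* a CLI (`indices`, `trends`, `simulate`, `recover`, `run`).

## Worked example

```r
library(hydroxyFA)

# Printed reference column: strain A (Flavobacterium pectinovorum-like),
# grown at 5 C and pH 8; 3-OH FA composition as % of total 3-OH FAs.
fx   <- load_fixture("table4")
col5 <- fixture_aggregate(fx, "temperature_C", 5)
class_totals(col5)
#>     iso anteiso  normal
#>   80.69    8.55   10.77
round(rian(col5), 2)
#> [1] -0.92
round(branching_ratios(col5), 2)
#>    iso_over_anteiso     iso_over_normal anteiso_over_normal
#>                9.44                7.49                0.79

# Synthetic culture series matched to that strain, then trend recovery.
spec   <- sim_preset("strainA", noise_sd = 0.05)
series <- generate_series(spec, seed = 42)
tr <- trend_report(series)
subset(tr, response %in% c("RIAN", "RAN15", "anteiso_over_normal"))
#>               response   slope intercept r_squared  p_value  n significant
#> 15                RIAN  0.0201    -1.006     0.969 3.60e-11 15        TRUE
#> 16               RAN15 -0.2214     6.329     0.942 2.05e-09 15        TRUE
#> 20 anteiso_over_normal -0.0327     0.862     0.913 2.81e-08 15        TRUE

# Inverse calibration: which growth temperature yields RAN15 = 3.0?
x   <- vapply(series$profiles, function(p) p$condition_value, numeric(1))
y   <- vapply(series$profiles, ran15, numeric(1))
fit <- fit_linear_trend(x, y, response_id = "RAN15")
inv <- invert_calibration(fit, y0 = 3.0)
#> temperature for RAN15 = 3.0: 15.0 C (95% CI 14.0-16.1)
```

Reading the numbers: the iso homologues dominate this strain (I = 80.7 %),
giving a strongly negative RIAN; the anteiso/normal ratio (0.79 at 5 °C)
falls steeply and significantly with temperature (slope −0.033/°C,
R² = 0.91 on the synthetic series), the adaptation signal the RAN proxies
exploit. The inversion recovers 15 °C for an index value on the fitted
line, with a ±1 °C interval at this noise level.

## Command line

```sh
Rscript inst/cli/hydroxyfa.R simulate --preset strainA --seed 42 --out sim.csv
Rscript inst/cli/hydroxyfa.R indices  --input sim.csv --out indices.csv
Rscript inst/cli/hydroxyfa.R trends   --input sim.csv --out trends.csv
Rscript inst/cli/hydroxyfa.R run      --input sim.csv --out-dir results/
```

(After installation the script lives at
`system.file("cli", "hydroxyfa.R", package = "hydroxyFA")`.)

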