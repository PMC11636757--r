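# gwquality

Seasonal groundwater quality assessment for drinking-water well
networks: hydrochemical facies and source diagnostics, an
entropy-weighted water quality index, USEPA-style non-carcinogenic
nitrate health risk, and inverse-distance-weighted maps — plus a
synthetic-data generator so the entire pipeline runs end to end with
no external data.

The package is aimed at hydrogeologists and environmental-health
analysts who have per-well major-ion chemistry for one or more seasons
(pH, EC, TDS, TH, BOD, COD, Ca²⁺, Mg²⁺, Na⁺, K⁺, HCO₃⁻, Cl⁻, SO₄²⁻,
NO₃⁻) and want reproducible, scriptable answers to three questions:
what kind of water is this and where do its solutes come from, is it
suitable for drinking, and what nitrate risk does it pose to adults,
children and infants.

## Methods at a glance

**Entropy-weighted water quality index (EWQI).** For a sample ×
parameter matrix `X`, columns are min–max normalised
(`y_ij = (x_ij − min_j)/(max_j − min_j)`), each parameter's Shannon
entropy is computed from the column proportions
`P_ij = y_ij / Σ_i y_ij` as `e_j = −(1/ln m) Σ_i P_ij ln P_ij`, and
its weight is the normalised information content
`ω_j = (1 − e_j) / Σ_j (1 − e_j)`. Measured values are rated against
drinking-water standards, `q_j = 100 C_j / S_j` (pH against its
6.5–8.5 band around neutrality), and the index is
`EWQI_i = Σ_j ω_j q_ij`, classified into ranks I–V at 25/50/100/150
(left-closed). `ewqi()` returns a classed fit with `print`, `summary`,
`coef` (the weights), `predict`, `plot` and `fitted` methods.

**Nitrate health risk.** Chronic daily intake
`CDI = C_w · IRW · EF · ED / (BW · AT) = C_w · k`, hazard quotient
`HQ = CDI / RfD` with RfD = 1.6 mg/kg/day for nitrate, and hazard
index `HI = Σ HQ`, banded as negligible (< 0.1), low ([0.1, 1)),
medium ([1, 4)) and high (≥ 4). Because HI is linear in `C_w`, a known
HI at a known concentration calibrates a receptor's effective
ingestion rate `k` (`calibrate_effective_rate()`), which then predicts
HI at any other concentration.

**Facies and source diagnostics.** Chadha-rectangle coordinates
(milliequivalent-percentage differences of alkaline earths vs alkalis
and weak- vs strong-acid anions) with quadrant water types, TDS–TH
water classes, the standard molar-ratio panel (Na/Cl, Ca/HCO₃,
Na-normalised ratios, the (Ca+Mg)/(HCO₃+SO₄) equivalent ratio) with
deterministic source labels, and per-season NO₃–Cl / NO₃–TDS Pearson
correlations.

**Spatial.** Exact-at-data inverse-distance-weighted interpolation
(power 2 by default, all neighbours), rasterisation to ESRI ASCII
grids, and left-closed raster classification.

**Synthetic generator.** `generate_groundwater()` draws a 27-well,
two-season network from Beta marginals matched to published
min/max/mean summaries, with a Gaussian copula carrying the NO₃–Cl
and NO₃–TDS correlations and named-well role constraints (seven
nitrate-exceeding wells per season, three hardness-exceeding wells in
the wet season, one soft well in the dry season).

## Worked example

```r
library(gwquality)

d <- generate_groundwater(seed = 1)          # 27 wells x 2 seasons
wet8 <- d[d$season == "wet" &
            d$well_id %in% generator_config()$ewqi_subset, ]
fit <- ewqi(wet8)                             # six-parameter EWQI
print(fit)
#> Entropy-weighted water quality index (8 samples, 6 parameters)
#> Weights:
#>     pH     TH    BOD    COD     Ca    NO3
#> 0.1415 0.2848 0.1589 0.1401 0.1997 0.0750
#> Scores:
#>   well   EWQI rank    class
#>  Ka-15  63.83  III moderate
#>  Sa-10 101.14   IV     poor
#>  ...
```

The weights say that, in this wet-season run, total hardness and
calcium vary most informatively across the eight wells and therefore
carry the largest weight; the scores place most wells in rank III
(moderate, marginally drinkable) with one rank-IV (poor) well.

```r
pr <- default_profiles()$infants
h <- hazard(d$NO3[d$season == "wet"], pr,
            well_id = d$well_id[d$season == "wet"], season = "wet")
head(h[order(-h$HI), ], 3)
#>  well_id season   group      CDI       HQ       HI category
#>    Ka-15    wet infants 2.965916 1.853698 1.853698   medium
#>    Sa-10    wet infants 2.891426 1.807141 1.807141   medium
#>    Na-16    wet infants 2.833602 1.771001 1.771001   medium
```

Infants at the highest-nitrate wells ingest about 2.9–3.0 mg of
nitrate per kg body weight per day — 1.8 times the reference dose,
a "medium" non-carcinogenic risk.

`run_pipeline(out_dir, seed = 1)` executes every stage (screening,
facies, EWQI per season, risk for all three receptor groups, IDW
rasters of NO₃/EWQI/HI) and writes CSV/JSON artifacts plus a markdown
report. A thin command-line front end with the same stages as
subcommands ships in `inst/cli/gwquality.R`.

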