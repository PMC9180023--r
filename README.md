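# equipanel

Quantifying the equity of health-resource allocation across the regions of
a tiered healthcare system.

Health planners tracking a three-tier rural network — county-level medical
and health institutions (CMHIs), township hospitals (THs) and village
clinics (VCs) — need to know not just how many institutions, beds and
personnel exist, but how fairly they are spread over provinces relative to
where people live (the *population calibre*) and over the land they must
cover (the *geography calibre*). `equipanel` turns a balanced
province-by-year panel of resource counts into the standard battery of
equity indices and trend tests used in health-resource studies:

- **Gini coefficient** on grouped data. Regions are sorted ascending by
  resource density `e_i / m_i` and the trapezoid rule is applied to the
  Lorenz curve:
  `G = 1 − Σ_i (X_i − X_{i−1})(Y_i + Y_{i−1})`,
  with `X` cumulative measure shares and `Y` cumulative resource shares.
  Fairness bands: `[0, 0.3)` optimal, `[0.3, 0.4)` normal, `[0.4, 0.5)`
  gap, `[0.5, 0.6)` alert, `[0.6, 1)` danger.
- **Health resource density index**:
  `HRDI = HR / √(A · P)` — resources per geometric mean of area and
  population, balancing per-capita against per-area density.
- **Theil index** (measure-weighted mean log deviation)
  `T = Σ_i (m_i/M) ln((m_i/M)/(e_i/E))`, decomposed exactly into a
  between-zone part (the index of the zone totals) and a within-zone part
  (the weighted sum of zone-internal indices), `T = T_inter + T_intra`,
  with contribution rates `T_intra/T` and `T_inter/T`.
- **Mann–Kendall trend test** with tie-corrected variance and continuity
  correction: `S = Σ_{i<j} sgn(x_j − x_i)`,
  `Var(S) = [n(n−1)(2n+5) − Σ_t f_t(f_t−1)(2f_t+5)]/18`,
  `Z = (S ∓ 1)/√Var(S)`, stars at α = 0.01 / 0.05 / 0.1.

A synthetic panel generator with realistic zone structure makes the whole
pipeline testable end to end without any external data.

## Worked example

```r
library(equipanel)

pan <- generate_panel(generator_config(), seed = 42)  # 31 provinces x 18 years
al  <- slice_allocation(pan, 2020, "cmhi", "bed", "population")

gini(al)
#>    year tier  kind  calibre     gini band
#> 1  2020 cmhi  bed   population 0.187 optimal

theil_decompose(al)
#> <theil_decomposition> T_total = 0.059711 (inter 0.034368 + intra 0.025343)
#>   within-zone contribution: 42.44%

h <- hrdi_table(pan, 2020, "zone")
h[h$tier == "cmhi" & h$kind == "bed", ]
#>   scope   level tier  kind   year  hrdi
#> 1 eastern zone  cmhi  bed    2020 2.84
#> 2 central zone  cmhi  bed    2020 0.968
#> 3 western zone  cmhi  bed    2020 0.380

mk_test(gini_series(pan, "cmhi", "bed", "population")$gini)
#>       n     S var_s     Z     p direction  stars
#> 1    18     1   697     0     1 increasing ""
```

The 2020 bed allocation of county-level institutions is population-fair
(G = 0.187, "optimal" band); inequity is split between the zones
(T_inter) and within them (T_intra); the eastern zone is about seven
times denser in beds than the western; and the 18-year Gini series shows
no significant trend under these null generator settings (no stars).

Run everything at once and write the report bundle (all index series,
the within-zone contribution table, and the three trend tables as CSV
plus a JSON manifest):

```r
bundle <- run_analysis(pan)
write_bundle(bundle, "out/")
```

A thin command-line wrapper is installed as `exec/equipanel`:

```sh
Rscript exec/equipanel simulate --out panel.csv --seed 3
Rscript exec/equipanel run --panel panel.csv --out out/ --calibre both
Rscript exec/equipanel mk --series some_series.csv --column value
```

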