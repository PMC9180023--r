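---
title: "Measuring equity of tiered health-resource allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring equity of tiered health-resource allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equipanel)
```

## The setting

A tiered rural healthcare network allocates three kinds of resources —
institutions, beds, personnel — across three facility tiers: county-level
medical and health institutions (`cmhi`), township hospitals (`th`) and
village clinics (`vc`). Village clinics carry no beds, so eight
tier-by-kind combinations exist. The analysis unit is a *balanced panel*:
every province observed in every year, with its population, land area and
the eight resource counts. Provinces belong to economic macro-zones
(default scheme: eastern / central / western), and the zone column is an
ordinary input, not hard-coded, so any grouping scheme works.

Equity is always judged against a *calibre* — the weighting base the
resource shares are compared with. The population calibre asks whether
resources follow people; the geography calibre asks whether they cover
territory. All indices below are share-based and therefore unit-free;
units enter only the density index, which has configurable display units.

## The indices

**Gini.** Regions are sorted ascending by resource density $e_i/m_i$
(ties broken by region id, for determinism), cumulative measure shares
$X_i$ and resource shares $Y_i$ are formed, the origin $(0,0)$ is
prepended, and the trapezoid rule gives

$$G = 1 - \sum_{i=1}^n (X_i - X_{i-1})(Y_i + Y_{i-1}).$$

This equals the measure-weighted relative mean absolute difference of
densities, which the test suite verifies as an independent oracle on
random instances. Sorting by the *active calibre's* density is a genuine
choice (the construction is sometimes left implicit in applied work):
it is the standard Lorenz ordering and the only one that guarantees
$G \ge 0$ for both calibres. Zero-resource regions are legal (density 0,
sorted first); an allocation with *no* resources at all is an error, not
$G = 0$. The fairness bands are half-open, $[0,0.3)$ optimal through
$[0.6,1)$ danger, so boundary values such as $G = 0.3$ map to exactly one
band (the conventional ranges overlap at their endpoints).

**HRDI.** The health resource density index is implemented as the
geometric-mean density

$$\mathrm{HRDI} = \frac{HR}{\sqrt{(A/a_0)\,(P/p_0)}},$$

with display units defaulting to $p_0 = 10^3$ persons and $a_0 = 1\,
\mathrm{km}^2$. This is the standard form that balances per-capita
against per-area density — an index proportional to the geometric mean of
$HR/P$ and $HR/A$. Zone and national values apply the formula to the
*summed* totals, never to the mean of member indices (the two differ, and
a counterexample test pins this down).

**Theil.** The measure-weighted mean log deviation (natural log)

$$T = \sum_i \frac{m_i}{M}\,\ln\!\frac{m_i/M}{e_i/E}
   = T_{\mathrm{inter}} + T_{\mathrm{intra}},$$

where $T_{\mathrm{inter}}$ is the same index on the zone totals and
$T_{\mathrm{intra}} = \sum_g (M_g/M)\, T_g$ weights the zone-internal
indices. The decomposition is exact and conservation is asserted to
1e-10 on a thousand random instances. Contribution rates are the
ratios $T_{\mathrm{intra}}/T$ and $T_{\mathrm{inter}}/T$; ratios of
Theils are invariant to the logarithm base, so the contribution table
would be identical under log10. Two conventions deserve note:

- A region with zero resources makes $T$ diverge. It raises an error
  naming the region — never a silent drop or an epsilon patch, because
  exclusion changes every share. `drop_zero_resources()` is the explicit,
  logged filter for users who want the sub-panel.
- When $T \approx 0$ (proportional allocation, threshold 1e-12) there is
  no inequity to apportion; the within-zone contribution is reported as
  100% and the between-zone as 0%, so a perfectly fair panel produces an
  all-100.00 contribution table rather than 0/0.

The mean-log-deviation form is unbounded above (its maximum is
$\ln(M/m_{\min})$), so the package asserts only $T \ge 0$ and makes no
claim that $T \le 1$. Theil reporting defaults to the population calibre,
which the dispersion indices track most directly; the geography-calibre
decomposition is available via an argument.

**Mann–Kendall.** For an annual index series $x_1, \dots, x_n$,

$$S = \sum_{i<j} \mathrm{sgn}(x_j - x_i), \qquad
\mathrm{Var}(S) = \tfrac{1}{18}\Big[n(n-1)(2n+5) -
  \sum_t f_t (f_t - 1)(2 f_t + 5)\Big],$$

with $f_t$ the tie-group sizes, and the continuity-corrected score
$Z = (S-1)/\sqrt{\mathrm{Var}}$ for $S > 0$, $0$ for $S = 0$,
$(S+1)/\sqrt{\mathrm{Var}}$ for $S < 0$. The orientation
$\mathrm{sgn}(x_j - x_i)$ is chosen so a rising series gives $S > 0$ —
some typeset presentations of the statistic print the opposite sign
order while still describing positive $Z$ as increasing; the behaviour
here follows the description. Significance stars use the two-sided
normal p-value at the $\alpha = 0.01/0.05/0.1$ ladder; a one-sided
option exists behind the `alternative` argument. The tie correction is
always applied in full (ties are near-impossible in real-valued index
series but free to handle). A strictly monotone 18-point series attains
the ceiling $Z = 152/\sqrt{697} \approx 5.757$; this identity is a
useful sanity check for any 18-year analysis, and `exact_null()`
provides the exact permutation distribution of $S$ (via the
inversion-number convolution, independent of `mk_s()`) as the small-$n$
oracle for the normal approximation. Sen's slope, seasonal variants and
prewhitening are deliberately out of scope.

**Growth rates.** "Average growth rate" of an annual series is
implemented as the compound (geometric) rate
$(v_T/v_0)^{1/(T-t_0)} - 1$; the arithmetic mean of yearly relative
changes is the other defensible reading and is available via
`growth_mean = "arithmetic"`.

## The synthetic generator

`generator_config()` emulates a provincial yearbook panel: 31 provinces
(11 eastern, 8 central, 12 western), years 2003–2020, lognormal
populations and areas, and lognormal resource densities

$$e_{it} = \mathrm{round}\big(\beta\,
  e^{\,\delta_{z(i)} + z_i \sigma(t) + \varepsilon_{it} + \tau (t - t_0)}
  \, P_i\big),$$

with a per-tier-kind base density $\beta$, zone offsets $\delta_z$
(defaults $+0.3 / 0 / -0.3$), a *persistent* province effect
$z_i \sim N(0,1)$ scaled by
$\sigma(t) = \sigma_w + \text{drift}\cdot(t-t_0)$ (default
$\sigma_w = 0.3$, drift 0), iid year noise $\varepsilon_{it}$ (default sd
0.05) and optional per-year drift $\tau$. Counts are rounded with a
floor of 1 (yearbook semantics); `continuous = TRUE` disables rounding
for exactness tests. Base densities are order-of-magnitude realistic for
provincial health systems (e.g. about 2 beds and 3 health workers per
thousand residents at the county tier, one village clinic per couple of
thousand residents).

Two structural defaults are worth explaining:

- *Zone-specific population/area locations* (eastern provinces denser
  and smaller, western sparser and larger) mirror the real east–west
  geography that the density index is designed to expose. With these
  shifts the zone-HRDI ordering eastern > central > western is implied
  by construction through the gap between the zone offsets and the
  sampling noise of the zone totals, and holds in well over 95% of
  seeds.
- *Year-level iid noise on top of the persistent province effect* makes
  a no-trend panel's index series exchangeable across years, which is
  exactly the null the Mann–Kendall test assumes. Without it, the index
  series of a no-drift panel would be constant and the null rejection
  rate degenerate; with it, the type-I error at $\alpha = 0.05$
  calibrates to $0.05 \pm 0.02$ (checked over 1000 seeds).

The generator does **not** emulate: spatial autocorrelation between
neighbouring provinces, administrative re-zoning, reporting breaks, the
merger dynamics that shrink village-clinic counts, or calibration to
real Chinese provincial magnitudes. Passing tests therefore demonstrate
the correctness and calibration of the *method*, not conclusions about
any real country's system.

`inject_trend()` deterministically reshapes a panel so a chosen index
trends in a chosen direction: for Gini/Theil it widens (or narrows) each
year's cross-section of log densities about its mean by a factor growing
linearly in time; for HRDI it drifts all counts by
$e^{\pm\,\text{strength}\,(t-t_0)}$. A deterministic transform of the
input panel was preferred over re-drawing from a config because it keeps
the operation a pure function of the panel and works on panels the
generator did not produce. Sign recovery of the induced trend is ≥ 95%
over seeds at the default strength (0.05/year).

## Numerical and design choices

- Canonical region order is lexicographic region id (C locale); every
  cumulative sum is taken in that order, so results are bit-reproducible
  regardless of input row order.
- Ties in the Lorenz sort are broken by region id; the origin (0,0) is
  always prepended so the first trapezoid term is well defined.
- Balanced panels are *required*; missing (region, year) cells are a
  validation error, never imputed, because imputation would silently
  change every index.
- `run_analysis()` is a pure function of (panel, arguments);
  `write_bundle()` output is byte-stable, and the manifest records md5
  hashes so identical runs are verifiable.
- Degenerate inputs: all-zero allocations error (`gini`, `lorenz_curve`);
  zero-resource regions error in Theil (see above); `Var(S) = 0` with
  $S \neq 0$ — impossible for genuine series — is guarded as corrupt
  input.

## Problem sizes in the test suite

Property tests run on random allocations up to $n = 50$ regions (1000
instances for the Gini oracle and Theil conservation), the exact
Mann–Kendall null up to $n = 8$ against brute permutation enumeration up
to $n = 5$, null calibration over 1000 generated panels and trend-sign
recovery over 200 — sizes at which the sampling error of the checked
frequencies is a few times smaller than the asserted margins.

## Known limitations

- The geography-calibre Gini sorts by per-area density (the active
  calibre's measure). Applied studies rarely state their sorting
  convention; comparisons with published coefficients computed under
  another ordering can differ.
- Absolute Theil values depend on the logarithm base (natural log here);
  only contribution rates are base-free.
- The HRDI's numeric scale depends on the chosen display units; only
  orderings and trends are comparable across studies unless units match.
- Population is treated as an opaque positive measure; whether it is
  registered or resident population is the user's modelling decision.
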