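---
title: "Simulating cotton fibre quality fruit by fruit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cotton fibre quality fruit by fruit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cottonfq)
```

## Why per-fruit simulation

A cotton plant carries tens of fruits of different ages. Fibre length (mm),
strength (cN tex⁻¹) and micronaire develop inside each boll over several
weeks, and because the fruits at different positions experience different
temperature windows, plant-level fibre quality is a mixture of very different
per-fruit outcomes — late, high-position bolls mature into the autumn cold
and end up with markedly poorer fibre. `cottonfq` therefore simulates the
plant one phytomer and one fruit at a time, on a daily timestep, and lets
management questions (when to sow, when to top, whether to mulch) be asked as
questions about the fruit population.

## Physiological time

All development is clocked in *physiological days*. A calendar day with mean
temperature $T$ contributes

$$E(T) = \frac{T - T_b}{T_o - T_b}, \qquad \text{clamped to } [0, 1],$$

with base temperature $T_b = 12$ °C and optimum $T_o = 25$ °C by default
(`thermal_params()`). The daily mean is simply $(T_{\min}+T_{\max})/2$; no
sub-daily integration is attempted. An organ's age is the running sum of
$E(T)$ since its appearance, so "one physiological day" means one calendar
day under optimal temperature.

## Plant architecture

The shoot is a sequence of phytomers. New main-stem phytomers appear once the
plant clock crosses successive multiples of the *plastochron*, which lies
between 3.0 and 3.5 physiological days; `plastochron()` maps plant density
onto that interval log-linearly (denser stands develop more slowly) and adds
0.25 days, capped at 3.5, when mepiquat chloride is applied. The exact
density map is a modelling choice, not a published calibration, and every
endpoint is a config key.

Fruiting branches start at main-stem rank 7; each carries up to
`nodes_per_branch` (default 3) fruiting nodes. A fruit's *cumulative phytomer
number* (CPN) counts phytomers from the cotyledon node: main-stem rank of the
subtending branch plus the node position along the branch. An organ of CPN
$c$ appears exactly at clock $\text{lag} + c \cdot \text{plastochron}$ (the
emergence lag, sowing to first phytomer, defaults to 8 physiological days),
so fruits sharing a CPN are exact age cohorts — a property the tests assert
rather than assume.

Each fruit passes square → flower → boll → open boll at fixed
physiological-day thresholds (squaring to flowering 23, flowering to opening
50; both config keys chosen in the spirit of the standard process-model
parameterisation). Open boll is absorbing. Closed fruits may abscise with an
age-dependent daily probability; the default table peaks for young bolls and
yields roughly three-quarters season retention, but it is explicitly a
placeholder — the calibrated rates live in companion process models and are
not published with the quality model.

*Topping* removes the apex and the top two phytomers of the affected axes
(the usual farmer practice), terminating new phytomer appearance. Fruits on
the removed phytomers are removed with them and recorded with fate
`"pruned"`, so the accounting identity *initiated = retained + abscised +
pruned* holds on every simulated day. Topping an already-topped axis is a
no-op.

## Fibre quality kinetics

Under optimal conditions, each quality index $i$ follows a logistic in fruit
age $t$ (physiological days after squaring):

$$Q_i(t) = \frac{Q_{\max,i}}{1 + e^{-K_i (t - t_{m,i})}}$$

with calibrated constants (length 30.47 mm / 0.28 d⁻¹ / 33.78 d; strength
30.94 cN tex⁻¹ / 0.23 / 39.97; micronaire 4.648 / 0.22 / 47.03). The actual
daily gain multiplies the potential increment along the fruit's own
thermal-age trajectory by temperature reduction factors:

* **length** — quadratic in daily mean temperature,
  $-0.0038\,\bar T^2 + 0.1904\,\bar T - 1.3694$, maximal near 25 °C and
  vanishing near the 9 and 42 °C growth thresholds;
* **strength** — the product of an increasing linear response to the daily
  mean ($0.0198\,\bar T + 0.4657$, saturating above 30 °C) and a decreasing
  linear response to the diurnal range ($-0.0216\,\mathrm{TD} + 1.136$);
* **micronaire** — an increasing linear response to the daily minimum
  ($0.0244\,T_{\min} + 0.3874$, saturating above 25 °C).

All factors are clamped to $[0,1]$: the raw length quadratic slightly
exceeds 1 at its vertex (1.016 at 25.05 °C), and clamping keeps the actual
increment bounded by the potential one. Raw values remain available via
`clamp = FALSE` for diagnostics. Note one consequence worth knowing: because
the length optimum sits at 25 °C while strength and micronaire saturate at
higher temperatures, there is only a narrow band of days (mean near 27 °C,
small range, warm nights) on which *all* factors equal 1 simultaneously.

A cold day acts twice — it slows the fruit's clock (smaller potential
increment) and scales that increment down. Accumulation starts at squaring
and stops at boll opening (age 73 physiological days by default) or season
end, whichever comes first; the choice to stop at opening rather than
harvest is a contract of `finalize`-time accounting, flagged here because
the alternative is defensible. Abscised and pruned fruits accumulate nothing
further and are excluded from every aggregate.

## Synthetic weather

`generate_weather()` draws a seasonal sinusoid for the daily mean
temperature, peaking in late July, with the minimum and maximum offset by
half the diurnal range plus independent Gaussian day-to-day noise; identical
seeds give identical series. `site_weather_spec()` provides presets for four
sites (Anyang, Huimin, Aksu, Yueyang) whose April–October *active
accumulated temperature* — the sum of daily means over days at or above
12 °C, the convention used to characterise Chinese cotton sites — matches
the published station values (4561, 4518, 4335 and 5245 degree-days) to
within a few percent. The generator emulates climatology only: no
autocorrelated cold spells, no precipitation or radiation, no trend. Tests
passing on synthetic weather show the model's internal logic is right, not
that any particular station year is reproduced.

Film mulching enters purely as weather: an additive increment (default 2 °C)
to both daily extremes from sowing for a configurable duration (default 60
days). The magnitude and duration are placeholders — the source models hold
the calibrated algorithm — and mulching has no other pathway into quality,
so its simulated effect is entirely mediated by the physiological clock.

## Scenarios and aggregation

`scenario_spec()` combines a region preset (Xinjiang: sow Apr 10, top main
stem Jul 20, top branches Aug 5, 18 plants m⁻², mulched; Yellow River:
Apr 25 / Jul 30 / Aug 15 at 6 plants m⁻²; Yangtze: Apr 10 / Aug 10 / Aug 25
at 6 plants m⁻²) with day offsets from the standard menus (sowing −20…+30,
main-stem topping −10…+15, branch topping 0…+30, mulch on/off).
`run_scenario()` simulates `n_plants` plants per year and aggregates over
*retained bolls* — abscised and pruned fruits carry no harvestable fibre, so
they are excluded from means, CPN profiles and histograms (the alternative,
averaging over all initiated fruits, would mix in fruits that never made
fibre). Histograms use the conventional reporting bins: 5-unit classes for
length and strength, 0.75-wide classes for micronaire, with open-ended bins
catching out-of-range values so counts always conserve.

Statistical testing of scenario contrasts is deliberately out of scope; the
sweep emits tidy means and standard deviations for external analysis.

## Calibration and evaluation

`fit_logistic()` estimates $(Q_{\max}, K, t_m)$ by bounded
Levenberg–Marquardt least squares (`minpack.lm`), restarted from three
deterministic initial points and keeping the best fit; bounds are
$Q_{\max} \in (0, 2\max y]$, $K \in (0, 2]$, $t_m \in (0, 120]$. The fit
reports standard errors, $R^2$ and RMSE. Goodness of fit uses
$\mathrm{RMSE} = \sqrt{\tfrac1N\sum (Y_i - X_i)^2}$ and a relative error
$\mathrm{RE} = 100\sqrt{\tfrac1N\sum ((Y_i - X_i)/X_i)^2}$; the RMS form of
RE is the convention in this modelling tradition, and a mean-absolute
variant is available behind `form = "absolute"` because the published
formula can be read either way.

## Numerical choices and problem sizes

Degenerate inputs fail loudly: weather files with gaps, inverted extremes or
missing columns report the offending row; two-point calibration series are
rejected as under-determined; constant series as degenerate. Ties at the
clamp boundaries resolve in favour of the clamp (a factor evaluating to
0.99992 at the nominal boundary is treated as reaching 1 only through the
clamp, never by rounding). The whole-season daily loop is exact arithmetic
on the clock — no interpolation — so one day simulated twice at half effect
reproduces the one-day totals bit for bit.

The shipped tests and examples run single plants (tens of fruits, ~200 days)
and scenario cells of one to six plants over one synthetic year; a full
four-treatment sweep at those sizes completes in seconds. These sizes were
chosen because the model's behaviour is already fully exercised at them;
scaling to multi-decade, multi-site sweeps is a matter of looping years and
supplying real weather files.

## Known limitations

No carbon budget: boll mass, yield and source–sink competition are outside
the model, as are water and nitrogen stress (the quality kinetics were
calibrated under non-limiting supply). Organ geometry, light interception
and 3D display are likewise out of scope — only topology matters for
quality. The abscission table, plastochron map, emergence lag and mulch
increment are placeholders pending calibration data, and high-CPN behaviour
depends on the configured nodes-per-branch cap; conclusions that hinge on
those should be re-run with site-calibrated values.
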