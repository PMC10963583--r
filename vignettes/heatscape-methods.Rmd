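---
title: "Methods: bias correction, radiation and thermal-stress climatology in heatscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bias correction, radiation and thermal-stress climatology in heatscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

heatscape projects pedestrian-level outdoor thermal stress for an urban site
at hourly and metre scale. The chain is: bias-correct hourly model
meteorology against a reference series, resolve the radiation field over a
1 m raster scene to obtain mean radiant temperature (T~mrt~), evaluate the
Universal Thermal Climate Index (UTCI), and summarise stress climatologies
for a historic and a future period. This vignette records the models, the
parameters that matter, and the design choices made where the design was
genuinely open.

## Four drivers and their correction

The UTCI depends on air temperature (°C), relative humidity (%), 10 m wind
speed (m/s) and downwelling shortwave radiation (W/m²) — the last through its
control of T~mrt~. Climate-model output carries biases in both the marginals
and the dependence between these variables, and a compound index is
sensitive to that dependence, so correction proceeds in two stages.

**Grouped quantile delta mapping (QDM).** Each variable is corrected within
(hour of day, week of year) groups; weeks 52 and 53 are merged so the last
group is not starved of data. For a projected value $x$ with level $\tau$
under its group's empirical projected quantile curve, the multiplicative
update is

$$\hat x = F^{-1}_{\mathrm{ref}}(\tau)\,\frac{x}{F^{-1}_{\mathrm{hist}}(\tau)},$$

which aligns the historical marginal with the reference while preserving the
model's projected *relative* change at every quantile. Adjustments are
multiplicative for all four variables; air temperature is shifted to kelvin
first, because a ratio across 0 °C is ill-posed, and shifted back afterwards.
Where a model quantile sits below the trace threshold the factor is
non-finite; for shortwave (a variable with genuine zeros at night and under
heavy cloud) such factors — including the 0/0 case — are set to zero and
counted in the diagnostics. For the other strictly positive variables a
non-finite factor indicates misconfiguration and is only warned about.

Empirical quantile curves use type-7 linear interpolation on
`n_quantiles = 100` evenly spaced levels. When a group holds no more members
than levels — the usual case — the exact type-7 knots (the sorted sample) are
used directly: the represented piecewise-linear curve is identical and free
of resampling error, which also makes small instances exactly reproducible
by brute force. Values beyond the training range extrapolate with the edge
adjustment factor held constant. Ties interpolate to the plateau midpoint.

**MBCn.** After univariate QDM, the N-dimensional multivariate correction
iterates: draw a Haar-random orthogonal rotation, apply *additive* QDM on
each rotated coordinate within (hour, day of year) groups (rotated
coordinates are signed, so a multiplicative update would be meaningless),
rotate back, and repeat until the energy distance between the corrected
historical sample and the reference stops improving by `mbcn_tol = 1e-4`
(between `mbcn_min_iter = 10` and `mbcn_max_iter = 30` iterations; the
energy distance is estimated on a deterministic 500-row subsample, and the
minimum iteration count guards against spurious plateaus in that noisy
estimate). The final output reorders the
univariate-QDM marginals to the rank order of the converged iterate within
each group and variable, so every corrected marginal is *exactly* its
univariate-QDM marginal while the rank-dependence structure comes from the
iteration. The rotation seed is part of the configuration and recorded in
the run manifest. Day 366 merges into day 365, mirroring the week merge.
Because daily groups hold only about as many values as there are years, an
optional wider grouping (`mbcn_mode = "weekly"`) is available for short
records; the daily default retains the diurnal and annual cycles most
strongly. Reordering within groups leaves group means untouched, which is
why seasonal mean change signals survive the multivariate stage unchanged.

## Radiation and mean radiant temperature

T~mrt~ is evaluated for a standing cylindrical person at 1.5 m above ground
at every 1 m cell. The mean radiant flux density is the view-weighted sum of
directional short- and long-wave fluxes,

$$S_{str} = a_k \sum_j w_j K_j + \epsilon_p \sum_j w_j L_j, \qquad
T_{mrt} = \left(\frac{S_{str}}{\epsilon_p \sigma}\right)^{1/4} - 273.15,$$

with shortwave absorption $a_k = 0.70$, body emissivity
$\epsilon_p = 0.97$, and cylinder view weights 0.06 (up), 0.06 (down) and
0.22 for each of the four lateral directions.

The scheme is a deliberately simplified relative of SOLWEIG-type models:

- **Shadows.** A discrete ray march from each cell towards the sun samples
  the DSM and canopy at one-cell steps; a cell is building-shadowed when the
  ray segment falls below the built surface and vegetation-shadowed when it
  crosses a crown volume (from `trunk_ratio = 0.25` of canopy height up to
  the canopy top). Foliage transmits 3% shortwave and 0% longwave; canopy
  albedo is 0.15 and emissivity 0.90 (standard evergreen values). The fast
  caster is whole-grid shifted arithmetic; an exhaustive per-cell
  ray-marching oracle in the test suite asserts exact mask equality on
  randomised scenes.
- **Sky view factor.** Hemispheric integration of the maximum horizon angle
  over ≥ 36 azimuthal directions, each wedge contributing cos² of its
  horizon angle; vegetation is opaque to longwave (weight
  1 − longwave transmissivity = 1). On an H/W = 1 canyon centre this
  reproduces the analytic cos(arctan 2) ≈ 0.447 to within the half-cell
  discretisation of the raster.
- **Diffuse split.** The Erbs clearness-index relation partitions global
  shortwave into direct and diffuse; direct-normal irradiance is capped at
  the solar constant with closure preserved. Solar geometry follows the
  NOAA closed-form algorithm (no refraction); the clear-sky envelope is the
  Meinel broadband transmittance $1367 \cdot 0.7^{AM^{0.678}}$ with
  Kasten-Young air mass — adequate for cloud-fraction estimation, not for
  radiometry.
- **Longwave.** Clear-sky emissivity follows Prata's closed form in
  precipitable water; cloud cover (diagnosed from the shortwave deficit by
  day, clear by night unless supplied) raises the effective emissivity via
  Crawford-Duchon mixing. Surface temperature is parameterised as air
  temperature plus `surface_warming = 15` °C scaled by the cell's received
  shortwave relative to the zenith clear-sky ceiling — a stand-in for a
  full surface energy balance. Reflected longwave closes with a
  blackbody-at-air-temperature ambient term, so an isothermal enclosure
  radiates exactly $\sigma T^4$ in every direction and T~mrt~ = T~air~ — the
  limit the tests pin down. Anisotropic sky radiance, wall temperature
  history and ground-view-factor refinements are intentionally out of scope.
- **Tiling.** Sites are evaluated in square tiles with a buffer wide enough
  to capture shadows cast into the tile; cores are cropped and concatenated.
  With a buffer at least as long as the longest shadow and the SVF search
  distance, the tiling is exactly invisible in the result (asserted to
  1e-9). Row 1 of every raster is the northern edge; azimuth is measured
  clockwise from north; cells are indexed at their centres.

## UTCI and stress categories

UTCI is the published sixth-order polynomial approximation of the
UTCI-Fiala reference model in (T~air~, v₁₀, T~mrt~ − T~air~, vapour
pressure), for a person walking at 4 km/h producing 135 W. Vapour pressure
uses Hardy's ITS-90 formulation of Wexler's saturation curve. The validity
window is T~air~ ∈ [−50, 50] °C, T~mrt~ − T~air~ ∈ [−30, 70] °C and wind
∈ [0.5, 17] m/s; inputs outside it are clamped and flagged. Note that the
UTCI *reference state* fixes humidity at 50% relative humidity only up to a
vapour pressure of 20 hPa (about 29 °C); the identity UTCI ≈ T~air~ at
reference conditions holds under that canonical definition, not under a
literal 50% at high temperatures.

Stress categories follow the standard assessment scale (heat above 26, 32,
38, 46 °C; cold below 0, −13, −27, −40 °C), configurable as a threshold
table. Heat thresholds are strict `>` and cold thresholds strict `<`, so an
exact boundary value falls in the milder class. Two scopes are
distinguished per timestamp from the site-wide extremes: *any-cell* stress
(the favourable extreme crosses the threshold) and *site-wide* stress
(the unfavourable extreme crosses it); site-wide stress logically implies
any-cell stress, an invariant asserted on every run.

## Climatology statistics

All summaries operate on per-timestamp site extremes: change fields by hour
× day of year (member-wise future-minus-historic period means, then
ensemble mean or n−1 standard deviation); future medians expressed as
percentile ranks within the historic distribution of the same (hour, day)
group (linear type-7 interpolation, 0/100 outside the historic range);
5th/50th/95th percentile bands of the extremes by hour; stress hours per
calendar month and per hour of day divided by the number of calendar years
(the June-May spans are used only for the cumulative-season statistics,
where a year of heat exposure naturally runs winter to winter in the
southern hemisphere); cumulative June-May totals with first-occurrence
dates, spans without any occurrence excluded from date medians but counted;
and a two-period summary table with net changes (future − historic means)
and change factors (future % / historic %), rounded for reporting to 1
decimal for means and 2 for percentages and factors, with raw values
retained.

## The synthetic generator

The generator emulates the statistical skeleton of an hourly reanalysis and
a biased model ensemble: per-variable diurnal and annual harmonic cycles,
AR(1) latent persistence, cross-correlated innovations (default: warm hours
drier and clearer), configurable bias (offset/scale) and a configurable
future change signal — additive for temperature (optionally per austral
season) and multiplicative for the rest — so the "truth" behind every
downstream estimate is known. Relative humidity is generated on the logit
scale of rh/100 and wind on the log scale, which respects physical bounds
without clipping artefacts; their configured means are therefore medians.
Shortwave is a clear-sky envelope times a beta-distributed cloud
transmittance whose Gaussian copula mixes a day-to-day AR(1) latent
(weight 0.7, persistence 0.6) with the fourth cross-correlated hourly
innovation channel — the daily latent provides realistic clear/overcast
persistence, the hourly channel keeps the configured 4×4 innovation
correlation meaningful for radiation. Default coordinates are central
Hobart (42.883° S, 147.330° E) with fixed local standard time UTC+10; the
calendar is proleptic Gregorian with leap days, and leap handling is owned
by the grouping rules above.

What the generator does *not* emulate: weather-system timescales beyond
AR(1), precipitation and longwave forcing, wind directionality, synoptic
cloud structure, or any particular reanalysis's actual statistics. Passing
tests therefore demonstrate correctness of the algorithms under known
structure, not skill on real data.

## Numerical choices and problem sizes

Degenerate groups of one value map through the identity; 0/0 adjustment
factors are zero by convention; relative humidity is clamped to [0, 100]
after correction with the count reported; rank ties in the MBCn reordering
break by position. The test suite exercises 10-year single-site series for
generator calibration, 1-2-year series for correction properties, scenes up
to 60 × 60 m for radiation (with a 200 × 40 m canyon for the SVF closed
form), and an end-to-end smoke run of one synthetic year over a 60 × 60 m
scene with a 20 m buffer; the ensemble parameter-recovery check uses three
members with four-year periods, where the sampling error of a seasonal mean
change is well below the 0.2 °C tolerance being asserted.

## Known limitations

Wind is used as supplied (no metre-scale wind modelling); trees are
evergreen with fixed radiative properties; the surface-temperature
parameterisation is a single-coefficient proxy; the anisotropic sky and
surface schemes of full radiation models are simplified as described; and
the operational UTCI polynomial carries its published ~1 °C RMSE against
the reference model. Site-mean UTCI reported by the pipeline evaluates the
polynomial at the site-mean T~mrt~ (a linearisation adequate for summary
tables, not for per-cell analysis).
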