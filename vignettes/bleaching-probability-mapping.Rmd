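---
title: "Mapping annual coral-bleaching probability by indicator kriging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping annual coral-bleaching probability by indicator kriging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Historical records of mass coral bleaching are point reports: a diver or
monitoring program at one site notes the percent of coral bleached in one
year. Reporting effort is severely clustered — well-monitored regions
generate many reports per event while vast reef areas generate none — so a
count of reports is a poor measure of how much reef actually bleached.
`coralkrige` turns severity-coded reports into annual maps of the
*probability that bleaching occurred* on a 0.04° × 0.04° reef grid, and
computes the downstream statistics those maps support: reef area above
probability thresholds, decadal contrasts in bleaching extent, and the
thermal stress associated with different bleaching probabilities.

## The model

### Presence and pseudo-absence

Bleaching *presence* in year $t$ is any reef cell containing at least one
report of severity 2 or 3 (more than 10 % of coral bleached). Milder or
unknown severities are excluded: they are the reports most likely to be
misread or non-thermal. Explicit absence surveys barely exist, so absences
are inferred from physics: any reef cell whose annual maximum Degree Heating
Weeks is exactly 0 °C-weeks experienced no thermal stress that year and is
coded as a *pseudo-absence*. A cell can carry both points in the same year
(bleaching observed under zero recorded stress); kriging then yields a
probability strictly below 1 — the estimate follows the fitted model, not
the raw report.

### Thermal stress

Degree Heating Weeks at time $t$ accumulate SST exceedances over the maximum
monthly mean (MMM) climatology:

$$\mathrm{DHW}(t) = \sum_{s \in (t-84\,\mathrm{d},\, t]}
  \frac{\mathrm{HotSpot}(s)}{7}\,\Delta_s \,
  \mathbf{1}\{\mathrm{HotSpot}(s) \ge 1\,^\circ\mathrm{C}\},
\qquad \mathrm{HotSpot} = \max(0,\, \mathrm{SST} - \mathrm{MMM}),$$

with $\Delta_s$ the days represented by each observation (1 for daily input,
3.5 for twice-weekly). The 84-day window, the 1 °C accumulation threshold and
the divide-by-7 conversion to °C-weeks follow the NOAA Coral Reef Watch
convention; both window and threshold are parameters of `dhw_series()`. The
annual maximum is the summary statistic throughout, because report timing
within a year is unreliable in observational databases. The `stressed`
indicator is `annual max DHW > 0`, and its complement defines the
pseudo-absence candidate set.

### Indicator variography

For each region and year the indicator points (presences = 1,
pseudo-absences = 0) feed a method-of-moments semi-variogram
$\hat\gamma(h) = \frac{1}{2N(h)}\sum_{(i,j)\in h}(z_i - z_j)^2$ on 15
equal-width distance bins up to half the maximum pairwise distance
(`n_bins`, `max_lag` are configurable). Distances are great-circle
(haversine, R = 6371 km) throughout, because the Pacific tiling is defined
in kilometres and one metric should serve both. Nine model families are then
fitted by bounded Levenberg–Marquardt least squares and the model with the
lowest RMSE is selected:

| family | $\gamma(h) = c_0 + c\,g(u)$, $u = h/a$ |
|---|---|
| exponential | $g = 1 - e^{-u}$ |
| gaussian | $g = 1 - e^{-u^2}$ |
| spherical | $g = 1.5u - 0.5u^3$ for $u \le 1$, else 1 |
| pentaspherical | $g = \tfrac{15}{8}u - \tfrac{5}{4}u^3 + \tfrac{3}{8}u^5$ for $u \le 1$, else 1 |
| circular | $g = \tfrac{2}{\pi}\left(\arcsin u + u\sqrt{1-u^2}\right)$ for $u \le 1$, else 1 |
| linear | $\gamma = c_0 + c\,u$ (unbounded slope $c/a$) |
| bessel | $g = 1 - J_0(u)$ (hole effect) |
| matern | $g = 1 - \frac{u^\kappa K_\kappa(u)}{2^{\kappa-1}\Gamma(\kappa)}$ |
| stein_matern | Matérn in Stein's parameterization, $u' = \sqrt{2\kappa}\,u$ |

The literature this procedure follows announces "eight" modeled
semi-variograms and then names nine families; we implement and fit all nine
rather than guess which one to drop. The Matérn smoothness $\kappa$ is held
fixed (default 0.5, at which Matérn equals the exponential) rather than
optimized: with 15 binned gammas a free $\kappa$ is weakly identified. The
fit objective is ordinary least squares on binned gammas by default;
Cressie-style weights $N(h)/h^2$ are available (`weights = "npairs"`). RMSE
is always recorded unweighted so that model ranking is comparable across
weighting schemes. Non-convergence is data, not an exception: a failed fit
carries `converged = FALSE` and a reason, and if *every* family fails the
region-year falls back to an all-zero probability surface — sparse years
underrepresent bleaching rather than invent it. The same fallback applies
when a region-year has no presence points at all.

### Ordinary indicator kriging

Each reef cell's probability is the ordinary-kriging predictor over its
`neighborhood` (default 64) nearest indicator points:

$$\begin{pmatrix}\Gamma & \mathbf{1}\\ \mathbf{1}^\top & 0\end{pmatrix}
\begin{pmatrix}\lambda\\ \mu\end{pmatrix} =
\begin{pmatrix}\gamma_0\\ 1\end{pmatrix},
\qquad \hat p(x_0) = \lambda^\top z \;\text{clamped to } [0,1].$$

The local-neighborhood formulation is used because pseudo-absences can
number in the tens of thousands globally; the weights-sum-to-one constraint
makes the predictor exact under constant data and is asserted per cell.
Indicator kriging can overshoot $[0,1]$, so predictions are clamped; the
clamp fraction is reported per cell via an attribute.

Kriging runs separately for the Caribbean, the Indian Ocean, the Eastern
Pacific, and the main Pacific split into three sections overlapping by
1000 km (≈ 9° of longitude at the equator). Estimates in the overlaps are
averaged cell-by-cell (`merge_overlaps()`), removing the arbitrary edge
effects of the split. Region boundaries are configurable boxes in 0–360°
longitude so that the Pacific is contiguous across the antimeridian.

## Numerical choices

* **Nugget convention in the kriging matrix.** `model_gamma(m, 0)` returns
  the nugget (the convention for reading a fitted model card), but inside
  the kriging system the self-distance diagonal is 0 while every
  between-point entry — including coincident distinct points, the
  $h \to 0^+$ limit — carries the nugget. A literal nugget on the diagonal
  would make the system singular for any coincident pair regardless of the
  nugget, and would break the presence-plus-pseudo-absence case the method
  depends on.
* **Coincident points under a zero nugget** are genuinely singular; they are
  collapsed to their mean indicator and the solve retried. Remaining
  ill-conditioned systems (e.g. a fitted model that is numerically zero
  everywhere, or a zero-nugget Gaussian model) are retried once with a tiny
  nugget ($\max(10^{-9}, 10^{-6}\,(c_0+c))$); only then does a typed failure
  escape.
* **Variogram cutoff fallback.** With strongly clustered points the default
  cutoff (half the maximum pairwise distance) can exclude *every* mixed
  presence/absence pair, leaving an identically-zero empirical variogram
  although the indicators are mixed. `krige_region()` detects that case and
  re-estimates with the cutoff extended to the full data extent — the same
  judgement a practitioner assessing the empirical variogram would make.
* **Severity band edges** are closed on the right: 0 → 0, (0, 10] → 1,
  (10, 50] → 2, (50, 100] → 3, missing → −1, so the printed labels "1–10 %",
  "11–50 %", ">50 %" are exclusive and exhaustive, and fractional percents
  between bands fall upward.
* **Probability classes** for the thermal-stress tables use strict lower and
  inclusive upper bounds ((0.50, 0.66], (0.66, 0.90], > 0.66, > 0.90), so
  bands never double count.
* **Weighted median** is the smallest value whose cumulative weight reaches
  half the total (the left-continuous, type-1 quantile of the
  area-expanded sample).
* **Grid convention**: cells are half-open $[{\rm edge}, {\rm edge}+0.04°)$,
  origin (−90°, −180°), longitudes normalized to $[{\rm lon}_0,
  {\rm lon}_0 + 360°)$. The source analyses never state their grid anchor or
  edge rule; these are declared, not inferred.
* **Pooling** for the DHW-by-class tables is over all (cell, year) pairs
  weighted by cell reef area, matching a single pooled value per class for
  the whole study period.

## What the synthetic generator emulates

`synth_config()` defines the study conditions the package is tested under:

* **Geography**: six ocean regions with the three main-Pacific sections
  overlapping by 1000 km; 150 reef cells per region in six equal archipelago
  clusters (cells scattered with 120 km dispersion around seeded centres);
  per-cell reef areas log-normal (meanlog 1.0, sdlog 0.35, ≈ 3 km² per
  cell — moderate dispersion so that a cluster's total area is a stable
  quantity).
* **Thermal forcing**: twice-weekly SST (Pathfinder-like cadence) with a
  seasonal cycle whose climatological peak equals the cell's MMM and
  truncated noise capped at 0.45 °C — below the 1 °C accumulation threshold,
  so cells without planted events have an annual maximum DHW of exactly
  zero by construction. Planted events add a 2.5 °C anomaly for 84 days
  placed inside each cell's own warm season and ending (north) or starting
  (south) at the seasonal peak, so accumulated stress decays to zero before
  the calendar year ends and never leaks into the next year's maximum.
* **Events**: an event strikes one whole archipelago cluster (footprint =
  the cluster's cells), because mass bleaching unfolds at regional scale and
  identical footprints make planted contrasts exact. Event years always
  strike two or more clusters of a region, which is what gives the regional
  empirical variograms mixed pairs at several scales. The default calendar
  plants 2 cluster-events before the 1997/1998 El Niño, 4 during it
  (excluded from the period contrast), and 16 after — a true 8× increase in
  late-period bleaching extent.
* **Bleaching and observation**: a latent probability field built from a
  Gaussian random field with a configured variogram (exponential, nugget
  0.02, partial sill 0.6, range 250 km), mapped through the normal CDF and
  anchored at a 2 % background rate; event footprints are raised to 0.9
  with a Gaussian taper. Surveys are spatially clustered (two fixed
  monitoring stations per region, survey probability decaying with 200 km
  e-folding) and intensify to a 0.85 survey rate over active event
  footprints — bleaching events attract opportunistic reporting, which is
  exactly the behaviour of real monitoring. Bleached surveyed cells report
  severity 2/3 percents, with 10 % mis-reported as mild; unbleached surveyed
  cells report severity 0.

What it does **not** emulate: taxon-level bleaching, depth effects, report
coordinate errors beyond the grid's own rounding, mortality coding, regional
differences in thermal tolerance, or observational metadata (site names,
citations) beyond schema validity. Passing tests therefore demonstrate that
the *method* recovers known structure under clustered, noisy sampling — not
that real bleaching databases are free of the biases the original compilers
document.

## Problem sizes and determinism

Default runs use 900 reef cells, 26 years, twice-weekly SST (≈ 2.4 million
SST values), and 12 event-years across regions; a full pipeline run takes
well under a minute and the test suite a few minutes. All generator
randomness flows from one master seed through derived per-stage seeds, and
the global RNG state is saved and restored around every draw, so identical
seeds give byte-identical worlds, manifests, and outputs. Recovery checks in
the tests use the latent field as ground truth: under dense sampling the
kriged surface achieves several-fold lower mean absolute error than the best
constant prediction, the error shrinks with sampling density, and the
recovered fold change for the > 50 % probability area falls in [6, 10]
around the planted 8.

## Known limitations

* Variograms are isotropic; anisotropy and maximum-likelihood estimation are
  out of scope.
* Thermal stress enters only through pseudo-absences — DHW is never a
  kriging covariate, so the maps reflect observations, reef geography, and
  the absence of stress, by design.
* The non-thermal-cause filter is a keyword list (freshwater, runoff, tidal,
  exposure, effluent, cold, configurable); the original quality control was
  done by reading reports, so any fixed list is an approximation.
* MMM climatologies are inputs; the package does not construct them from
  multi-decade SST archives.
* Region boundaries are rectangular in longitude/latitude; real regional
  delineations follow biogeography.
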