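---
title: "Models and methods: arsenic-phosphorus kinetics and drift backtracking"
author: "sargasso package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sargasso)
```

This vignette documents the models implemented by the package, the
assumptions behind them, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## 1. The uptake model and the As:P prediction

Arsenate enters macroalgal cells through the phosphate transport system.
Writing Michaelis–Menten kinetics for both ions, with maximal rates
$\mu_P, \mu_{As}$ and half-saturation constants $k_P, k_{As}$:

$$\rho_P = \mu_P \frac{[\mathrm{PO_4^{3-}}]}{k_P + [\mathrm{PO_4^{3-}}]},
\qquad
\rho_{As} = \mu_{As} \frac{[\mathrm{AsO_4^{3-}}]}{k_{As} + [\mathrm{AsO_4^{3-}}]}.$$

Open-ocean surface concentrations sit far below the half-saturation
constants, so uptake is approximately linear in concentration and the uptake
ratio collapses to

$$\frac{\rho_{As}}{\rho_P} =
\frac{\mu_{As}k_P}{\mu_P k_{As}}\frac{[\mathrm{AsO_4^{3-}}]}{[\mathrm{PO_4^{3-}}]}
\;\propto\; \frac{1}{[\mathrm{PO_4^{3-}}]},$$

the last step using the observation that surface arsenate is nearly uniform
(and uncorrelated with phosphate) across the tropical/subtropical Atlantic.
If tissue content mirrors proportionate uptake, tissue As:P is a hyperbola
in tissue %P: slope exactly $-1$ in log–log space. `predictedAspCurve()`
exposes both the linearized regime (slope $-1$ by construction) and the
full regime, which bends shallower than $-1$ as phosphate approaches
saturation. Calls in the linearized regime warn when the grid exceeds
$k_P/10$ — beyond that the linear approximation degrades at the percent
level (at $c = k/100$ the relative error is about 1 %, at $k/1000$ about
0.1 %, shrinking linearly).

### Fitting the observed exponent

`fitPowerLaw()` is ordinary least squares of $\log_{10}(\mathrm{As{:}P})$ on
$\log_{10}(\%P)$. Multiplicative, roughly lognormal error is the natural
model for composition ratios, which makes log-space OLS the natural
estimator. Two inference routes are reported side by side and labeled in
the output:

* a **nonparametric pair bootstrap** (default 10 000 resamples, percentile
  interval) that resamples records, not residuals, so heteroscedasticity in
  x does not bias the interval;
* conventional **t-tests** of the slope against $0$ and against $-1$.

The $-1$ reference matters because of the spurious-ratio problem: for *any*
two independent positive variables $a, b$, regressing $\log(a/b)$ on
$\log b$ gives slope $\mathrm{Cov}(\log a - \log b, \log b)/\mathrm{Var}(\log b)
= -1$. `spuriousRatioNull()` simulates that null; only a slope credibly
steeper than $-1$ (the field value is about $-1.3$) indicates coupling
beyond the ratio artifact. `correlationSummary()` makes the contrast an
output by fitting the companion ratios As:N vs %N and As:C vs %C, which
lack the transport coupling and should sit near the pure spurious value.

Non-positive or missing pairs are excluded and counted, never imputed;
every fit reports its effective $n$. With a fixed seed the bootstrap — and
therefore the whole fit report — is reproducible bit for bit.

### Isotope dilution

`isotopeMixing()` solves the two-end-member growth-dilution balance
$\delta_{final} = \delta_{init}/F + (1 - 1/F)\,\delta_{new}$ for the growth
factor $F$ and reports $\log_2 F$ doublings. With the regional end-members
(+7 ‰ initial, −2 ‰ for nitrogen fixation, +2 ‰ observed) this gives
$F = 2.25$, about 1.17 doublings. The target must lie strictly between the
end-members; equal end-members are rejected as degenerate rather than
returning an indeterminate ratio.

## 2. Tissue tables, regions, comparisons

Tissue records carry %C, %N, %P (percent dry weight), δ¹⁵N (‰) and arsenic
(µg g⁻¹ dry weight) with station metadata. Reading is strict about
structure (missing columns and empty files are hard errors) and lenient
about values: rows are rejected — with a logged reason — only for
unparseable/out-of-range coordinates, all-missing chemistry, or negative
contents; individual missing values stay `NA` and drop out of each
analysis pairwise, with counts reported.

Ratios interconvert exactly between weight and molar bases via the atomic
masses C 12.011, N 14.007, P 30.974, As 74.922 g mol⁻¹; arsenic converts
from µg g⁻¹ to percent by $10^{-4}$. The weight basis is the default for
As:P since the field measurements are gravimetric.

The published sample groupings are drawn as dashed lines on a map without
coordinates, so the default `RegionScheme` uses four configurable lon/lat
boxes (NSS 30–40° N, SS 22–30° N between 70–45° W; Caribbean west of
64° W; WTA south of 12° N) with a precedence order (NSS, SS, CAR, WTA)
that resolves overlaps and boundary points deterministically; anything else
is `other`. Point-in-polygon is even-odd ray casting, so user-supplied
schemes may be arbitrary simple polygons.

The statistical test behind the original regional contrasts is not stated,
so `compareGroups()` makes a labeled choice rather than a guess: Welch's
unequal-variance one-way test, pairwise Welch t-tests under Holm
correction, and an unpooled Cohen's d — with the method string carried in
every result so downstream users see exactly what was run.

## 3. The Lagrangian tracker

Particle state is (lon, lat) in degrees, longitude on $[-180, 180)$. Each
step adds:

1. **advection**: current velocity plus `windage` × wind velocity,
   interpolated trilinearly (bilinear in space, linear in time) at the
   particle; windage default 0.02, the mid-point of the 0.5–3 % range that
   best reproduces observed *Sargassum* drift, applied to the wind vector
   without a leeway angle;
2. **diffusion**: a Gaussian perturbation. The formula σ² = 4DΔt is read as
   the *total* 2-D displacement variance — the standard 2-D Fickian scaling
   MSD = 4Dt — i.e. variance 2DΔt per component. The alternative reading
   (4DΔt per component) is available as `sigmaScheme = "percomp"`, but the
   default is the one under which `estimateDiffusivity()` recovers the
   configured D. Default D = 4000 m² s⁻¹, an Argo-float-derived estimate
   for the region.

Metre displacements convert to degrees on the local tangent plane with
R = 6 371 000 m; this is accurate to well below the step noise for ≤ daily
steps at subtropical latitudes, and the tracker refuses poleward of
cos φ < 10⁻⁶. Backward runs negate the advective velocity and step earlier
in time; diffusion is applied with the same magnitude each step (random
walks are not time-reversible, so backward source-water tracking simply
runs the same stochastic model in reversed time).

**Integrator.** Fixed-step forward Euler is the default (it matches the
random-walk formulation's time discretization; dt default 6 h), with
classical RK4 as an option. In a rotational field Euler's orbit error is
first order — a 30-day solid-body orbit at 6-hour steps inflates the radius
by about 18 % — so validation against closed-form orbits uses RK4, which is
accurate to a few parts in 10⁵ there. For the diffusive backtracking
application itself the advective truncation error is far below the
prescribed eddy diffusion, which is why Euler remains an acceptable
default.

**Land and domain.** Masked (land) cells are never read as zero velocity:
interpolation near a masked node renormalizes over the unmasked nodes and
flags the point near-land, and a particle whose nearest node is masked
deactivates ("beached", conservative, no reflection). Particles leaving
the grid or hitting an undefined velocity deactivate with those reasons.
Deactivated particles freeze at their last position; the particle count is
conserved.

**Centroid.** Per-step means over active particles, with longitudes
averaged on the circle (each longitude is unwrapped about the ensemble's
vector-mean direction before averaging), so ensembles straddling the
dateline average to ±180°, never to 0°.

**Determinism.** One master seed; each operation derives a child seed from
a tag (e.g. the station id), so ensembles are bit-identical across reruns
and independent of station order.

## 4. Gridded fields and file formats

The package's gridded-field container stores u, v (m s⁻¹) on an ascending
lon × lat × time grid with a water mask. On read, 0–360 longitudes are
rewrapped with the arrays reordered, grids must be strictly monotone, and
declared units must be m s⁻¹ unless the caller registers a converter.
Fields, trajectories and configurations are exchanged as plain-text
formats: a long-format CSV with a units header for fields; CSV (with the
full configuration and seed embedded as JSON comment lines, making the
round trip lossless) and GeoJSON (one LineString per particle plus a
centroid line per station) for trajectories; YAML for region schemes and
run configurations. These text formats keep every artifact diffable and
generator-reproducible.

## 5. The synthetic-data generator

`genTissueDataset()` emulates the survey's statistical structure: the
era design 200 (2021) / 20 (1983–1987) / 21 (2015–2018); %P log-uniform
over 0.01–0.3 % dry weight (bracketing the plotted span of the field
data), shifted per region in log space (gyre regions P-poor, belt regions
P-rich); As:P = $10^{a + b\log_{10}\%P}$ × lognormal noise with defaults
$b = -1.3$, $a = -2.4$ and noise SD 0.15 log₁₀ units — the intercept
chosen so arsenic contents land in the realistic 30–150 µg g⁻¹ range;
%N and δ¹⁵N drawn with regional means (belt N-rich; northern Sargasso Sea
isotopically heaviest at +2 ‰, within-region SD 0.5 ‰ reflecting the
qualitative spread of the survey panels). Coordinates are drawn inside
each region's box, so region assignment round-trips.

What it does **not** emulate: spatial autocorrelation within regions,
station-level replicate correlation, species effects (species labels are
balanced but carry no offsets, matching the survey's finding of no
systematic species differences), measurement censoring near detection
limits, and any As speciation. Passing tests therefore demonstrate
estimator correctness under the assumed error model, not robustness to
every feature of field data.

`genField()` provides uniform, solid-body and gyre fields. The solid-body
field is defined in tangent-plane coordinates anchored at its center, with
the zonal component carrying the local $\cos\varphi/\cos\varphi_c$ metric
factor so that the returned closed-form circular trajectory is the *exact*
solution of the advection equations the tracker integrates — giving a true
oracle for convergence tests. Gyre grids must resolve the cell (≥ 8 nodes
per wavelength) or generation is refused.

## 6. Problem sizes and tolerances

The test-suite simulations are sized for tight Monte-Carlo error at
interactive runtimes: exponent recovery uses 100 generator seeds at n = 200
(slope standard error ≈ 0.0025 on the mean); diffusivity recovery uses
1000 particles × 30 days at 6-hour steps (MSD estimator error a few
percent); bootstrap coverage uses 500 datasets × 1000 resamples at
n = 200; the spurious-ratio null uses 200 replicates at n = 10⁴. Numeric
comparisons against closed forms use 10⁻¹⁰–10⁻¹² tolerances; stochastic
checks use 3–4 σ Monte-Carlo bands.

## 7. Known limitations

* Euler is first-order; strongly curved flows need RK4 or smaller steps.
* Beaching is conservative (no resuspension), so coastal ensembles lose
  particles faster than reality.
* The tracker is purely horizontal: no Stokes drift, vertical motion, or
  growth/mortality along trajectories.
* Region boxes approximate unpublished map groupings; users with the true
  polygons should supply them as a YAML scheme.
* The bootstrap percentile interval undercovers slightly at small n; at
  the survey's n ≈ 200 coverage is within the tested ±3 points of nominal.
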