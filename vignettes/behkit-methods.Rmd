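---
title: "Models and methods behind behkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind behkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behkit)
library(dplyr)
```

behkit analyses the computational side of "bulk enzyme heterojunction"
(BEH) electrochemical biosensors: electrode interfaces on which two
cascade enzymes (e.g. sarcosine oxidase and horseradish peroxidase) are
interleaved at nanometre spacing by rigid DNA scaffolds, so that the
diffusible intermediate (hydrogen peroxide) produced by the first enzyme
reaches the second before escaping into bulk solution. This vignette
documents the models implemented, their assumptions, the tunable
parameters, and the design decisions taken where conventions were open.

## Intermediate diffusion: the fixed-step random walk

`simulate_walks()` models the intermediate as an ensemble of independent
Pearson random walks released from the origin (the first enzyme's active
site). Per global step each particle moves a fixed length $L$ at a
uniformly random angle:

$$x_{t+1} = x_t + L\cos\theta, \qquad y_{t+1} = y_t + L\sin\theta,
\qquad \theta \sim \mathrm{Uniform}[0, 2\pi).$$

Parameters, with defaults:

* `step_length_nm` ($L$, default 0.287 nm) — the outer diameter of
  H$_2$O$_2$, so one step is one molecular displacement.
* `n_particles` (default 10,000) — ensemble size.
* `stop_radius_nm` (default 70 nm) — the first-passage stop: all
  particles advance synchronously, and after every global step the walk
  halts as soon as *any* particle's radial distance reaches this value.
  70 nm is the largest inter-enzyme distance in the scaffold designs the
  model supports. Set it to `Inf` to run a fixed number of steps.
* `dimension` — 2 by default. The update equations above are planar, and
  the radial density bookkeeping below uses planar annuli, so the planar
  walk is the reference model; a 3D walk (uniform directions on the
  sphere, Marsaglia sampling) is available behind the flag for
  sensitivity checks.
* `max_steps` (default $10^6$) — a termination guarantee. Hitting it is
  reported via `stopped_by_first_passage = FALSE`, not as an error.

Several consequences of this model matter for interpretation:

* After $n$ steps the radial displacement converges to a Rayleigh law,
  $P(r \le R) = 1 - e^{-R^2/(nL^2)}$, implemented as
  `rayleigh_fraction()` and used as the analytic oracle in the test
  suite (mean squared displacement $nL^2$, Kolmogorov–Smirnov distance
  of the radial CDF).
* The stopping step is an extreme-value statistic (the first of 10,000
  walkers to escape to 70 nm) and is strongly right-skewed across
  seeds. A single realization is therefore a poor summary; the
  acceptance script reports the *median* over replicate seeds.
* Step count does not map to physical time here: no diffusion
  coefficient enters the model, so all statements are per-step, not
  per-second.

`radial_density_profile()` bins final positions into integer-radius
annuli (default outer radii 1–70 nm) and reports cumulative counts
$N_r$ and annulus densities
$\rho_r = (N_r - N_{r-1}) / \big(\pi (r_r^2 - r_{r-1}^2)\big)$,
with particles beyond the last bin counted in the `n_beyond` attribute.
`localization_fraction()` reports two fractions at a bin edge $R$: the
count fraction $N_R / N_{\max}$ and the density fraction
$\sum_{r \le R} \rho_r / \sum_r \rho_r$. They answer different
questions — "what share of molecules sit within $R$" versus "how much of
the radial density profile's mass sits within $R$" — and both are always
returned. Under the default study conditions the density-based fraction
within 20 nm is the headline localization figure (~0.8), and it is the
one the acceptance tests track.

```{r diffusion-example, eval = FALSE}
ens <- simulate_walks(seed = 1)
prof <- radial_density_profile(ens)
localization_fraction(prof, c(10, 20, 30))
autoplot(prof)
```

## Spatial statistics of two-species placements

`heterotype_nn_distances()` measures, for every point of species A, the
Euclidean distance to the nearest point of species B — the inter-particle
distance of hetero-pairs digitized from electron micrographs. Design
decisions:

* **Directionality.** The default is A→nearest-B with reuse of B points
  allowed. Because the pairing rule used when such distances are read
  off micrographs is rarely stated, a stricter `mode = "mutual"`
  (mutual nearest-neighbour pairs only) is provided; the default is the
  directional rule.
* **Edges.** Distances are reported raw, with no edge correction. An
  optional `guard_nm` argument drops anchor points near the region
  boundary; the property tests use it when comparing against the
  complete-spatial-randomness closed form (mean nearest-neighbour
  distance $1/(2\sqrt{\lambda})$ at intensity $\lambda$), where edge
  inflation would otherwise bias the comparison.

`grid_heatmap()` partitions the region into $k \times k$ cells (6 × 6
cells of 50 × 50 nm for a 300 × 300 nm field) and averages the distances
anchored in each cell. Cells are half-open $[lo, hi)$ with the last
row/column closed, indices are 0-based, each distance is assigned by its
anchor (A) point, and empty cells are `NA`, never 0. The count-weighted
mean over cells equals the overall mean distance by construction, and a
test enforces it.

`distance_summary()` fixes the boxplot conventions: sample sd
($n-1$), type-7 (linearly interpolated) quartiles, and Tukey whiskers —
the most extreme observations within 1.5 × IQR of the box. Whisker
definitions vary across plotting traditions; this one is documented
rather than assumed universal.

## AC-voltammetry coverage and spacing

For a surface-confined reversible redox label, the average AC peak
current is linear in coverage $N$ (moles of label):

$$I_{avg}(E_0) = 2 n f F N\,
\frac{\sinh(nFE_{ac}/RT)}{\cosh(nFE_{ac}/RT) + 1}
= 2 n f F N \tanh\!\left(\frac{nFE_{ac}}{2RT}\right),$$

with $n$ electrons per event (2 for methylene blue, 1 for ferrocene),
frequency $f$, amplitude $E_{ac}$, and $F$, $R$, $T$ the Faraday
constant, gas constant and temperature. The $\tanh(x/2)$ identity is
used so large amplitudes cannot overflow the hyperbolics.
`coverage_from_current()` is the exact algebraic inverse;
`coverage_from_acv()` applies it row-wise to a measurement table and
derives molecule count ($N \cdot N_A$), areal density (per cm², the
unit in which coverages like $4.3 \times 10^{12}$ cm$^{-2}$ are
quoted), and spacing. $N$ itself is stored in moles, since that is the
unit the Faraday constant implies.

`electrode_area_from_charge()` converts the gold-oxide reduction charge
to electroactive area with the standard 422 µC cm$^{-2}$ factor.

`density_to_spacing()` converts areal density $\rho$ to a
characteristic spacing. How such a spacing "should" be defined is a
genuine convention choice, so three are implemented:

* `"disc"` (default): the diameter of the equal-area disc,
  $2/\sqrt{\pi\rho}$ — 5.44 nm at $4.3\times10^{12}$ cm$^{-2}$;
* `"square"`: the square-lattice pitch $1/\sqrt{\rho}$ — 4.82 nm;
* `"hex"`: the hexagonal-packing pitch $\sqrt{2/(\sqrt{3}\rho)}$ —
  5.18 nm.

The disc convention is the default because it is the one consistent
with quoted spacings near 5.5 nm at that density; the flag records that
this is a reverse-engineered convention, not a law.

## Sensor calibration and the 3δ detection limit

`fit_log_linear()` fits signal versus $\log_{10}$(concentration) by
ordinary least squares on per-level mean signals (so unbalanced
replication does not reweight the line), with the residual sd pooled
over all replicates around the fitted line. Concentrations are molar,
signals amperes, and rows with `concentration_m == 0` are blank
replicates.

`lod_3delta()` implements the 3δ rule in the signal domain: the
detection limit is the concentration whose predicted signal equals
`blank_mean + 3 * blank_sd` (sample sd), mapped through the inverse
calibration. An LOD below the lowest calibrated level is returned but
flagged as an extrapolation. The LOD rises with blank noise and, when
the blank threshold exceeds the intercept, falls with slope; both
monotonicities are tested.

`fit_inverse_distance()` fits the empirical inverse-distance law of
cascade velocity, $v = a/d + b$, optionally after dividing velocities
by per-distance assembly yields. `ccl_estimate()` derives the critical
coupling length (CCL) — the largest spacing at which the cascade still
couples efficiently — as the smallest measured distance whose
yield-corrected velocity is at least `threshold_fraction` (default 0.5)
of the maximum. The half-max rule is a package decision: published CCL
estimates of ~10 nm rest on a yield-correction procedure that is not
fully specified, so the threshold is exposed as a parameter and
recorded in the output rather than hidden.

## Biomarker discrimination

`roc_auc()` builds the ROC curve with thresholds at every distinct
value, positivity defined as *strictly greater than* the threshold
(ties count negative — the same convention `cutoff_metrics()` uses),
and AUC by the trapezoid rule, which for this construction equals the
case/control concordance probability with ties weighted ½. The test
suite enforces that identity to 1e-12 and cross-checks against pROC.

`cutoff_metrics()` defaults the cutoff to the mean marker level of the
control group — the field's habit for a single-cutoff
sensitivity/specificity quote — and reports both metrics at it.

`combine_markers()` combines two markers whose information is close to
orthogonal (e.g. a metabolite and a protein marker). Because no single
combination rule is canonical, two are provided and reported side by
side: `"zsum"` (default), the sum of control-standardized z-scores, and
`"or_rule"`, positive if either marker exceeds its own control-mean
cutoff. zsum preserves the single-marker AUC when markers are perfectly
correlated and improves it when they are independent; both properties
are tested.

`group_summary()` gives per-group boxplot statistics and Mann–Whitney
(Wilcoxon rank-sum) p-values for every pairwise contrast — a rank test
because marker levels are skewed and no distributional form should be
assumed. The exact null distribution is used when both groups have ≤ 20
samples and no ties; otherwise the normal approximation with continuity
and tie correction.

## What the synthetic generators emulate — and what they do not

All inputs the pipeline consumes can be generated in-package, seeded
and deterministic.

`make_point_pattern()` produces three regimes: `"beh_lattice"`
(scaffold-controlled pairs: jittered-grid anchors, one partner each at
a truncated-Normal distance, uniform angle), `"csr"` (two independent
homogeneous Poisson species — the naked-surface null), and
`"tethered"` (Poisson anchors with partner offsets, for loosely
tethered partners with larger spread). Pair-distance truncation at zero
is by resampling, and partner placement resamples the angle until the
point falls inside the region, which preserves the distance
distribution exactly. Defaults: pair distance 9.1 ± 2.8 nm (the
scaffold-controlled setpoint), anchor density 1.1 × 10$^{11}$ cm$^{-2}$
— about 100 pairs per 300 × 300 nm field, the pair count typical of a
digitized micrograph field. The electrode-scale coverage
(~4 × 10$^{12}$ cm$^{-2}$) is deliberately *not* the default: at that
pitch neighbouring anchors' partners sit closer than a point's own
partner and the nearest-neighbour distance no longer reflects the pair
setpoint, so it would not emulate what the micrograph analysis
measures.

`make_cohort()` draws lognormal marker levels per group (serum
metabolite and protein levels are positive and right-skewed) linked by
a Gaussian copula with exchangeable correlation (default 0, matching
the near-orthogonality of a metabolite and a protein marker). The
default sarcosine setpoints place the normal/cancer separation at an
analytic AUC of $\Phi(\delta/(\sigma\sqrt{2})) = 0.98$ at 45 + 45
samples, with the benign-hyperplasia group positioned so the
cancer-vs-benign AUC is 0.75; the PSA marker is elevated in both
patient groups and so discriminates them poorly. These are *setpoints
for the generator*, not estimates from any patient data.

`make_calibration_dataset()` emulates a titration with Gaussian signal
noise around the log-linear line. Its default blank mean is constructed
so that `blank_mean + 3 * noise_sd` maps exactly to the lowest level of
the default grid (50 nM across 5.3 decades), making the 3δ LOD of the
generated data a known quantity.

Passing tests on these generators shows that the estimators recover
known structure under the stated statistical models. It does not show
that real micrographs are free of detection artifacts, that serum
signals are homoscedastic on the log scale, or that clinical cohorts
are lognormal with a constant copula — none of which the generators
attempt to model.

## Numerical choices and problem sizes

* One global seeded RNG per generator/simulation call; identical seeds
  give bit-identical output.
* Walk ensembles in the test suite and acceptance script use the full
  10,000 walkers; distributional checks aggregate 10–11 seeds, and
  fixed-step oracle checks use 1,000 steps, where the Rayleigh limit
  law is accurate well inside Monte-Carlo noise.
* Nearest-neighbour searches are exact (full distance matrix); the
  intended pattern sizes (10²–10⁴ points) need no spatial index.
* Ties in nearest-neighbour searches break to the first point in input
  order; ROC thresholds are the distinct observed values.
* Degenerate inputs are errors, not silent results: empty ensembles,
  non-increasing bins, a localization radius that is not a bin edge,
  missing species (named in the message), fewer than 3 calibration
  levels, non-positive densities, empty ROC classes.

## Known limitations

* The diffusion model is a free walk: no hydrodynamics, crowding,
  absorbing enzymes or reaction kinetics, and no time calibration.
* The planar annulus-density convention is kept even for 3D walks, so
  3D profiles are projections by design.
* The stopping step of the first-passage rule varies severalfold across
  seeds; single-seed step counts should never be compared directly, only
  distributional summaries.
* No edge correction for point patterns beyond the guard-zone option.
* The CCL threshold and the marker-combination rule are documented
  conventions, not estimates; conclusions that depend on them should be
  checked at alternative settings.
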