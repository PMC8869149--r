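---
title: "Structure-based size estimation for STORM data: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based size estimation for STORM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stormsba)
```

## The model

Single-molecule localization microscopy reconstructs an image from the
fitted centers of sparsely activated fluorophores. Each localization is
the fluorophore's true position plus an error that is well described as
isotropic Gaussian with standard deviation $\sigma$ (the localization
precision). For a labeled structure whose fluorophore positions project
onto a chosen axis with normalized density $S(x)$ — the *structural
function* — the expected density of localizations along that axis is the
convolution

$$D(x) = (S * G)(x), \qquad G = \mathcal{N}(0, \sigma^2).$$

Structure-based analysis (SBA) fits

$$\mathbb{E}[\text{counts}_b] = w\,A\,D(x_b - c) + b$$

to a binned line profile (bin width $w$, bin centers $x_b$) by bounded
least squares over the structure radius $R$, the kernel width $\sigma$
(optionally fixed), the amplitude $A$ (total expected localizations), a
constant background $b \ge 0$ and the center $c$, and reports the
diameter $2\hat R$. The baseline against which SBA is judged is the full
width at half maximum (FWHM) of the same profile.

Four structural functions are provided (radius $R$, support $[-R, R]$):

| shape            | labeling                    | projection $S(x)$                          |
|------------------|-----------------------------|--------------------------------------------|
| `sphere_surface` | spherical shell             | $1/(2R)$ (uniform; hat-box property)       |
| `sphere_volume`  | solid ball                  | $3(R^2-x^2)/(4R^3)$                        |
| `disc_solid`     | filled in-plane disc        | $2\sqrt{R^2-x^2}/(\pi R^2)$                |
| `disc_ring`      | circle circumference        | $1/(\pi\sqrt{R^2-x^2})$ (rim-divergent)    |

`sphere_surface` is the default for spheres, beads and cylinder
cross-sections: immunolabeled structures are surface-decorated, and the
uniform-projection/erf model is the standard surface-labeling result.
`sphere_surface` and `sphere_volume` have closed forms in the normal
CDF/PDF; the disc shapes are integrated by high-order Gauss–Legendre
quadrature after the substitution $u = R\sin\theta$, which removes the
ring's rim singularity and leaves an analytic integrand. An independent
adaptive-quadrature oracle (`quadrature_oracle()`) evaluates the defining
integral per point; the two routes agree to well below $10^{-8}$ across
$R \in \{25, 50, 100\}$, $\sigma \in \{5, 20, 50\}$ nm, and the test
suite keeps them apart deliberately (closed forms and a fixed-order rule
on one side, `stats::integrate` on the other).

## Tunable parameters

* **`sigma_loc`** (nm, default 20) — generator localization precision.
  Typical of dye-based STORM with ~1000 photons per blink.
* **`bin_width`** (nm, default 10) — profile binning, about half a
  typical localization precision. Finer bins add empty-bin noise; coarser
  bins blur the shoulder that carries the size information.
* **`pad`** (default 4 bin widths) — profile window margin, enough to
  estimate the background level beyond the structure.
* **Clustering** `eps = 100` nm, `min_pts = 10`, minimum cluster size
  20 — tuned for the simulated fixtures; exposed everywhere.
* **Fit bounds** — $R, \sigma \in [w/10, \text{span}]$, $A > 0$,
  $b \ge 0$; three radius starts ($\times 0.5, 1, 2$) guard against
  local minima, the lowest residual sum of squares wins.

### Fitted versus fixed kernel width

Whether $\sigma$ should be a free parameter is genuinely open: nothing
in the procedure pins it down, and both options are defensible.
`fit_sba()` fits it jointly by default. The benchmarking pipeline,
however, fixes $\sigma$ to the median of the per-localization precision
column whenever one is present (`fix_sigma = "auto"`): the precision *is*
known there — the generator records it and the frame-level localizer
estimates it per spot — and with $\sigma$ free the radius–kernel
trade-off inflates the variance of $\hat d$ enough that SBA loses its
precision advantage over FWHM on 100 nm spheres ($N \approx 1000$
localizations), which contradicts the method's own rationale. Fixing
$\sigma$ from known precision restores it (SD 4.6 vs 6.2 nm over 123
replicates) and is what a practitioner with a calibrated localizer would
do.

## What the generator emulates — and what it does not

The fast path (`simulate_localizations()`) draws fluorophores uniformly
on the labeled geometry, a Poisson number of blinks per fluorophore
(mean 3), uniform frame assignments, and adds Gaussian localization
error. The slow path (`simulate_frames()` + `localize_spots()`) renders
each blink as an integrated-Gaussian spot (photons placed by sampling,
so photon count is conserved exactly), adds Poisson background, then
re-localizes spots by Poisson-weighted least squares on an integrated
2D Gaussian with constant background. Both paths share one blink
schedule under a common seed.

Deliberate simplifications, hence limits of what a green test proves:

* **No photokinetics.** Blinks are independent; no dark-state dwell
  times, no photobleaching trajectory.
* **No multi-emitter fitting.** Same-frame overlapping spots are merged
  by the localizer (anomalously wide merged spots are rejected by a
  width filter, but pairs closer than the PSF width are
  indistinguishable). This deflates frame-level size estimates by a few
  percent at realistic activation densities and is the main reason the
  frame-level and localization-level paths agree only to ~6 % rather
  than 5 % on 100 nm spheres (see the decisions ledger): multi-emitter
  fitting is out of scope.
* **No drift, no EMCCD excess noise, no 3D PSF.**
* **Principal-axis selection.** Profiles for round structures are taken
  along the long axis of the cluster, as the bead procedure prescribes.
  Selecting the axis of maximal sample variance inflates the projected
  spread at finite $N$ — about +4 % in mean fitted diameter at
  $N \approx 200$, shrinking with $N$. This is a property of the
  procedure itself, reproduced faithfully, not corrected.

### The cylinder cross-section

A genuinely 3D tube surface projects onto the transverse axis with an
edge-peaked (arcsine) density, *not* a uniform one. The validation
cylinders here (`cylinder_surface`) are the 2D construction whose
cross-section is uniform on $[-R, R]$ — a uniformly labeled band — which
is the construction consistent with the uniform-projection model used to
analyze them and with the published recoveries this package reproduces
(estimates slightly *below* truth). The exact tube is available as
`cylinder_tube` for studying the mismatch: fitting its arcsine
cross-section with the uniform-projection model overestimates a 200 nm
diameter by roughly 20 %.

## Numerical choices

* Convolutions inside the optimizer are closed-form where available and
  fixed-order Gauss–Legendre otherwise — never grid FFTs, whose
  discretization would interact with the optimizer.
* Optimization: bounded PORT iterations (`nlminb`, three starts)
  followed by a Levenberg–Marquardt polish with forward-difference
  Jacobians; this reaches $10^{-6}$-relative recovery on noiseless
  model data for every shape (self-consistency is a test).
* Standard errors come from $s^2 (J^\top W J)^{-1}$ at the optimum and
  are flagged unreliable when the convergence flag is false.
* FWHM crossings are linearly interpolated; with multiple crossings
  (edge-peaked profiles) the *outermost* pair is used, because total
  width is the estimand. Default baseline: mean of the outer 10 % of
  bins per side.
* `disc_ring` is never evaluated at its singular rim inside fits; the
  convolved form is finite everywhere.
* Binning is half-open $[{\rm left}, {\rm right})$; ties go right.
  Degenerate inputs (all-zero profiles, plateau profiles, boundary
  peaks, underdetermined fits) raise typed errors rather than returning
  numbers.
* Seeds: every stochastic routine consumes an explicit seed;
  replicate seeds are derived additively, keeping values within 32-bit
  integer range.

## Known limitations

Beyond the generator simplifications above: the fit assumes an isotropic
Gaussian kernel (no astigmatism, no z); profiles are localization-count
histograms (rendered-intensity profiles can be produced via
`render_storm_image()` but are not the primary path); model selection
between shapes is left to the user via the reported residuals; and the
frame-stack text format is an exchange stand-in, not a camera format.
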