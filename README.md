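# stormsba

Structure-based size estimation for single-molecule localization
microscopy (STORM/PALM).

## The problem

A STORM image is a list of fluorophore localizations, not a photograph.
The localization step collapses every point spread function (PSF) to its
fitted center, so the rendered cluster of a densely labeled structure no
longer carries the PSF width — and when neighboring fluorophores blink in
the same frame their overlapping PSFs are misread as one. Classical width
measures such as the full width at half maximum (FWHM) of a line profile
therefore estimate the size of nanoscale structures (protein inclusions,
postsynaptic densities, beads) with poor accuracy and high variance.

**Structure-based analysis (SBA)** uses prior knowledge of the labeled
geometry instead. For a structure whose fluorophore positions project onto
the profile axis with normalized density S(x), and localization errors
that are Gaussian with standard deviation σ, the expected localization
density along the axis is the convolution

    D(x) = (S * G)(x),        G = N(0, σ²)

SBA fits `counts_b ≈ w·A·D(x_b − c) + b` (bin width w, amplitude A,
background b, center c) to the binned localization line profile by
bounded nonlinear least squares and reports the structure diameter `2R`
from the fitted structural function. For a surface-labeled sphere, S is
uniform on [−R, R] (Archimedes' hat-box projection), giving the closed
form

    D(x) = [Φ((x+R)/σ) − Φ((x−R)/σ)] / (2R)

with Φ the standard normal CDF. Volume-labeled spheres, filled discs and
rings are also provided, with a brute-force quadrature oracle for
verification.

The package contains the full validation loop: a synthetic STORM
generator (localization-level fast path, and frame-level PSF rendering
with a 2D Gaussian spot localizer), DBSCAN cluster detection,
principal-axis line-profile extraction, the SBA fit, the FWHM baseline,
estimator benchmarking, localization-table IO (generic and
ThunderSTORM-style CSV dialects) and a command-line interface. All
lengths are nm.

## Worked example

A small synthetic bead dataset (100 nm surface-labeled sphere, σ_loc =
20 nm, ThunderSTORM-style columns) ships with the package:

```r
library(stormsba)

f <- system.file("extdata", "synthetic_thunderstorm_bead.csv",
                 package = "stormsba")
tab  <- read_localizations(f, dialect = "thunderstorm")   # 154 rows
cl   <- find_clusters(tab, eps = 100, min_pts = 10)
prof <- extract_profile(cl[[1]], tab, bin_width = 10)
fit  <- fit_sba(prof, "sphere_surface", fix_sigma = median(tab$precision))
fit
#> <sba_fit> shape=sphere_surface
#>   diameter      99.475 nm (se 9.04)
#>   sigma         20.000 nm [fixed]
#>   amplitude    156.292    (se 17.3)
#>   background     0.000    (se 0.918)
#>   center        -0.182 nm (se 2.67)
#>   rss 89.4019 on 18 dof; converged: TRUE (57 iter)
measure_fwhm(prof, "edge_mean")
#> <fwhm_result> FWHM = 103.12 nm (half level 9.5 at [-50.00, 53.12])
```

The fitted diameter (99.5 nm) recovers the true 100 nm bead; the
`diameter` standard error comes from the local quadratic approximation at
the optimum. The FWHM of the same profile (103.1 nm) is close here but is
far more variable across beads — reproducing that variance gap at scale
is what `run_benchmark()` does:

```r
bench <- run_benchmark(
  emitter_spec("sphere_surface", diameter = 100, n_fluorophores = 334L),
  sim_config(sigma_loc = 20, seed = 1), n_replicates = 123)
bench$summary   # mean/sd/bias/rmse per estimator; SD(SBA) < SD(FWHM)
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "stormsba", package="stormsba"))')
Rscript $CLI simulate  --geometry cylinder_surface --diameter 200 \
                       --length 2000 --sigma-loc 20 --n-loc 5000 \
                       --seed 1 --out out/sim
Rscript $CLI fit       --input out/sim/localizations.csv \
                       --shape sphere_surface --bin-width 10 \
                       --fix-sigma 20 --out out/fit
Rscript $CLI benchmark --preset beads --replicates 20 --seed 1 \
                       --out out/bench
```

Every run echoes its effective configuration as JSON into the output
directory; rerunning from that file reproduces the outputs bitwise. Exit
codes: 0 success, 2 usage error, 3 data error.

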