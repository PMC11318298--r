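# ivimtools

Quantification of intravoxel incoherent motion (IVIM) parameters from
diffusion-weighted MRI of skeletal muscle, with a focus on the question a
study analyst actually faces: *which fitting strategy should I trust, and
how repeatable are its outputs?*

IVIM attributes diffusion-weighted signal decay to two compartments —
tissue water diffusion and the pseudo-diffusion of capillary blood — via
the bi-exponential model

    S(b)/S0 = f · exp(−b·D*) + (1 − f) · exp(−b·D)

where `f` is the perfusion fraction, `D*` the pseudo-diffusion coefficient
and `D` the diffusion coefficient (mm²/s), plus the composite `fD*`. In
resting muscle, where perfusion is low, the estimates depend strongly on
the fitting strategy, so the package implements four of them behind one
interface:

* `nlls1` — 1-step bounded NLLS, all parameters simultaneously;
* `nlls2` — 2-step segmented NLLS: `D` from the high-b (> 200 s/mm²)
  points, then `f`, `D*` with `D` fixed;
* `nlls3` — 3-step segmented NLLS: `D` and `f` from a log-linear high-b
  fit extrapolated to b = 0, then `D*` alone;
* `bayes` — posterior mean under uniform box priors with the Gaussian
  noise scale marginalised (Jeffreys prior).

Around the fitters it provides the voxelwise image-processing chain
(median filter, direction/repeat averaging, SNR estimation, physicality
and at-constraint voxel exclusion with reason codes, NIfTI parameter
maps), Monte Carlo noise simulations scored by ICC(2,1) between truth and
fit, within-subject coefficient-of-variation (WS-CV) repeatability
statistics across repeats / slices / sessions, and a synthetic phantom
and cohort generator emulating a 13-b-value, 3-direction, 4-repeat
lumbar-spine acquisition so everything is testable without scanner data.

## Worked example

Fit one noisy decay curve (SNR 50) with all four strategies:

```r
library(ivimtools)
b <- ivim_protocol_bvalues()
truth <- ivim_params(f = 0.11, Dstar = 28.4e-3, D = 1.36e-3)
set.seed(42)
curve <- ivim_curve(b, add_noise(ivim_signal(truth, b), snr = 50),
                    normalize = FALSE)
ivim_fit_all(curve)
#> IVIM fits, 4 methods:
#>   nlls1  f=0.0921 D*=34.55e-3 D=1.340e-3 rss=0.00545
#>   nlls2  f=0.0902 D*=35.70e-3 D=1.348e-3 rss=0.00546
#>   nlls3  f=0.0595 D*=74.45e-3 D=1.429e-3 rss=0.00668
#>   bayes  f=0.0755 D*=165.23e-3 D=1.391e-3 rss=0.00746
```

Each line shows the estimated perfusion fraction, pseudo-diffusion and
diffusion coefficients and the squared residual norm: the 1-step fit has
the smallest residual by construction, while the estimates — especially
`D*`, the hardest parameter at this SNR — spread widely across methods
for one and the same curve. A single fit is a classed object with the
usual verbs (`coef`, `predict`, `residuals`, `plot`, `summary`,
`simulate`):

```r
summary(ivim_fit(curve, method = "nlls3"))
#> IVIM fit (nlls3)
#> IVIM parameters:
#>   f      = 0.0595
#>   D*     = 74.451 x 10^-3 mm^2/s
#>   D      = 1.429 x 10^-3 mm^2/s
#>   f.D*   = 4.429 x 10^-3 mm^2/s
#>   squared residual norm: 0.006678
#>   residuals: min -0.0347, median -0.000904, max 0.0403 (n = 13)
#>   high-b intercept A: 0.9405
```

How well does each method recover the truth as noise varies? The Monte
Carlo driver draws parameter combinations uniformly within the fit
constraints, corrupts the ideal curves and scores agreement by ICC(2,1):

```r
des <- ivim_sim_design(n_combinations = 200, snr_levels = c(30, 60), seed = 7)
sim <- run_simulation(des, methods = c("nlls1", "nlls3"))
subset(sim$icc, parameter != "Dstar")
#>  method snr parameter       icc n_used n_failed boundary_rate
#>   nlls1  30         f 0.9520788    200        0          0.36
#>   nlls3  30         f 0.8484487    200        0          0.45
#>   nlls1  60         f 0.9278226    200        0          0.28
#>   nlls3  60         f 0.9638546    200        0          0.33
#>   nlls1  30         D 0.9885309    200        0          0.36
#>   nlls3  30         D 0.9531025    200        0          0.45
#>   nlls1  60         D 0.9913879    200        0          0.28
#>   nlls3  60         D 0.9873809    200        0          0.33
```

`f` and `D` are recovered with excellent agreement (ICC > 0.8) already at
SNR 30; `boundary_rate` is the share of fits whose solution touched a
constraint. Voxelwise maps, ROI curves, phantom generation and the WS-CV
repeatability reports are driven the same way — see `?fit_voxelwise`,
`?generate_phantom`, `?temporal_stability` and the methods vignette
(`vignettes/ivim-methods.Rmd`). A thin command-line wrapper with
`phantom | fit | simulate | repeatability` subcommands lives in
`inst/cli/ivimtool.R`.

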