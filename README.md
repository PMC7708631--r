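# gazewalk

Dynamical models of human scan-path generation during scene viewing:
simulation, exact likelihood evaluation, Bayesian parameter inference,
and the gaze statistics used to evaluate such models.

## The problem

Where people look in a scene is only half the story — *static* saliency
models predict fixation densities well but say nothing about the order
of fixations, saccade amplitudes, or the strong sequential dependencies
in real gaze data (forward and return saccades, cardinal-direction
preferences, duration–direction coupling). `gazewalk` implements the
SceneWalk family of dynamical models, in which two neural activation
fields evolve over a grid laid on the image:

- an **attention** stream `A(t)` relaxing toward foveated saliency
  `S·G_A / Σ S·G_A` at rate `ω_A` (Gaussian aperture of width `σ_A` at
  the fixation), and
- an **inhibition** stream `F(t)` relaxing toward a Gaussian fixation
  tag (width `σ_F`) at the slower rate `ω_F = ω_A/10`, producing
  inhibition of return.

The streams combine into a priority map
`u = A^γ/ΣA^γ − C_F·F^γ/ΣF^γ`, which after rectification and mixing
with uniform noise `ζ` gives the probability map
`π = (1−ζ)·u*/Σu* + ζ/(n_x·n_y)` from which the next saccade target is
drawn. The **extended** variant adds the perisaccadic machinery: pre-
and post-saccadic covert attention shifts on a per-fixation phase
schedule, a retinotopic attention trace displaced `η` beyond the landing
point, facilitation of return (slower attention decay in a foveal window
at the previous fixation), center-bias initialization, and a plus-shaped
oculomotor potential `((x−x_f)²(y−y_f)²)^χ` that favors cardinal
saccade directions.

Scan-path likelihoods are exact: replaying observed fixations through
the model gives each fixation's probability from `π` at the selection
instant, reported in log2 units (bits per fixation; uniform selection on
a 128×128 grid scores −14 bits, a perfect predictor 0). A DREAM-class
differential-evolution MCMC sampler fits the five (baseline) or eight
(extended) free parameters per subject. The intended users are
eye-movement and visual-attention researchers who want a likelihood-based,
mechanistic alternative to static saliency scoring.

## Worked example

Simulate four subjects viewing a synthetic scene, score the data under
the generating model, and look at a signature gaze statistic:

```r
library(gazewalk)

g <- sw_grid(64, 48, extent_x = 32, extent_y = 24)   # cells in degrees
S <- make_saliency(g, n_blobs = 4, seed = 7)          # synthetic scene
params <- sw_params("extended")                       # published defaults

set.seed(42)
fx <- simulate_dataset(S, params, g, n_subjects = 4, n_paths = 10, n_fix = 30)
fx
#> # A tibble: 1,200 × 6
#>    subject image    path x_deg y_deg dur_s
#>    <chr>   <chr>   <int> <dbl> <dbl> <dbl>
#>  1 s01     image_1     1 17.8  14.8  0.395
#>  2 s01     image_1     1  3.75  1.25 0.211
#>  3 s01     image_1     1  3.25  6.75 0.264
#> # ...

dataset_mean_bits(fx, S, params, g)
#> [1] -9.401987
log2(1 / (64 * 48))     # uniform-selection null on this grid
#> [1] -11.58496
```

The model explains about 2.2 bits per fixation over the uniform null on
this grid. Saccade amplitude grows with turning angle — forward
saccades are short, return saccades long (means with bootstrap 95% CIs
across subjects):

```r
s <- saccades(fx)
binned_by_turning_angle(s, "amplitude", n_boot = 200)
#> # A tibble: 6 × 5
#>   angle_bin  mean ci_lower ci_upper n_subjects
#>       <dbl> <dbl>    <dbl>    <dbl>      <int>
#> 1        15  5.34     4.97     5.57          4
#> 2        45  6.26     5.84     6.66          4
#> 3        75  6.19     5.34     7.59          4
#> 4       105  6.52     5.26     7.60          4
#> 5        135 6.77     6.17     7.53          4
#> 6        165 7.69     6.68     8.60          4
```

Fitting a subject by MCMC and summarising the posterior the broom way:

```r
fit <- fit_scanpath_model(fx[fx$subject == "s01", ], S, g,
                          variant = "extended",
                          n_chains = 3, n_iter = 2000, seed = 1)
tidy(fit)      # HPD point estimates, credible intervals, R-hat
glance(fit)    # sampler settings, acceptance, max R-hat
autoplot(fit)  # trace plots
```

A thin command-line wrapper (`inst/cli/gazewalk.R`) exposes
`simulate`, `loglik`, `fit`, `stats` and `synth` subcommands over the
same functions; fixation tables are plain CSV
(`subject,image,x_deg,y_deg,dur_s`, degrees and seconds) and saliency
maps are text matrices or grayscale PNG.

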