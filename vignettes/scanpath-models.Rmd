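---
title: "Dynamical scan-path models with perisaccadic attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical scan-path models with perisaccadic attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(gazewalk)
library(ggplot2)
set.seed(1)
```

# The model

`gazewalk` implements the SceneWalk family of dynamical models of human
scan-path generation during free scene viewing, in two variants: a
*baseline* model (activation/inhibition dynamics only) and an *extended*
model that adds perisaccadic attention shifts, facilitation of return,
center-bias initialization, and an oculomotor potential.

Both variants maintain two neural activation fields on a discrete grid
laid over the image (cell centers in degrees of visual angle):

* an **attention** map $A_{ij}(t)$, driven by the saliency map seen
  through a Gaussian aperture of width $\sigma_A$ centered at the current
  fixation — *foveated saliency*;
* an **inhibition** map $F_{ij}(t)$, driven by a Gaussian of width
  $\sigma_F$ at the fixation — *inhibitory tagging* of visited locations.

Each field relaxes linearly toward its (sum-normalized) input at rate
$\omega$:
$$\frac{dA_{ij}}{dt} = \omega_A\left(\frac{S_{ij}G_A(x_i,y_j)}{\sum_{kl}S_{kl}G_A(x_k,y_l)} - A_{ij}\right),
\qquad
\frac{dF_{ij}}{dt} = \omega_F\left(\frac{G_F(x_i,y_j)}{\sum_{kl}G_F(x_k,y_l)} - F_{ij}\right),$$
with the inhibition stream an order of magnitude slower
($\omega_F = \omega_A/10$), so tagging outlives the attention trace and
produces inhibition of return. Because the input is constant within a
phase, the relaxation has the closed solution
$$M(t_0 + \Delta t) = M^\ast + e^{-\omega \Delta t}\,(M(t_0) - M^\ast),$$
which the package uses exclusively (`evolve_map()`); a Runge–Kutta
integrator exists only as a test oracle.

The two streams combine into a priority map, are rectified, and mixed
with uniform noise $\zeta$ to give the target-selection probability map
$$u_{ij} = \frac{A_{ij}^{\gamma}}{\sum_{kl}A_{kl}^{\gamma}}
         - C_F\,\frac{F_{ij}^{\gamma}}{\sum_{kl}F_{kl}^{\gamma}},\qquad
\pi(i,j) = (1-\zeta)\frac{u^{*}_{ij}}{\sum_{kl}u^{*}_{kl}} + \frac{\zeta}{n_x n_y},$$
where $u^* = \max(u, 0)$. The next fixation is a multinomial draw from
$\pi$. All normalizations are plain discrete sums over grid cells (no
cell-area factor), so Gaussians are implicitly border-truncated and
renormalized; $\pi$ is therefore invariant to rescaling the saliency map
by any positive constant.

```{r priority-map}
g <- sw_grid(64, 48, extent_x = 32, extent_y = 24)
S <- make_saliency(g, n_blobs = 4, seed = 7)
p <- sw_params("extended")
A <- attention_input(S, gaussian_map(c(10, 12), p$sigma_A, g))
F <- normalize_map(gaussian_map(c(10, 12), p$sigma_F, g))
plot_map(priority_probability(A, F, p, g, fix = c(10, 12)), g,
         name = expression(pi))
```

# The extended model's mechanisms

**Phase schedule.** Covert attention decouples from gaze around
saccades. Each fixation of duration $t_{\mathrm{fix}}$ runs through up
to three phases (`schedule_phases()`): a *post-saccadic shift*
($[0, \tau_{\mathrm{post}}]$, attention at the remap location), a *main
phase* (attention aligned with gaze), and a *pre-saccadic shift*
($[t_{\mathrm{fix}} - \tau_{\mathrm{pre}}, t_{\mathrm{fix}}]$, attention
already at the upcoming target). Inhibition stays centered on the
fixation throughout. The saccade target is selected from $\pi$ at
$t_{\mathrm{fix}} - \tau_{\mathrm{pre}}$. Defaults
$\tau_{\mathrm{pre}} = 0.1$ s, $\tau_{\mathrm{post}} = 0.05$ s.

**Post-saccadic remap.** The attention center right after a saccade is
the previous saccade vector extended by $\eta$ beyond the landing point
(`remap_location()`), a retinotopic attentional trace. With
$\eta = 0.415^\circ$ this adds activation slightly *beyond* the landing
point in the direction of travel, biasing short-latency saccades to
continue forward (saccadic momentum).

**Facilitation of return.** Inside a square window of half-width
$\nu = 2^\circ$ (roughly the fovea) around the *previous* fixation, the
attention map decays at the slower rate
$\omega_{\mathrm{FoR}} = \omega_A/10$ instead of $\omega_A$
(`evolve_attention_for()`). The window changes only the approach rate,
never the fixed point. Combined with slow global inhibition of return
this produces the distinct return-saccade peak.

**Center bias.** Trials start with activation concentrated at the image
center (widths $\sigma_{CB} = 4.3^\circ$), relaxing toward the first
fixation's local-saliency input at the slow rate
$\omega_{CB} = 1.5$/s during the first fixation. The inhibition map
starts at zero; the priority map simply omits the inhibition term while
$F \equiv 0$ (only possible at $t = 0$), since a sum-normalized all-zero
map is undefined.

**Oculomotor potential.** Saccades favor cardinal directions. A
plus-shaped map $\mathrm{OMP} = ((x-x_f)^2 (y-y_f)^2)^{\chi}$ — zero on
the cardinal cross through the fixation, growing away from it — is
sum-normalized and *subtracted* with weight $\psi$ from $u$ before
rectification, suppressing off-cardinal targets. The additive form
written with an absolute value would reward off-cardinal cells,
contradicting the mechanism's purpose and the observed cardinal peaks,
so subtraction is the default; the literal additive variant remains
available via `omp_sign = "literal"`. At $\chi = 0$ the value on the
cross is defined as $0$ (the limit from the potential's support), which
keeps the plus shape continuous in $\chi$.

# Parameters

Estimated per subject (defaults are across-subject point estimates for a
free-viewing corpus of natural scenes):

| parameter | unit | baseline | extended | role |
|---|---|---|---|---|
| $\omega_A$ | 1/s | 14.80 | 10.00 | attention decay |
| $\sigma_A$ | deg | 7.48 | 7.32 | attention span |
| $\sigma_F$ | deg | 4.63 | 6.83 | inhibition width |
| $\gamma$ | – | 0.935 | 0.956 | priority shaping |
| $\log\zeta$ | – | −1.13 | −1.73 | selection noise (log scale) |
| $\chi$ | – | – | 0.059 | oculomotor steepness |
| $\eta$ | deg | – | 0.415 | post-saccadic shift distance |
| $\log\psi$ | – | – | −0.613 | oculomotor weight (log scale) |

Fixed (enforced at construction and inside the likelihood, never
sampled): $\omega_F = \omega_{\mathrm{FoR}} = \omega_A/10$, $C_F = 0.3$,
$\sigma_{CB} = 4.3^\circ$, $\omega_{CB} = 1.5$/s, $\nu = 2^\circ$,
$\tau_{\mathrm{pre}} = 0.1$ s, $\tau_{\mathrm{post}} = 0.05$ s. $\zeta$
and $\psi$ live on the log scale because their plausible ranges span
orders of magnitude.

**The width of the post-saccadic Gaussian** $\sigma_{\mathrm{post}}$ is
a free parameter of the extension with no published point estimate. The
package defaults to $1^\circ$ (foveal scale, commensurate with $\eta$),
a deliberate design choice: the remap displacement is only
$\eta \approx 0.4^\circ$, so a trace as wide as the attention span
($\approx 7^\circ$) changes the input map by well under a percent and
the mechanism becomes unobservable — simulations then lose the
forward-turning mode, the forward peak of the saccade-relative landing
density, and the shorter-fixations-before-forward-saccades effect that
the post-saccadic shift exists to produce. A compact trace restores all
three. `sigma_post` is overridable for sensitivity analyses.

# Likelihood and inference

The likelihood is exact and *teacher-forced*: the observed fixations and
durations drive the map evolution, and each fixation's probability is
read off $\pi$ at the preceding fixation's selection instant
($P(f_1)$ comes from the initial map at $t = 0$). Log-probabilities are
base 2, so the per-fixation unit is the bit: uniform selection on the
default $128 \times 128$ grid scores $\log_2(1/128^2) = -14$ bits and a
perfect predictor scores 0. Model comparison uses the *mean* bits per
fixation; parameter estimation uses the unnormalized *sum* (in nats)
plus the log prior. $\zeta > 0$ bounds every per-fixation term below by
$\log_2(\zeta / n_x n_y)$, so likelihoods stay finite; a zero
probability (possible only in the $\zeta = 0$ comparators) is reported
as $-\infty$ with a warning, never dropped.

Two dynamics-free comparators calibrate the likelihood ladder:
*density sampling* (one static fixation density for every fixation) and
*local saliency* (saliency through the attention aperture at the
previous fixation, no evolving state).

Per-subject Bayesian inference uses a differential-evolution MCMC
sampler of the DREAM class (`run_mcmc()`): multiple chains propose jumps
along difference vectors of states sampled from the chains' joint past,
with subspace crossover moves, occasional snooker updates, and
occasional unit-scale jumps. This family mixes with as few as three
chains in moderate dimension, matching the published estimation protocol
(three chains, uniform priors broad enough to bracket the reported
per-subject estimates by several credibility widths). Point estimates
follow the published convention: the midpoint of the 50% highest-density
interval; `tidy()` additionally reports a 95% HPD credible interval and
the Gelman–Rubin $\hat R$ per parameter (values above 1.1 trigger a
warning — surfaced, never hidden). The first half of each chain is
discarded as burn-in by default.

The recorded log posterior of every draw equals the recomputed
log prior + log likelihood (a tested invariant), and per-path likelihood
terms are evaluated independently, so their summation order cannot
affect the result.

# Engines and numerical choices

Two interchangeable engines implement the replay and the simulator: a
readable R reference built from the exported per-operation functions,
and a compiled (Rcpp) twin used by default — the inference loop needs
roughly $10^4$ full-dataset likelihood evaluations per fit. The two
mirror each other operation for operation (including long-double sum
accumulation, matching base R's `sum()`), consume the RNG stream
identically, and are tested to agree elementwise to $10^{-12}$.

Other numerical decisions:

* **Short fixations** ($t_{\mathrm{fix}} < \tau_{\mathrm{pre}} +
  \tau_{\mathrm{post}}$): the pre-saccadic phase keeps priority (target
  selection must occur at $t_{\mathrm{fix}} - \tau_{\mathrm{pre}}$), the
  post-saccadic phase is truncated to the remainder, the main phase may
  be empty.
* **Zero-length saccades** (repeated fixation positions in data): the
  remap direction is undefined, so the post-saccadic phase is skipped
  and its time folded into the main phase. `remap_location()` itself
  errors on a zero vector.
* **First fixation**: no post-saccadic phase and no facilitation window
  (no previous saccade exists); under center bias the whole first
  fixation, including its pre-saccadic phase, evolves at $\omega_{CB}$.
* Maps are clipped at zero before the $\gamma$ power to absorb
  $-10^{-17}$-scale round-off from the subtraction.
* Gaussians are evaluated at cell centers (not integrated over cells);
  with grid-sum normalization the distinction is far below every
  tolerance used here.

# What the synthetic data does and does not emulate

`make_saliency()` builds mixture-of-Gaussians maps over a uniform floor
— reproducible stand-ins for empirical saliency, with realistic hot-spot
structure but none of the spatial statistics of natural images (no
oriented edges, no image-dependent cardinal anisotropy, no category
structure). `simulate_gaze_trace()` renders scan paths as 500 Hz
recordings with Gaussian fixational jitter and raised-cosine saccade
profiles; it omits drift, microsaccades, glissades and blinks, so the
velocity-based detector (`detect_saccades()`, 5-point smoothed
differentiation, elliptic median-based threshold at $\lambda = 6$,
minimum 6 samples and $0.5^\circ$ amplitude) faces idealized input.
Fixation durations are i.i.d. gamma draws — shape 9, scale 0.0305 s
(mean ≈ 275 ms, CV ≈ 1/3, typical scene-viewing values) — with no
dependence on local image content; temporal control of fixation
durations is outside the model. Passing tests on such data validates the
machinery (dynamics, likelihood, sampler, statistics), not the model's
adequacy for any particular empirical corpus.

The baseline variant starts at the image center with a fixed 0.275 s
first fixation (the original model gives no start rule; simulation needs
one); the extended variant draws its first fixation from the center-bias
map.

# Problem sizes

The package's own verification runs at desk scale, chosen to exercise
every mechanism: gaze-statistics simulations on a $96 \times 72$ grid
over a $32^\circ \times 24^\circ$ image (fine enough to resolve the
$0.4^\circ$ remap; 20 subjects × 30 paths × 30 fixations per variant);
parameter recovery on a $24 \times 18$ grid ($1.3^\circ$ cells) with 20
paths × 40 fixations per fit and 3 chains × 2000 iterations, five
replicates. At those sizes the four well-identified parameters
($\sigma_A$, $\omega_A$, $\gamma$, $\log\zeta$) are covered by their 95%
credible intervals in at least 4 of 5 replicates; $\eta$ and $\chi$ are
weakly identified at coarse grids, as expected for sub-cell-scale
mechanisms. Full-scale fits (e.g. $128 \times 128$ grids, 20000
iterations, whole corpora) use the same code paths unchanged.

# Known limitations

* Attention travels between phase centers discretely (constant within a
  phase); there is no continuous attention trajectory.
* The facilitation window applies to the immediately preceding fixation
  only.
* No hierarchical (shared-prior) multi-subject model and no marginal
  likelihood; subjects are fitted independently.
* The likelihood conditions on observed durations; the model does not
  generate durations from image content.
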