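---
title: "Modelling cue-induced bias in perceptual decisions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cue-induced bias in perceptual decisions: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cueddm)
```

## The scientific problem

In a cued random-dot-motion task, participants judge the direction of
coherent motion as quickly and accurately as possible. Each trial is preceded
by a neutral cue (a square) or a directional cue (an arrow) that predicts the
upcoming direction with 80% validity. `cueddm` models the resulting choices
and response times with a Wiener diffusion process: evidence accumulates at
drift rate $\delta$ between two absorbing boundaries separated by $\alpha$,
starting at a relative position $w \in (0,1)$, with a non-decision time
$\tau$ added outside the accumulation period. Under accuracy coding the upper
boundary is the correct response, collapsing left and right stimuli.

Probabilistic cues can act on this process in two distinct ways: by shifting
the starting point toward the cued boundary before evidence arrives, or by
changing the rate of evidence accumulation itself. The package implements
three hierarchical Bayesian models that embody these hypotheses:

* **M1_start** — a condition effect on the starting point only. Neutral
  trials are unbiased ($w = 0.5$); on valid trials participant $p$ uses
  $\beta_{p2} \sim \mathrm{TruncNormal}(0.5 + \theta\sigma_\varepsilon,
  \sigma_\varepsilon)$ on $(0.01, 0.99)$, and on invalid trials exactly
  $1 - \beta_{p2}$ (a symmetric effect). $\theta$ is a standardised effect
  size and $\sigma_\varepsilon$ the residual standard deviation, following
  the Bayesian-ANOVA convention of expressing effects in residual-SD units.
  Drift is shared across conditions.
* **M2_drift** — a symmetric condition effect on drift with $w = 0.5$
  everywhere: $\delta_{pc} \sim \mathrm{TruncNormal}(\mu_\delta + x_c\,
  \theta\sigma_\varepsilon, \sigma_\varepsilon)$ with $x = 0, +1, -1$ for
  neutral, valid, invalid.
* **M3_both** — both effects, with separate $(\theta, \sigma_\varepsilon)$
  pairs for the starting point and the drift.

The drift-effect structure deserves a note: with a condition effect present,
$\sigma_\varepsilon$ plays the participant-SD role for every condition's
drift (mirroring how $\sigma_\varepsilon$ is the only participant-level SD of
the starting point in M1), and the group drift SD $\sigma_\delta$ appears
only where drift is shared across conditions (M1). Whether the two effects in
M3 share a standardised effect size was genuinely open; we chose separate
$(\theta_\beta, \sigma_{\varepsilon\beta})$ and $(\theta_\delta,
\sigma_{\varepsilon\delta})$ so neither effect constrains the other.

The diffusion coefficient is fixed at 1 throughout (the Stan-style
convention). On the older Ratcliff convention ($s = 0.1$) all parameters are
ten times smaller; mixing the two scales is the most common source of
confusion when comparing fits across packages.

## Likelihood and kernel numerics

The first-passage-time density is evaluated through its small-time and
large-time series expansions, switching automatically to whichever needs
fewer terms at the target truncation error ($10^{-12}$ on the standardised
scale, comfortably below the $10^{-9}$ absolute error we consider
negligible). The lower-boundary density at decision time $u = t - \tau$ is

$$f_\mathrm{lower}(u \mid \delta, \alpha, w) = \frac{1}{\alpha^2}
\exp\!\left(-\delta\alpha w - \tfrac{1}{2}\delta^2 u\right)
f^*\!\left(\frac{u}{\alpha^2}, w\right),$$

with the upper boundary obtained by the reflection $(\delta, w) \to
(-\delta, 1 - w)$. Unit tests pin the implementation against independent
fixed-term evaluations of both series, against numerical quadrature of the
total absorption mass, and against an Euler–Maruyama simulation of the
process itself.

Two trial samplers are provided. The default inverts the numerically
integrated conditional CDF of the series density (boundary chosen from the
closed-form absorption probability $P(\mathrm{upper}) =
(1 - e^{-2\delta\alpha w})/(1 - e^{-2\delta\alpha})$); its error is governed
by the same density tolerance and a grid that extends until the residual
tail mass is negligible. The fallback simulates the diffusion path by
Euler–Maruyama with step $\le 10^{-4}$ s plus exact Brownian-bridge crossing
probabilities between grid points, which removes the $O(\sqrt{\Delta t})$
first-passage bias of naive discretisation. The two routes are compared in
the test suite; the Euler route doubles as the independent simulation oracle
for the density.

## MCMC

No gradient-based engine is used: the sampler is a blocked adaptive
Metropolis-within-Gibbs scheme designed around the model's factorisation.
Given the group-level parameters, participants are conditionally
independent, so each participant-level block (drift, boundary, non-decision
time, starting point; per condition where applicable) proposes one value per
participant and accepts each independently — a sweep costs a fixed small
number of C-level likelihood passes regardless of the number of
participants. Group-level parameters never enter the Wiener likelihood
directly (only through the truncated-normal participant priors), so their
scalar random-walk updates are cheap. Proposal scales adapt toward 44%
acceptance during burn-in and are frozen afterwards, keeping the retained
draws a valid fixed-kernel chain. Initial values are drawn uniformly over a
plausible region of the admissible ranges (for $\tau_p$, below the
participant's fastest response).

Default priors (configurable via `default_priors()`): $\mu_\delta \sim
N(1.5, 2)$ on $(-5, 10)$, $\mu_\alpha \sim N(1.5, 1)$ on $(0.1, 5)$,
$\mu_\tau \sim N(0.3, 0.25)$ s on $(0.05, 1)$, half-normal(0, 1) group SDs,
$\theta \sim \mathrm{Cauchy}(0, 1/\sqrt{2})$, and half-normal residual SDs
(0.5 for the starting point, 1 for drift). These are weakly informative on
the diffusion-coefficient-1 scale. Participant-level truncation bounds are
$\delta \in (-5, 10)$, $\alpha \in (0.1, 5)$, $\tau \in (0.05, 1)$ s,
$\beta_{p2} \in (0.01, 0.99)$, and the valid-condition mean
$0.5 + \theta\sigma_\varepsilon$ is constrained to $(0, 1)$.

The reference schedule is 3 chains of 15,000 iterations with a 6,000-draw
burn-in (27,000 retained draws); the packaged tests and the acceptance
script use reduced schedules (typically 1–2 chains of 600–2,600 iterations)
that we verified are long enough at the study sizes they run: recovery
studies of 50 participants by 200 trials, model-comparison studies of 20
participants, and plausible-value studies of up to 222 participants.
Convergence is monitored with the classic Gelman–Rubin statistic (split-R̂
available for single chains).

## Marginal likelihoods and Bayes factors

Marginal likelihoods are estimated by warp-III bridge sampling implemented
in the package. All sampled parameters (group and participant) enter the
integral in unconstrained space — logit transforms for interval-bounded
parameters, log for scale parameters, with Jacobians. Half of the retained
draws fix the warp (mean and covariance Cholesky factor); warp-III also
symmetrises skew by mixing the density over sign-flipped residuals. The
optimal-bridge fixed point is iterated to a relative tolerance of
$10^{-10}$ with a 20,000-iteration cap (the cap applies to the fixed-point
iteration; proposal sample size defaults to the bridge half of the
posterior sample). Six repetitions with fresh proposal draws are pooled by
the median, a robust choice that also exposes the Monte-Carlo spread. On a
20-dimensional conjugate normal model with a closed-form marginal
likelihood, the estimator is accurate to well under 0.01 log units with
repetition SDs under 0.02.

One practical caution surfaced during development: with parameter dimension
approaching the number of draws used to fit the warp, the proposal
covariance becomes noisy and the fixed point can stall. Model comparison
should therefore use at least ~15 retained draws per parameter; the package
warns when the draw count is low relative to the dimension.

## Plausible-values correlations

To relate participant-level parameters to a trait score without committing
to posterior point estimates, each retained draw's participant vector
(e.g. the starting-point effect $\beta_{p2} - 0.5$) is correlated with the
trait, giving a distribution of plausible sample correlations $r_k$ (3,000
draws by default, subsampled evenly across chains). For each $r_k$ the exact
posterior of the bivariate-normal population correlation $\rho$ is computed
analytically under a stretched-beta prior (uniform on $(-1,1)$ by default,
width configurable), using the hypergeometric form of the sampling density
of $r$; the test suite validates it against numerical integration of
Fisher's integral representation, to max absolute density error below
$10^{-4}$. The per-draw posteriors are averaged pointwise on a 2001-point
grid, renormalised, and summarised by the 95% equal-tail credible interval
and a Bayesian p-value. The underlying definition of that p-value — "the
area of the posterior above or below zero" — does not fix the side; we
report $\min\{P(\rho > 0), P(\rho < 0)\}$ and also expose both one-sided
areas. At $r = 0$ the posterior is exactly symmetric and the p-value is
exactly 0.5; the averaged posterior is never narrower than the posterior
implied by the mean $r$ alone.

## The synthetic-study generator

`synth_config()` defaults reproduce the emulated design: 222 participants,
5 blocks of 40 trials, half neutral cues, 80% cue validity, a 1.5 s response
deadline (trials slower than the deadline are dropped as misses, as they
would be absent from real data files), and an integer trait score with
population mean 17 and SD 6.77 clipped to [0, 50]. Condition counts are
assigned exactly within participant (100 neutral / 80 valid / 20 invalid)
to reduce recovery-test variance; Bernoulli assignment is available by
flag. Group-level truth defaults ($\mu_\delta = 1.0$, $\mu_\alpha = 1.35$,
$\mu_\tau = 0.25$ s, starting-point shift $\theta\sigma_\varepsilon = 0.08$)
were chosen once so that the generated behaviour matches the observed
pattern — neutral accuracy near 79%, valid above it, invalid well below,
median correct RTs around 0.6 s with valid trials fastest.

The trait can be linked to a chosen parameter (starting-point effect,
boundary separation, or valid-condition drift) at a population correlation
$\rho$. The linkage acts on the latent standard-normal score underlying the
truncated draw, so the achieved Pearson correlation after truncation is
verified empirically in the tests rather than assumed.

What the generator does **not** emulate: the adaptive staircase that set
each participant's motion coherence (difficulty is absorbed into the drift
rate), trial-to-trial parameter variability, response contaminants and
lapses, and sequential effects. Passing recovery tests therefore show that
the pipeline is correct under its own assumptions, not that those
assumptions hold in any particular dataset. One deliberate mismatch remains
available: with miss-censoring on, the likelihood does not model the
truncation of the RT distribution at the deadline, exactly as in the
emulated analysis; recovery tests generate uncensored data so that
estimator bias is not confounded with censoring bias.

## Degenerate inputs and edge cases

Response times at exactly 0.2 or 1.5 s are retained by the filter (strict
inequalities remove). Participants left with no trials are excluded from
fitting with a warning; participant-condition cells without correct trials
are dropped from RT summaries. Zero-variance draws are dropped (and counted)
in the plausible-values stage; $|r| = 1$ is rejected as degenerate. Constant
chains yield a defined Gelman–Rubin value with a warning. A sample
correlation is reported as missing, with a warning, whenever either variable
has zero variance.

## Known limitations

* The likelihood ignores deadline censoring and the removed fast guesses;
  with 98%+ retention this is a small perturbation, but parameters fitted
  to heavily censored data will be biased toward faster processes.
* No across-trial variability parameters (drift, starting point or
  non-decision time variability); these need more trials per participant
  than the emulated design provides.
* The Metropolis-within-Gibbs sampler mixes more slowly than a well-tuned
  gradient sampler on strongly correlated group-level posteriors; the
  weakly identified pair $(\theta, \sigma_\varepsilon)$ is the slowest
  direction. The identified product $\theta\sigma_\varepsilon$ mixes well
  and is the quantity used in recovery checks.
* Bridge-sampling estimates degrade when the number of retained draws is
  small relative to the parameter dimension (see above).
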