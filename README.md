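# cueddm

Hierarchical Bayesian diffusion modelling of cued perceptual decisions.

`cueddm` is for researchers analysing choice and response-time data from
two-alternative perceptual tasks in which probabilistic cues may bias the
decision process — for example, a random-dot-motion task where an arrow cue
predicts the upcoming direction with 80% validity. The central question the
package addresses: does prior information shift the **starting point** of
evidence accumulation, the **drift rate**, or both — and do individual
differences in these biases track a trait covariate (such as the Adult
Autism Spectrum Quotient, AQ)?

## The model

Each trial's choice and response time follow a Wiener diffusion process:
evidence accumulates at drift rate δ between boundaries separated by α,
starting at relative position *w* ∈ (0, 1), with non-decision time τ
(diffusion coefficient fixed at 1; upper boundary = correct response under
accuracy coding). Three hierarchical models embody competing hypotheses
about cue effects:

| model | condition effect |
|---|---|
| `M1_start` | starting point: neutral *w* = 0.5, valid β₍p2₎ ~ TruncNormal(0.5 + θσ_ε, σ_ε), invalid 1 − β₍p2₎ |
| `M2_drift` | drift: δ₍pc₎ ~ TruncNormal(μ_δ + x_c·θσ_ε, σ_ε), x = 0/+1/−1 |
| `M3_both`  | both, with separate (θ, σ_ε) pairs |

Participant parameters are drawn from truncated normals around group means;
θ is a standardised effect size in residual-SD (σ_ε) units. Models are fitted
by blocked adaptive Metropolis-within-Gibbs MCMC, compared via **warp-III
bridge sampling** log marginal likelihoods and Bayes factors, and related to
trait scores with the **plausible-values** procedure: the participant
parameter vector of each posterior draw is correlated with the trait, the
analytic posterior of the population correlation ρ is computed for each
plausible correlation, and these posteriors are averaged — propagating both
estimation and sampling uncertainty into one 95% equal-tail credible
interval and Bayesian p-value.

A synthetic-study generator reproduces the cued design (222 participants,
5 × 40 trials, half neutral cues, 80% validity, 1.5 s deadline, trait score
with mean 17 and SD 6.77) with known ground truth, so every stage of the
pipeline has a recovery test.

## Worked example

Simulate a 40-participant study with the default design, filter response
times, fit the starting-point model, and test for a trait correlation:

```r
library(cueddm)
study <- generate_study(synth_config(n_participants = 40, seed = 7))
flt   <- filter_rts(study$data)          # removes RTs < 0.2 s or > 1.5 s
summarize_behavior(flt$data)
```

```
  condition median_rt_mean median_rt_sd accuracy_mean accuracy_sd  n
1   neutral          0.546       0.0950          79.6       14.20 40
2     valid          0.497       0.0965          85.9        9.34 40
3   invalid          0.585       0.1331          71.6       19.18 40
```

Valid cues speed and improve responses, invalid cues do the opposite — the
qualitative signature of a cue-induced bias. Fit the hierarchical model and
check convergence:

```r
fit <- sample_posterior(build_model("M1_start", accuracy_code(flt$data)),
                        n_chains = 2, n_iter = 1500, burn_in = 700, seed = 11)
fit
```

```
ddm_fit: M1_start - 1600 retained draws ( 2 chains x 1500 iterations, 700 burn-in)
                 mean      sd   2.5%  97.5%
mu_delta       1.2207 0.10031 1.0282 1.4169
mu_alpha       1.3220 0.03560 1.2557 1.3937
mu_tau         0.2570 0.00736 0.2436 0.2727
theta_beta     1.5313 0.28830 0.9863 2.1276
sigma_eps_beta 0.0527 0.00759 0.0389 0.0699
...
```

The group starting-point shift θσ_ε ≈ 0.08 means valid cues move the start
about 8% of the boundary separation toward the correct response (the
generator's truth here was 0.08). `gelman_rubin(fit)` gives R̂ in
[1.000, 1.021]. Now the plausible-values correlation between the
starting-point effect β₍p2₎ − 0.5 and the trait score:

```r
correlate_trait(fit, "delta_beta", seed = 13)
```

```
Plausible-values correlation for delta_beta :
  mean plausible r: 0.155
population-correlation posterior: mean 0.143 , 95% equal-tail CI [ -0.191 , 0.454 ], Bayesian p = 0.197
```

The interval spans zero: no evidence for a trait link in this simulated
study (whose generating correlation was indeed 0). For model comparison,
fit the competing models and call `model_logml()` on each, then
`bayes_factors()`; `run_pipeline(run_config(...))` chains every stage with
one master seed, and `inst/scripts/cueddm.R` exposes the same stages as
shell subcommands.

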