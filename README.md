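# ivfjoint

Joint Bayesian modelling of success (live birth) and treatment
discontinuation in *in vitro* fertilization programs.

## The problem

Couples in an IVF program undergo up to four aspiration attempts. After a
failed attempt a couple may return or discontinue treatment, and
discontinuation is informative: unmeasured couple-specific factors
(prognosis, psychological burden) plausibly lower the chance of a live
birth *and* raise the chance of stopping. Ignoring that link biases
per-attempt success rates and center comparisons. `ivfjoint` is for
reproductive-medicine statisticians who want to analyze the two processes
jointly in a two-center design.

The core is a shared random-effects model: two mixed logistic regressions,
one for per-attempt success and one for discontinuation after a failure,

    logit(p_i)  = alpha_succ + beta_age_succ[age_i] + beta_center_succ * mid_i + f_i
    logit(pi_i) = alpha_disc + beta_age_disc[age_i] + beta_center_disc * mid_i
                  + lambda_{center_i} * f_i + eps_i

with a couple-level latent factor `f_i ~ N(0, sigma_f^2)` shared between
the equations. The center-specific loading `lambda` measures the link
between the processes in each center: `lambda < 0` means the shared
unmeasured factors act with opposite impact (what favors birth discourages
dropout). Fitting is by a Pólya-Gamma-augmented Gibbs sampler with
interweaved scale updates; `lambda = 0` is tested with partial Bayes
factors on the `L = 2 log BF` scale (no evidence above −2, significant at
or below −2, strong at or below −6). Because the study's medical-record
data are not deposited, the package ships a calibrated synthetic-cohort
generator with the same structure (informative dropout, administrative
censoring after attempt 4, two-center covariate margins).

## Worked example

```r
library(ivfjoint)

coh <- simulate_cohort(generator_config(seed = 1))   # 3,002 couples
coh
#> IVF cohort: 3002 couples, 6077 attempt records
#>   couples per center: MIDCITY=1394, PARIS=1608

attempt_rates(coh)
#> Live Birth rate (%)
#>   attempt 1: PARIS 22 (354/1608)   MIDCITY 23 (325/1394)
#>   attempt 2: PARIS 19 (150/793)   MIDCITY 20 (155/794)
#>   attempt 3: PARIS 19 (82/437)   MIDCITY 14 (70/490)
#>   attempt 4: PARIS 18 (44/242)   MIDCITY 16 (52/319)
#> Discontinuation rate (%)
#>   attempt 1: PARIS 37 (461/1254)   MIDCITY 26 (275/1069)
#>   attempt 2: PARIS 32 (206/643)   MIDCITY 23 (149/639)
#>   attempt 3: PARIS 32 (113/355)   MIDCITY 24 (101/420)

fit <- fit_mcmc(coh, prior_config(), desk_mcmc_config(seed = 2))
fit
#> Joint-model fit: 3002 couples, 2 chains x 1000 kept draws
#>   max R-hat: 1.029

or_summary(fit, "beta_center_disc")
#> Odds ratio for beta_center_disc (reference PARIS)
#>   median 0.58, mean 0.59, 95% CrI [0.44, 0.77]

bf <- partial_bayes_factor(coh, "MIDCITY", split_spec(2702, 300, seed = 3),
                           prior_config(),
                           desk_mcmc_config(seed = 4, n_iterations = 2500,
                                            burn_in = 500))
bf
#> Partial Bayes factor for lambda_midcity = 0 (split 2702/300, prior 'default')
#>   L = 2 log BF = 0.18 (mc error 0.20) -> NO_EVIDENCE
```

Reading the output: the simulated cohort reproduces the calibrated
first-attempt rates (22% live births in the Parisian center, 37%
discontinuation among its first-attempt failures). The fitted center
discontinuation odds ratio (median 0.58, 95% CrI [0.44, 0.77]) recovers the
generating value 0.55 — couples in the medium-sized-city center are roughly
half as likely to discontinue. The partial Bayes factor on a 300-couple
test sample is within Monte-Carlo noise of zero, i.e. this split carries no
evidence about the loading (see the vignette for why small test samples are
underpowered for `lambda`).

`run_analysis(analysis_config(...))` chains all stages — simulate or read a
cohort, descriptive tables, model fit, odds-ratio summaries, Bayes-factor
tests — and writes every table as CSV plus a short report, all seeded from
one master seed.

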