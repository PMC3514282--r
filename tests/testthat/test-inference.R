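test_that("intercept-only posterior matches a grid-integration oracle", {
  p <- model_params(alpha_succ = qlogis(0.3), alpha_disc = qlogis(0.4),
                    sigma_f = 0, sigma_eps = 0)
  coh <- simulate_cohort(generator_config(n_couples = 2000, params = p, seed = 15))
  pr <- prior_config(sigma_f_prior = list(family = "fixed", value = 0),
                     sigma_eps_prior = list(family = "fixed", value = 0))
  fit <- fit_mcmc(coh, pr,
                  desk_mcmc_config(seed = 3, n_iterations = 4000, burn_in = 500, thin = 2),
                  covariates = character(0), fix_lambda = c(paris = 0, midcity = 0))
  cc <- ivfjoint:::.cohort_counts(coh)
  grid <- seq(-3, 1, length.out = 20001)
  grid_mean <- function(k, M) {
    lp <- k * plogis(grid, log.p = TRUE) + (M - k) * plogis(-grid, log.p = TRUE) +
      dnorm(grid, 0, 10, log = TRUE)
    w <- exp(lp - max(lp))
    sum(grid * w) / sum(w)
  }
  expect_lt(abs(grid_mean(sum(cc$k), sum(cc$m)) -
                  mean(posterior_draws(fit, "alpha_succ"))), 0.02)
  expect_lt(abs(grid_mean(sum(cc$s), sum(cc$r)) -
                  mean(posterior_draws(fit, "alpha_disc"))), 0.02)
})

test_that("fitting is deterministic given the seed and draw counts obey the protocol", {
  coh <- simulate_cohort(generator_config(n_couples = 250, seed = 4))
  cfg <- desk_mcmc_config(seed = 10, n_iterations = 1200, burn_in = 200, thin = 4)
  f1 <- fit_mcmc(coh, prior_config(), cfg)
  f2 <- fit_mcmc(coh, prior_config(), cfg)
  expect_identical(f1$draws, f2$draws)
  expect_equal(dim(f1$draws)[1], (1200 - 200) %/% 4)
  expect_equal(dim(f1$draws)[2], 2)
  # paper protocol arithmetic: 2 x (300000 - 50000)/100 = 5000 retained
  pc <- mcmc_config()
  expect_equal(pc$n_chains * (pc$n_iterations - pc$burn_in) %/% pc$thin, 5000)
})

test_that("fit_mcmc rejects cohorts with inestimable effects", {
  coh <- cohort_from_histories(rep(list(history_df(1, 1, NA)), 10),
                               center = rep("PARIS", 10),
                               age_class = rep(age_classes(), 2))
  expect_error(fit_mcmc(coh, prior_config(), desk_mcmc_config()), "center absent")
  coh2 <- cohort_from_histories(rep(list(history_df(1, 1, NA)), 10),
                                center = rep(centers(), 5),
                                age_class = rep("30-34", 10))
  expect_error(fit_mcmc(coh2, prior_config(), desk_mcmc_config()), "age class absent")
})

test_that("posterior contraction: doubling n shrinks posterior sd by about sqrt(2)", {
  p <- model_params(alpha_succ = qlogis(0.3), alpha_disc = qlogis(0.4),
                    sigma_f = 0, sigma_eps = 0)
  pr <- prior_config(sigma_f_prior = list(family = "fixed", value = 0),
                     sigma_eps_prior = list(family = "fixed", value = 0))
  cfg <- desk_mcmc_config(seed = 6, n_iterations = 3000, burn_in = 500, thin = 2)
  sds <- vapply(c(1000, 2000), function(n) {
    coh <- simulate_cohort(generator_config(n_couples = n, params = p, seed = n))
    fit <- fit_mcmc(coh, pr, cfg, covariates = character(0),
                    fix_lambda = c(paris = 0, midcity = 0))
    sd(posterior_draws(fit, "alpha_succ"))
  }, 0)
  expect_gt(sds[1] / sds[2], 1.2)
  expect_lt(sds[1] / sds[2], 1.7)
})

test_that("a recovery run meets the R-hat convergence standard when run long enough", {
  coh <- simulate_cohort(generator_config(n_couples = 3002, seed = 818))
  fit <- fit_mcmc(coh, prior_config(),
                  desk_mcmc_config(seed = 819, n_iterations = 30000,
                                   burn_in = 5000, thin = 25))
  expect_lt(max(fit$rhat, na.rm = TRUE), 1.05)
})

test_that("Brooks-Gelman statistic separates converged from displaced chains", {
  set.seed(2)
  x <- rnorm(10000)
  expect_lt(abs(gelman_rubin(cbind(x, x)) - 1), 0.01)
  expect_lt(gelman_rubin(cbind(rnorm(10000), rnorm(10000))), 1.01)
  expect_gt(gelman_rubin(cbind(rnorm(200), rnorm(200, 10))), 1.1)
  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "two chains")
  expect_error(gelman_rubin(list(rnorm(10), rnorm(5))), "equal length")
})

test_that("odds-ratio summaries exponentiate draws with the five quantiles", {
  fit <- fake_fit(list(beta_center_disc = rep(log(2), 400)))
  o <- or_summary(fit, "beta_center_disc")
  expect_equal(unname(o$quantiles), rep(2, 5))
  expect_equal(o$mean, 2)
  expect_equal(o$reference, "PARIS")
  expect_error(or_summary(fit, "no_such"), "unknown")

  # mirror symmetry: OR quantiles of -c are reciprocals of reversed +c quantiles
  set.seed(9)
  d <- rnorm(4000, 0.3, 0.2)
  fp <- fake_fit(list(x = d)); fm <- fake_fit(list(x = -d))
  qp <- or_summary(fp, "x")$quantiles
  qm <- or_summary(fm, "x")$quantiles
  expect_equal(unname(qm), unname(rev(1 / qp)), tolerance = 1e-2)

  # sampling check against a known lognormal median
  set.seed(11)
  fit2 <- fake_fit(list(beta_center_disc = rnorm(5000, log(0.55), 0.01)))
  expect_equal(unname(or_summary(fit2, "beta_center_disc")$quantiles[3]), 0.55,
               tolerance = 0.01)
})

test_that("retained-draw autocorrelation is reported per parameter", {
  coh <- simulate_cohort(generator_config(n_couples = 200, seed = 44))
  fit <- fit_mcmc(coh, prior_config(), desk_mcmc_config(seed = 2, n_iterations = 1500,
                                                        burn_in = 300, thin = 3))
  ac <- posterior_autocorr(fit, lags = 1:5)
  expect_equal(dim(ac), c(length(fit$parameters), 5))
  expect_true(all(abs(ac[!is.na(ac)]) <= 1))
})
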