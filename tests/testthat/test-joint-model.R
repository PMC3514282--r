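test_that("per-attempt probabilities are the inverse-logit of the linear predictors", {
  p0 <- model_params(sigma_f = 1, sigma_eps = 0.5)
  expect_equal(success_probability("PARIS", "30-34", p0, f = 0), 0.5)
  expect_equal(discontinuation_probability("PARIS", "30-34", p0, f = 0, eps = 0), 0.5)

  p1 <- model_params(alpha_succ = qlogis(0.22))
  expect_equal(success_probability("PARIS", "30-34", p1, f = 0), 0.22)
  expect_equal(success_probability("PARIS", "30-34", p0, f = 1), plogis(1))

  # loading applies only through the tested center, scaled by f
  p2 <- model_params(lambda_midcity = -0.21)
  expect_equal(discontinuation_probability("MIDCITY", "30-34", p2, f = 1), plogis(-0.21))
  expect_equal(discontinuation_probability("PARIS", "30-34", p2, f = 1), 0.5)

  # odds-ratio arithmetic for the oldest age class
  p3 <- model_params(beta_age_disc = c("<25" = 0, "25-29" = 0, "35-39" = 0,
                                       ">=40" = log(2.9)))
  expect_equal(discontinuation_probability("PARIS", ">=40", p3), 2.9 / 3.9)
})

test_that("probabilities are strictly monotone in intercept, latent and loading", {
  for (i in 1:10) {
    set.seed(i)
    par <- random_params()
    fs <- sort(runif(5, -2, 2))
    ps <- success_probability("MIDCITY", "35-39", par, f = fs)
    expect_true(all(diff(ps) > 0))
    par2 <- par; par2$alpha_succ <- par$alpha_succ + 0.3
    expect_true(success_probability("PARIS", "<25", par2) >
                  success_probability("PARIS", "<25", par))
    # discontinuation increasing in lambda * f
    lf <- par$lambda_midcity * fs
    pd <- discontinuation_probability("MIDCITY", "30-34", par, f = fs)
    expect_true(all(diff(pd[order(lf)]) > 0 | diff(lf[order(lf)]) == 0))
  }
})

test_that("history log likelihood matches hand-computed cases and rejects invalid input", {
  par <- model_params() # p = pi = 0.5 everywhere
  expect_equal(couple_history_loglik(history_df(1, 1, NA), par,
                                     center = "PARIS", age_class = "30-34"),
               log(0.5))
  expect_equal(couple_history_loglik(history_df(1, 0, 1), par,
                                     center = "PARIS", age_class = "30-34"),
               2 * log(0.5))
  expect_error(couple_history_loglik(history_df(1:2, c(1, 0), c(NA, 0)), par,
                                     center = "PARIS", age_class = "30-34"),
               "invalid history")
})

test_that("the enumerated history tree is a probability distribution", {
  tree <- enumerate_history_tree()
  expect_length(tree, 8)
  for (i in 1:25) {
    set.seed(100 + i)
    par <- random_params()
    f <- rnorm(1); eps <- rnorm(1)
    cen <- sample(centers(), 1)
    tot <- sum(vapply(tree, function(h)
      exp(couple_history_loglik(h, par, f = f, eps = eps,
                                center = cen, age_class = "35-39")), 0))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("marginal likelihood collapses, factorizes and matches Monte Carlo", {
  h <- history_df(1:3, c(0, 0, 1), c(0, 0, NA))

  # degenerate measure: zero scales give the conditional at f = eps = 0
  par0 <- model_params(alpha_succ = 0.3, alpha_disc = -0.4, sigma_f = 0, sigma_eps = 0)
  expect_equal(marginal_couple_loglik(h, par0, 30, center = "PARIS", age_class = "30-34"),
               couple_history_loglik(h, par0, center = "PARIS", age_class = "30-34"))

  # lambda = 0, sigma_eps = 0: success factor (1-D integral) times a
  # closed-form discontinuation factor
  par1 <- model_params(alpha_succ = -0.8, alpha_disc = -0.5, sigma_f = 1.2,
                       sigma_eps = 0, lambda_paris = 0, lambda_midcity = 0)
  joint <- marginal_couple_loglik(h, par1, 40, center = "MIDCITY", age_class = "30-34")
  gh <- pracma::gaussHermite(40)
  fs <- sqrt(2) * par1$sigma_f * gh$x; w <- gh$w / sqrt(pi)
  p <- success_probability("MIDCITY", "30-34", par1, f = fs)
  succ_factor <- log(sum(w * p * (1 - p)^2))
  pi0 <- discontinuation_probability("MIDCITY", "30-34", par1)
  expect_equal(joint, succ_factor + 2 * log(1 - pi0), tolerance = 1e-8)

  # plain Monte-Carlo oracle
  set.seed(42)
  par <- random_params()
  q <- marginal_couple_loglik(h, par, 30, center = "MIDCITY", age_class = ">=40")
  f <- rnorm(2e5, 0, par$sigma_f); e <- rnorm(2e5, 0, par$sigma_eps)
  ll <- couple_history_loglik(h, par, f = f, eps = e,
                              center = "MIDCITY", age_class = ">=40")
  mc <- log(mean(exp(ll)))
  expect_equal(q, mc, tolerance = 5e-3)
})

test_that("log prior sums independent densities with the documented families", {
  pr <- prior_config() # N(0, 10^2) on 14 fixed effects, half-normal(1) scales
  par <- model_params(sigma_f = 1, sigma_eps = 0.5)
  want <- 14 * dnorm(0, 0, 10, log = TRUE) +
    log(2) + dnorm(1, 0, 1, log = TRUE) +
    log(2) + dnorm(0.5, 0, 1, log = TRUE)
  expect_equal(log_prior(par, pr), want)

  # doubling the fixed-effect sd lowers the log prior at 0 by n_fixed * log 2
  pr2 <- prior_config(fixed_effect_sd = 20)
  expect_equal(log_prior(par, pr) - log_prior(par, pr2), 14 * log(2))

  # out-of-support scale
  pr_fix <- prior_config(sigma_f_prior = list(family = "fixed", value = 0),
                         sigma_eps_prior = list(family = "fixed", value = 0))
  par0 <- model_params(sigma_f = 0, sigma_eps = 0)
  expect_equal(log_prior(par0, pr_fix), 14 * dnorm(0, 0, 10, log = TRUE))
  expect_equal(log_prior(par0, pr), -Inf)

  # independent density-summation oracle on random parameter sets
  for (i in 1:5) {
    set.seed(200 + i)
    par <- random_params()
    fe <- c(par$alpha_succ, par$alpha_disc, par$beta_age_succ, par$beta_age_disc,
            par$beta_center_succ, par$beta_center_disc,
            par$lambda_paris, par$lambda_midcity)
    oracle <- sum(dnorm(fe, 0, 10, log = TRUE)) +
      sum(log(2) + dnorm(c(par$sigma_f, par$sigma_eps), 0, 1, log = TRUE))
    expect_equal(log_prior(par, pr), oracle)
  }
})

test_that("model parameters serialize to YAML and JSON and back", {
  set.seed(33)
  par <- random_params()
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_model_params(par, path)
    back <- read_model_params(path)
    expect_equal(unclass(back), unclass(par), tolerance = 1e-12)
    unlink(path)
  }
})
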