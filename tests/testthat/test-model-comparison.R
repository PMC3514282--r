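test_that("cohort splitting is a seeded partition of the couples", {
  coh <- simulate_cohort(generator_config(n_couples = 400, seed = 3))
  sp <- split_spec(300, 100, seed = 5)
  h1 <- split_cohort(coh, sp)
  h2 <- split_cohort(coh, sp)
  expect_identical(as.data.frame(h1$learning), as.data.frame(h2$learning))
  expect_equal(n_couples(h1$learning), 300)
  expect_equal(n_couples(h1$test), 100)
  expect_length(intersect(h1$learning$couple_id, h1$test$couple_id), 0)
  expect_setequal(c(unique(h1$learning$couple_id), unique(h1$test$couple_id)),
                  unique(coh$couple_id))
  expect_error(split_cohort(coh, split_spec(390, 20)), "do not match")

  # the study's splits at the study size: test samples of 300/1500/2500
  sizes <- vapply(paper_splits(3002), function(s) s$n_test, 0L)
  expect_equal(sizes, c(300L, 1500L, 2500L))
})

test_that("evidence categories follow the 2logBF threshold rule", {
  expect_equal(classify_evidence(2.70), "NO_EVIDENCE")
  expect_equal(classify_evidence(-5.26), "SIGNIFICANT")
  expect_equal(classify_evidence(-2), "SIGNIFICANT")
  expect_equal(classify_evidence(-6), "STRONG")
  expect_equal(classify_evidence(-1.999), "NO_EVIDENCE")
  expect_error(classify_evidence(Inf), "finite")
  expect_error(classify_evidence(NA_real_), "finite")
})

test_that("predictive marginal reduces to the history likelihood for a point posterior", {
  par <- model_params(alpha_succ = 0.4, alpha_disc = -0.7, sigma_f = 0, sigma_eps = 0,
                      beta_center_succ = 0.2, beta_center_disc = -0.1)
  nm <- ivfjoint:::.param_names(c("age", "center"))$all
  vals <- setNames(rep(0, length(nm)), nm)
  vals["alpha_succ"] <- par$alpha_succ
  vals["alpha_disc"] <- par$alpha_disc
  vals["beta_center_succ"] <- par$beta_center_succ
  vals["beta_center_disc"] <- par$beta_center_disc
  fit <- fake_fit(lapply(as.list(vals), rep, times = 40))
  test_coh <- cohort_from_histories(list(history_df(1:2, c(0, 1), c(0, NA))),
                                    center = "MIDCITY", age_class = "30-34")
  pm <- predictive_log_marginal(test_coh, fit)
  expect_equal(pm$log_marginal,
               couple_history_loglik(history_df(1:2, c(0, 1), c(0, NA)), par,
                                     center = "MIDCITY", age_class = "30-34"),
               tolerance = 1e-10)
  expect_equal(pm$mc_error, 0)
  expect_error(predictive_log_marginal(test_coh[0, ], fit), "empty")
})

test_that("predictive marginal is a log probability and matches brute-force integration", {
  coh <- simulate_cohort(generator_config(n_couples = 220, seed = 55))
  sp <- split_cohort(coh, split_spec(200, 20, seed = 56))
  fit <- fit_mcmc(sp$learning, prior_config(),
                  desk_mcmc_config(seed = 57, n_iterations = 1500, burn_in = 500, thin = 20))
  pm <- predictive_log_marginal(sp$test, fit, quadrature_order = 25)
  expect_lt(pm$log_marginal, 0)

  # brute force: same posterior draws, latents re-integrated by plain MC
  pooled <- do.call(rbind, lapply(1:2, function(ch) fit$draws[, ch, ]))
  colnames(pooled) <- fit$parameters
  cc <- ivfjoint:::.cohort_counts(sp$test)
  set.seed(99)
  nmc <- 4000
  ll_t <- numeric(nrow(pooled))
  for (t in seq_len(nrow(pooled))) {
    pp <- ivfjoint:::.params_from_draw(fit, pooled[t, ])
    f <- rnorm(nmc, 0, pp$sigma_f); e <- rnorm(nmc, 0, pp$sigma_eps)
    tot <- 0
    for (i in seq_len(nrow(cc))) {
      p <- success_probability(cc$center[i], cc$age_class[i], pp, f)
      q <- discontinuation_probability(cc$center[i], cc$age_class[i], pp, f, e)
      lik <- p^cc$k[i] * (1 - p)^(cc$m[i] - cc$k[i]) *
        q^cc$s[i] * (1 - q)^(cc$r[i] - cc$s[i])
      tot <- tot + log(mean(lik))
    }
    ll_t[t] <- tot
  }
  mx <- max(ll_t)
  bf_est <- mx + log(mean(exp(ll_t - mx)))
  expect_equal(pm$log_marginal, bf_est, tolerance = max(0.05, 2 * pm$mc_error))
})

test_that("identical null and alternative models give L near zero", {
  coh <- simulate_cohort(generator_config(n_couples = 400, seed = 60))
  bf <- partial_bayes_factor(coh, "MIDCITY", split_spec(300, 100, seed = 61),
                             prior_config(),
                             desk_mcmc_config(seed = 62, n_iterations = 2500, burn_in = 500),
                             alt_fix_lambda = c(midcity = 0))
  expect_equal(bf$category, classify_evidence(bf$L))
  expect_equal(bf$bf, exp(bf$L / 2))
  expect_lt(abs(bf$L), max(6 * bf$mc_error, 0.6))
})

test_that("sensitivity analysis reduces to single runs and is seed-deterministic", {
  coh <- simulate_cohort(generator_config(n_couples = 300, seed = 70))
  sp <- split_spec(240, 60, seed = 71)
  mc <- desk_mcmc_config(seed = 72, n_iterations = 1200, burn_in = 300, thin = 6)
  sens <- bf_sensitivity(coh, "MIDCITY", prior_variants = list(prior_config()),
                         splits = list(sp), mcmc = mc)
  expect_length(sens, 1)
  mc1 <- mc; mc1$seed <- mc$seed + 10L
  single <- partial_bayes_factor(coh, "MIDCITY", sp, prior_config(), mc1)
  expect_equal(sens[[1]]$L, single$L)
  expect_true(is.logical(attr(sens, "stable")))
  expect_error(bf_sensitivity(coh, "MIDCITY", prior_variants = list(),
                              splits = list(sp)), "non-empty")
})
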