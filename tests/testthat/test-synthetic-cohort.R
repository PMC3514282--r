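test_that("default parameters carry the reported estimates and calibrated intercepts", {
  p <- default_paper_params()
  expect_equal(p$lambda_midcity, -0.21)
  expect_equal(p$lambda_paris, 0)
  expect_equal(p$beta_center_disc, log(0.55))
  expect_equal(p$beta_center_succ, log(0.97))
  expect_equal(unname(p$beta_age_disc[">=40"]), log(2.9))
  expect_equal(p$sigma_f, 1)
  expect_equal(p$sigma_eps, 0.5)

  er <- expected_rates(p)
  pa <- er$per_attempt
  first_paris <- pa[pa$center == "PARIS" & pa$attempt == 1, ]
  expect_equal(first_paris$live_birth_rate, 0.22, tolerance = 1e-6)
  expect_equal(first_paris$discontinuation_rate, 0.37, tolerance = 1e-6)
})

test_that("degenerate probabilities produce the forced one-attempt histories", {
  # success probability driven to 1
  p1 <- model_params(alpha_succ = Inf, sigma_f = 0, sigma_eps = 0)
  set.seed(1)
  h <- simulate_couple("PARIS", "30-34", p1)
  expect_equal(nrow(h), 1)
  expect_equal(h$success, 1L)
  expect_true(is.na(h$discontinued))

  # certain failure then certain discontinuation
  p2 <- model_params(alpha_succ = -Inf, alpha_disc = Inf, sigma_f = 0, sigma_eps = 0)
  h <- simulate_couple("MIDCITY", ">=40", p2)
  expect_equal(nrow(h), 1)
  expect_equal(h$success, 0L)
  expect_equal(h$discontinued, 1L)

  bad <- model_params()
  bad$sigma_f <- -1
  expect_error(simulate_couple("PARIS", "30-34", bad), "scales")
})

test_that("with zero latent scales history frequencies match the closed-form tree", {
  p <- model_params(alpha_succ = qlogis(0.3), alpha_disc = qlogis(0.35),
                    sigma_f = 0, sigma_eps = 0)
  n <- 1e5
  one_age <- matrix(rep(c(0, 0, 1, 0, 0), 2), ncol = 2,
                    dimnames = list(age_classes(), centers()))
  coh <- simulate_cohort(generator_config(
    n_couples = n, params = p, seed = 77,
    center_fractions = c(PARIS = 1, MIDCITY = 0),
    age_distribution = one_age))
  cc <- ivfjoint:::.cohort_counts(coh)
  emp <- table(paste(cc$m, cc$k, cc$s)) / n
  tree <- enumerate_history_tree()
  for (h in tree) {
    m <- nrow(h); k <- sum(h$success); s <- sum(h$discontinued, na.rm = TRUE)
    prob <- exp(couple_history_loglik(h, p, center = "PARIS", age_class = "30-34"))
    key <- paste(m, k, s)
    got <- if (key %in% names(emp)) as.numeric(emp[key]) else 0
    se <- sqrt(prob * (1 - prob) / n)
    expect_lt(abs(got - prob), 3 * se + 1e-12)
  }
})

test_that("cohort simulation is seed-reproducible and respects the margins", {
  cfg <- generator_config(n_couples = 20000, seed = 31)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))

  frac <- mean(a$center[!duplicated(a$couple_id)] == "PARIS")
  want <- 1556 / 3002
  expect_lt(abs(frac - want), 3 * sqrt(want * (1 - want) / 20000))

  expect_error(generator_config(n_couples = 0), "n_couples")
})

test_that("shared-latent structure drives the success-dropout association", {
  # lambda = 0 in both centers and sigma_eps = 0: conditional independence,
  # so the dropout decision carries no information about the latent f
  p0 <- model_params(alpha_succ = qlogis(0.25), alpha_disc = qlogis(0.3),
                     sigma_f = 1, sigma_eps = 0)
  coh <- simulate_cohort(generator_config(n_couples = 40000, params = p0, seed = 13))
  lat <- attr(coh, "latents")
  first <- coh[coh$attempt == 1 & coh$success == 0, ]
  f1 <- lat$f[match(first$couple_id, lat$couple_id)]
  r <- cor(f1, first$discontinued)
  expect_lt(abs(r), 3 / sqrt(nrow(first)))

  # negative loading: discontinuers among first-attempt failures have lower f
  pneg <- model_params(alpha_succ = qlogis(0.25), alpha_disc = qlogis(0.3),
                       sigma_f = 1, sigma_eps = 0.5,
                       lambda_paris = -0.6, lambda_midcity = -0.6)
  coh2 <- simulate_cohort(generator_config(n_couples = 40000, params = pneg, seed = 14))
  lat2 <- attr(coh2, "latents")
  first2 <- coh2[coh2$attempt == 1 & coh2$success == 0, ]
  f2 <- lat2$f[match(first2$couple_id, lat2$couple_id)]
  expect_lt(mean(f2[first2$discontinued == 1]), mean(f2[first2$discontinued == 0]))
})

test_that("expected_rates has its closed forms and matches large simulations", {
  # p = pi = 0.5, degenerate latents
  p <- model_params(sigma_f = 0, sigma_eps = 0)
  er <- expected_rates(p)
  expect_equal(er$per_attempt$live_birth_rate, rep(0.5, 8))
  expect_equal(er$per_attempt$discontinuation_rate[c(1:3, 5:7)], rep(0.5, 6))
  expect_equal(er$per_attempt$reach[er$per_attempt$attempt == 2], rep(0.25, 2))

  # the dropout probability cannot influence the first-attempt birth rate
  p2 <- p
  p2$alpha_disc <- 2
  er2 <- expected_rates(p2)
  expect_equal(er2$per_attempt$live_birth_rate[er2$per_attempt$attempt == 1],
               er$per_attempt$live_birth_rate[er$per_attempt$attempt == 1])

  # monotone in the success intercept
  phi <- default_paper_params()
  phi$alpha_succ <- phi$alpha_succ + 0.5
  expect_true(all(expected_rates(phi)$per_attempt$live_birth_rate >
                    expected_rates(default_paper_params())$per_attempt$live_birth_rate))

  # simulation agreement at the default parameters
  coh <- simulate_cohort(generator_config(n_couples = 2e5, seed = 99))
  ar <- attempt_rates(coh)
  er3 <- expected_rates(default_paper_params())
  for (cen in centers()) {
    for (j in 1:3) {
      for (ms in c("live_birth", "discontinuation")) {
        row <- ar[ar$center == cen & ar$attempt == j & ar$measure == ms, ]
        th <- er3$per_attempt[er3$per_attempt$center == cen &
                                er3$per_attempt$attempt == j, ]
        want <- if (ms == "live_birth") th$live_birth_rate else th$discontinuation_rate
        se <- sqrt(want * (1 - want) / row$at_risk)
        expect_lt(abs(row$rate - want), 3 * se + 2e-3)
      }
    }
  }
})
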