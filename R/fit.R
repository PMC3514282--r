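#' MCMC configuration
#'
#' Defaults are the study protocol: two independent chains of 300,000
#' iterations with a burn-in of 50,000 and every 100th draw kept, i.e.
#' retained samples of size 5,000. [desk_mcmc_config()] is a light preset
#' (2 x 6,000, burn-in 1,000, thin 5) suitable for simulation studies and
#' tests.
#'
#' @param n_chains Number of chains (>= 2 for between-chain diagnostics).
#' @param n_iterations Iterations per chain.
#' @param burn_in Burn-in iterations discarded per chain (< `n_iterations`).
#' @param thin Keep every `thin`-th post-burn-in draw (>= 1).
#' @param seed Integer master seed; chain c uses `seed + c - 1`.
#' @param init_spread Scale of the chain-specific offsets of the initial
#'   values around the prior mean.
#' @return Object of class `ivf_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2, n_iterations = 300000, burn_in = 50000,
                        thin = 100, seed = 1, init_spread = 1) {
  if (n_chains < 1) stop("n_chains must be >= 1", call. = FALSE)
  if (burn_in >= n_iterations) stop("burn_in must be < n_iterations", call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  if (init_spread <= 0) stop("init_spread must be > 0", call. = FALSE)
  if (abs(seed) > 2^31 - 10) stop("seed too large", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), init_spread = init_spread),
            class = "ivf_mcmc_config")
}

#' @rdname mcmc_config
#' @export
desk_mcmc_config <- function(seed = 1, n_chains = 2, n_iterations = 6000,
                             burn_in = 1000, thin = 5, init_spread = 1) {
  mcmc_config(n_chains = n_chains, n_iterations = n_iterations,
              burn_in = burn_in, thin = thin, seed = seed,
              init_spread = init_spread)
}

.param_names <- function(covariates) {
  nm_s <- "alpha_succ"
  nm_d <- "alpha_disc"
  if ("age" %in% covariates) {
    nm_s <- c(nm_s, sprintf("beta_age_succ[%s]", .NONREF_AGES))
    nm_d <- c(nm_d, sprintf("beta_age_disc[%s]", .NONREF_AGES))
  }
  if ("center" %in% covariates) {
    nm_s <- c(nm_s, "beta_center_succ")
    nm_d <- c(nm_d, "beta_center_disc")
  }
  list(succ = nm_s, disc = nm_d,
       all = c(nm_s, nm_d, "lambda_paris", "lambda_midcity", "sigma_f", "sigma_eps"))
}

.build_design <- function(counts, covariates) {
  n <- nrow(counts)
  X <- matrix(1, n, 1)
  if ("age" %in% covariates) {
    for (a in .NONREF_AGES) X <- cbind(X, as.numeric(counts$age_class == a))
  }
  if ("center" %in% covariates) X <- cbind(X, as.numeric(counts$center == "MIDCITY"))
  X
}

#' Fit the joint model by MCMC
#'
#' Data-augmented Gibbs sampler: every Bernoulli observation is augmented
#' with a Polya-Gamma variable, making the conditionals of all regression
#' coefficients, loadings and couple latents Gaussian; the latent scales move
#' by adaptive random-walk Metropolis on the log scale. Each chain starts
#' from chain-specific initial values (prior mean offset by
#' `+/- c * init_spread`) and its own seed, so runs are reproducible.
#'
#' @param cohort Non-empty [ivf_cohort()]. Every age class and center level
#'   used as a covariate must be present (otherwise the effect is
#'   inestimable and an error is raised).
#' @param prior A [prior_config()]. Use a `"fixed"` family to pin `sigma_f`
#'   or `sigma_eps` (e.g. `sigma_eps = 0` switches the disturbance off).
#' @param config An [mcmc_config()].
#' @param covariates Fixed effects to include (default age and center;
#'   `character(0)` fits intercept-only equations).
#' @param fix_lambda Optional named numeric, e.g. `c(midcity = 0)`, fixing a
#'   center's loading (used by the Bayes-factor null model).
#' @param save_latent Keep the per-couple latent factor draws.
#' @return Object of class `ivf_fit`: retained draws indexed (draw, chain,
#'   parameter), the configuration, per-parameter Brooks-Gelman R-hat, and
#'   sampler acceptance rates.
#' @export
fit_mcmc <- function(cohort, prior = prior_config(), config = mcmc_config(),
                     covariates = c("age", "center"), fix_lambda = NULL,
                     save_latent = FALSE) {
  stopifnot(inherits(cohort, "ivf_cohort"), inherits(prior, "ivf_prior"),
            inherits(config, "ivf_mcmc_config"))
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  if (length(covariates) > 0)
    covariates <- match.arg(covariates, c("age", "center"), several.ok = TRUE)
  else covariates <- character(0)

  cc <- .cohort_counts(cohort)
  if ("age" %in% covariates) {
    absent <- setdiff(age_classes(), unique(cc$age_class))
    if (length(absent) > 0)
      stop("age class absent from cohort (effect inestimable): ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  if ("center" %in% covariates) {
    absent <- setdiff(centers(), unique(cc$center))
    if (length(absent) > 0)
      stop("center absent from cohort (effect inestimable): ",
           paste(absent, collapse = ", "), call. = FALSE)
  }

  Xs <- .build_design(cc, covariates)
  Xd <- Xs # same covariate structure in both equations
  nm <- .param_names(covariates)

  if (!is.null(fix_lambda)) {
    bad <- setdiff(names(fix_lambda), c("paris", "midcity"))
    if (length(bad) > 0) stop("fix_lambda names must be 'paris'/'midcity'", call. = FALSE)
  }
  est_lam_p <- !"paris" %in% names(fix_lambda)
  est_lam_m <- !"midcity" %in% names(fix_lambda)
  lam_p_fix <- if (est_lam_p) 0 else unname(fix_lambda["paris"])
  lam_m_fix <- if (est_lam_m) 0 else unname(fix_lambda["midcity"])

  est_sf <- prior$sigma_f_prior$family == "halfnormal"
  est_se <- prior$sigma_eps_prior$family == "halfnormal"
  sf_fix <- if (est_sf) 0 else prior$sigma_f_prior$value
  se_fix <- if (est_se) 0 else prior$sigma_eps_prior$value
  hn_f <- if (est_sf) prior$sigma_f_prior$sd else 1
  hn_e <- if (est_se) prior$sigma_eps_prior$sd else 1

  # likelihood at the central starting point must be finite
  p0 <- plogis(Xs %*% rep(0, ncol(Xs)))
  ll0 <- cc$k * log(p0) + (cc$m - cc$k) * log1p(-p0)
  if (any(!is.finite(ll0)))
    stop("non-finite likelihood at initialization for couple ",
         cc$couple_id[which(!is.finite(ll0))[1]], call. = FALSE)

  n_keep <- (config$n_iterations - config$burn_in) %/% config$thin
  draws <- array(NA_real_, c(n_keep, config$n_chains, length(nm$all)),
                 dimnames = list(NULL, paste0("chain", seq_len(config$n_chains)),
                                 nm$all))
  acc <- matrix(NA_real_, config$n_chains, 2,
                dimnames = list(NULL, c("sigma_f", "sigma_eps")))
  latent <- if (save_latent) vector("list", config$n_chains) else NULL

  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    off <- (-1)^ch * ch * config$init_spread * 0.5
    beta_s0 <- rep(off, ncol(Xs))
    beta_d0 <- rep(-off, ncol(Xd))
    lam0 <- off * 0.2
    sig_f0 <- if (est_sf) exp(off * 0.3) else sf_fix
    sig_e0 <- if (est_se) exp(-off * 0.3) else se_fix
    res <- .gibbs_joint_cpp(Xs, Xd, cc$m, cc$k, cc$r, cc$s,
                            as.numeric(cc$center == "MIDCITY"),
                            as.integer(est_lam_p), as.integer(est_lam_m),
                            lam_p_fix, lam_m_fix,
                            as.integer(est_sf), sf_fix,
                            as.integer(est_se), se_fix,
                            prior$fixed_effect_sd, hn_f, hn_e,
                            config$n_iterations, config$burn_in, config$thin,
                            beta_s0, beta_d0, lam0, lam0, sig_f0, sig_e0,
                            save_latent)
    draws[, ch, ] <- res$draws
    acc[ch, ] <- c(res$accept_sigma_f, res$accept_sigma_eps)
    if (save_latent) latent[[ch]] <- res$latent_f
  }

  rhat <- apply(draws, 3, function(d) {
    if (ncol(d) < 2 || all(apply(d, 2, sd) == 0)) return(NA_real_)
    gelman_rubin(d)
  })
  structure(list(draws = draws, parameters = nm$all, config = config,
                 prior = prior, covariates = covariates,
                 fix_lambda = fix_lambda, rhat = rhat,
                 acceptance = acc, n_couples = nrow(cc),
                 couple_ids = cc$couple_id,
                 latent_f = latent),
            class = "ivf_fit")
}

#' @export
print.ivf_fit <- function(x, ...) {
  cat(sprintf("Joint-model fit: %d couples, %d chains x %d kept draws\n",
              x$n_couples, dim(x$draws)[2], dim(x$draws)[1]))
  cat(sprintf("  max R-hat: %.3f\n", max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Retained posterior draws of one parameter
#'
#' @param fit An [fit_mcmc()] result.
#' @param parameter Parameter name (see `fit$parameters`).
#' @param pooled Pool chains into one vector (default) or keep the
#'   draws-by-chain matrix.
#' @return Numeric vector or matrix.
#' @export
posterior_draws <- function(fit, parameter, pooled = TRUE) {
  stopifnot(inherits(fit, "ivf_fit"))
  if (!parameter %in% fit$parameters)
    stop("unknown parameter: ", parameter, call. = FALSE)
  d <- fit$draws[, , parameter, drop = TRUE]
  d <- matrix(d, nrow = dim(fit$draws)[1])
  if (pooled) as.vector(d) else d
}

#' Posterior summary table
#'
#' Means, standard deviations, equal-tailed quantiles and Brooks-Gelman
#' R-hat for every parameter, from the pooled retained draws.
#'
#' @param fit An [fit_mcmc()] result.
#' @return Data frame, one row per parameter.
#' @export
posterior_summary <- function(fit) {
  stopifnot(inherits(fit, "ivf_fit"))
  rows <- lapply(fit$parameters, function(pm) {
    d <- posterior_draws(fit, pm)
    q <- quantile(d, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
    data.frame(parameter = pm, mean = mean(d), sd = sd(d),
               q2.5 = q[1], q25 = q[2], median = q[3], q75 = q[4],
               q97.5 = q[5], rhat = unname(fit$rhat[pm]))
  })
  do.call(rbind, rows)
}

#' Posterior odds-ratio summary of a coefficient
#'
#' Exponentiates the pooled retained draws of a logit-scale coefficient and
#' reports the empirical quantiles at probabilities 0.025, 0.25, 0.5, 0.75,
#' 0.975 (the boxplot summary used for reporting) together with the
#' posterior mean odds ratio.
#'
#' @param fit An [fit_mcmc()] result.
#' @param coefficient Coefficient name, e.g. `"beta_center_disc"` or
#'   `"beta_age_disc[>=40]"`.
#' @return Object of class `ivf_or`: list with `coefficient`, `quantiles`,
#'   `mean`, `reference`.
#' @export
or_summary <- function(fit, coefficient) {
  stopifnot(inherits(fit, "ivf_fit"))
  if (!coefficient %in% fit$parameters)
    stop("unknown coefficient: ", coefficient, call. = FALSE)
  or <- exp(posterior_draws(fit, coefficient))
  qs <- quantile(or, c(0.025, 0.25, 0.5, 0.75, 0.975))
  ref <- if (grepl("center", coefficient)) "PARIS"
         else if (grepl("age", coefficient)) AGE_REFERENCE
         else "baseline"
  structure(list(coefficient = coefficient, quantiles = qs, mean = mean(or),
                 reference = ref), class = "ivf_or")
}

#' @export
print.ivf_or <- function(x, ...) {
  cat(sprintf("Odds ratio for %s (reference %s)\n", x$coefficient, x$reference))
  cat(sprintf("  median %.2f, mean %.2f, 95%% CrI [%.2f, %.2f]\n",
              x$quantiles[3], x$mean, x$quantiles[1], x$quantiles[5]))
  invisible(x)
}

#' Autocorrelation of retained draws
#'
#' Mean (across chains) autocorrelation of the retained draws at the given
#' lags, per parameter; the study protocol thins precisely to keep these
#' small.
#'
#' @param fit An [fit_mcmc()] result.
#' @param lags Integer lags (default 1:10).
#' @return Matrix parameters x lags.
#' @export
posterior_autocorr <- function(fit, lags = 1:10) {
  stopifnot(inherits(fit, "ivf_fit"))
  mx <- max(lags)
  out <- t(vapply(fit$parameters, function(pm) {
    d <- posterior_draws(fit, pm, pooled = FALSE)
    if (sd(as.vector(d)) == 0) return(rep(NA_real_, length(lags)))
    ac <- rowMeans(vapply(seq_len(ncol(d)), function(ch)
      as.vector(acf(d[, ch], lag.max = mx, plot = FALSE)$acf)[lags + 1],
      numeric(length(lags))))
    ac
  }, numeric(length(lags))))
  colnames(out) <- paste0("lag", lags)
  out
}
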