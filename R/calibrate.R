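#' Baseline margins of the two-center study population
#'
#' Center sizes (1,556 Parisian / 1,446 medium-sized city couples of 3,002)
#' and the per-center age-class distribution at the first aspiration, as
#' percentages of each center converted to fractions.
#'
#' @return List with `center_fractions` (named over centers, sums to 1) and
#'   `age_distribution` (5 x 2 matrix, age classes x centers, columns sum
#'   to 1).
#' @export
table1_margins <- function() {
  age <- cbind(PARIS = c(0.02, 0.21, 0.39, 0.29, 0.09),
               MIDCITY = c(0.03, 0.27, 0.41, 0.23, 0.06))
  rownames(age) <- age_classes()
  list(center_fractions = c(PARIS = 1556 / 3002, MIDCITY = 1446 / 3002),
       age_distribution = age)
}

#' Deterministic per-attempt and cumulative rates implied by the model
#'
#' Integrates the latent factors by Gauss-Hermite quadrature and averages
#' over the age margin of each center to obtain the marginal per-attempt
#' live-birth rate (among couples undergoing the attempt) and discontinuation
#' rate (among couples failing the attempt, attempts 1-3), the fraction of
#' couples reaching each attempt, and cumulative rates. Used as the
#' calibration oracle for the synthetic-cohort generator: the computation is
#' deterministic, so intercepts can be root-found against target rates.
#'
#' @param params A [model_params()].
#' @param margins Center/age margins as from [table1_margins()].
#' @param f_order,eps_order Quadrature orders for the two latent dimensions.
#' @return Object of class `ivf_expected_rates`: list with `per_attempt`
#'   (center, attempt, reach, live_birth_rate, discontinuation_rate as
#'   proportions) and `cumulative` (per center and overall).
#' @export
expected_rates <- function(params, margins = table1_margins(),
                           f_order = 40, eps_order = 20) {
  stopifnot(inherits(params, "ivf_params"))
  gh <- .gh_rule(f_order)
  fs <- if (params$sigma_f > 0) params$sigma_f * gh$x else 0
  wf <- if (params$sigma_f > 0) gh$w else 1
  ghe <- .gh_rule(eps_order)
  es <- if (params$sigma_eps > 0) params$sigma_eps * ghe$x else 0
  we <- if (params$sigma_eps > 0) ghe$w else 1

  per <- NULL
  cum <- NULL
  for (cen in centers()) {
    ages <- age_classes()
    wage <- margins$age_distribution[ages, cen]
    # accumulators over the (age, f, eps) mixture
    reach_num <- live_num <- fail_num <- disc_num <- numeric(4)
    cum_live <- cum_disc <- 0
    for (a in seq_along(ages)) {
      # full (f, eps) grid: both latents are constant across a couple's
      # attempts, so survival must be computed per node, not on averages
      p <- success_probability(cen, ages[a], params, f = fs)        # length F
      P <- matrix(p, length(fs), length(es))
      PI <- outer(fs, es, function(f, e)
        discontinuation_probability(cen, ages[a], params, f = f, eps = e))
      wgt <- wage[a] * outer(wf, we)
      reach <- matrix(1, length(fs), length(es))
      for (j in 1:4) {
        reach_num[j] <- reach_num[j] + sum(wgt * reach)
        live_num[j] <- live_num[j] + sum(wgt * reach * P)
        cum_live <- cum_live + sum(wgt * reach * P)
        if (j <= 3) {
          fail_num[j] <- fail_num[j] + sum(wgt * reach * (1 - P))
          disc_num[j] <- disc_num[j] + sum(wgt * reach * (1 - P) * PI)
          cum_disc <- cum_disc + sum(wgt * reach * (1 - P) * PI)
        }
        reach <- reach * (1 - P) * (1 - PI)
      }
    }
    per <- rbind(per, data.frame(
      center = cen, attempt = 1:4, reach = reach_num,
      live_birth_rate = live_num / reach_num,
      discontinuation_rate = c((disc_num / fail_num)[1:3], NA)))
    cum <- rbind(cum, data.frame(center = cen, live_birth = cum_live,
                                 discontinuation = cum_disc))
  }
  wc <- margins$center_fractions[cum$center]
  cum <- rbind(cum, data.frame(center = "OVERALL",
                               live_birth = sum(wc * cum$live_birth),
                               discontinuation = sum(wc * cum$discontinuation)))
  structure(list(per_attempt = per, cumulative = cum, margins = margins),
            class = "ivf_expected_rates")
}

#' @export
print.ivf_expected_rates <- function(x, ...) {
  cat("Model-implied rates (proportions)\n")
  print(transform(x$per_attempt, reach = round(reach, 3),
                  live_birth_rate = round(live_birth_rate, 3),
                  discontinuation_rate = round(discontinuation_rate, 3)),
        row.names = FALSE)
  cat("Cumulative:\n")
  print(transform(x$cumulative, live_birth = round(live_birth, 3),
                  discontinuation = round(discontinuation, 3)), row.names = FALSE)
  invisible(x)
}

#' Calibrate the intercepts to first-attempt target rates
#'
#' One-dimensional root-finds setting `alpha_succ` so that the marginalized
#' (quadrature-integrated, age-averaged) first-attempt live-birth rate in the
#' Parisian center hits its target, then `alpha_disc` likewise for the
#' first-attempt discontinuation rate among Parisian failures. Root-finding
#' against the marginal rate is needed because with `sigma_f > 0` the
#' logistic nonlinearity biases the naive logit-of-rate intercept.
#'
#' @param params Starting [model_params()]; all other fields are kept.
#' @param targets Named vector `c(success = ..., discontinuation = ...)` of
#'   first-attempt Parisian proportions.
#' @param margins Margins as from [table1_margins()].
#' @return `params` with calibrated intercepts.
#' @export
calibrate_intercepts <- function(params,
                                 targets = c(success = 0.22, discontinuation = 0.37),
                                 margins = table1_margins()) {
  first_rates <- function(p) {
    er <- expected_rates(p, margins)
    pa <- er$per_attempt
    c(success = pa$live_birth_rate[pa$center == "PARIS" & pa$attempt == 1],
      discontinuation = pa$discontinuation_rate[pa$center == "PARIS" & pa$attempt == 1])
  }
  p <- params
  p$alpha_succ <- uniroot(function(a) {
    p$alpha_succ <- a
    first_rates(p)["success"] - targets["success"]
  }, c(-8, 4), tol = 1e-9)$root
  p$alpha_disc <- uniroot(function(a) {
    p$alpha_disc <- a
    first_rates(p)["discontinuation"] - targets["discontinuation"]
  }, c(-8, 4), tol = 1e-9)$root
  p
}

#' Default generator parameters calibrated to the two-center study
#'
#' Returns the parameter set the synthetic-cohort generator uses by default:
#' the loading of the medium-sized city center at its reported posterior mean
#' (-0.21) and the Parisian loading at 0; center effects at the log of the
#' reported odds ratios (success 0.97, discontinuation 0.55); the
#' discontinuation effect of the oldest age class at log(2.9); the remaining
#' age effects at illustrative values chosen once to reproduce the inverse-J
#' (success) and J (discontinuation) age shapes; latent scales sigma_f = 1 and
#' sigma_eps = 0.5; and intercepts calibrated by [calibrate_intercepts()] so
#' the marginal first-attempt Parisian live-birth and discontinuation rates
#' are 22% and 37%. The result is memoized.
#'
#' @return A calibrated [model_params()].
#' @export
#' @examples
#' p <- default_paper_params()
#' p$lambda_midcity # -0.21
default_paper_params <- function() {
  if (!is.null(.ivfjoint_cache$default_params)) return(.ivfjoint_cache$default_params)
  base <- model_params(
    alpha_succ = qlogis(0.22), alpha_disc = qlogis(0.37),
    # illustrative non-reference age effects (log odds ratios vs 30-34)
    beta_age_succ = c("<25" = log(0.90), "25-29" = log(1.15),
                      "35-39" = log(0.65), ">=40" = log(0.35)),
    beta_age_disc = c("<25" = log(1.30), "25-29" = log(1.10),
                      "35-39" = log(1.60), ">=40" = log(2.9)),
    beta_center_succ = log(0.97),
    beta_center_disc = log(0.55),
    lambda_paris = 0, lambda_midcity = -0.21,
    sigma_f = 1, sigma_eps = 0.5)
  out <- calibrate_intercepts(base)
  .ivfjoint_cache$default_params <- out
  out
}
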