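.NONREF_AGES <- c("<25", "25-29", "35-39", ">=40")

#' Model parameters
#'
#' All parameters of the shared random-effects joint model on the logit
#' scale. The success equation is
#' `logit(p_i) = alpha_succ + beta_age_succ[age_i] + beta_center_succ * mid_i + f_i`
#' and the discontinuation equation is
#' `logit(pi_i) = alpha_disc + beta_age_disc[age_i] + beta_center_disc * mid_i +
#' lambda_{center_i} * f_i + eps_i`, with `f_i ~ N(0, sigma_f^2)` and
#' `eps_i ~ N(0, sigma_eps^2)` drawn once per couple. Reference levels
#' (`"30-34"`, `"PARIS"`) have effect 0 by construction; the age-effect
#' vectors are named over the four non-reference classes.
#'
#' @param alpha_succ,alpha_disc Intercepts (logit scale).
#' @param beta_age_succ,beta_age_disc Named numeric vectors over
#'   `c("<25","25-29","35-39",">=40")`.
#' @param beta_center_succ,beta_center_disc Effects of the medium-sized city
#'   center versus the Parisian reference.
#' @param lambda_paris,lambda_midcity Center-specific loadings of the shared
#'   latent factor in the discontinuation equation. A negative loading means
#'   the unmeasured couple-level factor raises success while lowering
#'   discontinuation (opposite impacts).
#' @param sigma_f Scale of the shared latent factor (must be >= 0; > 0 to
#'   enable the latent structure).
#' @param sigma_eps Scale of the couple-level discontinuation disturbance
#'   (>= 0).
#' @return An object of class `ivf_params`.
#' @export
#' @examples
#' p <- model_params(alpha_succ = qlogis(0.22))
#' success_probability("PARIS", "30-34", p, f = 0)
model_params <- function(alpha_succ = 0, alpha_disc = 0,
                         beta_age_succ = c("<25" = 0, "25-29" = 0, "35-39" = 0, ">=40" = 0),
                         beta_age_disc = c("<25" = 0, "25-29" = 0, "35-39" = 0, ">=40" = 0),
                         beta_center_succ = 0, beta_center_disc = 0,
                         lambda_paris = 0, lambda_midcity = 0,
                         sigma_f = 1, sigma_eps = 0.5) {
  chk_age <- function(b, nm) {
    if (!is.numeric(b) || is.null(names(b)) || !setequal(names(b), .NONREF_AGES))
      stop(nm, " must be a numeric vector named over ",
           paste(.NONREF_AGES, collapse = ", "), call. = FALSE)
    b[.NONREF_AGES]
  }
  sc1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x))
      stop(nm, " must be a single number", call. = FALSE)
    as.numeric(x)
  }
  p <- list(
    alpha_succ = sc1(alpha_succ, "alpha_succ"),
    alpha_disc = sc1(alpha_disc, "alpha_disc"),
    beta_age_succ = chk_age(beta_age_succ, "beta_age_succ"),
    beta_age_disc = chk_age(beta_age_disc, "beta_age_disc"),
    beta_center_succ = sc1(beta_center_succ, "beta_center_succ"),
    beta_center_disc = sc1(beta_center_disc, "beta_center_disc"),
    lambda_paris = sc1(lambda_paris, "lambda_paris"),
    lambda_midcity = sc1(lambda_midcity, "lambda_midcity"),
    sigma_f = sc1(sigma_f, "sigma_f"),
    sigma_eps = sc1(sigma_eps, "sigma_eps")
  )
  if (p$sigma_f < 0) stop("sigma_f must be >= 0", call. = FALSE)
  if (p$sigma_eps < 0) stop("sigma_eps must be >= 0", call. = FALSE)
  structure(p, class = "ivf_params")
}

#' @export
print.ivf_params <- function(x, ...) {
  cat("Joint-model parameters (logit scale)\n")
  cat(sprintf("  success:         alpha = %7.3f  center(MIDCITY) = %7.3f\n",
              x$alpha_succ, x$beta_center_succ))
  cat(sprintf("  discontinuation: alpha = %7.3f  center(MIDCITY) = %7.3f\n",
              x$alpha_disc, x$beta_center_disc))
  cat("  age effects (ref 30-34):\n")
  cat(sprintf("    success: %s\n", paste(sprintf("%s=%.3f", names(x$beta_age_succ),
                                                 x$beta_age_succ), collapse = "  ")))
  cat(sprintf("    disc:    %s\n", paste(sprintf("%s=%.3f", names(x$beta_age_disc),
                                                 x$beta_age_disc), collapse = "  ")))
  cat(sprintf("  loadings: lambda_paris = %.3f  lambda_midcity = %.3f\n",
              x$lambda_paris, x$lambda_midcity))
  cat(sprintf("  scales:   sigma_f = %.3f  sigma_eps = %.3f\n", x$sigma_f, x$sigma_eps))
  invisible(x)
}

#' Serialize model parameters to YAML or JSON
#'
#' The format is chosen from the file extension (`.yaml`/`.yml` or `.json`);
#' field names match the `ivf_params` fields exactly.
#'
#' @param params An [model_params()] object.
#' @param path Output (or input) file path.
#' @export
write_model_params <- function(params, path) {
  stopifnot(inherits(params, "ivf_params"))
  obj <- lapply(unclass(params), function(x) if (length(x) > 1) as.list(x) else x)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(obj, path, precision = 15L)
  } else if (ext == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported extension: ", ext, call. = FALSE)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported extension: ", ext, call. = FALSE)
  obj$beta_age_succ <- unlist(obj$beta_age_succ)
  obj$beta_age_disc <- unlist(obj$beta_age_disc)
  do.call(model_params, obj)
}

#' Prior configuration
#'
#' Independent priors: Normal(0, `fixed_effect_sd`^2) on both intercepts, all
#' age and center effects and both loadings; half-normal priors on the two
#' latent scales, or a fixed value (family `"fixed"`) to switch a scale off
#' (e.g. `sigma_eps = 0`). `informativeness_level` tags the variant used by
#' the Bayes-factor sensitivity analysis.
#'
#' @param fixed_effect_sd Prior standard deviation for all fixed effects and
#'   loadings (default 10, weakly informative on the logit scale).
#' @param sigma_f_prior,sigma_eps_prior Lists `list(family = "halfnormal",
#'   sd = ...)` or `list(family = "fixed", value = ...)`.
#' @param informativeness_level Free-text tag (`"default"`, `"more"`, `"less"`).
#' @return An object of class `ivf_prior`.
#' @export
prior_config <- function(fixed_effect_sd = 10,
                         sigma_f_prior = list(family = "halfnormal", sd = 1),
                         sigma_eps_prior = list(family = "halfnormal", sd = 1),
                         informativeness_level = "default") {
  chk <- function(pr, nm) {
    if (!is.list(pr) || is.null(pr$family)) stop(nm, " must be a list with a 'family'", call. = FALSE)
    if (pr$family == "halfnormal") {
      if (is.null(pr$sd) || pr$sd <= 0) stop(nm, ": halfnormal needs sd > 0", call. = FALSE)
    } else if (pr$family == "fixed") {
      if (is.null(pr$value) || pr$value < 0) stop(nm, ": fixed needs value >= 0", call. = FALSE)
    } else stop(nm, ": unknown family '", pr$family, "'", call. = FALSE)
    pr
  }
  if (!is.numeric(fixed_effect_sd) || fixed_effect_sd <= 0)
    stop("fixed_effect_sd must be > 0", call. = FALSE)
  structure(list(fixed_effect_sd = as.numeric(fixed_effect_sd),
                 sigma_f_prior = chk(sigma_f_prior, "sigma_f_prior"),
                 sigma_eps_prior = chk(sigma_eps_prior, "sigma_eps_prior"),
                 informativeness_level = informativeness_level),
            class = "ivf_prior")
}

#' Prior variants for the sensitivity analysis
#'
#' Scales all prior standard deviations by 0.1 (`"more"` informative) or 10
#' (`"less"` informative) relative to the default.
#'
#' @param level One of `"default"`, `"more"`, `"less"`.
#' @param base Prior to rescale.
#' @return An `ivf_prior`.
#' @export
prior_config_variant <- function(level = c("default", "more", "less"),
                                 base = prior_config()) {
  level <- match.arg(level)
  fac <- switch(level, default = 1, more = 0.1, less = 10)
  scale_pr <- function(pr) {
    if (pr$family == "halfnormal") pr$sd <- pr$sd * fac
    pr
  }
  prior_config(fixed_effect_sd = base$fixed_effect_sd * fac,
               sigma_f_prior = scale_pr(base$sigma_f_prior),
               sigma_eps_prior = scale_pr(base$sigma_eps_prior),
               informativeness_level = level)
}

#' Log prior density
#'
#' Sum of the independent log prior densities of all parameters under a
#' [prior_config()]. Scales outside their support (`sigma_f <= 0` when
#' estimated, `sigma_eps < 0`) give `-Inf`; a scale with a `"fixed"` family
#' contributes 0 (point mass).
#'
#' @param params [model_params()] values at which to evaluate.
#' @param prior [prior_config()].
#' @return Log density (scalar).
#' @export
log_prior <- function(params, prior = prior_config()) {
  stopifnot(inherits(params, "ivf_params"), inherits(prior, "ivf_prior"))
  fe <- c(params$alpha_succ, params$alpha_disc,
          params$beta_age_succ, params$beta_age_disc,
          params$beta_center_succ, params$beta_center_disc,
          params$lambda_paris, params$lambda_midcity)
  lp <- sum(dnorm(fe, 0, prior$fixed_effect_sd, log = TRUE))
  lhalf <- function(x, pr, strict_pos) {
    if (pr$family == "fixed") return(0)
    if ((strict_pos && x <= 0) || (!strict_pos && x < 0)) return(-Inf)
    log(2) + dnorm(x, 0, pr$sd, log = TRUE)
  }
  lp + lhalf(params$sigma_f, prior$sigma_f_prior, strict_pos = TRUE) +
    lhalf(params$sigma_eps, prior$sigma_eps_prior, strict_pos = FALSE)
}
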