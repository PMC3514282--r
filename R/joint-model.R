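# linear predictors of the two equations (without the latent terms)
.lin_succ <- function(center, age_class, params) {
  age_class <- .normalize_age(age_class)
  b_age <- ifelse(age_class == AGE_REFERENCE, 0, params$beta_age_succ[age_class])
  params$alpha_succ + as.numeric(b_age) +
    params$beta_center_succ * as.numeric(center == "MIDCITY")
}

.lin_disc <- function(center, age_class, params) {
  age_class <- .normalize_age(age_class)
  b_age <- ifelse(age_class == AGE_REFERENCE, 0, params$beta_age_disc[age_class])
  params$alpha_disc + as.numeric(b_age) +
    params$beta_center_disc * as.numeric(center == "MIDCITY")
}

.lambda_for <- function(center, params) {
  ifelse(center == "MIDCITY", params$lambda_midcity, params$lambda_paris)
}

#' Per-attempt success and discontinuation probabilities
#'
#' `success_probability()` is the inverse logit of the success linear
#' predictor plus the shared latent factor `f`; `discontinuation_probability()`
#' adds the center-specific loading times `f` and the couple disturbance
#' `eps`. Both are vectorized over `f` (and `eps`) and strictly increasing in
#' their latent arguments' coefficients.
#'
#' @param center `"PARIS"` or `"MIDCITY"`.
#' @param age_class One of [age_classes()] (`"17-24"` accepted for `"<25"`).
#' @param params A [model_params()].
#' @param f Shared latent factor value(s).
#' @param eps Discontinuation disturbance value(s).
#' @return Probabilities in (0, 1).
#' @export
#' @examples
#' success_probability("PARIS", "30-34", model_params(), f = 0) # 0.5
success_probability <- function(center, age_class, params, f = 0) {
  stopifnot(inherits(params, "ivf_params"))
  plogis(.lin_succ(center, age_class, params) + f)
}

#' @rdname success_probability
#' @export
discontinuation_probability <- function(center, age_class, params, f = 0, eps = 0) {
  stopifnot(inherits(params, "ivf_params"))
  plogis(.lin_disc(center, age_class, params) + .lambda_for(center, params) * f + eps)
}

# Bernoulli log likelihood from sufficient counts, vectorized over (p, pi)
.loglik_counts <- function(m, k, r, s, p, pi) {
  term <- function(cnt, lp) if (cnt == 0) 0 else cnt * lp
  term(k, log(p)) + term(m - k, log1p(-p)) +
    term(s, log(pi)) + term(r - s, log1p(-pi))
}

#' Conditional log likelihood of one couple's history
#'
#' Log probability of the observed attempt sequence given the couple's latent
#' values: a Bernoulli success term for every attempt undergone plus, for each
#' failed attempt among the first three, a Bernoulli term for the observed
#' continuation decision. Censored failed fourth attempts contribute only the
#' success term. Probabilities are constant across a couple's attempts, so the
#' result depends on the history only through its sufficient counts.
#'
#' @param history One couple's rows (columns `attempt`, `success`,
#'   `discontinued`, plus `center`/`age_class`, or pass `center`/`age_class`
#'   explicitly).
#' @param params A [model_params()].
#' @param f,eps Latent values (vectorized; recycled together).
#' @param center,age_class Covariates, read from `history` when present.
#' @return Log probability (<= 0), same length as `f`.
#' @export
couple_history_loglik <- function(history, params, f = 0, eps = 0,
                                  center = NULL, age_class = NULL) {
  stopifnot(inherits(params, "ivf_params"))
  v <- validate_history(history)
  if (length(v) > 0)
    stop("invalid history: ", paste(v, collapse = "; "), call. = FALSE)
  if (is.null(center)) center <- as.character(history$center[1])
  if (is.null(age_class)) age_class <- as.character(history$age_class[1])
  if (length(center) != 1 || is.na(center) || length(age_class) != 1 || is.na(age_class))
    stop("center and age_class must be available", call. = FALSE)
  m <- nrow(history)
  k <- sum(history$success)
  r <- sum(!is.na(history$discontinued))
  s <- sum(history$discontinued, na.rm = TRUE)
  p <- success_probability(center, age_class, params, f)
  pi <- discontinuation_probability(center, age_class, params, f, eps)
  .loglik_counts(m, k, r, s, p, pi)
}

# Gauss-Hermite rule rescaled for N(0, sigma^2): nodes sigma*sqrt(2)*x,
# weights w/sqrt(pi). Memoized.
.gh_rule <- function(order) {
  key <- paste0("gh", order)
  if (is.null(.ivfjoint_cache[[key]])) {
    gh <- pracma::gaussHermite(order)
    .ivfjoint_cache[[key]] <- list(x = gh$x * sqrt(2), w = gh$w / sqrt(pi))
  }
  .ivfjoint_cache[[key]]
}

#' Marginal log likelihood of a history (latents integrated out)
#'
#' Integrates `exp(couple_history_loglik)` against the product of
#' `N(0, sigma_f^2)` and `N(0, sigma_eps^2)` by Gauss-Hermite product
#' quadrature. Zero scales collapse the corresponding dimension, so with
#' `sigma_f = sigma_eps = 0` this equals the conditional log likelihood at
#' `f = eps = 0`.
#'
#' @inheritParams couple_history_loglik
#' @param quadrature_order Number of nodes per dimension (>= 1; default 30).
#' @return Log marginal probability (scalar, <= 0).
#' @export
marginal_couple_loglik <- function(history, params, quadrature_order = 30,
                                   center = NULL, age_class = NULL) {
  stopifnot(quadrature_order >= 1)
  if (is.null(center)) center <- as.character(history$center[1])
  if (is.null(age_class)) age_class <- as.character(history$age_class[1])
  gh <- .gh_rule(quadrature_order)
  fs <- if (params$sigma_f > 0) params$sigma_f * gh$x else 0
  wf <- if (params$sigma_f > 0) gh$w else 1
  es <- if (params$sigma_eps > 0) params$sigma_eps * gh$x else 0
  we <- if (params$sigma_eps > 0) gh$w else 1
  grid <- expand.grid(f = fs, e = es)
  wts <- as.vector(outer(wf, we))
  ll <- couple_history_loglik(history, params, f = grid$f, eps = grid$e,
                              center = center, age_class = age_class)
  mx <- max(ll)
  mx + log(sum(wts * exp(ll - mx)))
}

#' Enumerate the complete tree of possible attempt histories
#'
#' The discrete-time process has 8 terminal histories: a live birth at attempt
#' 1-4, a failure followed by discontinuation at attempt 1-3, and a censored
#' failure at attempt 4. Their conditional probabilities sum to 1 for any
#' parameter values and latents, which the test suite asserts by enumeration.
#'
#' @return List of data frames (`attempt`, `success`, `discontinued`), one per
#'   terminal history.
#' @export
enumerate_history_tree <- function() {
  out <- list()
  for (j in 1:4) out[[paste0("success_at_", j)]] <- .history_from_counts(j, 1L, j - 1L, 0L)
  for (j in 1:3) out[[paste0("discontinue_at_", j)]] <- .history_from_counts(j, 0L, j, 1L)
  out[["censored_at_4"]] <- .history_from_counts(4L, 0L, 3L, 0L)
  out
}
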