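#' Split specification for partial Bayes factors
#'
#' A seeded, uniformly random partition of a cohort into a learning sample
#' (which plays the role of the prior-updating data) and a test sample on
#' which the partial Bayes factor is evaluated.
#'
#' @param n_learning,n_test Sizes; must sum to the cohort size when used.
#' @param seed Integer seed of the partition.
#' @return Object of class `ivf_split`.
#' @export
split_spec <- function(n_learning, n_test, seed = 1) {
  if (n_learning < 1 || n_test < 1)
    stop("both split sizes must be >= 1", call. = FALSE)
  structure(list(n_learning = as.integer(n_learning), n_test = as.integer(n_test),
                 seed = as.integer(seed)), class = "ivf_split")
}

#' The study's three splits, scaled to a cohort size
#'
#' Learning samples of 2,702 / 1,502 / 502 of 3,002 couples (test samples of
#' 300 / 1,500 / 2,500); for other cohort sizes the same learning fractions
#' are applied and rounded.
#'
#' @param n_total Cohort size.
#' @param seeds Three partition seeds.
#' @return List of three [split_spec()]s.
#' @export
paper_splits <- function(n_total = 3002, seeds = c(101, 102, 103)) {
  stopifnot(length(seeds) == 3)
  frac <- c(2702, 1502, 502) / 3002
  lapply(seq_along(frac), function(i) {
    nl <- round(frac[i] * n_total)
    split_spec(nl, n_total - nl, seeds[i])
  })
}

#' Split a cohort into learning and test samples
#'
#' Disjoint, exhaustive, uniformly random over couples; reproducible given
#' the split seed.
#'
#' @param cohort An [ivf_cohort()].
#' @param spec A [split_spec()] whose sizes sum to `n_couples(cohort)`.
#' @return List with `learning` and `test` cohorts.
#' @export
split_cohort <- function(cohort, spec) {
  stopifnot(inherits(cohort, "ivf_cohort"), inherits(spec, "ivf_split"))
  ids <- unique(cohort$couple_id)
  if (spec$n_learning + spec$n_test != length(ids))
    stop(sprintf("split sizes (%d + %d) do not match cohort size (%d)",
                 spec$n_learning, spec$n_test, length(ids)), call. = FALSE)
  set.seed(spec$seed)
  learn_ids <- sample(ids, spec$n_learning)
  sub <- function(keep) {
    df <- as.data.frame(cohort)[cohort$couple_id %in% keep, , drop = FALSE]
    rownames(df) <- NULL
    class(df) <- c("ivf_cohort", "data.frame")
    df
  }
  list(learning = sub(learn_ids), test = sub(setdiff(ids, learn_ids)))
}

#' Classify partial-Bayes-factor evidence
#'
#' Evidence rule on the `L = 2 log BF` scale (null over alternative):
#' `L > -2` gives no evidence that the loading differs from 0, `-6 < L <= -2`
#' a significant difference, `L <= -6` a strong one.
#'
#' @param L Finite numeric value of 2 log BF.
#' @return `"NO_EVIDENCE"`, `"SIGNIFICANT"` or `"STRONG"`.
#' @export
#' @examples
#' classify_evidence(2.70)  # NO_EVIDENCE
#' classify_evidence(-5.26) # SIGNIFICANT
classify_evidence <- function(L) {
  if (!is.numeric(L) || length(L) != 1 || !is.finite(L))
    stop("L must be a single finite number", call. = FALSE)
  if (L <= -6) "STRONG" else if (L <= -2) "SIGNIFICANT" else "NO_EVIDENCE"
}

# group a cohort's couples into distinct (center, age, m, k, r, s) history
# types; the marginal likelihood depends only on these
.history_types <- function(cohort) {
  cc <- .cohort_counts(cohort)
  key <- paste(cc$center, cc$age_class, cc$m, cc$k, cc$r, cc$s)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, " ", fixed = TRUE)
  data.frame(center = vapply(parts, `[`, "", 1),
             age_class = vapply(parts, `[`, "", 2),
             m = as.integer(vapply(parts, `[`, "", 3)),
             k = as.integer(vapply(parts, `[`, "", 4)),
             r = as.integer(vapply(parts, `[`, "", 5)),
             s = as.integer(vapply(parts, `[`, "", 6)),
             count = agg$Freq, stringsAsFactors = FALSE)
}

# params list for one posterior draw of a fit
.params_from_draw <- function(fit, draw) {
  gv <- function(nm, default = 0) if (nm %in% fit$parameters) unname(draw[nm]) else default
  age_s <- age_d <- setNames(rep(0, 4), .NONREF_AGES)
  for (a in .NONREF_AGES) {
    age_s[a] <- gv(sprintf("beta_age_succ[%s]", a))
    age_d[a] <- gv(sprintf("beta_age_disc[%s]", a))
  }
  model_params(alpha_succ = gv("alpha_succ"), alpha_disc = gv("alpha_disc"),
               beta_age_succ = age_s, beta_age_disc = age_d,
               beta_center_succ = gv("beta_center_succ"),
               beta_center_disc = gv("beta_center_disc"),
               lambda_paris = unname(draw["lambda_paris"]),
               lambda_midcity = unname(draw["lambda_midcity"]),
               sigma_f = unname(draw["sigma_f"]),
               sigma_eps = unname(draw["sigma_eps"]))
}

#' Posterior-predictive log marginal likelihood of a test cohort
#'
#' Monte-Carlo average, over the retained posterior draws of a
#' learning-sample fit, of the test cohort's marginal likelihood (latents
#' integrated per couple by Gauss-Hermite product quadrature). Computed in
#' log space; the deterministic inner integral isolates the Monte-Carlo
#' error to the posterior-draw average, whose standard error is returned.
#'
#' @param test Non-empty test [ivf_cohort()].
#' @param posterior An [fit_mcmc()] result on the learning sample.
#' @param quadrature_order Gauss-Hermite order per latent dimension.
#' @return List (class `ivf_predml`) with `log_marginal`, `mc_error`,
#'   `n_draws`.
#' @export
predictive_log_marginal <- function(test, posterior, quadrature_order = 20) {
  stopifnot(inherits(posterior, "ivf_fit"))
  if (nrow(test) == 0) stop("test cohort is empty", call. = FALSE)
  types <- .history_types(test)
  gh <- .gh_rule(quadrature_order)

  nkeep <- dim(posterior$draws)[1]
  nch <- dim(posterior$draws)[2]
  pooled <- do.call(rbind, lapply(seq_len(nch), function(ch)
    posterior$draws[, ch, , drop = TRUE]))
  colnames(pooled) <- posterior$parameters
  Tn <- nrow(pooled)

  # per-type covariate combos
  combos <- unique(types[, c("center", "age_class")])
  type_combo <- match(paste(types$center, types$age_class),
                      paste(combos$center, combos$age_class))
  is_mid <- as.numeric(combos$center == "MIDCITY")
  age_mat_s <- vapply(.NONREF_AGES, function(a) as.numeric(combos$age_class == a),
                      numeric(nrow(combos)))

  loglik_t <- numeric(Tn)
  for (t in seq_len(Tn)) {
    pp <- .params_from_draw(posterior, pooled[t, ])
    fs <- if (pp$sigma_f > 0) pp$sigma_f * gh$x else 0
    wf <- if (pp$sigma_f > 0) gh$w else 1
    es <- if (pp$sigma_eps > 0) pp$sigma_eps * gh$x else 0
    we <- if (pp$sigma_eps > 0) gh$w else 1
    eta <- .lin_succ(combos$center, combos$age_class, pp)
    zeta <- .lin_disc(combos$center, combos$age_class, pp)
    lam <- ifelse(is_mid == 1, pp$lambda_midcity, pp$lambda_paris)
    # P: combos x F ; PI: combos x F x E collapsed over eps patterns below
    P <- plogis(outer(eta, fs, `+`))
    tot <- 0
    for (ty in seq_len(nrow(types))) {
      cb <- type_combo[ty]
      pvec <- P[cb, ]
      sfac <- pvec^types$k[ty] * (1 - pvec)^(types$m[ty] - types$k[ty])
      if (types$r[ty] > 0) {
        PIcb <- plogis(outer(zeta[cb] + lam[cb] * fs, es, `+`))
        dmat <- PIcb^types$s[ty] * (1 - PIcb)^(types$r[ty] - types$s[ty])
        dfac <- as.vector(dmat %*% we)
      } else dfac <- 1
      lik <- sum(wf * sfac * dfac)
      tot <- tot + types$count[ty] * log(lik)
    }
    loglik_t[t] <- tot
  }
  mx <- max(loglik_t)
  w <- exp(loglik_t - mx)
  logm <- mx + log(mean(w))
  mc_err <- sd(w) / (mean(w) * sqrt(Tn))
  structure(list(log_marginal = logm, mc_error = mc_err, n_draws = Tn),
            class = "ivf_predml")
}

#' Partial Bayes factor test of a center's loading
#'
#' Fits the full model M1 (both loadings free) and the null model M0 (the
#' tested center's loading fixed at 0) on the learning sample, then compares
#' their posterior-predictive marginal likelihoods on the held-out test
#' sample: `L = 2 [log m0(test) - log m1(test)]`, so negative L is evidence
#' that the loading differs from 0. The learning-sample posterior plays the
#' role of the prior, avoiding improper-prior indeterminacy.
#'
#' @param cohort Full [ivf_cohort()].
#' @param tested Center whose loading is tested (`"MIDCITY"` or `"PARIS"`).
#' @param spec A [split_spec()].
#' @param prior A [prior_config()].
#' @param mcmc An [mcmc_config()]; M0 uses `seed + 1`.
#' @param quadrature_order Gauss-Hermite order for the test-couple integrals.
#' @param alt_fix_lambda Optional constraint applied to the alternative model
#'   as well (diagnostic hook; fixing the tested loading to 0 in both models
#'   makes M0 and M1 identical and L should be 0 up to Monte-Carlo error).
#' @return Object of class `ivf_bf`: `L`, `bf = exp(L/2)`, evidence
#'   `category`, `tested_loading`, `split`, `mc_error`.
#' @export
partial_bayes_factor <- function(cohort, tested = c("MIDCITY", "PARIS"), spec,
                                 prior = prior_config(), mcmc = desk_mcmc_config(),
                                 quadrature_order = 20, alt_fix_lambda = NULL) {
  tested <- match.arg(tested)
  halves <- split_cohort(cohort, spec)
  key <- if (tested == "MIDCITY") "midcity" else "paris"
  null_fix <- c(setNames(0, key), alt_fix_lambda)
  null_fix <- null_fix[!duplicated(names(null_fix))]

  m1 <- fit_mcmc(halves$learning, prior, mcmc, fix_lambda = alt_fix_lambda)
  mcmc0 <- mcmc
  mcmc0$seed <- mcmc$seed + 1L
  m0 <- fit_mcmc(halves$learning, prior, mcmc0, fix_lambda = null_fix)

  pm1 <- predictive_log_marginal(halves$test, m1, quadrature_order)
  pm0 <- predictive_log_marginal(halves$test, m0, quadrature_order)
  L <- 2 * (pm0$log_marginal - pm1$log_marginal)
  mc_err <- 2 * sqrt(pm0$mc_error^2 + pm1$mc_error^2)
  structure(list(L = L, bf = exp(L / 2), category = classify_evidence(L),
                 tested_loading = tested, split = spec, mc_error = mc_err,
                 log_marginal_null = pm0$log_marginal,
                 log_marginal_alt = pm1$log_marginal,
                 prior_level = prior$informativeness_level),
            class = "ivf_bf")
}

#' @export
print.ivf_bf <- function(x, ...) {
  cat(sprintf("Partial Bayes factor for lambda_%s = 0 (split %d/%d, prior '%s')\n",
              tolower(x$tested_loading), x$split$n_learning, x$split$n_test,
              x$prior_level))
  cat(sprintf("  L = 2 log BF = %.2f (mc error %.2f) -> %s\n",
              x$L, x$mc_error, x$category))
  invisible(x)
}

#' Bayes-factor sensitivity analysis
#'
#' Recomputes the partial Bayes factor for every combination of prior
#' variant and split specification (one MCMC run each) and flags whether the
#' evidence category is stable across combinations.
#'
#' @param cohort Full [ivf_cohort()].
#' @param tested Center whose loading is tested.
#' @param prior_variants Non-empty list of [prior_config()]s.
#' @param splits Non-empty list of [split_spec()]s (default: the study's
#'   three, scaled to the cohort size).
#' @param mcmc An [mcmc_config()].
#' @param quadrature_order Passed to [predictive_log_marginal()].
#' @return List of [partial_bayes_factor()] results (class
#'   `ivf_bf_sensitivity`) with attribute `stable`.
#' @export
bf_sensitivity <- function(cohort, tested = c("MIDCITY", "PARIS"),
                           prior_variants = lapply(c("default", "more", "less"),
                                                   prior_config_variant),
                           splits = paper_splits(n_couples(cohort)),
                           mcmc = desk_mcmc_config(), quadrature_order = 20) {
  tested <- match.arg(tested)
  if (length(prior_variants) == 0 || length(splits) == 0)
    stop("prior_variants and splits must be non-empty", call. = FALSE)
  out <- list()
  i <- 0
  for (pr in prior_variants) {
    for (sp in splits) {
      i <- i + 1
      mc <- mcmc
      mc$seed <- mcmc$seed + 10L * i
      out[[i]] <- partial_bayes_factor(cohort, tested, sp, pr, mc, quadrature_order)
    }
  }
  cats <- vapply(out, function(b) b$category, "")
  structure(out, stable = length(unique(cats)) == 1,
            class = c("ivf_bf_sensitivity", "list"))
}

#' @export
print.ivf_bf_sensitivity <- function(x, ...) {
  cat("Partial-BF sensitivity analysis\n")
  for (b in x)
    cat(sprintf("  prior %-8s split %4d/%-4d  L = %7.2f  %s\n",
                b$prior_level, b$split$n_learning, b$split$n_test, b$L, b$category))
  cat(sprintf("category stable across runs: %s\n", attr(x, "stable")))
  invisible(x)
}
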