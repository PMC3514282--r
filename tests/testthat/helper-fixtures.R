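# small deterministic fixtures used across test files

# one couple's rows as a data frame
history_df <- function(attempt, success, discontinued) {
  data.frame(attempt = attempt, success = success, discontinued = discontinued)
}

# cohort built from a list of histories plus covariates
cohort_from_histories <- function(histories, center, age_class) {
  rows <- do.call(rbind, lapply(seq_along(histories), function(i) {
    h <- histories[[i]]
    data.frame(couple_id = sprintf("c%04d", i), center = center[i],
               age_class = age_class[i], h)
  }))
  ivf_cohort(rows)
}

# the 4-couple worked example: two births at attempt 1, one immediate
# discontinuation, one couple failing twice then discontinuing
four_couple_cohort <- function() {
  cohort_from_histories(
    list(history_df(1, 1, NA),
         history_df(1, 1, NA),
         history_df(1, 0, 1),
         history_df(1:2, c(0, 0), c(0, 1))),
    center = rep("PARIS", 4), age_class = rep("30-34", 4))
}

# random valid model parameters (bounded, for property loops)
random_params <- function() {
  model_params(
    alpha_succ = runif(1, -2, 1), alpha_disc = runif(1, -2, 1),
    beta_age_succ = setNames(runif(4, -1, 1), c("<25", "25-29", "35-39", ">=40")),
    beta_age_disc = setNames(runif(4, -1, 1), c("<25", "25-29", "35-39", ">=40")),
    beta_center_succ = runif(1, -1, 1), beta_center_disc = runif(1, -1, 1),
    lambda_paris = runif(1, -1, 1), lambda_midcity = runif(1, -1, 1),
    sigma_f = runif(1, 0.2, 1.5), sigma_eps = runif(1, 0, 1))
}

# minimal posterior object for summarization tests: draws [kept x chains x p]
fake_fit <- function(draw_list) {
  p <- length(draw_list)
  nk <- length(draw_list[[1]]) / 2
  draws <- array(NA_real_, c(nk, 2, p),
                 dimnames = list(NULL, c("chain1", "chain2"), names(draw_list)))
  for (i in seq_len(p)) draws[, , i] <- draw_list[[i]]
  structure(list(draws = draws, parameters = names(draw_list),
                 rhat = setNames(rep(NA_real_, p), names(draw_list))),
            class = "ivf_fit")
}
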