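#' Generator configuration
#'
#' Defaults reproduce the study conditions: 3,002 couples, the two-center
#' split and per-center age distributions of the baseline table, and
#' [default_paper_params()].
#'
#' @param n_couples Number of couples (>= 1).
#' @param center_fractions Named fractions per center, summing to 1.
#' @param age_distribution 5 x 2 matrix (age classes x centers), columns
#'   summing to 1.
#' @param params [model_params()] used for the event process.
#' @param seed Integer seed; the whole cohort is reproducible given it.
#' @return Object of class `ivf_generator_config`.
#' @export
generator_config <- function(n_couples = 3002,
                             center_fractions = table1_margins()$center_fractions,
                             age_distribution = table1_margins()$age_distribution,
                             params = default_paper_params(),
                             seed = 20120803) {
  if (!is.numeric(n_couples) || n_couples < 1)
    stop("n_couples must be >= 1", call. = FALSE)
  if (!setequal(names(center_fractions), centers()) ||
      abs(sum(center_fractions) - 1) > 1e-8)
    stop("center_fractions must be named over the centers and sum to 1", call. = FALSE)
  if (!all(rownames(age_distribution) == age_classes()) ||
      any(abs(colSums(age_distribution[, centers(), drop = FALSE]) - 1) > 1e-8))
    stop("age_distribution columns must cover the age classes and sum to 1", call. = FALSE)
  stopifnot(inherits(params, "ivf_params"))
  structure(list(n_couples = as.integer(n_couples),
                 center_fractions = center_fractions[centers()],
                 age_distribution = age_distribution[age_classes(), centers()],
                 params = params, seed = as.integer(seed)),
            class = "ivf_generator_config")
}

# vectorized discrete-time engine; consumes the current RNG stream.
# Draw order per couple block: f, eps, then per attempt the success draws for
# couples still at risk, then the discontinuation draws among their failures.
.simulate_histories <- function(center, age_class, params, id_prefix = "c") {
  if (params$sigma_f < 0 || params$sigma_eps < 0)
    stop("latent scales must be >= 0", call. = FALSE)
  n <- length(center)
  f <- rnorm(n, 0, params$sigma_f)
  eps <- rnorm(n, 0, params$sigma_eps)
  p <- plogis(.lin_succ(center, age_class, params) + f)
  pi <- plogis(.lin_disc(center, age_class, params) + .lambda_for(center, params) * f + eps)

  rows <- vector("list", 4)
  active <- seq_len(n)
  for (j in 1:4) {
    if (length(active) == 0) break
    succ <- rbinom(length(active), 1L, p[active])
    disc <- rep(NA_integer_, length(active))
    fail <- succ == 0L
    if (j <= 3 && any(fail))
      disc[fail] <- rbinom(sum(fail), 1L, pi[active][fail])
    rows[[j]] <- data.frame(i = active, attempt = j, success = succ,
                            discontinued = disc)
    active <- active[fail & !is.na(disc) & disc == 0L]
  }
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  df <- df[order(df$i, df$attempt), ]
  ids <- sprintf("%s%0*d", id_prefix, max(5L, nchar(n)), seq_len(n))
  out <- data.frame(couple_id = ids[df$i],
                    center = center[df$i],
                    age_class = age_class[df$i],
                    attempt = df$attempt,
                    success = df$success,
                    discontinued = df$discontinued,
                    stringsAsFactors = FALSE)
  attr(out, "latents") <- data.frame(couple_id = ids, center = center,
                                     age_class = age_class, f = f, eps = eps)
  out
}

#' Simulate a single couple's history
#'
#' Draws the couple's latent pair (`f`, `eps`) once, then walks the attempt
#' tree: per attempt a success draw; after a failure at attempts 1-3 a
#' discontinuation draw; a failed fourth attempt ends censored. Uses the
#' current RNG stream (seed with `set.seed()`). The couple's latent values
#' are attached as attributes `f` and `eps`.
#'
#' @param center,age_class Covariates of the couple.
#' @param params A [model_params()] (latent scales must be >= 0).
#' @return Data frame of the couple's attempt rows; passes
#'   [validate_history()].
#' @export
#' @examples
#' set.seed(1)
#' simulate_couple("PARIS", "30-34", default_paper_params())
simulate_couple <- function(center, age_class, params) {
  stopifnot(inherits(params, "ivf_params"))
  age_class <- .normalize_age(age_class)
  stopifnot(center %in% centers(), age_class %in% age_classes())
  df <- .simulate_histories(center, age_class, params)
  lat <- attr(df, "latents")
  out <- df[, c("attempt", "success", "discontinued")]
  out$center <- center
  out$age_class <- age_class
  attr(out, "f") <- lat$f
  attr(out, "eps") <- lat$eps
  out
}

#' Simulate a cohort
#'
#' Draws each couple's center and age class from the configured margins, then
#' simulates attempt histories with [simulate_couple()]'s engine. Fully
#' reproducible given `config$seed`. The generated latent values are attached
#' as `attr(cohort, "latents")`.
#'
#' @param config A [generator_config()].
#' @return An [ivf_cohort()].
#' @export
#' @examples
#' coh <- simulate_cohort(generator_config(n_couples = 200, seed = 7))
#' coh
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "ivf_generator_config"))
  set.seed(config$seed)
  n <- config$n_couples
  cen <- sample(centers(), n, replace = TRUE, prob = config$center_fractions)
  age <- character(n)
  for (cc in centers()) {
    idx <- which(cen == cc)
    if (length(idx) > 0)
      age[idx] <- sample(age_classes(), length(idx), replace = TRUE,
                         prob = config$age_distribution[, cc])
  }
  df <- .simulate_histories(cen, age, config$params)
  lat <- attr(df, "latents")
  cohort <- ivf_cohort(df)
  attr(cohort, "latents") <- lat
  cohort
}
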