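# half-up rounding (printed tables use integers; R's round() is banker's)
.round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Per-attempt live-birth and discontinuation rates by center
#'
#' The live-birth denominator at attempt j is the number of couples
#' undergoing attempt j; the discontinuation denominator is the number of
#' couples failing attempt j (attempts 1-3 only; failed fourth attempts are
#' censored and no discontinuation rate is defined for them). Percentages are
#' rounded half-up to `digits` for display; full-precision proportions are
#' kept in the `rate` column. Rates with a zero denominator are `NaN`.
#'
#' @param cohort Non-empty [ivf_cohort()].
#' @param digits Display rounding for the `pct` column (default 0, matching
#'   the printed tables).
#' @return Object of class `ivf_rate_table`: data frame with columns
#'   `center`, `attempt`, `measure`, `events`, `at_risk`, `rate`, `pct`.
#' @export
attempt_rates <- function(cohort, digits = 0) {
  df <- as.data.frame(cohort)
  if (nrow(df) == 0) stop("cohort is empty", call. = FALSE)
  out <- NULL
  for (cen in centers()) {
    for (j in 1:4) {
      rows <- df[df$center == cen & df$attempt == j, , drop = FALSE]
      lb_n <- nrow(rows)
      lb_e <- sum(rows$success)
      out <- rbind(out, data.frame(center = cen, attempt = j,
                                   measure = "live_birth",
                                   events = lb_e, at_risk = lb_n,
                                   rate = lb_e / lb_n))
      if (j <= 3) {
        fl <- rows[rows$success == 0, , drop = FALSE]
        d_n <- sum(!is.na(fl$discontinued))
        d_e <- sum(fl$discontinued, na.rm = TRUE)
        out <- rbind(out, data.frame(center = cen, attempt = j,
                                     measure = "discontinuation",
                                     events = d_e, at_risk = d_n,
                                     rate = d_e / d_n))
      }
    }
  }
  out$pct <- .round_half_up(100 * out$rate, digits)
  structure(out, class = c("ivf_rate_table", "data.frame"))
}

#' @export
print.ivf_rate_table <- function(x, ...) {
  for (ms in unique(x$measure)) {
    cat(sprintf("%s rate (%%)\n", tools::toTitleCase(gsub("_", " ", ms))))
    sub <- x[x$measure == ms, ]
    for (j in sort(unique(sub$attempt))) {
      row <- sub[sub$attempt == j, ]
      cells <- sprintf("%s %s (%d/%d)", row$center,
                       ifelse(is.nan(row$pct), "--", format(row$pct)),
                       row$events, row$at_risk)
      cat(sprintf("  attempt %d: %s\n", j, paste(cells, collapse = "   ")))
    }
  }
  invisible(x)
}

#' Cumulative live-birth and discontinuation percentages
#'
#' Cumulative live birth: couples with a live birth over all couples.
#' Cumulative discontinuation: couples whose final record is a
#' discontinuation over all couples. Reported by center and overall.
#'
#' @inheritParams attempt_rates
#' @return Data frame (class `ivf_cumulative`) with one row per center plus
#'   `OVERALL`: counts, proportions and half-up-rounded percentages.
#' @export
cumulative_rates <- function(cohort, digits = 0) {
  df <- as.data.frame(cohort)
  if (nrow(df) == 0) stop("cohort is empty", call. = FALSE)
  g <- match(df$couple_id, unique(df$couple_id))
  first <- !duplicated(g)
  ncpl <- sum(first)
  succ <- as.integer(rowsum(df$success, g)[, 1] > 0)
  disc <- as.integer(rowsum(ifelse(is.na(df$discontinued), 0L, df$discontinued), g)[, 1] > 0)
  cen <- df$center[first]
  one <- function(sel, label) {
    n <- sum(sel)
    data.frame(center = label, n = n,
               live_births = sum(succ[sel]), live_birth_rate = sum(succ[sel]) / n,
               discontinuations = sum(disc[sel]),
               discontinuation_rate = sum(disc[sel]) / n)
  }
  out <- rbind(one(cen == "PARIS", "PARIS"),
               one(cen == "MIDCITY", "MIDCITY"),
               one(rep(TRUE, ncpl), "OVERALL"))
  out$live_birth_pct <- .round_half_up(100 * out$live_birth_rate, digits)
  out$discontinuation_pct <- .round_half_up(100 * out$discontinuation_rate, digits)
  structure(out, class = c("ivf_cumulative", "data.frame"))
}

#' Pearson chi-square comparison of two centers
#'
#' Uncorrected Pearson chi-square on a 2 x K contingency table (centers in
#' rows), with K - 1 degrees of freedom. Zero row or column totals are an
#' error.
#'
#' @param counts Matrix of nonnegative integer counts, 2 rows, >= 2 columns.
#' @return List (class `ivf_chisq`) with `statistic`, `df`, `p_value`,
#'   `expected`.
#' @export
#' @examples
#' center_comparison(rbind(c(20, 10), c(10, 20)))
center_comparison <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("counts must have at least 2 rows and 2 columns", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column total", call. = FALSE)
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value), expected = ht$expected),
            class = "ivf_chisq")
}

#' @export
print.ivf_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Baseline age table by center
#'
#' Age-class distribution at the first attempt, as percentages of each
#' center's couples, with the chi-square center comparison.
#'
#' @inheritParams attempt_rates
#' @return List (class `ivf_baseline`) with `counts` (5 x 2), `percentages`
#'   (half-up to `digits`), `statistic`, `df`, `p_value`.
#' @export
baseline_table <- function(cohort, digits = 0) {
  df <- as.data.frame(cohort)
  if (nrow(df) == 0) stop("cohort is empty", call. = FALSE)
  base <- df[df$attempt == 1, ]
  counts <- table(factor(base$age_class, levels = age_classes()),
                  factor(base$center, levels = centers()))
  counts <- matrix(as.integer(counts), nrow = 5,
                   dimnames = list(age_classes(), centers()))
  pct <- sweep(counts, 2, colSums(counts), "/") * 100
  # the chi-square comparison uses only age classes that occur; with fewer
  # than two occupied classes the comparison is undefined
  keep <- rowSums(counts) > 0
  cmp <- if (sum(keep) >= 2) center_comparison(t(counts[keep, , drop = FALSE]))
         else list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
  structure(list(counts = counts,
                 percentages = .round_half_up(pct, digits),
                 statistic = cmp$statistic, df = cmp$df, p_value = cmp$p_value),
            class = "ivf_baseline")
}

#' @export
print.ivf_baseline <- function(x, ...) {
  cat("Age at first attempt (% of center)\n")
  print(x$percentages)
  cat(sprintf("chi-square = %.3f, df = %d, p = %.4g\n", x$statistic, x$df, x$p_value))
  invisible(x)
}
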