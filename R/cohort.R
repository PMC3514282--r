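#' Age classes and centers
#'
#' The woman's age at the first attempt is coded in five classes with
#' `"30-34"` as the reference level for all effect coding; `"17-24"` is
#' accepted on input as an alias for `"<25"`. The two IVF centers are a large
#' Parisian center (`"PARIS"`, the reference level) and a center in a
#' medium-sized city (`"MIDCITY"`).
#'
#' @return Character vector of canonical labels.
#' @export
#' @examples
#' age_classes()
#' centers()
age_classes <- function() c("<25", "25-29", "30-34", "35-39", ">=40")

#' @rdname age_classes
#' @export
centers <- function() c("PARIS", "MIDCITY")

AGE_REFERENCE <- "30-34"
CENTER_REFERENCE <- "PARIS"

.normalize_age <- function(x) {
  x <- trimws(as.character(x))
  x[x == "17-24"] <- "<25"
  x[x %in% c("≥40", ">= 40", "40+")] <- ">=40"
  x
}

#' Construct and validate a cohort
#'
#' A cohort is a long-format table with one row per couple-attempt and columns
#' `couple_id`, `center`, `age_class`, `attempt`, `success`, `discontinued`.
#' Discontinuation is recorded on the row of the failed attempt after which
#' the couple did not return; it is missing (`NA`) after a live birth and for
#' failed fourth attempts (administrative censoring: data collection stops
#' after the fourth aspiration). The constructor orders rows by couple and
#' attempt and checks every couple's history with [validate_history()].
#'
#' @param data Data frame with the six columns above.
#' @return An object of class `ivf_cohort` (a validated data frame).
#' @export
ivf_cohort <- function(data) {
  need <- c("couple_id", "center", "age_class", "attempt", "success", "discontinued")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df <- as.data.frame(data)[need]
  df$couple_id <- as.character(df$couple_id)
  df$center <- as.character(df$center)
  df$age_class <- .normalize_age(df$age_class)
  bad <- setdiff(unique(df$center), centers())
  if (length(bad) > 0)
    stop("unknown center label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$age_class), age_classes())
  if (length(bad) > 0)
    stop("unknown age_class label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  df$attempt <- as.integer(df$attempt)
  df$success <- as.integer(df$success)
  df$discontinued <- as.integer(df$discontinued)
  if (any(is.na(df$attempt)) || any(df$attempt < 1L) || any(df$attempt > 4L))
    stop("attempt must be an integer in 1..4", call. = FALSE)
  if (any(!df$success %in% c(0L, 1L)))
    stop("success must be 0 or 1", call. = FALSE)
  if (any(!is.na(df$discontinued) & !df$discontinued %in% c(0L, 1L)))
    stop("discontinued must be 0, 1 or missing", call. = FALSE)

  df <- df[order(match(df$couple_id, unique(df$couple_id)), df$attempt), ]
  rownames(df) <- NULL

  # per-couple covariates must not vary across rows
  cov_chk <- tapply(paste(df$center, df$age_class),
                    factor(df$couple_id, levels = unique(df$couple_id)),
                    function(x) length(unique(x)))
  if (any(cov_chk > 1))
    stop("center/age_class vary within couple(s): ",
         paste(names(cov_chk)[cov_chk > 1], collapse = ", "), call. = FALSE)

  bad <- .validate_cohort_vectorized(df)
  if (length(bad) > 0)
    stop("invalid attempt histories:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  class(df) <- c("ivf_cohort", "data.frame")
  df
}

# whole-cohort history validation in vectorized form (same rules as
# validate_history, applied to the ordered long table in one pass)
.validate_cohort_vectorized <- function(df) {
  g <- match(df$couple_id, unique(df$couple_id))
  pos <- sequence(tabulate(g))
  n_att <- tabulate(g)[g]
  is_last <- pos == n_att
  suc <- df$success
  dis <- df$discontinued
  att <- df$attempt

  flag <- function(cond, msg) {
    ids <- unique(df$couple_id[cond])
    if (length(ids) == 0) return(character(0))
    paste0(ids, ": ", msg)
  }
  c(flag(att != pos, "non-consecutive attempt indices (must be 1, 2, ... in order)"),
    flag(suc == 1 & !is_last, "record after success (a live birth must end the history)"),
    flag(!is.na(dis) & dis == 1 & !is_last,
         "record after discontinuation (a discontinuation must end the history)"),
    flag(suc == 1 & !is.na(dis),
         "discontinuation recorded on a live-birth attempt (must be missing)"),
    flag(att == 4 & suc == 0 & !is.na(dis),
         "discontinuation recorded on a censored failed fourth attempt (must be missing)"),
    flag(att < 4 & suc == 0 & is.na(dis),
         "missing discontinuation decision on a failed attempt before the fourth"),
    flag(is_last & suc == 0 & att < 4 & !is.na(dis) & dis == 0,
         "history ends with an unresolved failed attempt (neither birth, discontinuation nor censoring)"))
}

#' Validate one couple's attempt history
#'
#' Checks the outcome-sequencing rules of the study design: attempts are
#' numbered consecutively from 1 (at most 4); at most one live birth, which
#' ends the history; a discontinuation ends the history; the discontinuation
#' indicator is missing exactly after a live birth and for a failed fourth
#' attempt; and a failed, non-abandoned attempt before the fourth must be
#' followed by another attempt.
#'
#' @param history Data frame of one couple's rows with columns `attempt`,
#'   `success`, `discontinued` (extra columns are ignored).
#' @return Character vector of violation descriptions; empty if the history
#'   satisfies all invariants. Violations are returned, not raised.
#' @export
#' @examples
#' validate_history(data.frame(attempt = 1:2, success = c(0, 1),
#'                             discontinued = c(0, NA)))
validate_history <- function(history) {
  h <- as.data.frame(history)
  if (nrow(h) == 0) stop("history must contain at least one attempt", call. = FALSE)
  v <- character(0)
  att <- as.integer(h$attempt)
  suc <- as.integer(h$success)
  dis <- as.integer(h$discontinued)
  n <- nrow(h)
  if (!identical(att, seq_len(n)))
    v <- c(v, "non-consecutive attempt indices (must be 1, 2, ... in order)")
  if (n > 4) v <- c(v, "more than four attempts")
  if (sum(suc == 1, na.rm = TRUE) > 1) v <- c(v, "more than one live birth")
  if (any(suc[-n] == 1)) v <- c(v, "record after success (a live birth must end the history)")
  if (any(!is.na(dis[-n]) & dis[-n] == 1))
    v <- c(v, "record after discontinuation (a discontinuation must end the history)")
  if (any(suc == 1 & !is.na(dis)))
    v <- c(v, "discontinuation recorded on a live-birth attempt (must be missing)")
  if (any(att == 4 & suc == 0 & !is.na(dis)))
    v <- c(v, "discontinuation recorded on a censored failed fourth attempt (must be missing)")
  if (any(att < 4 & suc == 0 & is.na(dis)))
    v <- c(v, "missing discontinuation decision on a failed attempt before the fourth")
  last <- n
  if (suc[last] == 0 && att[last] < 4 && !is.na(dis[last]) && dis[last] == 0)
    v <- c(v, "history ends with an unresolved failed attempt (neither birth, discontinuation nor censoring)")
  v
}

#' Read / write a cohort CSV
#'
#' Long format, UTF-8, comma-separated, header required, 0/1 integers for the
#' binary outcomes and an empty field for a missing discontinuation decision.
#' `read_cohort_csv()` reports malformed rows with their file line number and
#' runs full history validation (errors name the offending `couple_id`);
#' `write_cohort_csv()` followed by `read_cohort_csv()` is the identity on any
#' valid cohort.
#'
#' @param path File path.
#' @return `read_cohort_csv()` returns an [ivf_cohort()].
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", na.strings = NULL,
                  fileEncoding = "UTF-8")
  need <- c("couple_id", "center", "age_class", "attempt", "success", "discontinued")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(raw))) {
    line <- i + 1L # header occupies line 1
    row <- raw[i, ]
    if (is.na(row$couple_id) || row$couple_id == "")
      stop(sprintf("line %d: empty couple_id", line), call. = FALSE)
    if (!.normalize_age(row$age_class) %in% age_classes())
      stop(sprintf("line %d: unknown age_class '%s'", line, row$age_class), call. = FALSE)
    if (!row$center %in% centers())
      stop(sprintf("line %d: unknown center '%s'", line, row$center), call. = FALSE)
    if (!grepl("^[1-4]$", row$attempt))
      stop(sprintf("line %d: attempt must be 1-4, got '%s'", line, row$attempt), call. = FALSE)
    if (!row$success %in% c("0", "1"))
      stop(sprintf("line %d: success must be 0 or 1, got '%s'", line, row$success), call. = FALSE)
    if (!row$discontinued %in% c("0", "1", ""))
      stop(sprintf("line %d: discontinued must be 0, 1 or empty, got '%s'",
                   line, row$discontinued), call. = FALSE)
  }
  raw$discontinued[raw$discontinued == ""] <- NA_character_
  ivf_cohort(raw)
}

#' @rdname read_cohort_csv
#' @param cohort An [ivf_cohort()].
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$discontinued <- ifelse(is.na(df$discontinued), "", as.character(df$discontinued))
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Number of couples in a cohort
#' @param cohort An [ivf_cohort()].
#' @return Integer count of distinct couples.
#' @export
n_couples <- function(cohort) length(unique(cohort$couple_id))

#' @export
print.ivf_cohort <- function(x, ...) {
  cat(sprintf("IVF cohort: %d couples, %d attempt records\n",
              n_couples(x), nrow(x)))
  tab <- table(x$center[!duplicated(x$couple_id)])
  cat("  couples per center:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}

# Per-couple sufficient counts for the likelihood: m attempts, k live births,
# r observed continuation decisions, s discontinuations. Probabilities are
# constant across a couple's attempts, so (m, k, r, s) with the covariates
# carry all the information.
.cohort_counts <- function(cohort) {
  df <- as.data.frame(cohort)
  g <- match(df$couple_id, unique(df$couple_id))
  first <- !duplicated(g)
  data.frame(
    couple_id = df$couple_id[first],
    center = df$center[first],
    age_class = df$age_class[first],
    m = as.integer(rowsum(rep(1L, nrow(df)), g)[, 1]),
    k = as.integer(rowsum(df$success, g)[, 1]),
    r = as.integer(rowsum(as.integer(!is.na(df$discontinued)), g)[, 1]),
    s = as.integer(rowsum(ifelse(is.na(df$discontinued), 0L, df$discontinued), g)[, 1]),
    stringsAsFactors = FALSE
  )
}

# rebuild attempt rows from sufficient counts (used by the tree enumeration)
.history_from_counts <- function(m, k, r, s) {
  att <- seq_len(m)
  suc <- c(rep(0L, m - 1L), k)
  dis <- rep(NA_integer_, m)
  if (m > 1L) dis[seq_len(m - 1L)] <- 0L
  if (k == 0L && m < 4L) dis[m] <- s
  if (k == 0L && m == 4L) dis[m] <- NA_integer_
  data.frame(attempt = att, success = suc, discontinued = dis)
}
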