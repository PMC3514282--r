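#' Brooks-Gelman potential scale reduction factor
#'
#' Corrected R-hat for one parameter from two or more chains: the ratio of
#' the pooled-variance estimate to the mean within-chain variance, with the
#' Brooks-Gelman finite-sample degrees-of-freedom correction
#' `(d + 3) / (d + 1)`, where `d` is moment-matched from the sampling
#' variance of the pooled estimate. Values near 1 indicate convergence.
#'
#' @param draws Iterations-by-chains numeric matrix, or a list of equal
#'   length numeric vectors (one per chain).
#' @return The corrected PSRF (scalar).
#' @export
#' @examples
#' set.seed(1)
#' gelman_rubin(cbind(rnorm(1000), rnorm(1000)))
gelman_rubin <- function(draws) {
  if (is.list(draws)) {
    if (length(unique(lengths(draws))) != 1)
      stop("chains must have equal length", call. = FALSE)
    draws <- do.call(cbind, draws)
  }
  draws <- as.matrix(draws)
  m <- ncol(draws)
  n <- nrow(draws)
  if (m < 2) stop("at least two chains are required", call. = FALSE)
  if (n < 2) stop("at least two draws per chain are required", call. = FALSE)

  xbar <- colMeans(draws)
  s2 <- apply(draws, 2, var)
  W <- mean(s2)
  B <- n * var(xbar)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sig2 <- (n - 1) / n * W + B / n
  Vhat <- sig2 + B / (m * n)

  # moment-matched df of the variance estimate (Brooks & Gelman 1998)
  var_V <- ((n - 1) / n)^2 / m * var(s2) +
    ((m + 1) / (m * n))^2 * 2 / (m - 1) * B^2 +
    2 * (m + 1) * (n - 1) / (m * n^2) * n / m *
      (cov(s2, xbar^2) - 2 * mean(xbar) * cov(s2, xbar))
  corr <- if (is.na(var_V) || var_V <= 0) 1 else {
    d <- 2 * Vhat^2 / var_V
    (d + 3) / (d + 1)
  }
  sqrt(corr * Vhat / W)
}
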