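#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino (1970) transformed skewness statistic and the
#' Anscombe-Glynn (1983) transformed kurtosis statistic into the omnibus
#' K2 = Zg1^2 + Zg2^2, referred to a chi-squared distribution with 2
#' degrees of freedom. This is the normality check used to gate the choice
#' between Welch's t-test and the Mann-Whitney test in
#' [univariate_panel()].
#'
#' @param x Numeric vector, n >= 8 (the kurtosis transformation is
#'   unreliable below that).
#' @return List of class `"htest"` with `statistic` (K2), `p.value`, and
#'   the two component z-scores in `estimate`.
#' @export
#' @examples
#' dagostino_pearson(rnorm(30))
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8)
    stop_ctx("D'Agostino-Pearson test requires at least 8 observations, got ",
             n, class = "insufficient_data_error")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0)
    stop_ctx("D'Agostino-Pearson test undefined for constant data",
             class = "validation_error")
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  ## skewness: D'Agostino's transformation to approximate normality
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * asinh(y / alpha)

  ## kurtosis: Anscombe-Glynn's transformation
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - e_b2) / sqrt(var_b2)
  sqrt_beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_beta1 *
    (2 / sqrt_beta1 + sqrt(1 + 4 / sqrt_beta1^2))
  cube <- (1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4)))
  cube_root <- sign(cube) * abs(cube)^(1 / 3)  # real cube root
  z_kurt <- ((1 - 2 / (9 * a)) - cube_root) / sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  structure(list(
    statistic = c(K2 = k2),
    parameter = c(df = 2),
    p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
    estimate = c(z_skewness = z_skew, z_kurtosis = z_kurt),
    method = "D'Agostino-Pearson omnibus normality test",
    data.name = deparse(substitute(x))), class = "htest")
}
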