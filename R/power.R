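# SNP-detection power calculus: non-central chi-square power at a fixed
# significance threshold, squared standardized coefficients, and
# full-vs-down power differences.

#' Critical chi-square value at a significance threshold
#'
#' The (1 - alpha) quantile of the central 1-df chi-square distribution;
#' about 29.7 at the genome-wide threshold 5e-8.
#'
#' @param alpha two-sided significance threshold, in (0, 1).
#' @export
chi2_critical <- function(alpha = 5e-8) {
  stopifnot(alpha > 0, alpha < 1)
  qchisq(alpha, df = 1, lower.tail = FALSE)
}

#' Squared standardized coefficient from a Z statistic
#'
#' Approximates the fraction of trait variance tagged by one SNP as
#' `r2 = Z^2 / N`.
#'
#' @param z association Z statistic (vectorized).
#' @param n (effective) sample size, positive.
#' @export
squared_std_coeff <- function(z, n) {
  if (any(n <= 0)) stop("sample size must be positive")
  z^2 / n
}

#' Power to detect a SNP effect at a significance threshold
#'
#' `1 - F(c; df = 1, ncp = N r2)` with `c` the critical value at `alpha`:
#' the probability that a 1-df association test with non-centrality
#' `lambda = N r2` exceeds the threshold. At `r2 = 0` this equals the test
#' size `alpha`.
#'
#' @param n effective sample size (vectorized).
#' @param r2 squared standardized coefficient, non-negative (vectorized).
#' @param alpha significance threshold (default genome-wide 5e-8).
#' @export
detection_power <- function(n, r2, alpha = 5e-8) {
  if (any(n <= 0)) stop("sample size must be positive")
  if (any(r2 < 0)) stop("r2 must be non-negative")
  pchisq(chi2_critical(alpha), df = 1, ncp = n * r2, lower.tail = FALSE)
}

#' Detection-power difference between full and down-sampled sample sizes
#'
#' @param n_full,n_down effective sample sizes, `n_full >= n_down > 0`.
#' @param r2 squared standardized coefficient.
#' @param alpha significance threshold.
#' @return Power difference in percentage points (full minus down).
#' @export
power_difference <- function(n_full, n_down, r2, alpha = 5e-8) {
  if (any(n_down <= 0) || any(n_full < n_down)) {
    stop("need n_full >= n_down > 0")
  }
  (detection_power(n_full, r2, alpha) - detection_power(n_down, r2, alpha)) * 100
}

#' Detection-power curve over assumed effect sizes
#'
#' The default grid covers magnitudes representative of effects reaching
#' genome-wide significance in recent large-scale GWAS (r2 of 0.003%,
#' 0.004%, 0.005%).
#'
#' @param n effective sample size.
#' @param r2_grid non-negative effect sizes.
#' @param alpha significance threshold.
#' @return data.frame with columns `r2` and `power`.
#' @export
power_curve <- function(n, r2_grid = c(3e-5, 4e-5, 5e-5), alpha = 5e-8) {
  if (!length(r2_grid)) stop("empty effect-size grid")
  data.frame(r2 = r2_grid, power = detection_power(n, r2_grid, alpha))
}
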