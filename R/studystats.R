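#' Two-group power, normal approximation
#'
#' Power of a two-sided two-sample comparison of means under the normal
#' approximation with unequal (Welch-type) group variances:
#' \deqn{power = \Phi\!\left(\frac{\Delta}{\sqrt{sd_1^2/n_1 + sd_2^2/n_2}}
#'   - z_{1-\alpha/2}\right)}
#' For a difference of 7 units with sd 2.5 in both groups of 4 this gives
#' 0.977; as the effect size goes to 0 the power tends to
#' \eqn{\alpha/2} and as it grows the power tends to 1.
#'
#' @param delta absolute difference of means (>= 0), any consistent unit
#' @param sd1,sd2 group standard deviations (> 0); \code{sd2} defaults to
#'   \code{sd1}
#' @param n1,n2 group sizes (integers >= 2); \code{n2} defaults to
#'   \code{n1}
#' @param alpha two-sided significance level in (0, 1), default 0.05
#' @return power in (0, 1)
#' @export
#' @examples
#' powerTwoGroupZ(delta = 7, sd1 = 2.5, n1 = 4)           # 0.977
#' powerTwoGroupZ(delta = 0.4, sd1 = 0.01, sd2 = 0.2, n1 = 4)  # 0.979
powerTwoGroupZ <- function(delta, sd1, sd2 = sd1, n1, n2 = n1,
                           alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)")
  stopifnot(delta >= 0, sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
  pnorm(delta / se - qnorm(1 - alpha / 2))
}

#' Mendelian genotype-ratio summary
#'
#' Summarises an observed genotype count against an expected Mendelian
#' proportion (default 1/4 for a homozygote class from a heterozygote
#' intercross): the observed percentage and a 1-degree-of-freedom
#' goodness-of-fit chi-squared test of (k, n - k) against
#' (n p0, n (1 - p0)), without continuity correction.
#'
#' @param k observed count in the category (0 <= k <= n)
#' @param n total count (> 0)
#' @param p0 expected proportion in (0, 1), default 0.25
#' @return list with \code{percent} (100 k / n, rounded to 1 decimal),
#'   \code{chi2} and \code{p} (upper tail, 1 df)
#' @export
#' @examples
#' ratioSummary(43, 242)  # 17.8% of pups homozygous
ratioSummary <- function(k, n, p0 = 0.25) {
  stopifnot(p0 > 0, p0 < 1)
  if (length(n) != 1L || n <= 0) stop("n must be a positive total count")
  stopifnot(k >= 0, k <= n)
  ct <- suppressWarnings(
    chisq.test(c(k, n - k), p = c(p0, 1 - p0), correct = FALSE))
  list(percent = round(100 * k / n, 1L),
       chi2 = unname(ct$statistic),
       p = unname(ct$p.value))
}
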