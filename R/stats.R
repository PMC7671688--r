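#' Adjusted R-squared
#'
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)` for a model with `p` fitted
#' parameters (excluding the intercept) on `n` observations.
#'
#' @param r2 plain coefficient of determination
#' @param n sample size
#' @param p_params number of model parameters excluding the intercept
#' @return adjusted R-squared (vectorised over `r2`)
#' @export
adjusted_r2 <- function(r2, n, p_params) {
  if (n <= p_params + 1)
    stop("n = ", n, " too small for p_params = ", p_params,
         " (need n > p_params + 1)")
  1 - (1 - r2) * (n - 1) / (n - p_params - 1)
}

#' Fisher r-to-z transform
#' @param r correlation(s) in (-1, 1)
#' @return atanh(r)
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("Fisher transform diverges at |r| = 1")
  atanh(r)
}

#' Compare two dependent correlations sharing one variable
#'
#' Meng-Rosenthal-Rubin z-test for the difference between `r_a = cor(x, a)`
#' and `r_b = cor(x, b)` when both involve the common variable `x` and the
#' non-shared variables are correlated `r_ab = cor(a, b)`:
#' \deqn{z = (z_a - z_b) \sqrt{\frac{n - 3}{2 (1 - r_{ab}) h}}, \quad
#'   h = \frac{1 - f \bar{r}^2}{1 - \bar{r}^2}, \quad
#'   f = \min\!\left(\frac{1 - r_{ab}}{2 (1 - \bar{r}^2)}, 1\right),}
#' with \eqn{\bar{r}^2 = (r_a^2 + r_b^2)/2} and `z_.` the Fisher
#' transforms.
#'
#' @param r_a,r_b correlations of the two competing variables with the
#'   common variable
#' @param r_ab correlation between the two competing variables
#' @param n sample size (>= 10)
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#' @return list with `z`, `p`, and the intermediate `h`, `f`
#' @export
compare_dependent_correlations <- function(r_a, r_b, r_ab, n,
                                           alternative = c("two.sided",
                                                           "greater",
                                                           "less")) {
  alternative <- match.arg(alternative)
  if (n < 10) stop("n must be >= 10")
  if (any(abs(c(r_a, r_b)) >= 1))
    stop("|r| = 1 input: Fisher transform diverges")
  if (abs(r_ab) > 1) stop("r_ab outside [-1, 1]")
  rbar2 <- (r_a^2 + r_b^2) / 2
  f <- min((1 - r_ab) / (2 * (1 - rbar2)), 1)
  h <- (1 - f * rbar2) / (1 - rbar2)
  if (1 - r_ab < 1e-12) {
    ## degenerate: the two competing variables coincide
    if (abs(r_a - r_b) < 1e-12) {
      z <- 0
    } else {
      stop("r_ab = 1 with unequal correlations: comparison degenerate")
    }
  } else {
    z <- (fisher_z(r_a) - fisher_z(r_b)) *
      sqrt((n - 3) / (2 * (1 - r_ab) * h))
  }
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(z = z, p = p, h = h, f = f)
}

#' Partial correlation after removing covariates
#'
#' Correlation of the least-squares residuals of `x` and `y` after
#' regressing each on the covariate columns (with intercept).
#'
#' @param x,y numeric vectors
#' @param covariates numeric matrix/data frame of covariates, or NULL/empty
#'   for the plain product-moment correlation
#' @return partial correlation coefficient
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0L ||
      (is.matrix(covariates) && nrow(covariates) == 0L))
    return(stats::cor(x, y))
  cv <- as.matrix(covariates)
  if (length(x) <= ncol(cv) + 2)
    stop("need n > #covariates + 2")
  if (qr(cbind(1, cv))$rank < ncol(cv) + 1L)
    stop("rank-deficient covariates")
  rx <- stats::lm.fit(cbind(1, cv), x)$residuals
  ry <- stats::lm.fit(cbind(1, cv), y)$residuals
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), 1e-300) ||
      stats::sd(ry) <= 1e-10 * max(stats::sd(y), 1e-300))
    stop("zero residual variance: partial correlation undefined")
  stats::cor(rx, ry)
}
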