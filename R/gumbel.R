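# Type-I extreme-value (Gumbel) utilities: maximum-likelihood fitting of
# null score distributions and conversion of scores to E-values.

#' Fit a Gumbel (type-I EVD) by maximum likelihood
#'
#' Location-scale Gumbel with density
#' \eqn{f(x) = (1/\beta) \exp(-z - e^{-z})}, \eqn{z = (x - \mu)/\beta}.
#' The scale is found by solving the 1-D profile-likelihood equation
#' \eqn{\beta = \bar x - \sum x_i e^{-x_i/\beta} / \sum e^{-x_i/\beta}}
#' with [stats::uniroot()], then the location in closed form.
#'
#' @param x Numeric sample (e.g. alignment scores of shuffled decoys).
#' @return List with `mu` (location), `beta` (scale) and
#'   `lambda = 1/beta` (the rate used in E-value formulas).
#' @export
fit_gumbel <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 10)
    stop("need at least 10 observations to fit a Gumbel", call. = FALSE)
  if (stats::sd(x) < 1e-12)
    stop("degenerate score distribution (all values equal); ",
         "increase the number of decoys", call. = FALSE)
  xbar <- mean(x)
  xmin <- min(x)
  g <- function(beta) {
    w <- exp(-(x - xmin) / beta)        # shift keeps exponents <= 0
    beta - xbar + sum(x * w) / sum(w)
  }
  s <- stats::sd(x)
  lo <- s * 1e-3                        # g(lo) ~ lo - xbar + xmin < 0
  hi <- s * 1e3                         # g(beta) ~ beta > 0 for large beta
  while (g(hi) < 0 && hi < s * 1e6) hi <- hi * 10
  beta <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  mu <- -beta * log(mean(exp(-(x - xmin) / beta))) + xmin
  list(mu = mu, beta = beta, lambda = 1 / beta)
}

#' Convert a score to an E-value under a fitted Gumbel null
#'
#' \eqn{E = n (1 - \exp(-e^{-\lambda (S - \mu)}))}, the expected number of
#' comparisons reaching score `score` or better among `n_comparisons`
#' independent trials. Strictly decreasing in `score`; floored at 1e-200 so
#' that \eqn{-\log_{10} E} stays finite for graph weights.
#'
#' @param score Numeric score(s).
#' @param evd List with `mu` and `lambda` (from [fit_gumbel()]).
#' @param n_comparisons Number of comparisons performed (>= 1).
#' @return E-value(s), in `(1e-200, n_comparisons]`.
#' @export
#' @examples
#' evd <- list(mu = 10, lambda = 0.5)
#' evalue_from_score(10, evd, 1)  # 1 - exp(-1) ~ 0.632
evalue_from_score <- function(score, evd, n_comparisons = 1L) {
  stopifnot(n_comparisons >= 1)
  z <- -evd$lambda * (score - evd$mu)
  p <- -expm1(-exp(z))                 # 1 - exp(-exp(z)), stable for small p
  small <- exp(z) < 1e-12
  p[small] <- exp(z)[small]            # first-order term when exp(z) tiny
  pmax(n_comparisons * p, 1e-200)
}

# density/quantile helpers (internal; used by tests and simulation)
rgumbel <- function(n, mu, beta) mu - beta * log(-log(runif(n)))
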