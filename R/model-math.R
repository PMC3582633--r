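#' Logit link and its inverse
#'
#' `logit(p) = log(p / (1 - p))` maps probabilities to the real line;
#' `inv_logit` is its inverse. `logit` is undefined at 0 and 1.
#'
#' @param p Probabilities strictly inside (0, 1).
#' @param psi Real-valued linear predictors.
#' @return Numeric vector.
#' @examples
#' inv_logit(0) # 0.5
#' logit(inv_logit(-3.7))
#' @export
logit <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p >= 1)) {
    abort("logit is defined only on the open interval (0, 1)")
  }
  qlogis(p)
}

#' @rdname logit
#' @export
inv_logit <- function(psi) plogis(psi)

# log(1 + exp(x)) without overflow for large x
log1pexp <- function(x) {
  out <- x
  small <- x < 35
  out[small] <- log1p(exp(x[small]))
  out
}

#' Binomial log-likelihood on the logit scale
#'
#' Log of `Binomial(y | n, inv_logit(psi))`, including the
#' `choose(n, y)` normalising constant. Vectorised over all arguments.
#'
#' @param y Wet counts, `0 <= y <= n`.
#' @param n Trial counts.
#' @param psi Linear predictors on the logit scale.
#' @return Numeric vector of log-likelihood contributions.
#' @examples
#' binomial_loglik(0, 1, 0) # log(0.5)
#' @export
binomial_loglik <- function(y, n, psi) {
  if (any(y < 0) || any(y > n)) abort("need 0 <= y <= n")
  lchoose(n, y) + y * psi - n * log1pexp(psi)
}

# Lower-triangular Cholesky draws from MVN(mean, cov); one draw as a vector,
# several as rows. Uses the ambient RNG stream so seeded runs are exact.
rmvn <- function(n, mean, cov) {
  p <- length(mean)
  L <- t(chol(cov))
  z <- matrix(rnorm(n * p), nrow = p)
  out <- t(L %*% z + mean)
  if (n == 1) drop(out) else out
}
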