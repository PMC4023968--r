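## Gaussian logistic response curve: the single evaluator shared by the
## simulator, the likelihood, and the prediction utilities, so the generative
## and inferential sides of the model cannot drift apart.
##
## logit(p_ij) = a_j - (x_i - opt_j)^2 / (2 tol_j^2) + eps_i

.niche_linpred <- function(x, opt, tol, a, eps = 0) {
  n <- length(x); m <- length(opt)
  if (m == 1L) {
    eta <- a - (x - opt)^2 * (0.5 / (tol * tol)) + eps
    dim(eta) <- c(n, 1L)
    return(eta)
  }
  d <- x - rep(opt, each = n)
  eta <- rep(a, each = n) - d * d * rep(0.5 / (tol * tol), each = n) + eps
  dim(eta) <- c(n, m)                   # eps recycles down columns (per site)
  eta
}

#' Occurrence probability under the Gaussian logistic response curve
#'
#' Evaluates `p = plogis(a - (x - opt)^2 / (2 tol^2) + site_effect)` for one
#' or more species. This one function defines the response curve everywhere in
#' the package (simulation, likelihood, prediction).
#'
#' @param x gradient values (length `n`).
#' @param opt,tol,a niche parameters, scalars or length-`m` vectors; `tol`
#'   must be strictly positive.
#' @param site_effect per-site random effect(s), scalar or length `n`.
#' @return an `n x m` probability matrix (dropped to a vector when `m = 1`).
#' @export
response_probability <- function(x, opt, tol, a, site_effect = 0) {
  if (any(tol <= 0)) stop("tol must be strictly positive")
  p <- stats::plogis(.niche_linpred(x, opt, tol, a, site_effect))
  if (length(opt) == 1L) drop(p) else p
}

#' Predict a species response curve along a gradient grid
#'
#' @param niche a [gaussian_niche()] (or list with `opt`, `tol`, `a`).
#' @param x_grid gradient values at which to evaluate the curve.
#' @param site_effect additive logit-scale offset (default 0, an average site).
#' @return numeric vector of occurrence probabilities; maximal at
#'   `x_grid = opt`.
#' @export
predict_curve <- function(niche, x_grid, site_effect = 0) {
  if (niche$tol <= 0) stop("tol must be strictly positive")
  response_probability(x_grid, niche$opt, niche$tol, niche$a, site_effect)
}

## Bernoulli log-likelihood of the full table at linear predictor eta:
## y*eta - log(1 + exp(eta)), computed on the stable branch of log1p.
.bern_loglik_cells <- function(y, eta) {
  (y - (eta > 0)) * eta - log1p(exp(-abs(eta)))
}

.deviance_from_state <- function(y, x, opt, tol, a, eps) {
  eta <- .niche_linpred(x, opt, tol, a, eps)
  -2 * sum(.bern_loglik_cells(y, eta))
}
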