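#' Log joint density of the full model state
#'
#' Evaluates log-likelihood plus log-priors for a complete parameter state:
#' Bernoulli occurrences with logit
#' `a_j - (x_i - opt_j)^2 / (2 tol_j^2) + eps_i`; species-level Gaussians
#' around the trait-linear means (tolerance on the log scale by default, or
#' linear and truncated at zero with `tol_model = "truncated"`); Gaussian site
#' effects; spike-and-slab (Bernoulli(0.5) indicator, double-exponential
#' slab `lambda/2 * exp(-lambda |beta|)`) or normal priors on slopes; uniform
#' priors on intercepts and on every standard deviation (evaluated as the
#' induced density on the stored variance); Gamma hyperprior on the slab
#' rate. States violating a constraint (`tol <= 0`, parameters outside the
#' uniform bounds, an indicator/slope mismatch) return `-Inf`.
#'
#' @param state list with `opt`, `tol`, `a`, `eps` and hyperparameters `mu`
#'   (named `opt`, `ltol`, `a`), `sigma2` (same names), `sigma2_site`;
#'   optionally `beta`, `gamma`, `lambda` (or `sigma2_beta` for the normal
#'   prior) and, for the latent model, raw weights `w`, `gamma_env`,
#'   `lambda_env`.
#' @param data list with the occurrence matrix `y`, the gradient `x` (or
#'   `env` for the latent model) and the trait matrix `Z` (or `NULL`).
#' @param opts an [mcmc_options()] supplying prior settings and bounds.
#' @return the log joint density; attribute `"components"` carries the
#'   individual terms (`loglik`, `prior_species`, `prior_sites`,
#'   `prior_slopes`, `prior_hyper`, `prior_weights`).
#' @export
log_joint <- function(state, data, opts = mcmc_options()) {
  y <- unclass(data$y)
  n <- nrow(y); m <- ncol(y)
  Z <- data$Z
  K <- if (is.null(Z)) 0L else ncol(Z)
  B <- opts$intercept_bound; Bsd <- opts$sd_bound
  spike <- opts$prior == "spike_slab"
  neg_inf <- function() structure(-Inf, components = NULL)

  if (any(!is.finite(state$tol)) || any(state$tol <= 0)) return(neg_inf())
  if (any(state$sigma2 <= 0) || state$sigma2_site <= 0) return(neg_inf())
  if (any(sqrt(state$sigma2) >= Bsd) || sqrt(state$sigma2_site) >= Bsd)
    return(neg_inf())
  if (any(abs(state$mu) >= B)) return(neg_inf())

  latent <- !is.null(state$w)
  x <- if (latent) drop(unclass(data$env) %*% .normalized_weights(state$w))
       else data$x

  eta <- .niche_linpred(x, state$opt, state$tol, state$a, state$eps)
  loglik <- sum(.bern_loglik_cells(y, eta))

  mean_of <- function(th, mu, beta) {
    if (K > 0L) mu + drop(Z %*% beta) else rep(mu, m)
  }
  bet <- state$beta
  if (is.null(bet)) bet <- list(opt = numeric(0), ltol = numeric(0), a = numeric(0))

  pr_sp <- sum(stats::dnorm(state$opt, mean_of("opt", state$mu[["opt"]], bet$opt),
                            sqrt(state$sigma2[["opt"]]), log = TRUE))
  mt <- mean_of("ltol", state$mu[["ltol"]], bet$ltol)
  sdt <- sqrt(state$sigma2[["ltol"]])
  if (opts$tol_model == "log") {
    pr_sp <- pr_sp + sum(stats::dnorm(log(state$tol), mt, sdt, log = TRUE))
  } else {
    # linear in tol, truncated below at 0: renormalize by P(T > 0)
    pr_sp <- pr_sp + sum(stats::dnorm(state$tol, mt, sdt, log = TRUE) -
                           stats::pnorm(mt / sdt, log.p = TRUE))
  }
  pr_sp <- pr_sp + sum(stats::dnorm(state$a, mean_of("a", state$mu[["a"]], bet$a),
                                    sqrt(state$sigma2[["a"]]), log = TRUE))

  pr_site <- sum(stats::dnorm(state$eps, 0, sqrt(state$sigma2_site), log = TRUE))

  pr_slopes <- 0
  if (K > 0L) {
    if (spike) {
      if (is.null(state$lambda) || state$lambda <= 0) return(neg_inf())
      for (th in c("opt", "ltol", "a")) {
        b <- bet[[th]]; g <- state$gamma[[th]]
        if (any(b[g == 0] != 0)) return(neg_inf())
        pr_slopes <- pr_slopes + K * log(0.5) +
          sum((log(state$lambda / 2) - state$lambda * abs(b))[g == 1])
      }
    } else {
      if (any(sqrt(state$sigma2_beta) >= Bsd)) return(neg_inf())
      for (th in c("opt", "ltol", "a")) {
        pr_slopes <- pr_slopes +
          sum(stats::dnorm(bet[[th]], 0, sqrt(state$sigma2_beta[[th]]), log = TRUE))
      }
    }
  }

  # uniform priors: intercepts on (-B, B); sds on (0, Bsd), evaluated as the
  # induced density 1 / (2 * Bsd * sd) on the stored variance
  pr_hyper <- -3 * log(2 * B) -
    sum(log(2 * Bsd * sqrt(state$sigma2))) - log(2 * Bsd * sqrt(state$sigma2_site))
  if (K > 0L && spike && is.null(opts$fixed_lambda)) {
    pr_hyper <- pr_hyper + stats::dgamma(state$lambda, opts$lambda_hyper[["shape"]],
                                         opts$lambda_hyper[["rate"]], log = TRUE)
  }
  if (K > 0L && !spike) {
    pr_hyper <- pr_hyper - sum(log(Bsd * 2 * sqrt(state$sigma2_beta)))
  }

  pr_w <- 0
  if (latent) {
    if (is.null(state$lambda_env) || state$lambda_env <= 0) return(neg_inf())
    g <- state$gamma_env
    if (any(state$w[g == 0] != 0)) return(neg_inf())
    L <- length(state$w)
    pr_w <- L * log(0.5) +
      sum((log(state$lambda_env / 2) - state$lambda_env * abs(state$w))[g == 1]) +
      stats::dgamma(state$lambda_env, opts$lambda_hyper[["shape"]],
                    opts$lambda_hyper[["rate"]], log = TRUE)
  }

  total <- loglik + pr_sp + pr_site + pr_slopes + pr_hyper + pr_w
  structure(total, components = list(loglik = loglik, prior_species = pr_sp,
                                     prior_sites = pr_site,
                                     prior_slopes = pr_slopes,
                                     prior_hyper = pr_hyper,
                                     prior_weights = pr_w))
}
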