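#' MCMC options for the hierarchical niche model
#'
#' @param n_iter total iterations per chain (default 10000; latent-gradient
#'   fits conventionally use far more, see [fit_latent()]).
#' @param burn_in iterations discarded (default first half).
#' @param n_chains number of independent chains (default 3).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer; fixes the entire draw sequence (chain `c` uses
#'   `seed + c - 1`).
#' @param prior `"spike_slab"` (point mass at 0 plus double-exponential slab,
#'   Bernoulli(0.5) inclusion indicators) or `"normal"` (plain Gaussian
#'   shrinkage) for the trait slopes.
#' @param lambda_hyper shape/rate of the Gamma hyperprior on the slab rate.
#' @param fixed_lambda optional fixed slab rate (skips the hyperprior).
#' @param intercept_bound half-width `B` of the Uniform(-B, B) prior on the
#'   submodel intercepts.
#' @param sd_bound upper bound of the Uniform(0, B) prior on every standard
#'   deviation (residual sds, site-effect sd, normal-mode slope sd).
#' @param tol_model `"log"` (default: the tolerance submodel acts on
#'   log tolerance, guaranteeing positivity) or `"truncated"` (linear in
#'   tolerance, truncated at 0; density evaluation only, see [log_joint()]).
#' @param adapt_interval proposal scales adapt every this many iterations
#'   during burn-in, then freeze.
#' @param target_accept target Metropolis acceptance rate for the adaptation.
#' @param update character vector of blocks to update, or `"all"`. Blocks:
#'   `opt`, `ltol`, `a`, `eps`, `mu`, `beta`, `sigma`, `sigma_site`,
#'   `lambda`, `weights`. Freezing blocks is mainly for calibration tests.
#' @param chain_jitter jitter starting values of chains beyond the first.
#' @return an `mcmc_options` list.
#' @export
mcmc_options <- function(n_iter = 10000L, burn_in = floor(n_iter / 2),
                         n_chains = 3L, thin = 1L, seed = 1L,
                         prior = c("spike_slab", "normal"),
                         lambda_hyper = c(shape = 1, rate = 1),
                         fixed_lambda = NULL,
                         intercept_bound = 100, sd_bound = 100,
                         tol_model = c("log", "truncated"),
                         adapt_interval = 50L, target_accept = 0.44,
                         update = "all", chain_jitter = TRUE) {
  prior <- match.arg(prior)
  tol_model <- match.arg(tol_model)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (n_chains < 1L) stop("n_chains must be at least 1")
  if (thin < 1L) stop("thin must be at least 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains), thin = as.integer(thin),
                 seed = as.integer(seed), prior = prior,
                 lambda_hyper = lambda_hyper, fixed_lambda = fixed_lambda,
                 intercept_bound = intercept_bound, sd_bound = sd_bound,
                 tol_model = tol_model,
                 adapt_interval = as.integer(adapt_interval),
                 target_accept = target_accept,
                 update = update, chain_jitter = isTRUE(chain_jitter)),
            class = "mcmc_options")
}

## ---- small samplers ---------------------------------------------------------

.logsumexp2 <- function(a, b) {
  mx <- pmax(a, b)
  mx + log(exp(a - mx) + exp(b - mx))
}

## N(mu, sd) truncated to (0, Inf); inverse-cdf with a tail rejection fallback
.rtnorm_pos <- function(mu, sd) {
  alpha <- -mu / sd
  if (alpha < 10) {
    pu <- stats::pnorm(alpha, lower.tail = FALSE)
    x <- stats::qnorm(stats::runif(1) * pu, lower.tail = FALSE)
  } else {
    repeat {                            # Robert (1995) shifted-exponential
      z <- alpha + stats::rexp(1) / alpha
      if (log(stats::runif(1)) < -(z - alpha)^2 / 2) { x <- z; break }
    }
  }
  mu + sd * x
}

## N(mu, sd) truncated to (lo, hi) by inverse cdf
.rtnorm_interval <- function(mu, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mu, sd)
  p_hi <- stats::pnorm(hi, mu, sd)
  if (p_hi - p_lo <= 0) return(min(max(mu, lo), hi))
  x <- stats::qnorm(p_lo + stats::runif(1) * (p_hi - p_lo), mu, sd)
  min(max(x, lo), hi)
}

## variance draw under Uniform(0, B) prior on the sd:
## sigma^2 | SS ~ InvGamma((n-1)/2, SS/2), rejected at the bound
.rvar_unif_sd <- function(SS, n, bound) {
  if (n < 2L) stop("variance update needs at least 2 units")
  for (i in 1:100) {
    s2 <- SS / stats::rchisq(1, df = n - 1L)
    if (sqrt(s2) < bound) return(max(s2, 1e-12))
  }
  (0.99 * bound)^2
}

## univariate slice sampler (stepping out + shrinkage) on (lower, upper)
.slice1 <- function(x0, logf, lower, upper, w = 1, max_steps = 50L) {
  ly <- logf(x0) + log(stats::runif(1))
  u <- stats::runif(1)
  L <- max(x0 - u * w, lower); R <- max(min(L + w, upper), L)
  k <- max_steps
  while (k > 0 && L > lower && logf(L) > ly) { L <- max(L - w, lower); k <- k - 1 }
  k <- max_steps
  while (k > 0 && R < upper && logf(R) > ly) { R <- min(R + w, upper); k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > ly) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

## joint (gamma, beta) draw for one slope under the spike-and-slab prior,
## conditional on a Gaussian linear submodel: closed-form normal-Laplace
## convolution for the slab marginal, exact truncated-normal slab draw
.update_beta_ss <- function(Szz, Szr, sigma2, lambda) {
  v <- sigma2 / Szz
  mhat <- Szr / Szz
  sv <- sqrt(v)
  lw0 <- -mhat^2 / (2 * v)
  lIp <- -lambda * mhat + lambda^2 * v / 2 +
    stats::pnorm((mhat - lambda * v) / sv, log.p = TRUE)
  lIm <- lambda * mhat + lambda^2 * v / 2 +
    stats::pnorm(-(mhat + lambda * v) / sv, log.p = TRUE)
  lsum <- .logsumexp2(lIp, lIm)
  lw1 <- log(lambda / 2) + 0.5 * log(2 * pi * v) + lsum
  p1 <- 1 / (1 + exp(lw0 - lw1))
  if (stats::runif(1) < p1) {
    if (log(stats::runif(1)) < lIp - lsum) {
      list(beta = .rtnorm_pos(mhat - lambda * v, sv), gamma = 1L)
    } else {
      list(beta = -.rtnorm_pos(-(mhat + lambda * v), sv), gamma = 1L)
    }
  } else {
    list(beta = 0, gamma = 0L)
  }
}

## ---- state construction -----------------------------------------------------

.state_from_bundle <- function(bundle, K, n, opts) {
  pad <- function(v) { v <- as.numeric(v); length(v) <- K; v[is.na(v)] <- 0; v }
  beta <- list(opt = pad(bundle$submodels$opt$slopes),
               ltol = pad(bundle$submodels$ltol$slopes),
               a = pad(bundle$submodels$a$slopes))
  list(opt = as.numeric(bundle$niches$opt),
       ltol = log(as.numeric(bundle$niches$tol)),
       a = as.numeric(bundle$niches$a),
       eps = rep(0, n),
       mu = c(opt = bundle$submodels$opt$intercept,
              ltol = bundle$submodels$ltol$intercept,
              a = bundle$submodels$a$intercept),
       beta = beta,
       gamma = lapply(beta, function(b) rep(1L, length(b))),
       sigma2 = c(opt = max(bundle$submodels$opt$sigma2, 1e-4),
                  ltol = max(bundle$submodels$ltol$sigma2, 1e-4),
                  a = max(bundle$submodels$a$sigma2, 1e-4)),
       sigma2_site = max(bundle$sigma2_site, 1e-4),
       lambda = 1,
       sigma2_beta = c(opt = 1, ltol = 1, a = 1))
}

.prior_means <- function(st, Z) {
  if (is.null(Z)) {
    list(opt = st$mu[["opt"]], ltol = st$mu[["ltol"]], a = st$mu[["a"]])
  } else {
    list(opt = st$mu[["opt"]] + drop(Z %*% st$beta$opt),
         ltol = st$mu[["ltol"]] + drop(Z %*% st$beta$ltol),
         a = st$mu[["a"]] + drop(Z %*% st$beta$a))
  }
}

.normalized_weights <- function(w) {
  nw <- sqrt(sum(w * w))
  if (nw == 0) w else w / nw
}

.data_fingerprint <- function(y, gradient) {
  c(dim(y), sum(y), round(sum(gradient^2), 6), round(sum(gradient), 6))
}

## ---- the chain --------------------------------------------------------------

.run_chain <- function(y, Z, opts, state, chain_seed, chain_index,
                       x_fixed = NULL, Env = NULL, anchor = 1L,
                       weight_scale_init = 0.3) {
  set.seed(chain_seed)
  n <- nrow(y); m <- ncol(y)
  K <- if (is.null(Z)) 0L else ncol(Z)
  latent <- !is.null(Env)
  L <- if (latent) ncol(Env) else 0L
  upd_all <- identical(opts$update, "all")
  upd <- function(b) upd_all || b %in% opts$update
  B <- opts$intercept_bound; Bsd <- opts$sd_bound
  spike <- opts$prior == "spike_slab"

  st <- state
  if (latent && is.null(st$w)) stop("latent chain needs weight state")

  # overdispersed starts for chains beyond the first
  if (opts$chain_jitter && chain_index > 1L) {
    st$opt <- st$opt + stats::rnorm(m, 0, 0.25)
    st$ltol <- st$ltol + stats::rnorm(m, 0, 0.15)
    st$a <- st$a + stats::rnorm(m, 0, 0.25)
    st$mu <- st$mu + stats::rnorm(3, 0, 0.25)
    if (latent && upd("weights"))
      st$w <- st$w + stats::rnorm(L, 0, 0.1) * (st$gamma_env == 1)
  }

  x <- if (latent) drop(Env %*% .normalized_weights(st$w)) else x_fixed

  # proposal scales
  sc <- list(opt = rep(0.4, m), ltol = rep(0.25, m), a = rep(0.4, m),
             eps = rep(0.4, n), w = weight_scale_init, w_add = 1.0)
  acc_ct <- list(opt = numeric(m), ltol = numeric(m), a = numeric(m),
                 eps = numeric(n), w = 0, w_try = 0)
  post_ct <- list(opt = 0, ltol = 0, a = 0, eps = 0, w = 0, w_try = 0)
  batch_iters <- 0L

  tol <- exp(st$ltol)
  eta <- .niche_linpred(x, st$opt, tol, st$a, st$eps)
  cl <- colSums(.bern_loglik_cells(y, eta))

  n_keep <- (opts$n_iter - opts$burn_in) %/% opts$thin
  par_names <- c(paste0("opt[", seq_len(m), "]"),
                 paste0("ltol[", seq_len(m), "]"),
                 paste0("a[", seq_len(m), "]"),
                 paste0("eps[", seq_len(n), "]"),
                 "mu_opt", "mu_ltol", "mu_a",
                 "sigma2_opt", "sigma2_ltol", "sigma2_a", "sigma2_site")
  if (K > 0L) {
    for (th in c("opt", "ltol", "a"))
      par_names <- c(par_names, paste0("beta_", th, "[", seq_len(K), "]"))
    if (spike) {
      for (th in c("opt", "ltol", "a"))
        par_names <- c(par_names, paste0("gamma_", th, "[", seq_len(K), "]"))
      par_names <- c(par_names, "lambda")
    } else {
      par_names <- c(par_names, "sigma_beta_opt", "sigma_beta_ltol", "sigma_beta_a")
    }
  }
  if (latent) {
    par_names <- c(par_names, paste0("c_env[", seq_len(L), "]"),
                   paste0("gamma_env[", seq_len(L), "]"), "lambda_env")
  }
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  deviance <- numeric(n_keep)
  keep_i <- 0L

  for (it in seq_len(opts$n_iter)) {
    pm <- .prior_means(st, Z)
    sd_th <- sqrt(st$sigma2)
    batch_iters <- batch_iters + 1L

    ## -- species niche parameters (vectorized random-walk Metropolis) --------
    if (upd("opt")) {
      prop <- st$opt + sc$opt * stats::rnorm(m)
      eta_p <- .niche_linpred(x, prop, tol, st$a, st$eps)
      cl_p <- colSums(.bern_loglik_cells(y, eta_p))
      lr <- cl_p - cl +
        stats::dnorm(prop, pm$opt, sd_th[["opt"]], log = TRUE) -
        stats::dnorm(st$opt, pm$opt, sd_th[["opt"]], log = TRUE)
      acc <- log(stats::runif(m)) < lr
      if (any(acc)) {
        st$opt[acc] <- prop[acc]
        eta[, acc] <- eta_p[, acc]
        cl[acc] <- cl_p[acc]
      }
      acc_ct$opt <- acc_ct$opt + acc
      if (it > opts$burn_in) post_ct$opt <- post_ct$opt + mean(acc)
    }
    if (upd("ltol")) {
      prop <- st$ltol + sc$ltol * stats::rnorm(m)
      tol_p <- exp(prop)
      eta_p <- .niche_linpred(x, st$opt, tol_p, st$a, st$eps)
      cl_p <- colSums(.bern_loglik_cells(y, eta_p))
      lr <- cl_p - cl +
        stats::dnorm(prop, pm$ltol, sd_th[["ltol"]], log = TRUE) -
        stats::dnorm(st$ltol, pm$ltol, sd_th[["ltol"]], log = TRUE)
      acc <- log(stats::runif(m)) < lr
      if (any(acc)) {
        st$ltol[acc] <- prop[acc]
        tol[acc] <- tol_p[acc]
        eta[, acc] <- eta_p[, acc]
        cl[acc] <- cl_p[acc]
      }
      acc_ct$ltol <- acc_ct$ltol + acc
      if (it > opts$burn_in) post_ct$ltol <- post_ct$ltol + mean(acc)
    }
    if (upd("a")) {
      prop <- st$a + sc$a * stats::rnorm(m)
      eta_p <- eta + rep(prop - st$a, each = n)
      cl_p <- colSums(.bern_loglik_cells(y, eta_p))
      lr <- cl_p - cl +
        stats::dnorm(prop, pm$a, sd_th[["a"]], log = TRUE) -
        stats::dnorm(st$a, pm$a, sd_th[["a"]], log = TRUE)
      acc <- log(stats::runif(m)) < lr
      if (any(acc)) {
        st$a[acc] <- prop[acc]
        eta[, acc] <- eta_p[, acc]
        cl[acc] <- cl_p[acc]
      }
      acc_ct$a <- acc_ct$a + acc
      if (it > opts$burn_in) post_ct$a <- post_ct$a + mean(acc)
    }

    ## -- site effects ---------------------------------------------------------
    if (upd("eps")) {
      prop <- st$eps + sc$eps * stats::rnorm(n)
      eta_p <- eta + (prop - st$eps)     # recycles per row, column-major
      cells_cur <- .bern_loglik_cells(y, eta)
      cells_p <- .bern_loglik_cells(y, eta_p)
      sdsite <- sqrt(st$sigma2_site)
      lr <- rowSums(cells_p) - rowSums(cells_cur) +
        stats::dnorm(prop, 0, sdsite, log = TRUE) -
        stats::dnorm(st$eps, 0, sdsite, log = TRUE)
      acc <- log(stats::runif(n)) < lr
      if (any(acc)) {
        st$eps[acc] <- prop[acc]
        eta[acc, ] <- eta_p[acc, ]
        cl <- colSums(.bern_loglik_cells(y, eta))
      }
      acc_ct$eps <- acc_ct$eps + acc
      if (it > opts$burn_in) post_ct$eps <- post_ct$eps + mean(acc)
    }

    ## -- submodel hyperparameters (Gibbs) -------------------------------------
    for (th in c("opt", "ltol", "a")) {
      tvec <- switch(th, opt = st$opt, ltol = st$ltol, a = st$a)
      fitted <- if (K > 0L) drop(Z %*% st$beta[[th]]) else rep(0, m)
      if (upd("mu")) {
        st$mu[[th]] <- .rtnorm_interval(mean(tvec - fitted),
                                        sqrt(st$sigma2[[th]] / m), -B, B)
      }
      resid <- tvec - st$mu[[th]] - fitted
      if (K > 0L && upd("beta")) {
        beta <- st$beta[[th]]; gam <- st$gamma[[th]]
        for (k in seq_len(K)) {
          zk <- Z[, k]
          r <- resid + zk * beta[k]
          Szz <- sum(zk * zk)
          Szr <- sum(zk * r)
          if (spike) {
            dr <- .update_beta_ss(Szz, Szr, st$sigma2[[th]], st$lambda)
            beta[k] <- dr$beta; gam[k] <- dr$gamma
          } else {
            vpost <- 1 / (Szz / st$sigma2[[th]] + 1 / st$sigma2_beta[[th]])
            beta[k] <- stats::rnorm(1, vpost * Szr / st$sigma2[[th]], sqrt(vpost))
            gam[k] <- 1L
          }
          resid <- r - zk * beta[k]
        }
        st$beta[[th]] <- beta; st$gamma[[th]] <- gam
      }
      if (upd("sigma") && m >= 2L) {
        st$sigma2[[th]] <- .rvar_unif_sd(sum(resid^2), m, Bsd)
      }
    }
    if (upd("sigma_site") && n >= 2L) {
      st$sigma2_site <- .rvar_unif_sd(sum(st$eps^2), n, Bsd)
    }
    if (K > 0L && spike && upd("lambda") && is.null(opts$fixed_lambda)) {
      bact <- unlist(st$beta)[unlist(st$gamma) == 1L]
      st$lambda <- stats::rgamma(1, opts$lambda_hyper[["shape"]] + length(bact),
                                 opts$lambda_hyper[["rate"]] + sum(abs(bact)))
    }
    if (K > 0L && !spike && upd("lambda")) {
      for (th in c("opt", "ltol", "a")) {
        b2sum <- sum(st$beta[[th]]^2)
        lf <- function(s) -K * log(s) - b2sum / (2 * s * s)
        snew <- .slice1(sqrt(st$sigma2_beta[[th]]), lf, 1e-6, Bsd, w = 0.5)
        st$sigma2_beta[[th]] <- snew^2
      }
    }

    ## -- latent gradient weights ----------------------------------------------
    if (latent && upd("weights")) {
      ll_tot <- sum(cl)
      lam_e <- st$lambda_env
      # add / delete toggles, one per variable
      for (l in seq_len(L)) {
        if (st$gamma_env[l] == 0L) {
          wl <- stats::rnorm(1, 0, sc$w_add)
          w2 <- st$w; w2[l] <- wl
          x2 <- drop(Env %*% .normalized_weights(w2))
          eta2 <- .niche_linpred(x2, st$opt, tol, st$a, st$eps)
          cl2 <- colSums(.bern_loglik_cells(y, eta2))
          lacc <- sum(cl2) - ll_tot +
            (log(lam_e / 2) - lam_e * abs(wl)) -
            stats::dnorm(wl, 0, sc$w_add, log = TRUE)
          if (log(stats::runif(1)) < lacc) {
            st$w <- w2; st$gamma_env[l] <- 1L
            x <- x2; eta <- eta2; cl <- cl2; ll_tot <- sum(cl)
          }
        } else {
          w2 <- st$w; w2[l] <- 0
          x2 <- drop(Env %*% .normalized_weights(w2))
          eta2 <- .niche_linpred(x2, st$opt, tol, st$a, st$eps)
          cl2 <- colSums(.bern_loglik_cells(y, eta2))
          lacc <- sum(cl2) - ll_tot +
            stats::dnorm(st$w[l], 0, sc$w_add, log = TRUE) -
            (log(lam_e / 2) - lam_e * abs(st$w[l]))
          if (log(stats::runif(1)) < lacc) {
            st$w <- w2; st$gamma_env[l] <- 0L
            x <- x2; eta <- eta2; cl <- cl2; ll_tot <- sum(cl)
          }
        }
      }
      # joint random walk on the included weights
      idx <- which(st$gamma_env == 1L)
      if (length(idx) > 0L) {
        w2 <- st$w
        w2[idx] <- w2[idx] + sc$w * stats::rnorm(length(idx))
        x2 <- drop(Env %*% .normalized_weights(w2))
        eta2 <- .niche_linpred(x2, st$opt, tol, st$a, st$eps)
        cl2 <- colSums(.bern_loglik_cells(y, eta2))
        lacc <- sum(cl2) - sum(cl) - lam_e * (sum(abs(w2[idx])) - sum(abs(st$w[idx])))
        acc_ct$w_try <- acc_ct$w_try + 1
        if (it > opts$burn_in) post_ct$w_try <- post_ct$w_try + 1
        if (log(stats::runif(1)) < lacc) {
          st$w <- w2; x <- x2; eta <- eta2; cl <- cl2
          acc_ct$w <- acc_ct$w + 1
          if (it > opts$burn_in) post_ct$w <- post_ct$w + 1
        }
      }
      # slab rate for the weights
      wact <- st$w[st$gamma_env == 1L]
      st$lambda_env <- stats::rgamma(1, opts$lambda_hyper[["shape"]] + length(wact),
                                     opts$lambda_hyper[["rate"]] + sum(abs(wact)))
      # deterministic sign gauge: anchor weight kept non-negative
      anc <- if (st$w[anchor] != 0) anchor else which(st$w != 0)[1L]
      if (!is.na(anc) && st$w[anc] < 0) {
        st$w <- -st$w
        st$opt <- -st$opt
        st$mu[["opt"]] <- -st$mu[["opt"]]
        if (K > 0L) st$beta$opt <- -st$beta$opt
        x <- -x                           # eta is invariant under the flip
      }
    }

    ## -- adaptation (burn-in only) --------------------------------------------
    if (it <= opts$burn_in && it %% opts$adapt_interval == 0L) {
      gain <- function(rate) exp(pmin(pmax(rate - opts$target_accept, -0.5), 0.5))
      sc$opt <- pmin(pmax(sc$opt * gain(acc_ct$opt / batch_iters), 1e-3), 10)
      sc$ltol <- pmin(pmax(sc$ltol * gain(acc_ct$ltol / batch_iters), 1e-3), 10)
      sc$a <- pmin(pmax(sc$a * gain(acc_ct$a / batch_iters), 1e-3), 10)
      sc$eps <- pmin(pmax(sc$eps * gain(acc_ct$eps / batch_iters), 1e-3), 10)
      if (latent && acc_ct$w_try > 0) {
        sc$w <- min(max(sc$w * gain(acc_ct$w / acc_ct$w_try), 1e-3), 10)
      }
      acc_ct <- list(opt = numeric(m), ltol = numeric(m), a = numeric(m),
                     eps = numeric(n), w = 0, w_try = 0)
      batch_iters <- 0L
    }

    ## -- bookkeeping ----------------------------------------------------------
    if (!all(is.finite(cl)))
      stop("non-finite likelihood in accepted state at iteration ", it,
           "; state summary: opt range ", paste(round(range(st$opt), 3), collapse = ".."),
           ", ltol range ", paste(round(range(st$ltol), 3), collapse = ".."))
    if (it > opts$burn_in && (it - opts$burn_in) %% opts$thin == 0L) {
      keep_i <- keep_i + 1L
      if (keep_i <= n_keep) {
        row <- c(st$opt, st$ltol, st$a, st$eps, st$mu,
                 st$sigma2, st$sigma2_site)
        if (K > 0L) {
          row <- c(row, st$beta$opt, st$beta$ltol, st$beta$a)
          if (spike) row <- c(row, st$gamma$opt, st$gamma$ltol, st$gamma$a, st$lambda)
          else row <- c(row, sqrt(st$sigma2_beta))
        }
        if (latent) {
          row <- c(row, .normalized_weights(st$w), st$gamma_env, st$lambda_env)
        }
        draws[keep_i, ] <- row
        deviance[keep_i] <- -2 * sum(cl)
      }
    }
  }

  niter_post <- opts$n_iter - opts$burn_in
  rates <- c(opt = post_ct$opt / niter_post, ltol = post_ct$ltol / niter_post,
             a = post_ct$a / niter_post, eps = post_ct$eps / niter_post)
  rates <- rates[vapply(names(rates), upd, logical(1))]
  if (latent && post_ct$w_try > 0) rates <- c(rates, weights = post_ct$w / post_ct$w_try)
  zero <- names(rates)[rates == 0]
  if (length(zero) > 0L)
    warning("zero post-burn-in acceptance in block(s): ", paste(zero, collapse = ", "))

  list(draws = draws, deviance = deviance, accept = rates,
       scales = sc, seed = chain_seed, final_state = st)
}

## ---- user-facing fits -------------------------------------------------------

.build_fit <- function(chains, y, Z, opts, inits, x_fixed = NULL, Env = NULL,
                       anchor = NULL) {
  n <- nrow(y); m <- ncol(y)
  grad <- if (is.null(Env)) x_fixed else as.numeric(Env)
  structure(list(chains = chains,
                 param_names = colnames(chains[[1L]]$draws),
                 options = opts, inits = inits,
                 data = list(y = y, x = x_fixed, env = Env, Z = Z,
                             anchor = anchor),
                 n = n, m = m,
                 K = if (is.null(Z)) 0L else ncol(Z),
                 L = if (is.null(Env)) 0L else ncol(Env),
                 latent = !is.null(Env),
                 fingerprint = .data_fingerprint(y, grad)),
            class = "niche_fit")
}

#' Fit the trait-modulated Gaussian logistic niche model
#'
#' Runs the blocked random-walk-within-Gibbs sampler for the hierarchical
#' model: Bernoulli occurrences with logit
#' `a_j - (x_i - opt_j)^2 / (2 tol_j^2) + eps_i`, species niche parameters
#' drawn around trait-linear means (the optimum and maximum coefficient on
#' their natural scale, the tolerance on the log scale), Gaussian site
#' effects, and spike-and-slab or normal priors on the trait slopes. Species
#' niche parameters and site effects move by adaptive random-walk Metropolis
#' (scales adapt during burn-in only); intercepts, slopes/indicators,
#' variances and the slab rate are exact Gibbs draws.
#'
#' @param occ an [occurrence_matrix()].
#' @param x standardized gradient vector, length `n`.
#' @param traits standardized [trait_table()] or `NULL` (no-traits model).
#' @param opts an [mcmc_options()].
#' @param inits an `init_bundle` from [initial_values()] (computed
#'   automatically when omitted), or a full state list for expert use.
#' @return a `niche_fit`: per-chain kept draws (named columns), per-draw
#'   deviance, acceptance rates, options, inits and a data fingerprint.
#' @seealso [fit_without_traits()], [fit_latent()], [posterior_summary()],
#'   [compute_dic()]
#' @export
fit_niche <- function(occ, x, traits = NULL, opts = mcmc_options(),
                      inits = NULL) {
  if (!inherits(occ, "occurrence_matrix")) occ <- occurrence_matrix(occ)
  y <- unclass(occ)
  n <- nrow(y); m <- ncol(y)
  if (length(x) != n) stop("gradient length must match the number of sites")
  Z <- if (is.null(traits) || ncol(traits) == 0L) NULL else unclass(traits)
  if (!is.null(Z) && nrow(Z) != m)
    stop("trait table rows must match the number of species")
  K <- if (is.null(Z)) 0L else ncol(Z)
  if (is.null(inits)) inits <- initial_values(occ, x, traits)
  state <- if (inherits(inits, "init_bundle"))
    .state_from_bundle(inits, K, n, opts) else inits
  chains <- lapply(seq_len(opts$n_chains), function(ch) {
    .run_chain(y, Z, opts, state,
               chain_seed = (opts$seed + ch - 1L) %% .Machine$integer.max,
               chain_index = ch, x_fixed = x)
  })
  .build_fit(chains, y, Z, opts, inits, x_fixed = x)
}

#' Fit the niche model without traits
#'
#' The reference model in which every trait slope is zero; its residual
#' variances are the "without traits" components of the explained-variance
#' comparison (see [variance_explained()]).
#'
#' @inheritParams fit_niche
#' @return a `niche_fit`.
#' @export
fit_without_traits <- function(occ, x, opts = mcmc_options(), inits = NULL) {
  fit_niche(occ, x, traits = NULL, opts = opts, inits = inits)
}

## ---- summaries --------------------------------------------------------------

#' Pool kept draws across chains
#'
#' @param fit a `niche_fit`.
#' @param pattern optional regular expression selecting parameter columns.
#' @return matrix of pooled draws (rows = draws, columns = parameters).
#' @export
extract_draws <- function(fit, pattern = NULL) {
  d <- do.call(rbind, lapply(fit$chains, function(ch) ch$draws))
  if (!is.null(pattern)) d <- d[, grepl(pattern, colnames(d)), drop = FALSE]
  d
}

#' Posterior summary table
#'
#' @param fit a `niche_fit`.
#' @param pattern optional regular expression selecting parameters.
#' @return data frame with mean, median, sd and the 2.5/97.5 percentiles of
#'   every selected parameter, pooled over chains.
#' @export
posterior_summary <- function(fit, pattern = NULL) {
  d <- extract_draws(fit, pattern)
  data.frame(parameter = colnames(d),
             mean = colMeans(d),
             median = apply(d, 2L, stats::median),
             sd = apply(d, 2L, stats::sd),
             q2.5 = apply(d, 2L, stats::quantile, probs = 0.025, names = FALSE),
             q97.5 = apply(d, 2L, stats::quantile, probs = 0.975, names = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.niche_fit <- function(x, ...) {
  cat("Trait-modulated Gaussian logistic niche model fit\n")
  cat(sprintf("  sites: %d, species: %d, traits: %d%s\n", x$n, x$m, x$K,
              if (x$latent) sprintf(", latent gradient over %d variables", x$L) else ""))
  cat(sprintf("  prior: %s; chains: %d; kept draws/chain: %d\n",
              x$options$prior, length(x$chains), nrow(x$chains[[1L]]$draws)))
  cat(sprintf("  mean deviance: %.1f\n",
              mean(unlist(lapply(x$chains, function(ch) ch$deviance)))))
  invisible(x)
}

## posterior-mean state of a fit (log-tolerance back-transformed), used by
## the deviance-at-mean evaluation of the DIC
.posterior_mean_state <- function(fit) {
  d <- extract_draws(fit)
  cm <- colMeans(d)
  pick <- function(stem, len)
    unname(cm[paste0(stem, "[", seq_len(len), "]")])
  st <- list(opt = pick("opt", fit$m),
             tol = exp(pick("ltol", fit$m)),
             a = pick("a", fit$m),
             eps = pick("eps", fit$n))
  if (fit$latent) {
    w <- pick("c_env", fit$L)
    st$weights <- .normalized_weights(w)
    st$x <- drop(fit$data$env %*% st$weights)
  } else {
    st$x <- fit$data$x
  }
  st
}
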