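# shared helpers: small simulated fixtures and a minimal fit-shaped object
# for diagnostics tests

# community drawn from the generative model with a single strong trait effect
sim_recovery <- function(seed, n = 200, m = 30, beta1 = 1.5, K = 4) {
  bet <- if (K == 0) NULL else
    list(opt = c(beta1, rep(0, K - 1)), ltol = rep(0, K), a = rep(0, K))
  cfg <- synthetic_config(
    n = n, m = m, L = 1, K_cont = K, K_bin = 0,
    mu = c(opt = 0, ltol = 0, a = 0.5),
    beta = bet,
    sigma_opt = 0.5, sigma_tol = 0.2, sigma_a = 0.5, sigma_site = 0.5,
    seed = seed)
  simulate_community(cfg)
}

# fit-shaped object from bare draw matrices (one per chain), for testing
# summaries and diagnostics without running the sampler
fake_fit <- function(draws_list, deviance_list = NULL, K = 0L, L = 0L,
                     Z = NULL, env = NULL) {
  chains <- lapply(seq_along(draws_list), function(i) {
    list(draws = draws_list[[i]],
         deviance = if (is.null(deviance_list)) numeric(0) else deviance_list[[i]],
         accept = c())
  })
  structure(list(chains = chains,
                 param_names = colnames(draws_list[[1]]),
                 options = mcmc_options(n_iter = 10, n_chains = length(chains)),
                 data = list(Z = Z, env = env),
                 n = 0L, m = 0L, K = K, L = L, latent = !is.null(env),
                 fingerprint = NULL),
            class = "niche_fit")
}

# direct nonlinear maximum likelihood of the Gaussian logistic curve,
# parameterized as (opt, log tol, a): the independent oracle for the
# GLM + reparametrization route
direct_ml_niche <- function(y, x) {
  nll <- function(par) {
    eta <- par[3] - (x - par[1])^2 / (2 * exp(2 * par[2]))
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- optim(c(mean(x[y == 1]), 0, 0), nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  fit <- optim(fit$par, nll, method = "BFGS", control = list(maxit = 1000))
  list(opt = fit$par[1], tol = exp(fit$par[2]), a = fit$par[3])
}

# exhaustive two-sample Wilcoxon rank-sum p-value by enumerating every
# assignment of the pooled observations to group 1
wilcox_exact_enum <- function(v1, v2) {
  pooled <- c(v1, v2)
  r <- rank(pooled)
  n1 <- length(v1)
  idx <- utils::combn(length(pooled), n1)
  # statistic: rank sum of group 1, centered (two-sided)
  obs <- sum(r[seq_len(n1)])
  all_sums <- apply(idx, 2, function(i) sum(r[i]))
  ev <- n1 * (length(pooled) + 1) / 2
  mean(abs(all_sums - ev) >= abs(obs - ev) - 1e-9)
}
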