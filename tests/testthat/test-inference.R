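# small fit used by several blocks below
small_fit <- function(seed = 21, prior = "spike_slab", n_iter = 400,
                      n_chains = 1, K = 2) {
  sim <- sim_recovery(seed = 101, n = 60, m = 6, beta1 = 1, K = K)
  fit <- fit_niche(sim$occ, sim$truth$x, sim$traits,
                   mcmc_options(n_iter = n_iter, n_chains = n_chains,
                                seed = seed, prior = prior))
  list(sim = sim, fit = fit)
}

test_that("log_joint at the optimum of a single cell is log(1/2)", {
  st <- list(opt = 1.3, tol = 1, a = 0, eps = 0,
             mu = c(opt = 0, ltol = 0, a = 0),
             beta = NULL, gamma = NULL,
             sigma2 = c(opt = 1, ltol = 1, a = 1), sigma2_site = 1)
  lj <- log_joint(st, list(y = matrix(1, 1, 1), x = 1.3, Z = NULL))
  expect_equal(attr(lj, "components")$loglik, log(0.5), tolerance = 1e-10)
})

test_that("log_joint equals a term-by-term hand computation", {
  set.seed(15)
  n <- 4; m <- 3; K <- 2
  y <- matrix(rbinom(n * m, 1, 0.5), n, m)
  x <- rnorm(n)
  Z <- matrix(rnorm(m * K), m, K)
  st <- list(opt = rnorm(m), tol = exp(rnorm(m, 0, 0.3)), a = rnorm(m),
             eps = rnorm(n, 0, 0.5),
             mu = c(opt = 0.2, ltol = -0.1, a = 0.4),
             beta = list(opt = c(0.8, 0), ltol = c(0, 0), a = c(0, -0.5)),
             gamma = list(opt = c(1L, 0L), ltol = c(0L, 0L), a = c(0L, 1L)),
             sigma2 = c(opt = 0.8, ltol = 0.3, a = 1.2), sigma2_site = 0.4,
             lambda = 1.5)
  opts <- mcmc_options()
  lj <- log_joint(st, list(y = y, x = x, Z = Z), opts)

  # independent recomputation
  eta <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m)
    eta[i, j] <- st$a[j] - (x[i] - st$opt[j])^2 / (2 * st$tol[j]^2) + st$eps[i]
  ll <- sum(dbinom(y, 1, plogis(eta), log = TRUE))
  pr <- sum(dnorm(st$opt, st$mu[["opt"]] + Z %*% st$beta$opt, sqrt(0.8), log = TRUE)) +
    sum(dnorm(log(st$tol), st$mu[["ltol"]] + Z %*% st$beta$ltol, sqrt(0.3), log = TRUE)) +
    sum(dnorm(st$a, st$mu[["a"]] + Z %*% st$beta$a, sqrt(1.2), log = TRUE)) +
    sum(dnorm(st$eps, 0, sqrt(0.4), log = TRUE))
  laplace <- function(b, lam) log(lam / 2) - lam * abs(b)
  slopes <- 6 * log(0.5) + laplace(0.8, 1.5) + laplace(-0.5, 1.5)
  hyper <- -3 * log(200) - sum(log(2 * 100 * sqrt(c(0.8, 0.3, 1.2, 0.4)))) +
    dgamma(1.5, 1, 1, log = TRUE)
  expect_equal(as.numeric(lj), ll + pr + slopes + hyper, tolerance = 1e-10)

  # slab density at beta = 0 with gamma = 1 contributes log(lambda/2) = log(0.5)
  st2 <- st
  st2$lambda <- 1
  st2$beta$opt <- c(0, 0); st2$gamma$opt <- c(1L, 0L)
  lj2 <- log_joint(st2, list(y = y, x = x, Z = Z), opts)
  st3 <- st2; st3$gamma$opt <- c(0L, 0L)
  lj3 <- log_joint(st3, list(y = y, x = x, Z = Z), opts)
  expect_equal(as.numeric(lj2) - as.numeric(lj3), log(0.5), tolerance = 1e-10)

  # constraint violations yield -Inf
  st4 <- st; st4$tol[1] <- -1
  expect_identical(as.numeric(log_joint(st4, list(y = y, x = x, Z = Z), opts)), -Inf)
  st5 <- st; st5$gamma$opt <- c(0L, 0L)   # beta nonzero but indicator zero
  expect_identical(as.numeric(log_joint(st5, list(y = y, x = x, Z = Z), opts)), -Inf)
})

test_that("identical seeds give bit-identical draws", {
  f1 <- small_fit(seed = 33)$fit
  f2 <- small_fit(seed = 33)$fit
  expect_identical(f1$chains[[1]]$draws, f2$chains[[1]]$draws)
  expect_identical(f1$chains[[1]]$deviance, f2$chains[[1]]$deviance)
  f3 <- small_fit(seed = 34)$fit
  expect_false(identical(f1$chains[[1]]$draws, f3$chains[[1]]$draws))
})

test_that("spike-and-slab zeros are exact and consistent with indicators", {
  res <- small_fit(seed = 35, n_iter = 600)
  d <- extract_draws(res$fit)
  for (th in c("opt", "ltol", "a")) {
    for (k in 1:2) {
      b <- d[, sprintf("beta_%s[%d]", th, k)]
      g <- d[, sprintf("gamma_%s[%d]", th, k)]
      expect_true(all(b[g == 0] == 0))
      expect_true(all(b[g == 1] != 0))
    }
  }
})

test_that("gradient translation shifts posterior optima by the same constant", {
  # the posterior is exactly translation-equivariant; the Monte-Carlo paths
  # are not (floating-point rounding decouples them), so the check is
  # statistical: shifted posterior means agree within Monte-Carlo error
  sim <- sim_recovery(seed = 102, n = 200, m = 6, K = 2)
  opts <- mcmc_options(n_iter = 2000, n_chains = 1, seed = 44)
  f0 <- fit_niche(sim$occ, sim$truth$x, sim$traits, opts)
  cshift <- 1.7
  f1 <- fit_niche(sim$occ, sim$truth$x + cshift, sim$traits, opts)
  m0 <- colMeans(extract_draws(f0, "^opt\\["))
  m1 <- colMeans(extract_draws(f1, "^opt\\["))
  expect_equal(unname(m1 - m0), rep(cshift, 6), tolerance = 0.1)
})

test_that("a zero-column trait table reduces exactly to the no-traits model", {
  sim <- sim_recovery(seed = 103, n = 50, m = 5, K = 2)
  opts <- mcmc_options(n_iter = 300, n_chains = 1, seed = 55)
  ib <- initial_values(sim$occ, sim$truth$x, NULL)
  f_null <- fit_without_traits(sim$occ, sim$truth$x, opts, inits = ib)
  z0 <- trait_table(matrix(numeric(0), 5, 0), standardized = TRUE)
  f_zero <- fit_niche(sim$occ, sim$truth$x, z0, opts, inits = ib)
  expect_identical(f_null$chains[[1]]$draws, f_zero$chains[[1]]$draws)
  expect_true(all(is.finite(f_null$chains[[1]]$deviance)))
})

test_that("recorded deviance matches recomputation from the same draw", {
  res <- small_fit(seed = 36, n_iter = 300)
  fit <- res$fit
  d <- fit$chains[[1]]$draws
  y <- unclass(fit$data$y)
  for (i in c(1, nrow(d) %/% 2, nrow(d))) {
    opt <- d[i, sprintf("opt[%d]", 1:fit$m)]
    tol <- exp(d[i, sprintf("ltol[%d]", 1:fit$m)])
    a <- d[i, sprintf("a[%d]", 1:fit$m)]
    eps <- d[i, sprintf("eps[%d]", 1:fit$n)]
    p <- response_probability(fit$data$x, opt, tol, a, eps)
    dev <- -2 * sum(dbinom(y, 1, p, log = TRUE))
    expect_equal(fit$chains[[1]]$deviance[i], dev, tolerance = 1e-8)
  }
})

test_that("kept draw count honours burn-in and thinning", {
  sim <- sim_recovery(seed = 104, n = 40, m = 4, K = 0)
  fit <- fit_niche(sim$occ, sim$truth$x, NULL,
                   mcmc_options(n_iter = 500, burn_in = 200, thin = 3,
                                n_chains = 2, seed = 66))
  expect_equal(nrow(fit$chains[[1]]$draws), 100L)
  expect_equal(nrow(fit$chains[[2]]$draws), 100L)
  expect_error(mcmc_options(n_iter = 100, burn_in = 100), "smaller")
})
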