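test_that("latent scores are the normalized linear combination", {
  env <- env_table(rbind(c(1, 1), c(2, -1)), standardized = TRUE)

  one <- env_table(cbind(v = c(0.5, -0.5)), standardized = TRUE)
  expect_equal(unname(latent_scores(one, 1)), c(0.5, -0.5))

  expect_equal(unname(latent_scores(env, c(0.6, 0.8))[1]), 1.4)

  # weights are normalized to unit Euclidean norm before use
  expect_equal(latent_scores(env, c(3, 4)), latent_scores(env, c(0.6, 0.8)))

  expect_error(latent_scores(env, c(1, 1, 1)), "length")
})

test_that("latent_weights enforces norm, sign and indicator consistency", {
  w <- latent_weights(c(3, -4, 0))
  expect_equal(sum(w$weights^2), 1, tolerance = 1e-12)
  expect_true(w$weights[1] >= 0)
  expect_equal(w$indicators, c(1L, 1L, 0L))

  # anchor with zero weight: sign fixed by the first non-zero weight
  w2 <- latent_weights(c(0, -2, 1))
  expect_true(w2$weights[2] > 0)

  expect_error(latent_weights(c(1, 0), indicators = c(1L, 1L)), "indicators")
  expect_error(latent_weights(c(0, 0)), "non-zero")
})

test_that("with fixed weights the latent sampler reduces to the plain fit", {
  cfg <- synthetic_config(n = 50, m = 5, L = 3,
                          mu = c(opt = 0, ltol = 0, a = 0.5),
                          latent_weights = c(1, -1, 0), seed = 16)
  sim <- simulate_community(cfg)
  w0 <- c(1, -1, 0) / sqrt(2)
  scores <- latent_scores(sim$env, w0)
  ib <- initial_values(sim$occ, scores, NULL)
  opts <- mcmc_options(n_iter = 300, n_chains = 1, seed = 77)
  f_lat <- fit_latent(sim$occ, sim$env, NULL, opts, inits = ib,
                      weights_init = w0, update_weights = FALSE)
  f_plain <- fit_niche(sim$occ, scores, NULL, opts, inits = ib)
  shared <- colnames(f_plain$chains[[1]]$draws)
  expect_identical(f_lat$chains[[1]]$draws[, shared],
                   f_plain$chains[[1]]$draws)
  # frozen weights are reported unchanged
  expect_true(all(abs(sweep(extract_draws(f_lat, "^c_env"), 2, w0)) < 1e-12))
})

test_that("excluded environmental variables have weight exactly zero in draws", {
  cfg <- synthetic_config(n = 80, m = 8, L = 3,
                          mu = c(opt = 0, ltol = 0, a = 0.5),
                          latent_weights = c(1, 0, 0), seed = 17)
  sim <- simulate_community(cfg)
  fit <- fit_latent(sim$occ, sim$env, NULL,
                    mcmc_options(n_iter = 800, n_chains = 1, seed = 88))
  cw <- extract_draws(fit, "^c_env\\[")
  gw <- extract_draws(fit, "^gamma_env\\[")
  expect_true(all(cw[gw == 0] == 0))
  expect_true(any(gw == 0))              # at least some delete moves accepted
  # sign convention holds on every draw: anchor weight never negative
  expect_true(all(cw[, 1] >= 0))
})

test_that("a single environmental variable reproduces the measured-gradient fit", {
  cfg <- synthetic_config(n = 120, m = 10, L = 1,
                          mu = c(opt = 0, ltol = 0, a = 0.5),
                          sigma_opt = 1, seed = 18)
  sim <- simulate_community(cfg)
  x <- unclass(sim$env)[, 1]
  opts <- mcmc_options(n_iter = 1500, n_chains = 1, seed = 99)
  f_lat <- fit_latent(sim$occ, sim$env, NULL, opts)
  f_plain <- fit_niche(sim$occ, x, NULL, opts)
  # with L = 1 the normalized weight is +1, so niche posteriors must agree
  # up to Monte-Carlo error
  expect_true(all(extract_draws(f_lat, "^c_env") %in% c(0, 1)))
  o_lat <- colMeans(extract_draws(f_lat, "^opt\\["))
  o_plain <- colMeans(extract_draws(f_plain, "^opt\\["))
  expect_gt(cor(o_lat, o_plain), 0.98)
  expect_lt(max(abs(o_lat - o_plain)), 0.35)
})

test_that("sign-flip gauge leaves the log joint unchanged", {
  cfg <- synthetic_config(n = 40, m = 5, L = 4,
                          mu = c(opt = 0, ltol = 0, a = 0.5),
                          latent_weights = c(1, -1, 0.5, 0), seed = 19)
  sim <- simulate_community(cfg)
  set.seed(20)
  for (i in 1:5) {
    st <- list(opt = rnorm(5), tol = exp(rnorm(5, 0, 0.3)), a = rnorm(5),
               eps = rnorm(40, 0, 0.5),
               mu = c(opt = rnorm(1), ltol = 0, a = 0.3),
               beta = NULL, gamma = NULL,
               sigma2 = c(opt = 1, ltol = 0.2, a = 0.8), sigma2_site = 0.3,
               w = rnorm(4) * c(1, 1, 1, 0), gamma_env = c(1L, 1L, 1L, 0L),
               lambda_env = runif(1, 0.5, 3))
    dat <- list(y = sim$occ, env = sim$env, Z = NULL)
    lj <- log_joint(st, dat)
    flip <- st
    flip$w <- -st$w; flip$opt <- -st$opt; flip$mu[["opt"]] <- -st$mu[["opt"]]
    expect_equal(as.numeric(log_joint(flip, dat)), as.numeric(lj),
                 tolerance = 1e-10)
  }
})
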