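test_that("absence augmentation appends zeros strictly outside the range", {
  x <- seq(0, 10, length.out = 21)
  y <- as.numeric(x > 6)
  aug <- augment_absences(y, x)
  expect_length(aug$y, length(y) + 50)
  expect_identical(aug$y[seq_along(y)], y)          # originals first, unchanged
  expect_identical(aug$x[seq_along(x)], x)
  added <- aug$x[-seq_along(x)]
  expect_true(all(aug$y[-seq_along(y)] == 0))
  expect_equal(sum(added > -10 & added < 0), 25)
  expect_equal(sum(added > 10 & added < 20), 25)
  expect_true(all(added < 0 | added > 10))

  # n_aug = 0 is the identity
  expect_identical(augment_absences(y, x, n_aug = 0), list(y = y, x = x))
  expect_error(augment_absences(y, rep(1, length(y))), "non-constant")
})

test_that("augmentation turns a monotone (truncated) species into a proper curve", {
  set.seed(4)
  x <- rnorm(300)
  # optimum far outside the sampled range: monotone increase within it
  p <- response_probability(x, opt = 4, tol = 1.5, a = 2)
  y <- rbinom(300, 1, p)
  aug <- augment_absences(y, x)
  fit <- fit_species_glm(aug$y, aug$x)
  expect_lt(fit$b2, 0)
  niche <- poly_to_niche(fit)
  expect_gt(niche$opt, 1)                # optimum pulled toward the upper edge
})

test_that("quadratic-logit GLM estimates the Bernoulli ML solution", {
  # symmetry about zero forces the linear coefficient to vanish
  x <- seq(-3, 3, by = 0.1)
  y <- as.numeric(abs(x) <= 1)
  fit <- fit_species_glm(y, x)
  expect_lt(abs(fit$b1), 1e-6)

  expect_error(fit_species_glm(rep(0, 10), 1:10), "degenerate response")
  expect_error(fit_species_glm(rep(1, 10), 1:10), "degenerate response")

  # ML recovery on a simulated species, against direct nonlinear ML
  set.seed(5)
  x <- rnorm(2000)
  y <- rbinom(2000, 1, response_probability(x, opt = 0.5, tol = 1, a = 1))
  glm_niche <- poly_to_niche(fit_species_glm(y, x))
  ml <- direct_ml_niche(y, x)
  expect_equal(glm_niche$opt, ml$opt, tolerance = 1e-4)
  expect_equal(glm_niche$tol, ml$tol, tolerance = 1e-4)
  expect_equal(glm_niche$a, ml$a, tolerance = 1e-4)
  # and close to the generating values at this sample size
  expect_equal(glm_niche$opt, 0.5, tolerance = 0.15)
  expect_equal(glm_niche$tol, 1, tolerance = 0.15)
})

test_that("poly_to_niche applies the closed-form reparametrization", {
  n1 <- poly_to_niche(list(b0 = 0, b1 = 0, b2 = -0.5))
  expect_equal(unlist(n1[c("opt", "tol", "a", "p_max")]),
               c(opt = 0, tol = 1, a = 0, p_max = 0.5))

  n2 <- poly_to_niche(list(b0 = -2, b1 = 4, b2 = -2))
  expect_equal(n2$opt, 1)
  expect_equal(n2$tol, 0.5)
  expect_equal(n2$a, 0)
  # argmax and value check on a dense grid of the quadratic itself
  g <- seq(-3, 3, by = 1e-4)
  q <- -2 + 4 * g - 2 * g^2
  expect_equal(g[which.max(q)], n2$opt, tolerance = 1e-3)
  expect_equal(max(q), n2$a, tolerance = 1e-6)

  expect_error(poly_to_niche(list(b0 = 0, b1 = 0, b2 = 0.1)),
               "no interior optimum")
})

test_that("niche -> quadratic -> niche is the identity", {
  set.seed(6)
  for (i in 1:20) {
    niche <- gaussian_niche(rnorm(1, 0, 2), exp(rnorm(1, 0, 0.5)), rnorm(1))
    back <- poly_to_niche(niche_to_poly(niche))
    expect_equal(back$opt, niche$opt, tolerance = 1e-12)
    expect_equal(back$tol, niche$tol, tolerance = 1e-12)
    expect_equal(back$a, niche$a, tolerance = 1e-12)
  }
})

test_that("initial_values handles null designs, fallbacks and OLS submodels", {
  set.seed(7)
  sim <- sim_recovery(seed = 71, n = 80, m = 12)
  occ <- sim$occ

  # all-zero trait columns: slopes zero, intercepts are the niche means
  Z0 <- trait_table(matrix(0.0, 12, 2), kinds = c("continuous", "continuous"),
                    standardized = TRUE)
  ib <- initial_values(occ, sim$truth$x, Z0)
  expect_equal(ib$submodels$opt$slopes, c(0, 0))
  expect_equal(ib$submodels$opt$intercept, mean(ib$niches$opt))

  # an all-absent species takes the fallback path
  y <- unclass(occ)
  y[, 3] <- 0
  ib2 <- initial_values(occurrence_matrix(y), sim$truth$x, NULL)
  expect_true(ib2$niches$fallback[3])
  expect_equal(ib2$niches$opt[3], 0)
  expect_equal(ib2$niches$tol[3], 1)

  # JSON round trip
  path <- tempfile(fileext = ".json")
  write_init_bundle(ib2, path)
  back <- read_init_bundle(path)
  expect_equal(back$niches$opt, ib2$niches$opt, tolerance = 1e-12)
  expect_equal(back$submodels$opt$sigma2, ib2$submodels$opt$sigma2,
               tolerance = 1e-12)
})

test_that("recovered OLS slope signs match strong generating effects", {
  sim <- sim_recovery(seed = 72, n = 200, m = 30, beta1 = 1.5)
  ib <- initial_values(sim$occ, sim$truth$x, sim$traits)
  expect_gt(ib$submodels$opt$slopes[1], 0)
  expect_gt(abs(ib$submodels$opt$slopes[1]),
            max(abs(ib$submodels$opt$slopes[-1])))
})
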