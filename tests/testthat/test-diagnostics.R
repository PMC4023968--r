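test_that("DIC matches hand computation on tiny deviance traces", {
  # constant deviance: both p_D estimators vanish
  r0 <- compute_dic(rep(100, 5), D_hat = 100)
  expect_equal(r0$p_D_classic, 0)
  expect_equal(r0$p_D_var, 0)
  expect_equal(r0$DIC_classic, 100)
  expect_equal(r0$DIC_var, 100)

  # one chain {98, 102}, D_hat = 99
  r <- compute_dic(c(98, 102), D_hat = 99)
  expect_equal(r$D_bar, 100)
  expect_equal(r$p_D_classic, 1)
  expect_equal(r$DIC_classic, 101)
  expect_equal(r$p_D_var, 4)            # var with n-1 denominator: 8/2
  expect_equal(r$DIC_var, 104)
  expect_false(r$flag_negative_pD)

  # negative classic p_D is reported and flagged, never truncated
  rn <- compute_dic(c(98, 102), D_hat = 105)
  expect_equal(rn$p_D_classic, -5)
  expect_true(rn$flag_negative_pD)

  expect_error(compute_dic(100, D_hat = 99), "at least 2")
  expect_error(compute_dic(c(98, NaN), D_hat = 99), "non-finite")
})

test_that("DIC identities hold on a real fit", {
  sim <- sim_recovery(seed = 105, n = 60, m = 6, K = 0)
  fit <- fit_niche(sim$occ, sim$truth$x, NULL,
                   mcmc_options(n_iter = 400, n_chains = 2, seed = 23))
  r <- compute_dic(fit)
  expect_equal(r$DIC_classic, r$D_bar + r$p_D_classic, tolerance = 1e-10)
  expect_equal(r$DIC_classic, r$D_hat + 2 * r$p_D_classic, tolerance = 1e-10)
  expect_equal(r$DIC_var, r$D_bar + r$p_D_var, tolerance = 1e-10)
  expect_gte(r$p_D_var, 0)
})

test_that("variance-explained fractions follow the defining identity", {
  expect_equal(variance_explained_pct(2.0, 1.0), 50)
  expect_equal(variance_explained_pct(1.3, 1.3), 0)

  # published-style arithmetic: components 2.31 / 1.14 give about 50.6%,
  # consistent with a printed 50.45 once the components are rounded to
  # two decimals
  pct <- variance_explained_pct(2.31, 1.14)
  expect_equal(pct, 50.649, tolerance = 1e-3)
  lo <- variance_explained_pct(2.305, 1.145)
  hi <- variance_explained_pct(2.315, 1.135)
  expect_true(lo <= 50.45 && 50.45 <= hi)

  # antisymmetry: fraction(a,b) = -fraction(b,a) * sigma_b / sigma_a
  set.seed(24)
  for (i in 1:10) {
    s <- runif(2, 0.1, 5)
    expect_equal(variance_explained_pct(s[1], s[2]),
                 -variance_explained_pct(s[2], s[1]) * s[2] / s[1],
                 tolerance = 1e-10)
  }
})

test_that("variance_explained compares matched fits only", {
  sim <- sim_recovery(seed = 106, n = 50, m = 6, K = 2)
  opts <- mcmc_options(n_iter = 300, n_chains = 1, seed = 25)
  f_with <- fit_niche(sim$occ, sim$truth$x, sim$traits, opts)
  f_wo <- fit_without_traits(sim$occ, sim$truth$x, opts)
  ve <- variance_explained(f_with, f_wo)
  expect_equal(ve$parameter, c("opt", "ltol", "a"))
  expect_true(all(ve$fraction_pct <= 100))
  expect_equal(ve$fraction_pct,
               100 * (ve$sigma2_without - ve$sigma2_with) / ve$sigma2_without)

  sim2 <- sim_recovery(seed = 107, n = 50, m = 6, K = 2)
  f_other <- fit_without_traits(sim2$occ, sim2$truth$x, opts)
  expect_error(variance_explained(f_with, f_other), "fingerprint")
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(26)
  mk <- function(v) matrix(v, ncol = 1, dimnames = list(NULL, "theta"))
  good <- fake_fit(list(mk(rnorm(2000)), mk(rnorm(2000))))
  r <- convergence_report(good)
  expect_lt(abs(r$rhat - 1), 0.05)

  bad <- fake_fit(list(mk(rnorm(500)), mk(rnorm(500, 10))))
  rb <- convergence_report(bad)
  expect_gt(rb$rhat, 1.1)
  expect_identical(attr(rb, "flagged"), "theta")

  # single chain: R-hat omitted with a notice, ESS still reported
  single <- fake_fit(list(mk(rnorm(500))))
  expect_message(rs <- convergence_report(single), "single chain")
  expect_true(is.na(rs$rhat))
  expect_gt(rs$ess, 0)
})

test_that("ESS tracks the analytic value for an AR(1) chain", {
  set.seed(27)
  N <- 40000
  rho <- 0.5
  ar <- as.numeric(stats::filter(rnorm(N), rho, method = "recursive"))
  f <- fake_fit(list(matrix(ar, ncol = 1, dimnames = list(NULL, "theta"))))
  suppressMessages(r <- convergence_report(f))
  expect_equal(r$ess / N, (1 - rho) / (1 + rho), tolerance = 0.2)

  # cross-check the estimator against an established implementation
  expect_equal(r$ess, unname(coda::effectiveSize(coda::mcmc(ar))),
               tolerance = 0.25)
})

test_that("inclusion probabilities average the indicator draws", {
  g <- cbind("gamma_opt[1]" = c(1, 1, 0, 1), "gamma_opt[2]" = rep(0, 4),
             "beta_opt[1]" = rnorm(4), "beta_opt[2]" = rep(0, 4))
  f <- fake_fit(list(g), K = 2L, Z = matrix(0, 3, 2,
                dimnames = list(NULL, c("volume", "mucilage"))))
  ip <- inclusion_probabilities(f)
  expect_equal(ip$prob[ip$variable == "volume"], 0.75)
  expect_equal(ip$prob[ip$variable == "mucilage"], 0)

  f2 <- fake_fit(list(cbind("beta_opt[1]" = rnorm(4))), K = 1L)
  expect_error(inclusion_probabilities(f2), "no indicators")
})
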