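test_that("log prior is additive over components and enforces supports", {
  p <- parameter_set(); op <- observation_params(); pr <- prior_spec()
  lp <- log_prior(p, op, pr)
  expect_true(is.finite(lp))
  comp <- attr(lp, "components")
  # dropping one component changes the total by exactly that density
  lp_noM0 <- log_prior(p, op, pr, drop = "M0")
  expect_equal(as.numeric(lp) - as.numeric(lp_noM0), comp[["M0"]])
  # a non-negative selectivity is outside the truncated-normal support
  bad <- p; bad$sel[2] <- 0.1
  expect_equal(as.numeric(log_prior(bad, op, pr)), -Inf)
  # a beta beyond its uniform upper limit has zero density
  bad2 <- p; bad2$beta0 <- 2 * pr$uppers$beta0
  expect_equal(as.numeric(log_prior(bad2, op, pr)), -Inf)
})

test_that("log posterior assembles likelihood, process terms and priors", {
  cfg <- noise_free(short_scenario())
  d <- generate_dataset(cfg)
  p <- cfg$params; p$sigma_E <- 0.3; p$sigma_O <- 0.3; p$sigma_U <- 0.1
  op <- observation_params()
  pr <- prior_spec()
  lp <- log_posterior(d$truth$latent, d$obs, p, op, pr)
  expect_true(is.finite(lp))
  comp <- attr(lp, "components")
  expect_equal(as.numeric(lp), sum(comp))
  expect_equal(comp[["likelihood"]],
               log_likelihood(d$truth$latent, d$obs, op))
  # dropping the likelihood leaves process + prior + init
  lp2 <- log_posterior(d$truth$latent, d$obs, p, op, pr,
                       drop = "likelihood")
  expect_equal(as.numeric(lp) - as.numeric(lp2), comp[["likelihood"]])
  # out-of-support parameter: -Inf by contract
  bad <- p; bad$sel[1] <- 0.5
  expect_equal(as.numeric(log_posterior(d$truth$latent, d$obs, bad, op, pr)),
               -Inf)
})

test_that("the log posterior is stationary at the noise-free truth", {
  cfg <- noise_free(short_scenario())
  d <- generate_dataset(cfg)
  covars <- d$covars
  p <- cfg$params; p$sigma_E <- 0.2; p$sigma_O <- 0.2; p$sigma_U <- 0.1
  op <- observation_params()
  pr <- prior_spec()
  Y <- cfg$ages$n_years
  # survey-index terms peak exactly at the generating latents; landings are
  # excluded because their mean-one correction shifts the mode when the
  # evaluation sigma_C differs from the (zero) generating value
  obs <- d$obs
  obs$landings[] <- NA_real_

  lp_at <- function(h, y) {
    sh <- d$truth$latent$shocks
    sh$eps_E[y] <- sh$eps_E[y] + h
    lat <- simulate_forward(p, covars, d$truth$latent$N[, 1], shocks = sh)
    as.numeric(log_posterior(lat, obs, p, op, pr))
  }
  for (y in c(2, 7)) {
    g <- (lp_at(1e-4, y) - lp_at(-1e-4, y)) / 2e-4
    expect_lt(abs(g), 0.01)
  }
})

test_that("scale-reduction diagnostics are calibrated on white noise", {
  set.seed(1)
  chains <- coda::mcmc.list(lapply(1:3, function(i) coda::mcmc(
    cbind(theta = rnorm(4000), phi = rnorm(4000, 5, 2)))))
  rep <- convergence_report(chains)
  expect_equal(rep$rhat, c(1, 1), tolerance = 0.01)
  expect_true(all(rep$rhat_ok & rep$geweke_ok & rep$autocorr_ok))
  expect_true(all(rep$ess > 1000))
})

test_that("disagreeing chains are detected", {
  set.seed(2)
  x <- rnorm(2000)
  chains <- coda::mcmc.list(coda::mcmc(cbind(theta = x)),
                            coda::mcmc(cbind(theta = x + 3)))
  rep <- convergence_report(chains)
  expect_gt(rep$rhat, 1.5)
  expect_false(rep$rhat_ok)
  expect_error(convergence_report(coda::mcmc.list(coda::mcmc(cbind(x)))),
               "at least 2 chains")
})

test_that("thinning an AR(1) chain by 10 nearly removes lag-1 autocorrelation", {
  set.seed(3)
  full <- as.numeric(arima.sim(list(ar = 0.5), 40000))
  thinned <- full[seq(1, 40000, by = 10)]
  chains <- coda::mcmc.list(coda::mcmc(cbind(theta = thinned[1:2000])),
                            coda::mcmc(cbind(theta = thinned[2001:4000])))
  rep <- convergence_report(chains)
  # 0.5^10 ~ 0.001, indistinguishable from white noise at this length
  expect_lt(abs(rep$lag1_autocorr), 0.05)
  expect_true(rep$autocorr_ok)
})

test_that("the uniform-upper audit flags posteriors that hit their bounds", {
  pr <- prior_spec()
  fake_fit <- function(beta0) {
    m <- cbind(beta0 = beta0, sigma_E = rep(0.7, 100))
    structure(list(mcmc = coda::mcmc.list(coda::mcmc(m))),
              class = "codcycle_fit")
  }
  ok <- audit_uniform_uppers(fake_fit(rep(2e-9, 100)), pr)
  expect_false(any(ok$flag))
  expect_warning(bad <- audit_uniform_uppers(fake_fit(rep(9.9e-9, 100)), pr),
                 "upper limit")
  expect_true(bad$flag[bad$parameter == "beta0"])
})

test_that("fits are exactly reproducible given the seed", {
  d <- generate_dataset(reduced_scenario(n_years = 10L, seed = 5))
  cfg <- fit_config(n_chains = 2, n_adapt = 100, n_burn = 100, n_iter = 150,
                    thin = 1, monitor_latent = FALSE, seed = 42)
  f1 <- suppressWarnings(fit_lifecycle(d$obs, d$covars,
                                       priors = reduced_priors(),
                                       config = cfg))
  f2 <- suppressWarnings(fit_lifecycle(d$obs, d$covars,
                                       priors = reduced_priors(),
                                       config = cfg))
  expect_identical(as.matrix(f1$mcmc), as.matrix(f2$mcmc))
  expect_equal(f1$meta$backend, f2$meta$backend)
  expect_true(all(c("M0", "MJ", "beta0", "sigma_E") %in%
                    coda::varnames(f1$mcmc)))
})

test_that("credible intervals cover the truth across replicate fits", {
  # scaled-down recovery study: reduced model, 20 short replicate fits
  pars <- c("M0", "MJ", "beta0", "beta[1]", "beta[2]", "beta[3]", "sigma_E")
  truth <- c(0.35, 0.15, 1.82e-9, 9.48e-11, 1.69e-10, 2.27e-10, 0.7)
  names(truth) <- pars
  n_rep <- 20
  covered <- matrix(NA, n_rep, length(pars),
                    dimnames = list(NULL, pars))
  for (i in seq_len(n_rep)) {
    d <- generate_dataset(reduced_scenario(n_years = 15L, seed = 100 + i))
    cfg <- fit_config(n_chains = 2, n_adapt = 100, n_burn = 500,
                      n_iter = 700, thin = 1, monitor_latent = FALSE,
                      seed = i)
    fit <- suppressWarnings(fit_lifecycle(d$obs, d$covars,
                                          priors = reduced_priors(),
                                          config = cfg))
    ps <- posterior_summary(fit)
    rownames(ps) <- ps$parameter
    covered[i, ] <- ps[pars, "lower"] <= truth & truth <= ps[pars, "upper"]
  }
  # overall and per-parameter coverage of the 95% intervals
  expect_gte(mean(covered), 0.9)
  expect_true(all(colMeans(covered) >= 0.85))
})
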