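make_draws <- function(MJ, b1, b2, b3) {
  m <- cbind(MJ, b1, b2, b3)
  colnames(m) <- c("MJ", "beta[1]", "beta[2]", "beta[3]")
  m
}

test_that("survival from age 1 to 4 follows the cohort through the BH terms", {
  N <- matrix(1e9, 3, 6, dimnames = list(1:3, 2000:2005))
  # density-independent: exp(-3 MJ) for every cohort
  d0 <- make_draws(0.15, 0, 0, 0)
  out <- survival_1to4(d0, N)
  expect_equal(out$median, rep(exp(-0.45), 4), tolerance = 1e-12)
  # abundances back-solved so the three age survivals are 0.77, 0.75, 0.76
  b <- c(9.48e-11, 1.69e-10, 2.27e-10)
  n_abc <- (exp(-0.15) / c(0.77, 0.75, 0.76) - 1) / b
  N2 <- matrix(rep(n_abc, 6), 3, 6)
  out2 <- survival_1to4(make_draws(0.15, b[1], b[2], b[3]), N2)
  expect_equal(out2$median[1], 0.77 * 0.75 * 0.76, tolerance = 1e-6)
  # survival decreases in every age-class abundance
  for (a in 1:3) {
    N3 <- N2; N3[a, ] <- N3[a, ] * 10
    out3 <- survival_1to4(make_draws(0.15, b[1], b[2], b[3]), N3)
    expect_true(all(out3$median < out2$median))
  }
  # draw-order invariance of the percentile summaries
  dr <- make_draws(runif(200, 0.1, 0.2), runif(200, 0, 2e-10),
                   runif(200, 0, 2e-10), runif(200, 0, 3e-10))
  expect_equal(survival_1to4(dr, N2), survival_1to4(dr[sample(200), ], N2))
})

test_that("interannual variance uses the sample convention on logs", {
  expect_equal(interannual_variance(rep(3.7, 10)), 0)
  # alternating exp(+/- sigma): sample variance is sigma^2 * n/(n-1)
  sig <- 0.6; n <- 20
  series <- exp(rep(c(sig, -sig), n / 2))
  expect_equal(interannual_variance(series), sig^2 * n / (n - 1))
  expect_error(interannual_variance(c(1, -2, 3)), "strictly positive")
  expect_error(interannual_variance(2), "at least 2")
})

test_that("year-class ratios measure max/min cohort strength", {
  expect_equal(yearclass_ratio(rep(5, 8)), 1)
  expect_equal(yearclass_ratio(c(2, 86)), 43)
  expect_error(yearclass_ratio(numeric(0)), "empty")
  expect_error(yearclass_ratio(c(1, 0, 2)), "strictly positive")
})

test_that("variance dampening shows up in stage variances and year-class ratios", {
  cfg <- scenario_config(seed = 5)
  covars <- generate_covariates(cfg)
  Y <- cfg$ages$n_years
  p_off <- cfg$params
  p_off$beta0 <- 0; p_off$beta <- c(0, 0, 0)
  set.seed(31)
  ratio_damped <- logical(30)
  var_damped <- logical(30)
  for (i in 1:30) {
    sh <- list(eps_E = rnorm(Y, 0, cfg$params$sigma_E),
               eps_O = rnorm(Y, 0, cfg$params$sigma_O),
               u_innov = rnorm(Y, 0, cfg$params$sigma_U))
    on <- simulate_forward(cfg$params, covars, cfg$initial_N, shocks = sh)
    v <- variance_by_stage(on)
    var_damped[i] <- v["age1"] > v["age4"]
    ratio_damped[i] <- yearclass_ratio(on$N[4, ]) < yearclass_ratio(on$N[1, ])
  }
  expect_gte(mean(var_damped), 0.95)
  expect_gte(mean(ratio_damped), 0.95)
})

test_that("recruits per 0-group decline with 0-group abundance under DD", {
  cfg <- noise_free(scenario_config(seed = 9))
  # spawning stochasticity varies the 0-group; with intracohort DD only,
  # recruits-per-0-group is a deterministic decreasing function of it
  cfg$params$sigma_E <- 0.7
  cfg$params$beta0 <- 0
  d <- generate_dataset(cfg)
  rp <- recruits_per_0group(d$truth$latent)
  expect_equal(nrow(rp), cfg$ages$n_years - 4)
  expect_true(all(rp$recruits_per_0group > 0))
  expect_lt(cor(rp$zerogroup, rp$recruits_per_0group, method = "spearman"),
            -0.99)
})

test_that("bootstrap survival correlation detects density dependence without shared-error bias", {
  # accurate surveys, no catchability regime change, strong intracohort DD
  quality <- observation_params(q_pre = exp(c(-11.5, -11.3)),
                                q_post = exp(c(-11.5, -11.3)),
                                sigma_I = rep(0.15, 9), sigma_year = 0.05,
                                sigma_0g = 0.15)
  p_dd <- parameter_set(sigma_E = 1.2, sigma_O = 0.05, beta0 = 0,
                        beta = 3 * c(9.48e-11, 1.69e-10, 2.27e-10))
  strong <- scenario_config(params = p_dd, obs_params = quality,
                            winter_start = 1959L, seed = 14)
  d <- generate_dataset(strong)
  r2 <- bootstrap_survival_correlation(d$obs$index_winter, 2,
                                       n_boot = 2000, seed = 1)
  expect_lt(r2$ci[2], 0) # upper bound below zero: DD detected

  # same observation quality, no density dependence: CI covers zero
  p_off <- p_dd
  p_off$beta <- c(0, 0, 0)
  off <- scenario_config(params = p_off, obs_params = quality,
                         winter_start = 1959L, seed = 14)
  d0 <- generate_dataset(off)
  r0 <- bootstrap_survival_correlation(d0$obs$index_winter, 2,
                                       n_boot = 2000, seed = 1)
  expect_gt(r0$ci[2], 0)
  expect_lt(r0$ci[1], 0)

  # deterministic resampling given a seed
  ra <- bootstrap_survival_correlation(d$obs$index_winter, 3,
                                       n_boot = 500, seed = 7)
  rb <- bootstrap_survival_correlation(d$obs$index_winter, 3,
                                       n_boot = 500, seed = 7)
  expect_identical(ra, rb)
  expect_error(bootstrap_survival_correlation(d$obs$index_winter[, 1:5], 2),
               "at least 5")
})

test_that("predicted age-class curves have the right limits and bands", {
  grid <- seq(1e8, 2e10, length.out = 40)
  # point draws with beta = 0: straight line of slope exp(-MJ)
  d0 <- make_draws(0.15, 0, 0, 0)
  out <- predicted_ageclass_curve(d0, 1, grid)
  expect_equal(out$median, grid * exp(-0.15), tolerance = 1e-12)
  # saturation at exp(-MJ)/beta for N far beyond 1/beta
  d1 <- make_draws(0.15, 9.48e-11, 1.69e-10, 2.27e-10)
  far <- seq(1e8, 2e11, length.out = 40)
  out1 <- predicted_ageclass_curve(d1, 2, far)
  expect_equal(out1$median[40], exp(-0.15) / 1.69e-10, tolerance = 0.05)
  # wider posterior spread of beta widens the band
  set.seed(2)
  narrow <- make_draws(rep(0.15, 500), 0, runif(500, 1.4e-10, 2.0e-10), 0)
  wide <- make_draws(rep(0.15, 500), 0, runif(500, 0.4e-10, 3.0e-10), 0)
  bn <- predicted_ageclass_curve(narrow, 2, grid)
  bw <- predicted_ageclass_curve(wide, 2, grid)
  expect_true(all(bw$upper - bw$lower >= bn$upper - bn$lower))
})

test_that("temperature-recruit pairs align cohorts four years apart", {
  cfg <- noise_free(short_scenario())
  d <- generate_dataset(cfg)
  tr <- temp_recruit_table(d$truth$latent, d$covars)
  expect_equal(tr$recruits, d$truth$latent$N[4, 5:cfg$ages$n_years],
               ignore_attr = TRUE)
  expect_equal(tr$temperature, d$covars$temperature[1:(cfg$ages$n_years - 4)])
})
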