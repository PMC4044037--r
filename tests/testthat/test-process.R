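test_that("spawning stock biomass sums abundance x weight x maturity", {
  # single mature age class: 1e9 fish x 2 kg x 0.5 maturity
  N <- numeric(9); w <- rep(1, 9); p <- numeric(9)
  N[6] <- 1e9; w[6] <- 2; p[6] <- 0.5
  expect_equal(compute_ssb(N, w, p), 1e9)
  expect_equal(compute_ssb(N, w, numeric(9)), 0)
  expect_equal(compute_ssb(c(1e8, 2e8, 3e8), c(1, 2, 3), c(0, 0.5, 1)),
               1.1e9)
  expect_error(compute_ssb(N, w[1:5], p), "same age range")
})

test_that("egg production converts fecundity per gram and applies the shock", {
  expect_equal(egg_production(1e9, 235), 2.35e14)
  expect_equal(egg_production(0, 235), 0)
  expect_equal(egg_production(1e9, 235, eps = 0.7) / egg_production(1e9, 235),
               exp(0.7))
  expect_error(egg_production(-1, 235), "non-negative")
})

test_that("egg to larva survival is exponential in egg mortality and duration", {
  expect_equal(egg_to_larva(1, 0.169, 20), exp(-3.38))
  expect_equal(egg_to_larva(5e8, 0.169, 0), 5e8)
  expect_equal(egg_to_larva(2.35e14, 0.169, 20), 2.35e14 * exp(-3.38))
})

test_that("larva to 0-group survival splits larval and early-juvenile phases", {
  p <- parameter_set(gamma = 0)
  # 60 d at 0.075/d plus 60 d at 0.04/d
  expect_equal(larva_to_zerogroup(1, 0, p), exp(-6.9))
  # zero anomaly: gamma irrelevant
  expect_equal(larva_to_zerogroup(1e12, 0, parameter_set(gamma = 0.01)),
               larva_to_zerogroup(1e12, 0, p))
  # gamma = ln(1.5)/(2 * 60) gives a 1.5-fold survival span over +/-1 degree
  g <- log(1.5) / 120
  pg <- parameter_set(gamma = g)
  expect_equal(larva_to_zerogroup(1, 1, pg) / larva_to_zerogroup(1, -1, pg),
               1.5)
  # implausibly warm year: survival capped at 1, with a warning
  hot <- parameter_set(gamma = 0.1)
  expect_warning(o <- larva_to_zerogroup(1e6, 10, hot), "capped")
  expect_equal(o, 1e6)
})

test_that("0-group to age 1 survival is Beverton-Holt in cannibal abundance", {
  p <- parameter_set(M0 = 0.35)
  expect_equal(zerogroup_to_age1(1, 0, p), exp(-0.35))
  # at the reported cannibal coefficient and ~4e8 cannibals, survival ~0.41
  s <- zerogroup_to_age1(1, 4e8, p) # beta0 = 1.82e-9 default
  expect_equal(s, exp(-0.35) / (1 + 1.82e-9 * 4e8))
  expect_true(abs(s - 0.41) < 0.01)
  # a large positive shock cannot push survival above 1
  expect_equal(zerogroup_to_age1(1, 0, p, eps = 5), 1)
  expect_error(zerogroup_to_age1(-1, 0, p), "non-negative")
})

test_that("juvenile transition is compensatory with the right asymptote", {
  p0 <- parameter_set(MJ = 0.15, beta = c(0, 0, 0))
  expect_equal(juvenile_transition(1, 1, p0), exp(-0.15))
  # reported beta1 at calibrated age-1 abundance gives survival ~0.77
  p <- parameter_set(MJ = 0.15)
  s1 <- juvenile_transition(1.25e9, 1, p) / 1.25e9
  expect_equal(s1, exp(-0.15) / (1 + 9.48e-11 * 1.25e9))
  expect_true(abs(s1 - 0.77) < 0.01)
  # monotone increasing, saturating at exp(-MJ)/beta
  grid <- 10^seq(6, 12, by = 0.5)
  out <- juvenile_transition(grid, 2, p)
  expect_true(all(diff(out) > 0))
  expect_lt(max(out), exp(-p$MJ) / p$beta[2])
  expect_gt(juvenile_transition(1e13, 2, p), 0.99 * exp(-p$MJ) / p$beta[2])
  expect_error(juvenile_transition(1e9, 5, p), "no intracohort")
})

test_that("adult transition and separable fishing mortality behave as contracts say", {
  expect_equal(adult_transition(1, 0, 0.2), exp(-0.2))
  expect_equal(adult_transition(1, 0.5, 0.2), exp(-0.7))
  expect_equal(adult_transition(0, 0.5, 0.2), 0)
  expect_equal(fishing_mortality(-1.6, 0), exp(-1.6))
  # separability: a log(2) effort change doubles F at every age
  s <- c(-1.6, -1.2, -0.8)
  expect_equal(fishing_mortality(s, log(2)), 2 * fishing_mortality(s, 0))
  expect_equal(fishing_mortality(-1.6, 0.4) / fishing_mortality(-1.2, 0.4),
               exp(-0.4))
  # matrix builder: zero below recruitment age, separable across years
  ages <- age_structure(n_years = 5)
  Fm <- fishing_mortality_matrix(parameter_set(), c(0, 0.1, 0.2, 0.1, 0),
                                 ages)
  expect_true(all(Fm[1:3, ] == 0))
  ratio <- Fm[5, ] / Fm[9, ]
  expect_equal(ratio, rep(ratio[1], 5), ignore_attr = TRUE)
})

test_that("effort random walk accumulates variance linearly", {
  expect_equal(effort_step(0.3, 0), 0.3)
  set.seed(42)
  k <- 9; M <- 4000; sigma <- 0.3
  final <- replicate(M, {
    u <- 0
    for (i in seq_len(k)) u <- effort_step(u, sigma)
    u
  })
  expect_equal(var(final), k * sigma^2, tolerance = 0.1)
})

test_that("Baranov catch equation conserves removals", {
  expect_equal(baranov_catch(1e6, 0, 0.2), 0)
  expect_equal(baranov_catch(1, 0.2, 0.2), 0.5 * (1 - exp(-0.4)))
  expect_equal(baranov_catch(1e6, 0, 0), 0) # F + M = 0 limit
  expect_gt(baranov_catch(1e6, 1e4, 0.2), 1e6 * 0.9999)
  # catch / total deaths = F / (F + M) exactly
  N <- 1e8
  for (F in c(0.1, 0.4, 1.2)) {
    C <- baranov_catch(N, F, 0.2)
    deaths <- N * (1 - exp(-(F + 0.2)))
    expect_equal(C / deaths, F / (F + 0.2), tolerance = 1e-12)
    expect_lt(C, N)
  }
})

test_that("deterministic forward simulation matches the closed-form survival product", {
  cfg <- noise_free(short_scenario())
  p <- cfg$params
  p$beta0 <- 0; p$beta <- c(0, 0, 0); p$gamma <- 0
  covars <- generate_covariates(cfg)
  Y <- cfg$ages$n_years
  N0 <- cfg$initial_N
  lat <- simulate_forward(p, covars, N0, shocks = zero_shocks(Y))

  # ages 1-3 decay by exp(-MJ) per year; adults by exp(-(MA + F))
  for (k in 1:3) {
    expect_equal(lat$N[1 + k, 1 + k], N0[1] * exp(-k * p$MJ),
                 tolerance = 1e-10)
  }
  expect_equal(lat$N[6, 3], N0[4] * exp(-2 * p$MA - lat$F[4, 1] - lat$F[5, 2]),
               tolerance = 1e-10)
  # egg -> larva -> 0-group chain in one year
  expect_equal(lat$larvae[1], lat$eggs[1] * exp(-p$M_egg * p$t_EL),
               tolerance = 1e-12)
  expect_equal(lat$zerogroup[1],
               lat$larvae[1] *
                 exp(-p$M_larv_daily * p$t_larv - p$M_juv_daily * p$t_ejuv),
               tolerance = 1e-12)
  # 0-group -> age 1 without cannibalism
  expect_equal(lat$N[1, 2], lat$zerogroup[1] * exp(-p$M0), tolerance = 1e-10)
})

test_that("forward simulation is reproducible and respects invariants", {
  cfg <- short_scenario()
  covars <- generate_covariates(cfg)
  a <- simulate_forward(cfg$params, covars, cfg$initial_N, seed = 99)
  b <- simulate_forward(cfg$params, covars, cfg$initial_N, seed = 99)
  expect_identical(a, b)
  expect_true(all(a$N >= 0) && all(a$catch >= 0) && all(a$F >= 0))
  expect_true(all(a$catch <= a$N))
  expect_equal(a$U[1], 0)
  expect_true(all(a$F[1:3, ] == 0))
})

test_that("density dependence shrinks the interannual variance of recruitment", {
  p_off <- parameter_set()
  p_off$beta0 <- 0; p_off$beta <- c(0, 0, 0)
  v_on <- v_off <- numeric(20)
  for (i in 1:20) {
    # same seed, same shock draws: a paired on/off experiment
    on <- generate_dataset(scenario_config(seed = 500 + i))$truth$latent
    off <- generate_dataset(scenario_config(params = p_off,
                                            seed = 500 + i))$truth$latent
    v_on[i] <- var(log(on$N[4, ]))
    v_off[i] <- var(log(off$N[4, ]))
  }
  # compensation shrinks recruitment variance by a large factor on average
  # (individual trajectories diverge once states differ, so the contrast is
  # an ensemble property, not a per-replicate one)
  expect_lt(mean(v_on), 0.5 * mean(v_off))
})
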