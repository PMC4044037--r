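# Shared fixtures, all generated in code.

# Default-scale scenario over a shortened year range (keeps the full age
# structure and all survey windows that intersect it).
short_scenario <- function(n_years = 15L, seed = 1L, ...) {
  scenario_config(ages = age_structure(first_year = 1981L, n_years = n_years),
                  egg_years = 1981:1990, larv_years = 1981:1990,
                  zg_start = 1981L, winter_start = 1981L,
                  landings_start = 1981L, seed = seed, ...)
}

# Reduced model (6 ages, short series) used for replicate fitting
# experiments: same structure, ~4x cheaper per MCMC iteration.
reduced_scenario <- function(n_years = 20L, seed = 1L,
                             sigma_E = 0.7, sigma_O = 0.7) {
  ages <- age_structure(first_year = 1981L, n_years = n_years, max_age = 6L)
  params <- parameter_set(sel = c(-1.0, -0.6, -0.4), sigma_E = sigma_E,
                          sigma_O = sigma_O)
  scenario_config(
    ages = ages, params = params,
    initial_N = c(1.25e9, 9.6e8, 7.1e8, 5.3e8, 3.3e8, 2.0e8),
    egg_years = 1981:1990, larv_years = 1981:1990,
    zg_start = 1981L, winter_start = 1981L, landings_start = 1981L,
    seed = seed)
}

reduced_priors <- function() {
  prior_spec(mu_init = log(c(1.25e9, 9.6e8, 7.1e8, 5.3e8, 3.3e8, 2.0e8)))
}

# Deterministic (all process and observation noise zero) variant of a config.
noise_free <- function(config) {
  p <- config$params
  p$sigma_E <- 0; p$sigma_O <- 0; p$sigma_U <- 0
  op <- config$obs_params
  op$sigma_C <- 0; op$sigma_I[] <- 0; op$sigma_year <- 0
  op$sigma_egg <- 0; op$sigma_larv <- 0; op$sigma_0g <- 0
  config$params <- p
  config$obs_params <- op
  config
}

zero_shocks <- function(Y) {
  list(eps_E = numeric(Y), eps_O = numeric(Y), u_innov = numeric(Y))
}
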