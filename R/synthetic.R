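#' Scenario configuration for synthetic data generation
#'
#' Bundles everything needed to generate a complete synthetic dataset with
#' the statistical structure the analysis assumes: the age/year layout, the
#' true process and observation parameters, covariate-generator settings, a
#' piecewise effort history, the survey missingness windows, and a master
#' seed. Defaults emulate the Northeast Arctic cod study system: years
#' 1959-2010, egg/larval surveys available 1959-1990 only, the 0-group index
#' from 1966, winter bottom-trawl ages 1-9 from 1981, and landings from 1959.
#'
#' The default initial age structure and effort level are calibrated so that
#' age-1 abundance fluctuates around ~1.25e9 individuals, which puts the
#' intracohort density-dependence terms (beta * N of order 0.1-0.3) at the
#' strength the reported posterior medians imply.
#'
#' @param ages An \code{\link{age_structure}} (default 1959-2010, ages 1-9).
#' @param params True \code{\link{parameter_set}}.
#' @param obs_params True \code{\link{observation_params}}.
#' @param initial_N Age-1..max_age abundances seeding the burn-in.
#' @param burn_in Years of spin-up discarded before the first output year
#'   (at least max_age, so no output year is an initial-condition artifact).
#' @param temp_sd,temp_phi Stationary SD (degrees C) and AR(1) coefficient of
#'   the temperature anomaly series.
#' @param effort_knots Data frame with columns \code{frac} (position in
#'   [0, 1] along the output years) and \code{U} (mean log effort), linearly
#'   interpolated; random-walk innovations with SD \code{params$sigma_U} are
#'   added on top. The first knot must be (0, 0).
#' @param egg_years,larv_years Calendar years with egg / larval indices.
#' @param zg_start,winter_start,landings_start First calendar year of the
#'   0-group index, the winter survey, and the landings series.
#' @param seed Master seed; the same config and seed give identical datasets.
#'
#' @return An object of class \code{"scenario_config"}.
#' @export
scenario_config <- function(ages = age_structure(),
                            params = parameter_set(),
                            obs_params = observation_params(),
                            initial_N = c(1.25e9, 9.6e8, 7.1e8, 5.3e8,
                                          3.3e8, 2.0e8, 1.2e8, 7e7, 4e7),
                            burn_in = 2L * ages$max_age,
                            temp_sd = 0.5, temp_phi = 0.5,
                            effort_knots = data.frame(
                              frac = c(0, 0.58, 0.66, 0.77, 1),
                              U = c(0, 0.35, -0.35, 0.15, -0.5)),
                            egg_years = 1959:1990,
                            larv_years = 1959:1990,
                            zg_start = 1966L,
                            winter_start = 1981L,
                            landings_start = 1959L,
                            seed = 1L) {
  stopifnot(inherits(ages, "age_structure"),
            inherits(params, "parameter_set"),
            inherits(obs_params, "observation_params"))
  if (burn_in < ages$max_age)
    stop("burn_in must be at least max_age years")
  if (length(initial_N) != ages$max_age)
    stop("initial_N must cover ages 1..max_age")
  rng <- range(ages$years)
  win <- function(y) y[y >= rng[1] & y <= rng[2]]
  structure(list(ages = ages, params = params, obs_params = obs_params,
                 initial_N = initial_N, burn_in = as.integer(burn_in),
                 temp_sd = temp_sd, temp_phi = temp_phi,
                 effort_knots = effort_knots,
                 egg_years = win(egg_years), larv_years = win(larv_years),
                 zg_start = as.integer(zg_start),
                 winter_start = as.integer(winter_start),
                 landings_start = as.integer(landings_start),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate synthetic covariates
#'
#' Weight-at-age follows a cubed von Bertalanffy growth curve with smooth
#' multiplicative year-to-year condition variation; maturity-at-age is a
#' logistic ogive centred near age 6.8 (typical maturation at 6-8 years),
#' essentially 0 at age 1 and above 0.95 by age 9; the temperature anomaly is
#' a centred stationary AR(1) series.
#'
#' @param config A \code{\link{scenario_config}}.
#' @param n_extra Extra leading years to generate (used internally for the
#'   burn-in period).
#' @return A \code{\link{covariates}} object over
#'   \code{n_extra + n_years} years (the age structure is extended backwards
#'   when \code{n_extra > 0}).
#' @export
generate_covariates <- function(config, n_extra = 0L) {
  set.seed(config$seed)
  ag <- config$ages
  if (n_extra > 0L)
    ag <- age_structure(ag$first_year - n_extra, ag$n_years + n_extra,
                        ag$max_age, ag$recruit_age, ag$cannibal_ages,
                        ag$dd_ages)
  A <- ag$max_age; Y <- ag$n_years
  a <- seq_len(A)

  w_mean <- 14 * (1 - exp(-0.13 * (a + 0.5)))^3            # kg at age
  cond <- as.numeric(stats::arima.sim(list(ar = 0.7), Y,
                                      sd = 0.05 * sqrt(1 - 0.7^2)))
  weight <- outer(w_mean, exp(cond))

  mid <- 6.8 + stats::rnorm(Y, 0, 0.08)                    # maturation age
  maturity <- vapply(seq_len(Y),
                     function(y) stats::plogis((a - mid[y]) / 0.6),
                     numeric(A))

  innov_sd <- config$temp_sd * sqrt(1 - config$temp_phi^2)
  temp <- as.numeric(stats::arima.sim(list(ar = config$temp_phi), Y,
                                      sd = innov_sd))
  temp <- temp - mean(temp)

  covariates(weight, maturity, temp, ag)
}

effort_mean_path <- function(config) {
  Y <- config$ages$n_years
  k <- config$effort_knots
  stats::approx(k$frac, k$U, xout = seq(0, 1, length.out = Y))$y
}

#' Generate a complete synthetic dataset
#'
#' Runs the process model forward (with a discarded burn-in of at least
#' max_age years so the output years carry no initial-condition signature),
#' then generates survey indices and landings through the observation model
#' with the configured missingness windows. Returns the observations, the
#' covariates, and a truth record holding every latent state and parameter
#' for recovery scoring.
#'
#' @param config A \code{\link{scenario_config}}.
#' @return A list with elements \code{obs} (\code{\link{observation_set}}),
#'   \code{covars} (\code{\link{covariates}}), and \code{truth} (list with
#'   the latent state, the winter-survey year effects \code{delta}, the true
#'   \code{params} and \code{obs_params}, and the \code{config}).
#' @export
generate_dataset <- function(config) {
  ag <- config$ages
  A <- ag$max_age; Y <- ag$n_years; B <- config$burn_in
  covars_ext <- generate_covariates(config, n_extra = B)

  set.seed(config$seed + 1L)
  p <- config$params
  Ytot <- Y + B
  u_mean <- c(numeric(B), effort_mean_path(config))
  u_innov <- diff(c(0, u_mean)) + c(numeric(B),
                                    stats::rnorm(Y, 0, p$sigma_U))
  shocks <- list(eps_E = stats::rnorm(Ytot, 0, p$sigma_E),
                 eps_O = stats::rnorm(Ytot, 0, p$sigma_O),
                 u_innov = u_innov)
  lat_ext <- simulate_forward(p, covars_ext, config$initial_N,
                              shocks = shocks)

  keep <- (B + 1L):Ytot
  latent <- structure(list(
    eggs = lat_ext$eggs[keep], larvae = lat_ext$larvae[keep],
    zerogroup = lat_ext$zerogroup[keep],
    N = lat_ext$N[, keep, drop = FALSE], SSB = lat_ext$SSB[keep],
    F = lat_ext$F[, keep, drop = FALSE], U = lat_ext$U[keep],
    catch = lat_ext$catch[, keep, drop = FALSE],
    shocks = lapply(lat_ext$shocks, `[`, keep), ages = ag),
    class = "latent_state")
  dimnames(latent$N) <- dimnames(latent$F) <- dimnames(latent$catch) <-
    list(age = 1:A, year = ag$years)
  covars <- covariates(covars_ext$weight[, keep, drop = FALSE],
                       covars_ext$maturity[, keep, drop = FALSE],
                       covars_ext$temperature[keep], ag)

  op <- config$obs_params
  landings <- matrix(NA_real_, A, Y)
  fished <- ag$recruit_age:A
  obs_l <- ag$years >= config$landings_start
  landings[fished, obs_l] <-
    observe_landings(latent$catch[fished, obs_l, drop = FALSE], op$sigma_C)

  delta <- stats::rnorm(Y, 0, op$sigma_year)
  index_winter <- matrix(NA_real_, A, Y)
  for (y in which(ag$years >= config$winter_start))
    index_winter[, y] <- observe_winter_survey(latent$N[, y], ag$years[y],
                                               op, delta = delta[y])

  idx_stage <- function(x, q, sig, years_ok) {
    out <- rep(NA_real_, Y)
    sel <- ag$years %in% years_ok
    out[sel] <- observe_stage_index(x[sel], q, sig)
    out
  }
  index_egg <- idx_stage(latent$eggs, op$q_egg, op$sigma_egg,
                         config$egg_years)
  index_larv <- idx_stage(latent$larvae, op$q_larv, op$sigma_larv,
                          config$larv_years)
  index_0g <- idx_stage(latent$zerogroup, op$q_0g, op$sigma_0g,
                        ag$years[ag$years >= config$zg_start])

  obs <- observation_set(landings, index_winter, index_egg, index_larv,
                         index_0g, ag)
  list(obs = obs, covars = covars,
       truth = list(latent = latent, delta = delta, params = p,
                    obs_params = op, config = config))
}
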