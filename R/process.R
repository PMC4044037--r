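#' Spawning stock biomass
#'
#' SSB in a year is the abundance-weighted mass of mature fish,
#' \eqn{\sum_a N_a w_a p_a}.
#'
#' @param N Abundance-at-age (individuals), ages 1..A.
#' @param w Weight-at-age (kg), same length.
#' @param p Probability of being mature at age, same length.
#' @return SSB in kg.
#' @export
compute_ssb <- function(N, w, p) {
  if (length(N) != length(w) || length(N) != length(p))
    stop("N, w and p must cover the same age range")
  sum(N * w * p)
}

#' Egg production from spawning stock biomass
#'
#' \eqn{E = 1000 f \cdot SSB \cdot e^{\epsilon_E}} where \eqn{f} is mean
#' fecundity in eggs per gram (the factor 1000 converts to eggs per kg of
#' SSB) and \eqn{\epsilon_E} is a Gaussian process error on the log scale
#' capturing stochasticity in the spawning process.
#'
#' @param ssb Spawning stock biomass, kg.
#' @param fecundity Mean fecundity, eggs per gram of SSB.
#' @param eps Log-scale spawning shock (0 for the deterministic mean path).
#' @return Number of eggs.
#' @export
egg_production <- function(ssb, fecundity, eps = 0) {
  if (any(ssb < 0)) stop("SSB must be non-negative")
  1000 * fecundity * ssb * exp(eps)
}

#' Egg to larva transition
#'
#' Exponential decay at the egg daily mortality over the days between the
#' egg and larval surveys: \eqn{L = E e^{-M_{egg} t_{EL}}}.
#'
#' @param eggs Egg abundance.
#' @param M_egg Egg daily mortality (day^-1).
#' @param t_EL Days between egg and larval surveys.
#' @return Larval abundance.
#' @export
egg_to_larva <- function(eggs, M_egg, t_EL) {
  if (any(eggs < 0)) stop("egg abundance must be non-negative")
  if (t_EL < 0) stop("t_EL must be non-negative")
  eggs * exp(-M_egg * t_EL)
}

#' Larva to 0-group transition with temperature-dependent larval survival
#'
#' Survival over the larva -> 0-group period is split into a larval phase,
#' whose daily mortality is reduced by \code{gamma} per degree of positive
#' temperature anomaly, and an early-juvenile phase with fixed daily
#' mortality:
#' \eqn{O = L \exp\{-(M_{larv} - \gamma T) t_{larv} - M_{juv} t_{ejuv}\}}.
#' The realized survival fraction is capped at 1 (with a warning) in case a
#' large anomaly would otherwise imply net production.
#'
#' @param larvae Larval abundance.
#' @param temp Temperature anomaly (degrees C) during larval development.
#' @param params A \code{\link{parameter_set}}.
#' @return 0-group abundance.
#' @export
larva_to_zerogroup <- function(larvae, temp, params) {
  if (any(larvae < 0)) stop("larval abundance must be non-negative")
  surv <- exp(-(params$M_larv_daily - params$gamma * temp) * params$t_larv -
                params$M_juv_daily * params$t_ejuv)
  if (any(surv > 1)) {
    warning("larva->0-group survival exceeded 1 after temperature adjustment; capped")
    surv <- pmin(surv, 1)
  }
  larvae * surv
}

#' 0-group to age-1 transition with cannibalism
#'
#' Beverton-Holt style intercohort density dependence: survival is
#' \eqn{S = \min(1, e^{-M_0 + \epsilon_O} / (1 + \beta_0 N_{cann}))}, where
#' \eqn{N_{cann}} is the summed abundance of the cannibalistic age classes in
#' the same year and \eqn{\epsilon_O} is a lognormal process shock on
#' survival. The cap keeps realized survival below 1.
#'
#' @param zerogroup 0-group abundance.
#' @param n_cannibals Summed abundance of the cannibal ages (3 + 4).
#' @param params A \code{\link{parameter_set}} (uses \code{M0}, \code{beta0}).
#' @param eps Log-scale process shock (0 for the mean path).
#' @return Age-1 abundance the following year.
#' @export
zerogroup_to_age1 <- function(zerogroup, n_cannibals, params, eps = 0) {
  if (any(zerogroup < 0) || any(n_cannibals < 0))
    stop("abundances must be non-negative")
  s <- pmin(1, exp(-params$M0 + eps) / (1 + params$beta0 * n_cannibals))
  zerogroup * s
}

#' Juvenile transition with intracohort density dependence
#'
#' For ages with intracohort regulation the next age class is
#' \eqn{N_{a+1} = N_a e^{-M_J} / (1 + \beta_a N_a)}: compensatory
#' (Beverton-Holt) survival, strictly increasing and saturating in \eqn{N_a}
#' at \eqn{e^{-M_J}/\beta_a}, with no overcompensation.
#'
#' @param N_a Abundance at age \code{a}.
#' @param a Age (must be one of the density-dependent ages, default 1-3).
#' @param params A \code{\link{parameter_set}} (uses \code{MJ}, \code{beta}).
#' @param dd_ages The set of density-dependent ages.
#' @return Abundance at age \code{a + 1} the following year.
#' @export
juvenile_transition <- function(N_a, a, params, dd_ages = 1:3) {
  if (!(a %in% dd_ages))
    stop(sprintf("age %d has no intracohort density-dependence term", a))
  if (any(N_a < 0)) stop("abundance must be non-negative")
  N_a * exp(-params$MJ) / (1 + params$beta[[match(a, dd_ages)]] * N_a)
}

#' Adult transition under natural and fishing mortality
#'
#' \eqn{N_{a+1,y+1} = N_{a,y} e^{-(M_A + F_{a,y})}}; natural and fishing
#' mortality act simultaneously through the year. Fish older than the
#' maximum age leave the model (no plus group).
#'
#' @param N_a Abundance at age.
#' @param F_a Instantaneous fishing mortality on that age in that year.
#' @param MA Adult natural mortality (year^-1).
#' @return Abundance at the next age the following year.
#' @export
adult_transition <- function(N_a, F_a, MA) {
  if (any(N_a < 0) || any(F_a < 0) || MA < 0)
    stop("abundance and mortalities must be non-negative")
  N_a * exp(-(MA + F_a))
}

#' Separable fishing mortality
#'
#' \eqn{F_{a,y} = e^{s_a + U_y}}: a fixed age selectivity pattern scaled by a
#' year effect (log effort). Ages below recruitment take F = 0 by contract.
#'
#' @param s_a Log selectivity at age (negative).
#' @param U_y Log effort in the year (0 in the first modelled year).
#' @return Fishing mortality (year^-1).
#' @export
fishing_mortality <- function(s_a, U_y) exp(s_a + U_y)

#' Full fishing mortality matrix
#'
#' @param params A \code{\link{parameter_set}} (uses \code{sel}).
#' @param U Log-effort vector over years.
#' @param ages An \code{\link{age_structure}}.
#' @return A max_age x n_years matrix; zero below the recruitment age.
#' @export
fishing_mortality_matrix <- function(params, U, ages) {
  A <- ages$max_age; Y <- ages$n_years; r <- ages$recruit_age
  if (length(U) != Y) stop("U must have one value per year")
  if (length(params$sel) != A - r + 1L)
    stop("selectivity vector must cover ages recruit_age..max_age")
  F <- matrix(0, A, Y, dimnames = list(age = 1:A, year = ages$years))
  F[r:A, ] <- exp(outer(params$sel, U, `+`))
  F
}

#' One step of the log-effort random walk
#'
#' \eqn{U_y \sim N(U_{y-1}, \sigma_U^2)}; the first year's effort is pinned
#' at 0 for identifiability.
#'
#' @param U_prev Previous log effort.
#' @param sigma_U Innovation SD.
#' @return Next log effort (uses the current RNG state).
#' @export
effort_step <- function(U_prev, sigma_U) {
  if (sigma_U < 0) stop("sigma_U must be >= 0")
  stats::rnorm(1, U_prev, sigma_U)
}

#' Baranov catch equation
#'
#' Catch is the fishing share of total annual removals:
#' \eqn{C = N \frac{F}{F + M_A} (1 - e^{-(F + M_A)})}. The F = M = 0 limit
#' returns 0 (no removals at all).
#'
#' @param N Abundance at the start of the year.
#' @param F Instantaneous fishing mortality.
#' @param MA Natural mortality.
#' @return Catch in individuals; always in [0, N).
#' @export
baranov_catch <- function(N, F, MA) {
  if (any(N < 0) || any(F < 0) || any(MA < 0))
    stop("N, F and MA must be non-negative")
  Z <- F + MA
  frac <- ifelse(Z > 0, F / Z * (1 - exp(-Z)), 0)
  N * frac
}

#' Forward simulation of the full life cycle
#'
#' Runs the complete process model over all years: SSB -> eggs -> larvae ->
#' 0-group within a year, then the 0-group -> age-1 (cannibalism), juvenile
#' (intracohort Beverton-Holt) and adult (natural + fishing mortality)
#' transitions into the next year, with separable fishing mortality driven by
#' a random-walk log effort and catches from the Baranov equation. Cohort
#' bookkeeping maps age a in year y to age a + 1 in year y + 1; the oldest
#' age leaves the model.
#'
#' Stochasticity enters through the spawning shock (\code{eps_E}), the
#' 0-group survival shock (\code{eps_O}) and the effort innovations
#' (\code{u_innov}). Passing all-zero shocks gives the exactly reproducible
#' deterministic mean path.
#'
#' @param params A \code{\link{parameter_set}}.
#' @param covars A \code{\link{covariates}} object covering all years.
#' @param initial_N Abundance-at-age vector (ages 1..max_age) in the first
#'   year.
#' @param shocks Optional list with numeric vectors \code{eps_E},
#'   \code{eps_O}, \code{u_innov}, each of length n_years (the first entry of
#'   \code{u_innov} is ignored: first-year effort is 0). If \code{NULL} they
#'   are drawn from the model's process distributions.
#' @param seed Optional integer seed used when shocks are drawn.
#' @return A \code{"latent_state"} list with elements \code{eggs},
#'   \code{larvae}, \code{zerogroup}, \code{SSB}, \code{U} (year vectors),
#'   \code{N}, \code{F}, \code{catch} (max_age x n_years matrices), the
#'   shocks used, and the age structure.
#' @export
simulate_forward <- function(params, covars, initial_N, shocks = NULL,
                             seed = NULL) {
  ages <- covars$ages
  A <- ages$max_age; Y <- ages$n_years; r <- ages$recruit_age
  if (length(initial_N) != A) stop("initial_N must cover ages 1..max_age")
  if (any(initial_N < 0)) stop("initial abundances must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(shocks)) {
    shocks <- list(eps_E = stats::rnorm(Y, 0, params$sigma_E),
                   eps_O = stats::rnorm(Y, 0, params$sigma_O),
                   u_innov = stats::rnorm(Y, 0, params$sigma_U))
  }
  stopifnot(length(shocks$eps_E) == Y, length(shocks$eps_O) == Y,
            length(shocks$u_innov) == Y)

  N <- matrix(NA_real_, A, Y, dimnames = list(age = 1:A, year = ages$years))
  N[, 1] <- initial_N
  eggs <- larvae <- zg <- SSB <- U <- numeric(Y)

  U[1] <- 0
  for (y in 2:Y) U[y] <- U[y - 1] + shocks$u_innov[y]
  F <- fishing_mortality_matrix(params, U, ages)

  for (y in seq_len(Y)) {
    SSB[y] <- compute_ssb(N[, y], covars$weight[, y], covars$maturity[, y])
    eggs[y] <- egg_production(SSB[y], params$fecundity, shocks$eps_E[y])
    larvae[y] <- egg_to_larva(eggs[y], params$M_egg, params$t_EL)
    zg[y] <- larva_to_zerogroup(larvae[y], covars$temperature[y], params)
    if (y < Y) {
      n_cann <- sum(N[ages$cannibal_ages, y])
      N[1, y + 1] <- zerogroup_to_age1(zg[y], n_cann, params,
                                       eps = shocks$eps_O[y])
      for (a in ages$dd_ages)
        N[a + 1, y + 1] <- juvenile_transition(N[a, y], a, params,
                                               dd_ages = ages$dd_ages)
      for (a in r:(A - 1))
        N[a + 1, y + 1] <- adult_transition(N[a, y], F[a, y], params$MA)
    }
  }
  catch <- baranov_catch(N, F, params$MA)
  structure(list(eggs = eggs, larvae = larvae, zerogroup = zg, N = N,
                 SSB = SSB, F = F, U = U, catch = catch,
                 shocks = shocks, ages = ages),
            class = "latent_state")
}
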