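#' Process and observation parameters of the life-cycle model
#'
#' Bundles every quantity the process and observation models need. Defaults
#' are the fixed constants used throughout (mean fecundity, egg/larval/early-
#' juvenile daily mortalities and stage durations, adult natural mortality)
#' together with representative values for the estimated parameters
#' (posterior medians reported for Northeast Arctic cod): density-independent
#' 0-group and juvenile annual mortalities, cannibalism and intracohort
#' density-dependence coefficients, and process error standard deviations.
#'
#' Units: \code{fecundity} is eggs per gram of spawning stock biomass (SSB is
#' carried in kg, so the egg equation converts with a factor 1000); daily
#' mortalities are per day with stage durations in days; \code{M0}, \code{MJ},
#' \code{MA} are annual instantaneous rates; the \code{beta} coefficients are
#' per individual.
#'
#' @param fecundity Mean fecundity, eggs per gram of SSB.
#' @param sigma_E SD (log scale) of the spawning process error.
#' @param M_egg Egg daily mortality (day^-1).
#' @param t_EL Days between the egg and larval surveys.
#' @param M_larv_daily,M_juv_daily Daily mortality during the larval and
#'   early-juvenile phases of the larva -> 0-group period (day^-1).
#' @param t_larv,t_ejuv Durations (days) of those two phases.
#' @param gamma Temperature effect on larval-phase daily mortality
#'   (per degree C anomaly; positive values mean warm years survive better).
#' @param M0 0-group density-independent annual mortality (year^-1).
#' @param beta0 Intercohort cannibalism coefficient (per cannibal individual).
#' @param sigma_O SD (log scale) of the 0-group survival process error.
#' @param MJ Juvenile (ages 1-3) density-independent annual mortality.
#' @param beta Named or positional vector of intracohort density-dependence
#'   coefficients for the transitions from ages 1, 2 and 3.
#' @param MA Adult annual natural mortality (fixed at 0.2 year^-1).
#' @param sel Log fishing selectivities for ages \code{recruit_age..max_age};
#'   must be negative.
#' @param sigma_U SD of the log-effort random-walk innovations.
#'
#' @return An object of class \code{"parameter_set"} (a list).
#' @export
parameter_set <- function(fecundity = 235, sigma_E = 0.7,
                          M_egg = 0.169, t_EL = 20,
                          M_larv_daily = 0.075, t_larv = 60,
                          M_juv_daily = 0.04, t_ejuv = 60,
                          gamma = 3.38e-3,
                          M0 = 0.35, beta0 = 1.82e-9, sigma_O = 0.7,
                          MJ = 0.15, beta = c(9.48e-11, 1.69e-10, 2.27e-10),
                          MA = 0.2,
                          sel = c(-1.0, -0.6, -0.4, -0.3, -0.25, -0.25),
                          sigma_U = 0.1) {
  p <- list(fecundity = fecundity, sigma_E = sigma_E, M_egg = M_egg,
            t_EL = t_EL, M_larv_daily = M_larv_daily, t_larv = t_larv,
            M_juv_daily = M_juv_daily, t_ejuv = t_ejuv, gamma = gamma,
            M0 = M0, beta0 = beta0, sigma_O = sigma_O, MJ = MJ,
            beta = as.numeric(beta), MA = MA, sel = as.numeric(sel),
            sigma_U = sigma_U)
  validate_parameter_set(p)
  class(p) <- "parameter_set"
  p
}

validate_parameter_set <- function(p) {
  nonneg <- c("sigma_E", "M_egg", "t_EL", "M_larv_daily", "t_larv",
              "M_juv_daily", "t_ejuv", "M0", "beta0", "sigma_O", "MJ",
              "MA", "sigma_U")
  for (nm in nonneg)
    if (p[[nm]] < 0) stop(sprintf("parameter '%s' must be >= 0", nm))
  if (any(p$beta < 0)) stop("intracohort beta coefficients must be >= 0")
  if (p$fecundity <= 0) stop("fecundity must be > 0")
  if (any(p$sel >= 0)) stop("log selectivities must be negative")
  invisible(p)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Life-cycle parameter set\n")
  cat(sprintf("  fecundity %.0f eggs/g | M_egg %.3f/d x %g d | larval %.3f/d x %g d + %.3f/d x %g d\n",
              x$fecundity, x$M_egg, x$t_EL, x$M_larv_daily, x$t_larv,
              x$M_juv_daily, x$t_ejuv))
  cat(sprintf("  gamma %.3g/degC | M0 %.3g | beta0 %.3g | MJ %.3g | beta %s | MA %.2f\n",
              x$gamma, x$M0, x$beta0, x$MJ,
              paste(signif(x$beta, 3), collapse = ", "), x$MA))
  cat(sprintf("  sel %s | sigma_E %.2f sigma_O %.2f sigma_U %.2f\n",
              paste(signif(x$sel, 2), collapse = ", "),
              x$sigma_E, x$sigma_O, x$sigma_U))
  invisible(x)
}

#' Covariate tables for the process model
#'
#' @param weight Matrix (max_age x n_years) of weight-at-age in kg.
#' @param maturity Matrix (max_age x n_years) of probabilities of being
#'   mature, in [0, 1].
#' @param temperature Numeric vector (n_years) of the June-August temperature
#'   anomaly (degrees C, centred).
#' @param ages Age structure the tables conform to.
#'
#' @return An object of class \code{"covariates"}.
#' @export
covariates <- function(weight, maturity, temperature, ages) {
  stopifnot(inherits(ages, "age_structure"))
  weight <- as.matrix(weight); maturity <- as.matrix(maturity)
  A <- ages$max_age; Y <- ages$n_years
  if (!all(dim(weight) == c(A, Y)) || !all(dim(maturity) == c(A, Y)))
    stop("weight and maturity must be max_age x n_years matrices")
  if (length(temperature) != Y)
    stop("temperature must have one value per year")
  if (any(weight <= 0)) stop("weights must be positive for all modelled ages")
  if (any(maturity < 0 | maturity > 1)) stop("maturity must lie in [0, 1]")
  dimnames(weight) <- dimnames(maturity) <- list(age = 1:A, year = ages$years)
  structure(list(weight = weight, maturity = maturity,
                 temperature = as.numeric(temperature), ages = ages),
            class = "covariates")
}
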