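#' Observation-model parameters
#'
#' Catchabilities and error standard deviations linking latent abundances to
#' survey indices and reported landings. The winter bottom-trawl survey
#' changed its sampling area and codend mesh around 1993/1994; indices for
#' ages 3+ are assumed corrected upstream, while ages 1-2 get separate
#' catchabilities before and after the regime year.
#'
#' @param q_egg,q_larv,q_0g Stage-index catchabilities (index units per
#'   individual).
#' @param q_pre,q_post Winter-survey catchabilities for ages 1 and 2 before /
#'   from the regime year (length-2 vectors).
#' @param q Winter-survey catchabilities for ages 3..max_age.
#' @param sigma_C Landings observation error SD (log scale).
#' @param sigma_I Age-specific winter-survey error SDs (ages 1..max_age).
#' @param sigma_year SD of the shared within-year winter-survey effect.
#' @param sigma_egg,sigma_larv,sigma_0g Stage-index error SDs.
#' @param regime_year First survey year using the post-change catchabilities
#'   (default 1994).
#'
#' @return An object of class \code{"observation_params"}.
#' @export
observation_params <- function(q_egg = exp(-25), q_larv = exp(-22),
                               q_0g = exp(-16),
                               q_pre = exp(c(-11.5, -11.3)),
                               q_post = exp(c(-11.0, -10.8)),
                               q = exp(-11 - 0.15 * (0:6)),
                               sigma_C = 0.1,
                               sigma_I = c(0.45, 0.4, 0.35, 0.3, 0.25,
                                           0.2, 0.25, 0.3, 0.35),
                               sigma_year = 0.2,
                               sigma_egg = 0.5, sigma_larv = 0.5,
                               sigma_0g = 0.6,
                               regime_year = 1994L) {
  p <- list(q_egg = q_egg, q_larv = q_larv, q_0g = q_0g,
            q_pre = q_pre, q_post = q_post, q = q,
            sigma_C = sigma_C, sigma_I = as.numeric(sigma_I),
            sigma_year = sigma_year, sigma_egg = sigma_egg,
            sigma_larv = sigma_larv, sigma_0g = sigma_0g,
            regime_year = as.integer(regime_year))
  qs <- c(p$q_egg, p$q_larv, p$q_0g, p$q_pre, p$q_post, p$q)
  if (any(qs <= 0)) stop("all catchabilities must be > 0")
  sds <- c(p$sigma_C, p$sigma_I, p$sigma_year, p$sigma_egg, p$sigma_larv,
           p$sigma_0g)
  if (any(sds < 0)) stop("all observation SDs must be >= 0")
  class(p) <- "observation_params"
  p
}

#' Effective winter-survey catchability
#'
#' Ages 1-2 use the pre- or post-regime catchability depending on the survey
#' year; older ages use a single catchability.
#'
#' @param a Age.
#' @param year Calendar survey year.
#' @param obs_params An \code{\link{observation_params}}.
#' @return Catchability for that age and year.
#' @export
effective_catchability <- function(a, year, obs_params) {
  if (a <= 2L) {
    if (year >= obs_params$regime_year) obs_params$q_post[a]
    else obs_params$q_pre[a]
  } else {
    obs_params$q[a - 2L]
  }
}

#' Reported landings with bias-corrected lognormal error
#'
#' Reported landings are \eqn{C^{obs} = C e^{\epsilon - \sigma_C^2/2}} with
#' \eqn{\epsilon \sim N(0, \sigma_C^2)}; the \eqn{-\sigma_C^2/2} term makes
#' the multiplicative error mean-one, so landings are unbiased for the true
#' catch. A zero true catch has no lognormal observation and yields NA.
#'
#' @param C_true True catch, individuals.
#' @param sigma_C Landings error SD.
#' @param eps Optional log-scale error draws (drawn from the current RNG if
#'   omitted).
#' @return Reported landings (NA where \code{C_true} is 0).
#' @export
observe_landings <- function(C_true, sigma_C, eps = NULL) {
  if (any(C_true < 0)) stop("true catch must be non-negative")
  if (is.null(eps)) eps <- stats::rnorm(length(C_true), 0, sigma_C)
  out <- C_true * exp(eps - sigma_C^2 / 2)
  out[C_true == 0] <- NA_real_
  out
}

#' Winter bottom-trawl survey indices for one year
#'
#' \eqn{I_{a,y} = q_{a,y} N_{a,y} e^{\delta_y + \epsilon_{a,y}}}: a shared
#' year effect \eqn{\delta_y} induces correlated observation errors across
#' ages within a survey year, on top of independent age-specific errors.
#'
#' @param N Abundance-at-age vector for the year.
#' @param year Calendar survey year (decides the catchability regime).
#' @param obs_params An \code{\link{observation_params}}.
#' @param delta Optional shared year effect (drawn if omitted).
#' @param eps Optional age-specific error vector (drawn if omitted).
#' @return Index-at-age vector.
#' @export
observe_winter_survey <- function(N, year, obs_params, delta = NULL,
                                  eps = NULL) {
  if (any(N < 0)) stop("abundance must be non-negative")
  A <- length(N)
  if (is.null(delta)) delta <- stats::rnorm(1, 0, obs_params$sigma_year)
  if (is.null(eps)) eps <- stats::rnorm(A, 0, obs_params$sigma_I[seq_len(A)])
  q <- vapply(seq_len(A), effective_catchability, numeric(1),
              year = year, obs_params = obs_params)
  q * N * exp(delta + eps)
}

#' Stage index (eggs, larvae or 0-group)
#'
#' \eqn{I = q \cdot X e^{\epsilon}} with stage-specific catchability and
#' error SD; the three stage surveys are independent of each other and of
#' the winter survey year effect.
#'
#' @param abundance Stage abundance.
#' @param q_stage Stage catchability.
#' @param sigma_stage Stage error SD.
#' @param eps Optional log-scale error (drawn if omitted).
#' @return Index value.
#' @export
observe_stage_index <- function(abundance, q_stage, sigma_stage, eps = NULL) {
  if (any(abundance < 0)) stop("abundance must be non-negative")
  if (is.null(eps)) eps <- stats::rnorm(length(abundance), 0, sigma_stage)
  q_stage * abundance * exp(eps)
}

#' Observation set container
#'
#' Survey indices and landings with missingness encoded as NA. All present
#' values must be strictly positive (lognormal support); zeros are rejected.
#'
#' @param landings max_age x n_years matrix of reported landings
#'   (individuals), NA where unobserved.
#' @param index_winter max_age x n_years matrix of winter survey indices.
#' @param index_egg,index_larv,index_0g Year vectors of stage indices.
#' @param ages The \code{\link{age_structure}}.
#' @return An object of class \code{"observation_set"}.
#' @export
observation_set <- function(landings, index_winter, index_egg, index_larv,
                            index_0g, ages) {
  stopifnot(inherits(ages, "age_structure"))
  A <- ages$max_age; Y <- ages$n_years
  landings <- as.matrix(landings); index_winter <- as.matrix(index_winter)
  if (!all(dim(landings) == c(A, Y)) || !all(dim(index_winter) == c(A, Y)))
    stop("landings and index_winter must be max_age x n_years matrices")
  for (v in list(landings, index_winter, index_egg, index_larv, index_0g))
    if (any(v <= 0, na.rm = TRUE))
      stop("observed values must be strictly positive (use NA for missing)")
  if (length(index_egg) != Y || length(index_larv) != Y ||
      length(index_0g) != Y)
    stop("stage indices must have one (possibly NA) value per year")
  dimnames(landings) <- dimnames(index_winter) <-
    list(age = 1:A, year = ages$years)
  structure(list(landings = landings, index_winter = index_winter,
                 index_egg = as.numeric(index_egg),
                 index_larv = as.numeric(index_larv),
                 index_0g = as.numeric(index_0g), ages = ages),
            class = "observation_set")
}

#' Log-likelihood of an observation set given latent states
#'
#' Sums lognormal log-densities over all observed (non-NA) cells: landings
#' against Baranov catches with the mean-one bias correction, winter indices
#' against catchability-scaled abundances with the shared year effect, and
#' the three stage indices against eggs, larvae and 0-group abundance.
#' Masked (NA) cells contribute exactly 0. The year effects \code{delta} are
#' conditioned on (they are latent variables integrated by MCMC during
#' fitting); they default to zero.
#'
#' @param latent A \code{"latent_state"} from \code{\link{simulate_forward}}.
#' @param obs An \code{\link{observation_set}}.
#' @param obs_params An \code{\link{observation_params}}.
#' @param delta Optional vector of winter-survey year effects (length
#'   n_years, default all zero).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(latent, obs, obs_params, delta = NULL) {
  ages <- obs$ages
  A <- ages$max_age; Y <- ages$n_years
  if (is.null(delta)) delta <- numeric(Y)
  stopifnot(length(delta) == Y, all(dim(latent$N) == c(A, Y)))
  ll <- 0

  dln <- function(x, meanlog, sd) stats::dlnorm(x, meanlog, sd, log = TRUE)

  for (y in seq_len(Y)) {
    for (a in seq_len(A)) {
      if (!is.na(obs$landings[a, y])) {
        ll <- ll + dln(obs$landings[a, y],
                       log(latent$catch[a, y]) - obs_params$sigma_C^2 / 2,
                       obs_params$sigma_C)
      }
      if (!is.na(obs$index_winter[a, y])) {
        q <- effective_catchability(a, ages$years[y], obs_params)
        ll <- ll + dln(obs$index_winter[a, y],
                       log(q * latent$N[a, y]) + delta[y],
                       obs_params$sigma_I[a])
      }
    }
    if (!is.na(obs$index_egg[y]))
      ll <- ll + dln(obs$index_egg[y], log(obs_params$q_egg * latent$eggs[y]),
                     obs_params$sigma_egg)
    if (!is.na(obs$index_larv[y]))
      ll <- ll + dln(obs$index_larv[y],
                     log(obs_params$q_larv * latent$larvae[y]),
                     obs_params$sigma_larv)
    if (!is.na(obs$index_0g[y]))
      ll <- ll + dln(obs$index_0g[y],
                     log(obs_params$q_0g * latent$zerogroup[y]),
                     obs_params$sigma_0g)
  }
  ll
}
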