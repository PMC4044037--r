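#' Prior specification for Bayesian estimation
#'
#' Encodes the prior distributions used when fitting the life-cycle model:
#' informative lognormal priors for the density-independent 0-group and
#' juvenile mortalities (medians 0.425 and 0.2, log-scale variance 0.5);
#' vague normal priors (variance 1000) for the log catchabilities (means 0
#' for the age-specific and 0-group catchabilities, -25 for eggs and larvae),
#' the log selectivities (mean -1.6, truncated to negative values) and the
#' temperature effect (mean 0, sign-unconstrained); and Uniform(0, upper)
#' priors for the density-dependence coefficients and every process and
#' observation SD. Adult natural mortality is fixed, not estimated.
#'
#' The uniform upper limits are configurable; they must not be approached by
#' the posterior (check with \code{\link{audit_uniform_uppers}}). The
#' log-scale "variance 0.5" of the mortality priors is the variance of the
#' underlying normal.
#'
#' @param M0_median,MJ_median Medians of the lognormal mortality priors.
#' @param M_logvar Log-scale variance of those priors.
#' @param lq_mean_stage Prior mean of the egg/larval log catchabilities.
#' @param lq_var Variance of all vague normal priors.
#' @param sel_mean Prior mean of the log selectivities.
#' @param uppers Named list of uniform upper limits: \code{beta0},
#'   \code{beta} (intracohort), \code{sigma_E}, \code{sigma_O},
#'   \code{sigma_U}, \code{sigma_C}, \code{sigma_I}, \code{sigma_year},
#'   \code{sigma_egg}, \code{sigma_larv}, \code{sigma_0g}.
#' @param mu_init,sd_init Mean (log scale, by age) and SD of the lognormal
#'   prior on first-year abundances-at-age.
#' @param MA Fixed adult natural mortality.
#'
#' @return An object of class \code{"prior_spec"}.
#' @export
prior_spec <- function(M0_median = 0.425, MJ_median = 0.2, M_logvar = 0.5,
                       lq_mean_stage = -25, lq_var = 1000, sel_mean = -1.6,
                       uppers = list(beta0 = 1e-8, beta = 2e-9,
                                     sigma_E = 3, sigma_O = 3, sigma_U = 2,
                                     sigma_C = 1, sigma_I = 2,
                                     sigma_year = 2, sigma_egg = 3,
                                     sigma_larv = 3, sigma_0g = 3),
                       mu_init = log(c(1.25e9, 9.6e8, 7.1e8, 5.3e8, 3.3e8,
                                       2.0e8, 1.2e8, 7e7, 4e7)),
                       sd_init = 2, MA = 0.2) {
  need <- c("beta0", "beta", "sigma_E", "sigma_O", "sigma_U", "sigma_C",
            "sigma_I", "sigma_year", "sigma_egg", "sigma_larv", "sigma_0g")
  missing <- setdiff(need, names(uppers))
  if (length(missing))
    stop("uppers is missing: ", paste(missing, collapse = ", "))
  if (any(unlist(uppers) <= 0)) stop("uniform uppers must be positive")
  structure(list(M0_median = M0_median, MJ_median = MJ_median,
                 M_logvar = M_logvar, lq_mean_stage = lq_mean_stage,
                 lq_var = lq_var, sel_mean = sel_mean, uppers = uppers,
                 mu_init = mu_init, sd_init = sd_init, MA = MA),
            class = "prior_spec")
}

#' Log prior density of a parameter set
#'
#' Sums the prior log-densities of every estimated parameter. Returns
#' \code{-Inf} for parameters outside their support (e.g. non-negative log
#' selectivities or a density-dependence coefficient beyond its uniform
#' upper limit).
#'
#' @param params A \code{\link{parameter_set}}.
#' @param obs_params An \code{\link{observation_params}}.
#' @param priors A \code{\link{prior_spec}}.
#' @param drop Character vector of prior components to omit (useful for
#'   additivity checks); component names are returned by
#'   \code{attr(, "components")}.
#' @return Scalar log prior density, with a named \code{"components"}
#'   attribute.
#' @export
log_prior <- function(params, obs_params, priors, drop = character()) {
  up <- priors$uppers
  sdM <- sqrt(priors$M_logvar)
  sdq <- sqrt(priors$lq_var)
  dunif_log <- function(x, upper) {
    sum(stats::dunif(x, 0, upper, log = TRUE))
  }
  comp <- c(
    M0 = stats::dlnorm(params$M0, log(priors$M0_median), sdM, log = TRUE),
    MJ = stats::dlnorm(params$MJ, log(priors$MJ_median), sdM, log = TRUE),
    gamma = stats::dnorm(params$gamma, 0, sdq, log = TRUE),
    beta0 = dunif_log(params$beta0, up$beta0),
    beta = dunif_log(params$beta, up$beta),
    sel = if (any(params$sel >= 0)) -Inf else {
      # normal truncated to (-Inf, 0): renormalized by P(X < 0)
      sum(stats::dnorm(params$sel, priors$sel_mean, sdq, log = TRUE) -
            stats::pnorm(0, priors$sel_mean, sdq, log.p = TRUE))
    },
    sigma_E = dunif_log(params$sigma_E, up$sigma_E),
    sigma_O = dunif_log(params$sigma_O, up$sigma_O),
    sigma_U = dunif_log(params$sigma_U, up$sigma_U),
    sigma_C = dunif_log(obs_params$sigma_C, up$sigma_C),
    sigma_I = dunif_log(obs_params$sigma_I, up$sigma_I),
    sigma_year = dunif_log(obs_params$sigma_year, up$sigma_year),
    sigma_egg = dunif_log(obs_params$sigma_egg, up$sigma_egg),
    sigma_larv = dunif_log(obs_params$sigma_larv, up$sigma_larv),
    sigma_0g = dunif_log(obs_params$sigma_0g, up$sigma_0g),
    lq_stage = sum(stats::dnorm(log(c(obs_params$q_egg, obs_params$q_larv)),
                                priors$lq_mean_stage, sdq, log = TRUE)),
    lq_age = sum(stats::dnorm(log(c(obs_params$q_0g, obs_params$q_pre,
                                    obs_params$q_post, obs_params$q)),
                              0, sdq, log = TRUE))
  )
  comp[names(comp) %in% drop] <- 0
  out <- sum(comp)
  attr(out, "components") <- comp
  out
}

#' Joint log posterior density (up to a constant)
#'
#' Assembles the full state-space joint density: the observation
#' log-likelihood, the process-error log-densities (spawning shocks, 0-group
#' survival shocks, effort random-walk innovations, winter-survey year
#' effects, and the first-year abundance prior), and the parameter log
#' priors. This is the density the MCMC sampler explores; parameters outside
#' their support give \code{-Inf} by contract.
#'
#' @param latent A \code{"latent_state"} (its stored shocks are the latent
#'   process errors being scored).
#' @param obs An \code{\link{observation_set}}.
#' @param params,obs_params,priors Model parameters and priors.
#' @param delta Winter-survey year effects (default all zero).
#' @param drop Components to omit: any of \code{"likelihood"},
#'   \code{"process"}, \code{"prior"}, \code{"init"}.
#' @return Scalar log posterior (unnormalized), with a \code{"components"}
#'   attribute.
#' @export
log_posterior <- function(latent, obs, params, obs_params, priors,
                          delta = NULL, drop = character()) {
  Y <- latent$ages$n_years
  if (is.null(delta)) delta <- numeric(Y)
  lp_prior <- log_prior(params, obs_params, priors)
  if (!is.finite(lp_prior)) return(structure(-Inf, components = c(
    likelihood = NA, process = NA, prior = -Inf, init = NA)))

  sh <- latent$shocks
  lp_process <-
    sum(stats::dnorm(sh$eps_E, 0, params$sigma_E, log = TRUE)) +
    sum(stats::dnorm(sh$eps_O[seq_len(Y - 1)], 0, params$sigma_O,
                     log = TRUE)) +
    sum(stats::dnorm(sh$u_innov[-1], 0, params$sigma_U, log = TRUE)) +
    sum(stats::dnorm(delta, 0, obs_params$sigma_year, log = TRUE))
  lp_init <- sum(stats::dnorm(log(latent$N[, 1]), priors$mu_init,
                              priors$sd_init, log = TRUE))
  comp <- c(likelihood = log_likelihood(latent, obs, obs_params,
                                        delta = delta),
            process = lp_process, prior = as.numeric(lp_prior),
            init = lp_init)
  comp[names(comp) %in% drop] <- 0
  structure(sum(comp), components = comp)
}

#' Audit uniform-prior upper limits against posterior draws
#'
#' The uniform upper limits are valid only if the posterior never approaches
#' them. Flags (with a warning) every Uniform-prior parameter whose maximum
#' posterior draw exceeds \code{frac} of its upper limit.
#'
#' @param fit A fit from \code{\link{fit_lifecycle}}.
#' @param priors The \code{\link{prior_spec}} used for the fit.
#' @param frac Fraction of the upper limit that must not be exceeded.
#' @return Data frame with parameter, maximum draw, upper limit and flag;
#'   invisibly when no parameter is flagged.
#' @export
audit_uniform_uppers <- function(fit, priors, frac = 0.95) {
  draws <- as.matrix(fit$mcmc)
  up <- priors$uppers
  spec <- list(beta0 = "beta0", `beta[1]` = "beta", `beta[2]` = "beta",
               `beta[3]` = "beta", sigma_E = "sigma_E", sigma_O = "sigma_O",
               sigma_U = "sigma_U", sigma_C = "sigma_C",
               sigma_year = "sigma_year", sigma_egg = "sigma_egg",
               sigma_larv = "sigma_larv", sigma_0g = "sigma_0g")
  for (a in 1:9) spec[[sprintf("sigma_I[%d]", a)]] <- "sigma_I"
  present <- intersect(names(spec), colnames(draws))
  out <- data.frame(
    parameter = present,
    max_draw = vapply(present, function(p) max(draws[, p]), numeric(1)),
    upper = vapply(present, function(p) up[[spec[[p]]]], numeric(1)),
    row.names = NULL)
  out$flag <- out$max_draw > frac * out$upper
  if (any(out$flag))
    warning("posterior approaches the uniform upper limit for: ",
            paste(out$parameter[out$flag], collapse = ", "),
            "; raise the limit and refit")
  if (any(out$flag)) out else invisible(out)
}
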