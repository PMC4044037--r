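#' MCMC sampler configuration
#'
#' Two profiles are provided. \code{"desk"} (the default) is sized for
#' interactive work and simulation studies: 3 chains, 400 adaptation and 800
#' burn-in iterations, 1200 kept draws per chain. \code{"paper"} reproduces
#' the full-scale published setup: 3 chains, 250 000 burn-in, 250 000
#' posterior samples per chain with thinning 1000 (750 kept draws in total).
#'
#' @param profile \code{"desk"} or \code{"paper"}.
#' @param n_chains Number of chains (at least 2 for convergence diagnostics).
#' @param n_adapt,n_burn,n_iter,thin Adaptation, burn-in and sampling
#'   iterations, and thinning interval; defaults follow the profile.
#' @param monitor_latent Monitor latent states (abundances, SSB, stage
#'   abundances, effort, year effects) in addition to parameters.
#' @param regime_year First survey year with post-change catchability for
#'   winter-survey ages 1-2.
#' @param seed Integer seed; chains get distinct, reproducible RNG streams
#'   derived from it.
#' @return An object of class \code{"fit_config"}.
#' @export
fit_config <- function(profile = c("desk", "paper"), n_chains = 3L,
                       n_adapt = NULL, n_burn = NULL, n_iter = NULL,
                       thin = NULL, monitor_latent = TRUE,
                       regime_year = 1994L, seed = 1L) {
  profile <- match.arg(profile)
  def <- switch(profile,
                desk = list(n_adapt = 400L, n_burn = 800L,
                            n_iter = 1200L, thin = 1L),
                paper = list(n_adapt = 1000L, n_burn = 250000L,
                             n_iter = 250000L, thin = 1000L))
  if (n_chains < 2L) stop("need at least 2 chains for convergence diagnostics")
  structure(list(profile = profile, n_chains = as.integer(n_chains),
                 n_adapt = as.integer(n_adapt %||% def$n_adapt),
                 n_burn = as.integer(n_burn %||% def$n_burn),
                 n_iter = as.integer(n_iter %||% def$n_iter),
                 thin = as.integer(thin %||% def$thin),
                 monitor_latent = isTRUE(monitor_latent),
                 regime_year = as.integer(regime_year),
                 seed = as.integer(seed)),
            class = "fit_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Empirical starting values: run the deterministic mean path at the prior
# medians and match each catchability to the mean log ratio of its observed
# indices to the implied latents. Chains are jittered and given distinct,
# reproducible RNG streams.
jags_inits <- function(obs, covars, priors, constants, config) {
  ages <- obs$ages
  A <- ages$max_age; Y <- ages$n_years
  nsel <- A - ages$recruit_age + 1L
  p0 <- constants
  p0$M0 <- priors$M0_median; p0$MJ <- priors$MJ_median
  p0$gamma <- 0
  p0$beta0 <- 0.1 * priors$uppers$beta0
  p0$beta <- rep(0.05 * priors$uppers$beta, 3)
  p0$sel <- rep(-0.7, nsel)
  zero <- list(eps_E = numeric(Y), eps_O = numeric(Y), u_innov = numeric(Y))
  path <- simulate_forward(p0, covars, exp(priors$mu_init), shocks = zero)

  mean_lr <- function(o, l) {
    ok <- !is.na(o) & l > 0
    if (!any(ok)) return(0)
    mean(log(o[ok]) - log(l[ok]))
  }
  lqW <- matrix(0, A, 2)
  for (a in 1:A) {
    if (a <= 2L) {
      pre <- ages$years < config$regime_year
      lqW[a, 1] <- mean_lr(obs$index_winter[a, pre], path$N[a, pre])
      lqW[a, 2] <- mean_lr(obs$index_winter[a, !pre], path$N[a, !pre])
    } else {
      lqW[a, ] <- mean_lr(obs$index_winter[a, ], path$N[a, ])
    }
  }
  lq_egg <- mean_lr(obs$index_egg, path$eggs)
  lq_larv <- mean_lr(obs$index_larv, path$larvae)
  lq_0g <- mean_lr(obs$index_0g, path$zerogroup)

  base <- list(M0 = priors$M0_median, MJ = priors$MJ_median, gamma = 0,
               b0r = 0.1, br = rep(0.05, 3), s = rep(-0.7, nsel),
               sigma_E = 0.5, sigma_O = 0.5, sigma_U = 0.1, sigma_C = 0.2,
               sigma_I = rep(0.4, A), sigma_year = 0.3, sigma_egg = 0.5,
               sigma_larv = 0.5, sigma_0g = 0.5,
               lN1 = priors$mu_init,
               eps_E = numeric(Y), eps_O = numeric(Y - 1),
               U = c(NA, numeric(Y - 1)), delta = numeric(Y))

  lapply(seq_len(config$n_chains), function(ch) {
    set.seed(config$seed * 1000L + ch)
    ini <- base
    jit <- function(x, s = 0.1) x + stats::rnorm(length(x), 0, s)
    ini$s <- pmin(jit(ini$s), -0.05)
    ini$lN1 <- jit(ini$lN1, 0.2)
    # lqW rows 1-2 are stochastic (split by regime); rows 3+ enter as lq_age
    lqW_ini <- matrix(NA_real_, A, 2)
    lqW_ini[1:2, ] <- jit(lqW[1:2, ], 0.1)
    ini$lqW <- lqW_ini
    ini$lq_age <- jit(lqW[3:A, 1], 0.1)
    ini$lq_egg <- jit(lq_egg, 0.1)
    ini$lq_larv <- jit(lq_larv, 0.1)
    ini$lq_0g <- jit(lq_0g, 0.1)
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- config$seed * 1000L + ch
    ini
  })
}

#' Fit the life-cycle state-space model by MCMC
#'
#' Estimates all process and observation parameters and the latent states
#' from an observation set, using JAGS (Gibbs/slice sampling) with the priors
#' in \code{\link{prior_spec}}. Runs are exactly reproducible given the
#' configuration seed. After sampling, convergence diagnostics are computed
#' for all scalar parameters and stored in the metadata; a failed diagnostic
#' set triggers a warning but still returns the samples.
#'
#' @param obs An \code{\link{observation_set}}.
#' @param covars The matching \code{\link{covariates}}.
#' @param priors A \code{\link{prior_spec}}.
#' @param config A \code{\link{fit_config}}.
#' @param constants A \code{\link{parameter_set}} supplying the fixed
#'   constants (fecundity, egg/larval mortalities and durations); its
#'   estimated-parameter slots are ignored.
#' @param quiet Suppress JAGS progress output.
#' @return An object of class \code{"codcycle_fit"}: a list with \code{mcmc}
#'   (a \code{coda::mcmc.list} over monitored nodes) and \code{meta}
#'   (config, seed, backend, runtime, parameter names, convergence report
#'   and flag).
#' @export
fit_lifecycle <- function(obs, covars, priors = prior_spec(),
                          config = fit_config(),
                          constants = parameter_set(), quiet = TRUE) {
  stopifnot(inherits(obs, "observation_set"), inherits(covars, "covariates"))
  jd <- jags_data(obs, covars, constants, priors)
  jd$data$reg <- ifelse(obs$ages$years >= config$regime_year, 2L, 1L)
  model_code <- jags_model_string(obs$ages, jd$have)
  inits <- jags_inits(obs, covars, priors, constants, config)

  pars <- c("M0", "MJ", "gamma", "beta0", "beta", "s",
            "sigma_E", "sigma_O", "sigma_U", "sigma_C", "sigma_I",
            "sigma_year", "sigma_egg", "sigma_larv", "sigma_0g",
            "lq_egg", "lq_larv", "lq_0g", "lqW")
  monitors <- pars
  if (config$monitor_latent)
    monitors <- c(monitors, "N", "SSB", "E", "L", "O", "U", "delta")

  t0 <- proc.time()[["elapsed"]]
  run <- function() {
    jm <- rjags::jags.model(textConnection(model_code), data = jd$data,
                            inits = inits, n.chains = config$n_chains,
                            n.adapt = config$n_adapt, quiet = quiet)
    stats::update(jm, config$n_burn, progress.bar = "none")
    rjags::coda.samples(jm, monitors, n.iter = config$n_iter,
                        thin = config$thin, progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()
  runtime <- proc.time()[["elapsed"]] - t0

  par_cols <- grep("^(M0|MJ|gamma|beta0|beta\\[|s\\[|sigma|lq)",
                   coda::varnames(samples), value = TRUE)
  conv <- convergence_report(samples[, par_cols, drop = FALSE])
  ok <- all(conv$rhat_ok & conv$geweke_ok & conv$autocorr_ok, na.rm = TRUE)
  if (!ok)
    warning("convergence diagnostics failed for: ",
            paste(utils::head(conv$parameter[!(conv$rhat_ok & conv$geweke_ok &
                                                 conv$autocorr_ok)], 10),
                  collapse = ", "))
  structure(list(mcmc = samples,
                 meta = list(config = config, seed = config$seed,
                             backend = paste("rjags", utils::packageVersion("rjags")),
                             runtime_s = runtime, parameters = par_cols,
                             convergence = conv, converged = ok)),
            class = "codcycle_fit")
}

#' @export
print.codcycle_fit <- function(x, ...) {
  cfg <- x$meta$config
  cat(sprintf("Life-cycle model fit (%s profile): %d chains x %d iterations (thin %d)\n",
              cfg$profile, cfg$n_chains, cfg$n_iter, cfg$thin))
  cat(sprintf("  backend %s | seed %d | %.1f s | converged: %s\n",
              x$meta$backend, x$meta$seed, x$meta$runtime_s,
              x$meta$converged))
  invisible(x)
}

#' Posterior draws as a matrix
#'
#' Pools all chains into one draws-by-node matrix.
#'
#' @param fit A \code{"codcycle_fit"}.
#' @param pattern Optional regular expression selecting node names.
#' @return Numeric matrix of posterior draws.
#' @export
posterior_matrix <- function(fit, pattern = NULL) {
  m <- as.matrix(fit$mcmc)
  if (!is.null(pattern)) m <- m[, grep(pattern, colnames(m)), drop = FALSE]
  m
}

#' Posterior summary table
#'
#' Medians and central credible intervals for monitored nodes.
#'
#' @param fit A \code{"codcycle_fit"}.
#' @param pattern Regular expression selecting nodes (default: parameters).
#' @param level Credible level.
#' @return Data frame with median and interval bounds per node.
#' @export
posterior_summary <- function(fit, pattern = NULL, level = 0.95) {
  m <- if (is.null(pattern)) {
    posterior_matrix(fit)[, fit$meta$parameters, drop = FALSE]
  } else posterior_matrix(fit, pattern)
  a <- (1 - level) / 2
  qs <- t(apply(m, 2, stats::quantile, probs = c(a, 0.5, 1 - a)))
  data.frame(parameter = rownames(qs), lower = qs[, 1], median = qs[, 2],
             upper = qs[, 3], row.names = NULL)
}
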