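# JAGS translation of the life-cycle state-space model. The model string is
# assembled per dataset so that observation blocks with no observed cells are
# omitted entirely (JAGS cannot loop over an empty range); with every series
# masked out the remaining graph is the joint prior, which is what the
# prior-only sampling check exploits.

jags_model_string <- function(ages, have) {
  r <- ages$recruit_age
  A <- ages$max_age
  cann <- paste(sprintf("N[%d, y]", ages$cannibal_ages), collapse = " + ")
  dd <- ages$dd_ages

  header <- "
model {
  # --- parameter priors ---
  M0 ~ dlnorm(lmed_M0, tau_M)
  MJ ~ dlnorm(lmed_MJ, tau_M)
  gamma ~ dnorm(0, tau_vague)
  b0r ~ dunif(0, 1)
  beta0 <- b0r * up_beta0
  for (j in 1:3) {
    br[j] ~ dunif(0, 1)
    beta[j] <- br[j] * up_beta
  }
  for (i in 1:nsel) {
    s[i] ~ dnorm(sel_mean, tau_vague) T(, 0)
  }
  sigma_E ~ dunif(0, up_sE)
  tau_E <- pow(sigma_E, -2)
  sigma_O ~ dunif(0, up_sO)
  tau_O <- pow(sigma_O, -2)
  sigma_U ~ dunif(0, up_sU)
  tau_U <- pow(sigma_U, -2)
  sigma_C ~ dunif(0, up_sC)
  tau_C <- pow(sigma_C, -2)
  for (a in 1:A) {
    sigma_I[a] ~ dunif(0, up_sI)
    tau_I[a] <- pow(sigma_I[a], -2)
  }
  sigma_year ~ dunif(0, up_syr)
  tau_yr <- pow(sigma_year, -2)
  sigma_egg ~ dunif(0, up_seg)
  tau_eg <- pow(sigma_egg, -2)
  sigma_larv ~ dunif(0, up_sla)
  tau_la <- pow(sigma_larv, -2)
  sigma_0g ~ dunif(0, up_s0g)
  tau_0g <- pow(sigma_0g, -2)
  lq_egg ~ dnorm(lq_stage_mean, tau_vague)
  lq_larv ~ dnorm(lq_stage_mean, tau_vague)
  lq_0g ~ dnorm(0, tau_vague)
  for (a in 1:2) {
    lqW[a, 1] ~ dnorm(0, tau_vague)   # pre-regime catchability, ages 1-2
    lqW[a, 2] ~ dnorm(0, tau_vague)   # post-regime
  }
  for (a in 3:A) {
    lq_age[a - 2] ~ dnorm(0, tau_vague)
    lqW[a, 1] <- lq_age[a - 2]
    lqW[a, 2] <- lq_age[a - 2]
  }
"
  process <- sprintf("
  # --- latent process ---
  for (a in 1:A) {
    lN1[a] ~ dnorm(mu_init[a], tau_init)
    N[a, 1] <- exp(lN1[a])
  }
  U[1] <- 0
  for (y in 2:Y) {
    U[y] ~ dnorm(U[y - 1], tau_U)
  }
  for (y in 1:Y) {
    delta[y] ~ dnorm(0, tau_yr)
    eps_E[y] ~ dnorm(0, tau_E)
    SSB[y] <- inprod(N[1:A, y], wp[1:A, y])
    E[y] <- fec_kg * SSB[y] * exp(eps_E[y])
    L[y] <- E[y] * exp(-M_egg * t_EL)
    O[y] <- L[y] * min(1, exp(-(M_larv - gamma * temp[y]) * t_larv
                              - M_juv * t_ejuv))
    for (i in 1:nsel) {
      F[%d + i, y] <- exp(s[i] + U[y])
      C[%d + i, y] <- N[%d + i, y] * F[%d + i, y] / (F[%d + i, y] + MA) *
                      (1 - exp(-(F[%d + i, y] + MA)))
    }
  }
  for (y in 1:(Y - 1)) {
    eps_O[y] ~ dnorm(0, tau_O)
    N[1, y + 1] <- O[y] * min(1, exp(-M0 + eps_O[y]) / (1 + beta0 * (%s)))
    for (a in %d:%d) {
      N[a + 1, y + 1] <- N[a, y] * exp(-MJ) / (1 + beta[a] * N[a, y])
    }
    for (a in %d:%d) {
      N[a + 1, y + 1] <- N[a, y] * exp(-(MA + F[a, y]))
    }
  }
", r - 1L, r - 1L, r - 1L, r - 1L, r - 1L, r - 1L,
   cann, min(dd), max(dd), r, A - 1L)

  obs <- ""
  if (have["landings"]) obs <- paste0(obs, "
  for (k in 1:nL) {
    Lnd[k] ~ dlnorm(log(C[La[k], Ly[k]]) - pow(sigma_C, 2) / 2, tau_C)
  }
")
  if (have["winter"]) obs <- paste0(obs, "
  for (k in 1:nW) {
    W[k] ~ dlnorm(lqW[Wa[k], reg[Wy[k]]] + log(N[Wa[k], Wy[k]]) + delta[Wy[k]],
                  tau_I[Wa[k]])
  }
")
  if (have["egg"]) obs <- paste0(obs, "
  for (k in 1:nE) {
    Ieg[k] ~ dlnorm(lq_egg + log(E[Ey[k]]), tau_eg)
  }
")
  if (have["larv"]) obs <- paste0(obs, "
  for (k in 1:nLa) {
    Ila[k] ~ dlnorm(lq_larv + log(L[Lay[k]]), tau_la)
  }
")
  if (have["zg"]) obs <- paste0(obs, "
  for (k in 1:nO) {
    Izg[k] ~ dlnorm(lq_0g + log(O[Oy[k]]), tau_0g)
  }
")
  paste0(header, process, obs, "}\n")
}

# Flatten the observation set into the vectors + index arrays the JAGS model
# expects, plus covariates, fixed constants and prior hyperparameters.
jags_data <- function(obs, covars, params, priors) {
  ages <- obs$ages
  A <- ages$max_age; Y <- ages$n_years
  dat <- list(
    A = A, Y = Y, nsel = A - ages$recruit_age + 1L,
    wp = covars$weight * covars$maturity,
    temp = covars$temperature,
    fec_kg = 1000 * params$fecundity,
    M_egg = params$M_egg, t_EL = params$t_EL,
    M_larv = params$M_larv_daily, t_larv = params$t_larv,
    M_juv = params$M_juv_daily, t_ejuv = params$t_ejuv,
    MA = priors$MA,
    lmed_M0 = log(priors$M0_median), lmed_MJ = log(priors$MJ_median),
    tau_M = 1 / priors$M_logvar,
    tau_vague = 1 / priors$lq_var,
    sel_mean = priors$sel_mean,
    lq_stage_mean = priors$lq_mean_stage,
    up_beta0 = priors$uppers$beta0, up_beta = priors$uppers$beta,
    up_sE = priors$uppers$sigma_E, up_sO = priors$uppers$sigma_O,
    up_sU = priors$uppers$sigma_U, up_sC = priors$uppers$sigma_C,
    up_sI = priors$uppers$sigma_I, up_syr = priors$uppers$sigma_year,
    up_seg = priors$uppers$sigma_egg, up_sla = priors$uppers$sigma_larv,
    up_s0g = priors$uppers$sigma_0g,
    mu_init = priors$mu_init, tau_init = 1 / priors$sd_init^2)

  have <- c(landings = FALSE, winter = FALSE, egg = FALSE, larv = FALSE,
            zg = FALSE)

  lcells <- which(!is.na(obs$landings), arr.ind = TRUE)
  if (nrow(lcells)) {
    if (any(lcells[, 1] < ages$recruit_age))
      stop("landings reported below the recruitment age ",
           ages$recruit_age, "; the model has no fishery there")
    have["landings"] <- TRUE
    dat$nL <- nrow(lcells)
    dat$Lnd <- obs$landings[lcells]
    dat$La <- lcells[, 1]; dat$Ly <- lcells[, 2]
  }
  wcells <- which(!is.na(obs$index_winter), arr.ind = TRUE)
  if (nrow(wcells)) {
    have["winter"] <- TRUE
    dat$nW <- nrow(wcells)
    dat$W <- obs$index_winter[wcells]
    dat$Wa <- wcells[, 1]; dat$Wy <- wcells[, 2]
  }
  # regime indicator needed whenever the winter block is present
  dat$reg <- ifelse(ages$years >= 1994L, 2L, 1L)
  ey <- which(!is.na(obs$index_egg))
  if (length(ey)) {
    have["egg"] <- TRUE
    dat$nE <- length(ey); dat$Ieg <- obs$index_egg[ey]; dat$Ey <- ey
  }
  ly <- which(!is.na(obs$index_larv))
  if (length(ly)) {
    have["larv"] <- TRUE
    dat$nLa <- length(ly); dat$Ila <- obs$index_larv[ly]; dat$Lay <- ly
  }
  oy <- which(!is.na(obs$index_0g))
  if (length(oy)) {
    have["zg"] <- TRUE
    dat$nO <- length(oy); dat$Izg <- obs$index_0g[oy]; dat$Oy <- oy
  }
  list(data = dat, have = have)
}
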