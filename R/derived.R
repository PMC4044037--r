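#' Cohort survival from age 1 to age 4
#'
#' For each posterior draw the survival of the cohort that is age 1 in year
#' y is the product of the three density-dependent juvenile transitions
#' along the cohort diagonal,
#' \eqn{\prod_{a=1}^{3} e^{-M_J} / (1 + \beta_a N_{a, y+a-1})}, evaluated
#' draw by draw so that parameter correlations propagate into the credible
#' band. Cohorts with missing abundance cells are omitted.
#'
#' @param draws Matrix or data frame of posterior draws with columns
#'   \code{MJ}, \code{beta[1]}, \code{beta[2]}, \code{beta[3]} (a single set
#'   of point values also works as a 1-row input).
#' @param N Abundance-at-age matrix (ages in rows, years in columns; needs
#'   ages 1-3).
#' @param level Credible level for the band.
#' @return Data frame with the cohort year (year at age 1), posterior median
#'   survival, and interval bounds.
#' @export
survival_1to4 <- function(draws, N, level = 0.95) {
  draws <- as.matrix(draws)
  need <- c("MJ", "beta[1]", "beta[2]", "beta[3]")
  if (!all(need %in% colnames(draws)))
    stop("draws must contain columns ", paste(need, collapse = ", "))
  Y <- ncol(N)
  yrs <- seq_len(Y - 2)
  a_probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  out <- lapply(yrs, function(y) {
    n3 <- c(N[1, y], N[2, y + 1], N[3, y + 2])
    if (any(is.na(n3))) return(NULL)
    s <- exp(-3 * draws[, "MJ"]) /
      ((1 + draws[, "beta[1]"] * n3[1]) *
         (1 + draws[, "beta[2]"] * n3[2]) *
         (1 + draws[, "beta[3]"] * n3[3]))
    q <- stats::quantile(s, a_probs)
    data.frame(year = if (!is.null(colnames(N))) as.integer(colnames(N)[y])
               else y,
               lower = q[1], median = q[2], upper = q[3])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Recruits (age 4) per 0-group individual
#'
#' Follows each 0-group cohort to recruitment: the cohort that is 0-group in
#' year y reaches age 4 in year y + 4. Under compensatory density dependence
#' the ratio declines with 0-group abundance.
#'
#' @param latent A \code{"latent_state"}.
#' @return Data frame with year, 0-group abundance, recruit abundance and
#'   recruits per 0-group.
#' @export
recruits_per_0group <- function(latent) {
  ages <- latent$ages
  Y <- ages$n_years
  r <- ages$recruit_age
  y <- seq_len(Y - r)
  data.frame(year = ages$years[y],
             zerogroup = latent$zerogroup[y],
             recruits = latent$N[r, y + r],
             recruits_per_0group = latent$N[r, y + r] / latent$zerogroup[y])
}

#' Interannual variance of a log abundance series
#'
#' Sample variance (n - 1 denominator) of the natural-log series; the
#' summary behind the variance-dampening comparison across life stages.
#'
#' @param series Positive abundance series (a numeric vector, or a list of
#'   them).
#' @return Scalar variance, or a named vector for list input.
#' @export
interannual_variance <- function(series) {
  if (is.list(series))
    return(vapply(series, interannual_variance, numeric(1)))
  series <- series[!is.na(series)]
  if (length(series) < 2) stop("series must have at least 2 observations")
  if (any(series <= 0)) stop("series must be strictly positive to take logs")
  stats::var(log(series))
}

#' Variance of log abundance by life stage
#'
#' Interannual variances of the log series for SSB, eggs, larvae, 0-group
#' and ages 1 to \code{max_age_shown} from one latent trajectory: the
#' dampening pattern rises from SSB to age 1 and falls again towards
#' recruitment when juvenile density dependence is active.
#'
#' @param latent A \code{"latent_state"}.
#' @param max_age_shown Oldest age class included (default 4, the
#'   recruitment age).
#' @return Named numeric vector of variances.
#' @export
variance_by_stage <- function(latent, max_age_shown = 4L) {
  stages <- c(list(SSB = latent$SSB, eggs = latent$eggs,
                   larvae = latent$larvae, zerogroup = latent$zerogroup),
              stats::setNames(lapply(seq_len(max_age_shown),
                                     function(a) latent$N[a, ]),
                              paste0("age", seq_len(max_age_shown))))
  interannual_variance(stages)
}

#' Year-class strength ratio
#'
#' Ratio of the largest to the smallest cohort abundance in a series; the
#' drop in this ratio between age 1 and age 4 measures how much juvenile
#' density dependence dampens recruitment variability.
#'
#' @param series Positive abundance series.
#' @return max/min ratio (always >= 1).
#' @export
yearclass_ratio <- function(series) {
  series <- series[!is.na(series)]
  if (!length(series)) stop("empty series")
  if (any(series <= 0)) stop("series must be strictly positive")
  max(series) / min(series)
}

#' Bootstrap correlation between log abundance and a survival index
#'
#' The survival index for the cohort that is age a in year y follows the
#' cohort from the previous to the subsequent age-class,
#' \eqn{s_y = \log I_{a+1,y+1} - \log I_{a-1,y-1}}. The index of age a in
#' year y itself is deliberately left out of the difference, so the
#' estimation errors of the survival index and of the abundance
#' \eqn{\log I_{a,y}} are independent by construction and a negative
#' correlation is evidence of density-dependent survival rather than shared
#' observation noise (the shared within-year survey effect cannot enter
#' either, since the three terms come from three different survey years).
#' Uncertainty comes from resampling the available (abundance, survival)
#' pairs with replacement.
#'
#' @param index Winter-survey index matrix (ages x years; NA where
#'   unobserved).
#' @param age Age class a.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Optional seed for the resampling.
#' @param index_prev Index series of the previous age-class by year; defaults
#'   to row \code{age - 1} of \code{index}. For age 1 supply the 0-group
#'   index series.
#' @return List with the point estimate (Pearson correlation on logs), the
#'   bootstrap median and 95 percent interval, and the number of pairs.
#' @export
bootstrap_survival_correlation <- function(index, age, n_boot = 10000,
                                           seed = NULL, index_prev = NULL) {
  Y <- ncol(index)
  if (is.null(index_prev)) {
    if (age < 2) stop("for age 1 supply index_prev (the 0-group index)")
    index_prev <- index[age - 1, ]
  }
  y <- 2:(Y - 1)
  la <- log(index[age, y])
  s <- log(index[age + 1, y + 1]) - log(index_prev[y - 1])
  ok <- !is.na(la) & !is.na(s)
  la <- la[ok]; s <- s[ok]
  n <- length(la)
  if (n < 5) stop("need at least 5 abundance-survival pairs")
  if (!is.null(seed)) set.seed(seed)
  est <- stats::cor(la, s)
  boot <- vapply(seq_len(n_boot), function(i) {
    k <- sample.int(n, n, replace = TRUE)
    if (stats::sd(la[k]) == 0 || stats::sd(s[k]) == 0) return(NA_real_)
    stats::cor(la[k], s[k])
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  q <- stats::quantile(boot, c(0.025, 0.5, 0.975))
  list(estimate = est, median = unname(q[2]),
       ci = unname(q[c(1, 3)]), n_pairs = n, n_boot = n_boot)
}

#' Predicted relationship between consecutive juvenile age classes
#'
#' Evaluates \eqn{N_{a+1} = N_a e^{-M_J} / (1 + \beta_a N_a)} over a grid of
#' current abundances for every posterior draw, giving a pointwise median
#' curve with a credible band that reflects the joint posterior of
#' \eqn{M_J} and \eqn{\beta_a} (draws are used jointly, never summarised
#' first, so parameter correlations are respected). The curve saturates at
#' \eqn{e^{-M_J}/\beta_a}.
#'
#' @param draws Posterior draws with columns \code{MJ} and
#'   \code{beta[a]}.
#' @param age Age a (one of the density-dependent ages 1-3).
#' @param grid Abundance grid for \eqn{N_a}.
#' @param level Credible level.
#' @return Data frame with grid value, median and band bounds.
#' @export
predicted_ageclass_curve <- function(draws, age,
                                     grid = seq(1e7, 5e9, length.out = 50),
                                     level = 0.95) {
  draws <- as.matrix(draws)
  bcol <- sprintf("beta[%d]", age)
  if (!all(c("MJ", bcol) %in% colnames(draws)))
    stop("draws must contain MJ and ", bcol)
  a <- (1 - level) / 2
  pred <- vapply(grid, function(g) {
    v <- g * exp(-draws[, "MJ"]) / (1 + draws[, bcol] * g)
    stats::quantile(v, c(a, 0.5, 1 - a))
  }, numeric(3))
  data.frame(N_a = grid, lower = pred[1, ], median = pred[2, ],
             upper = pred[3, ])
}

#' Temperature-recruitment pairs
#'
#' Pairs each year's larval-stage temperature anomaly with the abundance of
#' recruits (age 4) from that year's spawning four years later.
#'
#' @param latent A \code{"latent_state"}.
#' @param covars The matching \code{\link{covariates}}.
#' @return Data frame with year, temperature anomaly and recruit abundance.
#' @export
temp_recruit_table <- function(latent, covars) {
  ages <- latent$ages
  r <- ages$recruit_age
  y <- seq_len(ages$n_years - r)
  data.frame(year = ages$years[y],
             temperature = covars$temperature[y],
             recruits = latent$N[r, y + r])
}
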