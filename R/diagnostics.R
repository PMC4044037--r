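#' Convergence diagnostics for MCMC output
#'
#' Computes, per monitored node: the split-chain potential scale reduction
#' factor (each chain halved, so at least four half-chains enter the
#' between/within variance comparison), the Geweke z-score (largest absolute
#' value across chains), the lag-1 autocorrelation of the thinned chains
#' (averaged across chains), and the multi-chain effective sample size; plus
#' pass flags (Rhat < 1.05, |z| < 2, lag-1 autocorrelation < 0.2). The
#' pairwise posterior cross-correlation matrix is attached as an attribute.
#'
#' @param samples A \code{coda::mcmc.list} (at least 2 chains) or a
#'   \code{"codcycle_fit"} (its parameter nodes are used).
#' @return Data frame with one row per node and a \code{"crosscorr"}
#'   attribute.
#' @export
convergence_report <- function(samples) {
  if (inherits(samples, "codcycle_fit"))
    samples <- samples$mcmc[, samples$meta$parameters, drop = FALSE]
  if (!inherits(samples, "mcmc.list"))
    samples <- coda::as.mcmc.list(samples)
  if (length(samples) < 2L)
    stop("split-chain scale reduction needs at least 2 chains")
  vn <- coda::varnames(samples)
  n <- nrow(samples[[1]])
  half <- floor(n / 2)

  rhat_one <- function(x) {   # x: iterations x chains, already split
    m <- ncol(x); nn <- nrow(x)
    mu <- colMeans(x); v <- apply(x, 2, stats::var)
    B <- nn * stats::var(mu); W <- mean(v)
    if (W == 0) return(NA_real_)
    sqrt(((nn - 1) / nn * W + B / nn) / W)
  }

  rhat <- geweke <- lag1 <- numeric(length(vn))
  for (j in seq_along(vn)) {
    ch <- lapply(samples, function(s) as.numeric(s[, j]))
    split <- do.call(cbind, lapply(ch, function(x)
      cbind(x[seq_len(half)], x[(n - half + 1):n])))
    rhat[j] <- rhat_one(split)
    gz <- vapply(ch, function(x) {
      z <- tryCatch(coda::geweke.diag(coda::mcmc(x))$z,
                    error = function(e) NA_real_)
      as.numeric(z)
    }, numeric(1))
    geweke[j] <- gz[which.max(abs(gz))]
    lag1[j] <- mean(vapply(ch, function(x) {
      if (stats::sd(x) == 0) return(0)
      stats::cor(x[-length(x)], x[-1])
    }, numeric(1)))
  }
  ess <- coda::effectiveSize(samples)[vn]

  out <- data.frame(parameter = vn, rhat = rhat, geweke_z = geweke,
                    lag1_autocorr = lag1, ess = as.numeric(ess),
                    row.names = NULL)
  out$rhat_ok <- is.na(out$rhat) | out$rhat < 1.05
  out$geweke_ok <- is.na(out$geweke_z) | abs(out$geweke_z) < 2
  out$autocorr_ok <- out$lag1_autocorr < 0.2
  attr(out, "crosscorr") <- coda::crosscorr(samples)
  out
}
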