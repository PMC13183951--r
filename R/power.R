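## Monte Carlo power for maternal-vs-paternal coefficient differences:
## estimate-level simulation of the two coefficients from their sampling
## distribution, two-sided Wald equality test, with an analytic
## normal-theory cross-check.

#' Analytic normal-theory power of the Wald difference test
#'
#' Closed form for a two-sided z-test of `b1 = b2` with known standard
#' error of the difference: `Phi(|d|/se - z) + Phi(-|d|/se - z)`.
#'
#' @param deltaBeta true coefficient difference.
#' @param seDiff standard error of the difference.
#' @param alpha two-sided level.
#' @return power in `[0, 1]`.
#' @export
powerWaldAnalytic <- function(deltaBeta, seDiff, alpha = 0.05) {
  z <- qnorm(1 - alpha / 2)
  r <- abs(deltaBeta) / seDiff
  pnorm(r - z) + pnorm(-r - z)
}

#' Monte Carlo power of the Wald test for a coefficient difference
#'
#' Per replication, draws the maternal and paternal coefficient estimates
#' from a bivariate normal with means `(0, deltaBeta)`, the stated standard
#' errors and correlation, and applies the two-sided Wald equality test at
#' level `alpha`. Power is the rejection fraction, with its binomial Monte
#' Carlo standard error and the analytic normal-theory value alongside.
#'
#' @param deltaBeta true maternal-paternal difference.
#' @param seMaternal,sePaternal per-coefficient standard errors (> 0).
#' @param corrEstimates correlation between the two estimates (|corr| < 1).
#' @param nReps replications (>= 100).
#' @param alpha two-sided level.
#' @param seed optional integer seed.
#' @return one-row `"PowerGrid"` data.frame: `delta_beta`, SEs, `n_reps`,
#'   `alpha`, `power`, `mc_se`, `analytic`.
#' @export
powerWaldDifference <- function(deltaBeta, seMaternal, sePaternal,
                                corrEstimates = 0, nReps = 1000L,
                                alpha = 0.05, seed = NULL) {
  if (seMaternal <= 0 || sePaternal <= 0) stop("standard errors must be > 0")
  if (nReps < 100) stop("nReps must be >= 100")
  if (abs(corrEstimates) >= 1) stop("|corrEstimates| must be < 1")
  if (!is.null(seed)) set.seed(seed)
  covAB <- corrEstimates * seMaternal * sePaternal
  seDiff <- sqrt(seMaternal^2 + sePaternal^2 - 2 * covAB)
  b1 <- rnorm(nReps, 0, seMaternal)
  b2 <- corrEstimates * sePaternal / seMaternal * b1 +
    rnorm(nReps, 0, sePaternal * sqrt(1 - corrEstimates^2)) + deltaBeta
  zstat <- (b2 - b1) / seDiff
  rej <- abs(zstat) > qnorm(1 - alpha / 2)
  pw <- mean(rej)
  out <- data.frame(
    delta_beta = deltaBeta, se_maternal = seMaternal,
    se_paternal = sePaternal, corr = corrEstimates,
    n_reps = as.integer(nReps), alpha = alpha,
    power = pw, mc_se = sqrt(pw * (1 - pw) / nReps),
    analytic = powerWaldAnalytic(deltaBeta, seDiff, alpha))
  class(out) <- c("PowerGrid", class(out))
  out
}

#' Power grid from a fitted parent-of-origin model
#'
#' Evaluates [powerWaldDifference()] at the observed maternal-paternal
#' difference and at both endpoints of its 95% CI, for the transmitted and
#' non-transmitted score pairs of a [fitPoe()] result.
#'
#' @param fit a `"PoeFit"`.
#' @param nReps replications per grid point.
#' @param alpha two-sided level.
#' @param seed integer seed (each row uses a derived sub-seed).
#' @return `"PowerGrid"` data.frame with one row per constraint x
#'   {ci_lower, observed, ci_upper}.
#' @export
powerGridFromFit <- function(fit, nReps = 1000L, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(fit, "PoeFit"))
  est <- setNames(fit$coef$estimate, fit$coef$term)
  se <- setNames(fit$coef$se, fit$coef$term)
  if (anyNA(se)) stop("fit is missing standard errors / CIs")
  rows <- list()
  cons <- list(transmitted = c("maternal_T", "paternal_T"),
               non_transmitted = c("maternal_NT", "paternal_NT"))
  k <- 0L
  for (cn in names(cons)) {
    tt <- cons[[cn]]
    d <- unname(est[tt[1]] - est[tt[2]])
    V <- fit$robustVcov[tt, tt]
    sed <- unname(sqrt(V[1, 1] + V[2, 2] - 2 * V[1, 2]))
    pts <- c(ci_lower = d - qnorm(0.975) * sed, observed = d,
             ci_upper = d + qnorm(0.975) * sed)
    for (pn in names(pts)) {
      k <- k + 1L
      r <- powerWaldDifference(unname(pts[pn]), se[tt[1]], se[tt[2]],
                               corrEstimates = 0, nReps = nReps,
                               alpha = alpha, seed = seed + k)
      r$constraint <- cn
      r$point <- pn
      rows[[k]] <- r
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("PowerGrid", "data.frame")
  out
}
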