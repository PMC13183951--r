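## Shared fixtures, built once per test run.

## small marker-level trio cohort with recombination, no phase errors
smallTrioCohort <- function(seed = 101, nFamilies = 40, nMarkers = 600,
                            nChrom = 2, crossoverRate = 1.5,
                            fractionTrios = 1, phaseErrorRate = 0,
                            sibFraction = 0) {
  simulateCohort(generativeParams(
    nFamilies = nFamilies, nMarkersPerChrom = nMarkers,
    nChromosomes = nChrom, crossoverRate = crossoverRate,
    fractionTrios = fractionTrios, phaseErrorRate = phaseErrorRate,
    sibFraction = sibFraction, seed = seed))
}

## score-level cohort merged with phenotypes at a given wave
scoreData <- function(params, wave = 1, seed = NULL) {
  sc <- simulateScoreCohort(params, seed = seed)
  ph <- sc$phenotypes
  if (!is.null(wave)) ph <- ph[ph$wave == wave, ]
  merge(ph, sc$scores,
        by.x = c("individual_id", "family_id"),
        by.y = c("offspring_id", "family_id"))
}

## a bare-bones JointFit for arithmetic-only operations
fakeJointFit <- function(beta_t, beta_nt, family = "gaussian") {
  structure(list(outcome = "x", family = family, beta_t = beta_t,
                 beta_nt = beta_nt, beta_dgt = beta_t - beta_nt),
            class = "JointFit")
}

## a bare-bones PoeFit with a given coefficient table and robust covariance
fakePoeFit <- function(est, V) {
  terms <- names(est)
  structure(list(
    coef = data.frame(term = terms, estimate = unname(est),
                      se = sqrt(diag(V)),
                      ci_lo = unname(est) - 1.96 * sqrt(diag(V)),
                      ci_hi = unname(est) + 1.96 * sqrt(diag(V)),
                      p = NA_real_),
    robustVcov = V, engine = "synthetic", n = 0L, nFamilies = 0L),
    class = "PoeFit")
}
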