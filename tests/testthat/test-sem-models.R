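test_that("the path model equals OLS on complete data", {
  p <- generativeParams(nFamilies = 1200, fractionTrios = 1,
                        sibFraction = 0, seed = 51)
  d <- scoreData(p)
  pf <- fitPoe(d, outcome = "y")
  expect_identical(pf$engine, "closed-form ML")
  z <- function(x) (x - mean(x)) / sd(x)
  ols <- lm(z(y) ~ z(pgs_t_maternal) + z(pgs_nt_maternal) +
              z(pgs_t_paternal) + z(pgs_nt_paternal) + z(age) +
              I(sex == "male"), data = d)
  est <- setNames(pf$coef$estimate, pf$coef$term)
  expect_lt(abs(est["maternal_T"] - coef(ols)[2]), 1e-6)
  expect_lt(abs(est["maternal_NT"] - coef(ols)[3]), 1e-6)
  expect_lt(abs(est["paternal_T"] - coef(ols)[4]), 1e-6)
  expect_lt(abs(est["paternal_NT"] - coef(ols)[5]), 1e-6)
  ## robust covariance is symmetric PSD
  ev <- eigen(pf$robustVcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
})

test_that("the FIML optimizer reproduces the closed form on complete data", {
  p <- generativeParams(nFamilies = 400, fractionTrios = 1,
                        sibFraction = 0, seed = 52)
  d <- scoreData(p)
  pfC <- fitPoe(d, outcome = "y")
  pfF <- fitPoe(d, outcome = "y", forceFiml = TRUE)
  expect_identical(pfF$engine, "FIML")
  expect_lt(max(abs(pfC$coef$estimate - pfF$coef$estimate)), 1e-4)
  expect_lt(abs(pfC$loglik - pfF$loglik), 1e-4)
})

test_that("FIML recovers parent-specific effects and handles MCAR missingness", {
  truthMT <- 0.124; truthPT <- 0.155
  p <- generativeParams(nFamilies = 2500, fractionTrios = 1, sibFraction = 0,
                        parentEffects = list(mT = truthMT, mNT = 0.039,
                                             pT = truthPT, pNT = 0.036),
                        sigmaResid = 0.92, seed = 53)
  d <- scoreData(p)
  pf <- fitPoe(d, outcome = "y")
  est <- setNames(pf$coef$estimate, pf$coef$term)
  se <- setNames(pf$coef$se, pf$coef$term)
  expect_lt(abs(est["maternal_T"] - truthMT), 3 * se["maternal_T"])
  expect_lt(abs(est["paternal_T"] - truthPT), 3 * se["paternal_T"])
  ## MCAR missingness on the paternal NT score: FIML point estimates stay
  ## unbiased across replicates
  nRep <- 30
  bias <- matrix(NA_real_, nRep, 2)
  for (r in seq_len(nRep)) {
    pr <- generativeParams(nFamilies = 500, fractionTrios = 1,
                           sibFraction = 0,
                           parentEffects = list(mT = truthMT, mNT = 0.039,
                                                pT = truthPT, pNT = 0.036),
                           sigmaResid = 0.92, seed = 5300 + r)
    dr <- scoreData(pr)
    set.seed(8800 + r)
    dr$pgs_nt_paternal[runif(nrow(dr)) < 0.4] <- NA
    pfr <- fitPoe(dr, outcome = "y")
    er <- setNames(pfr$coef$estimate, pfr$coef$term)
    bias[r, ] <- c(er["maternal_T"] - truthMT, er["paternal_T"] - truthPT)
  }
  mcse <- apply(bias, 2, sd) / sqrt(nRep)
  expect_lt(abs(mean(bias[, 1])), 3 * mcse[1])
  expect_lt(abs(mean(bias[, 2])), 3 * mcse[2])
})

test_that("a score column that is entirely missing is rejected", {
  p <- generativeParams(nFamilies = 200, fractionTrios = 1, sibFraction = 0,
                        seed = 54)
  d <- scoreData(p)
  d$pgs_nt_paternal <- NA_real_
  expect_error(fitPoe(d, outcome = "y"), "entirely missing")
})

test_that("Wald equality matches its scalar closed form", {
  V <- matrix(c(0.0002, 0.00003, 0.00003, 0.00025), 2, 2,
              dimnames = list(c("maternal_T", "paternal_T"),
                              c("maternal_T", "paternal_T")))
  fit <- fakePoeFit(c(maternal_T = 0.124, paternal_T = 0.155), V)
  w <- waldEquality(fit, c("maternal_T", "paternal_T"))
  varD <- V[1, 1] + V[2, 2] - 2 * V[1, 2]
  expect_equal(w$delta_chi2, (0.124 - 0.155)^2 / varD)
  expect_equal(w$df, 1L)
  expect_equal(w$p, pchisq(w$delta_chi2, 1, lower.tail = FALSE))
  ## identical coefficients: statistic 0, p 1
  fit3 <- fakePoeFit(c(maternal_T = 0.1, paternal_T = 0.1),
                     matrix(c(2e-4, 1e-5, 1e-5, 2e-4), 2, 2,
                            dimnames = dimnames(V)))
  w3 <- waldEquality(fit3)
  expect_equal(w3$delta_chi2, 0)
  expect_equal(w3$p, 1)
  expect_error(waldEquality(fit3, c("maternal_T", "nope")), "unknown")
})

test_that("the scalar Wald example equals delta^2 over its variance", {
  V <- matrix(c(0.0003129, 0, 0, 0), 2, 2,
              dimnames = list(c("maternal_T", "paternal_T"),
                              c("maternal_T", "paternal_T")))
  ## variance fully on the first coefficient so Var(delta) = 0.0003129
  fit <- fakePoeFit(c(maternal_T = 0.031, paternal_T = 0), V)
  expect_error(waldEquality(fit), NA)
  w <- waldEquality(fit)
  expect_equal(w$delta_chi2, 0.031^2 / 0.0003129)
})

test_that("the Wald equality test holds its size under true equality", {
  nRep <- 120
  rej <- logical(nRep)
  for (r in seq_len(nRep)) {
    p <- generativeParams(nFamilies = 300, fractionTrios = 1,
                          sibFraction = 0,
                          parentEffects = list(mT = 0.14, mNT = 0.03,
                                               pT = 0.14, pNT = 0.03),
                          sigmaResid = 0.95, seed = 6000 + r)
    d <- scoreData(p)
    pf <- fitPoe(d, outcome = "y")
    rej[r] <- waldEquality(pf)$p < 0.05
  }
  ## binomial band around 5%
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / nRep) + 0.01)
})

test_that("mediation recovers calibrated indirect effects with honest CIs", {
  ## maternal transmitted indirect a x b calibrated to 0.026
  p <- generativeParams(nFamilies = 4000, fractionTrios = 1, sibFraction = 0,
                        aM = 0.4 * sqrt(2), aP = 0.4 * sqrt(2),
                        bM = 0.065, bP = 0.02, betaNurture = 0.01,
                        seed = 55)
  d <- scoreData(p)
  m <- fitMediation(d, outcome = "y", nBoot = 200, seed = 7)
  eff <- m$effects
  matT <- eff[eff$term == "maternal_T", ]
  expect_lt(abs(matT$indirect - 0.026), 2 * (matT$ci_hi - matT$ci_lo) / 3.92)
  expect_true(matT$significant)
  ## maternal - paternal ordering matches the generative b_m > b_p
  expect_gt(m$contrasts$delta_indirect[m$contrasts$type == "transmitted"], 0)
  ## standardized indirect equals the product of its standardized paths
  expect_equal(eff$indirect, eff$a * eff$b, tolerance = 1e-12)
  ## total = direct + indirect in the point fit and in every bootstrap draw
  expect_equal(eff$total, eff$cprime + eff$indirect, tolerance = 1e-10)
  ind <- m$draws[, paste0("ind_", eff$term)]
  tot <- m$draws[, paste0("tot_", eff$term)]
  dir <- m$draws[, paste0("dir_", eff$term)]
  expect_lt(max(abs(tot - (dir + ind))), 1e-10)
})

test_that("null mediation yields intervals covering zero", {
  p <- generativeParams(nFamilies = 2500, fractionTrios = 1, sibFraction = 0,
                        bM = 0, bP = 0, seed = 56)
  d <- scoreData(p)
  m <- fitMediation(d, outcome = "y", nBoot = 150, seed = 8)
  expect_true(all(m$effects$ci_lo <= 0 & m$effects$ci_hi >= 0))
  ## same seed, same intervals
  m2 <- fitMediation(d, outcome = "y", nBoot = 150, seed = 8)
  expect_identical(m$effects$ci_lo, m2$effects$ci_lo)
  expect_identical(m$draws, m2$draws)
  expect_warning(fitMediation(d[1:80, ], outcome = "y", nBoot = 50, seed = 9),
                 "nBoot")
})

test_that("no assortative mating shows up as near-zero modeled covariances", {
  p <- generativeParams(nFamilies = 3000, fractionTrios = 1, sibFraction = 0,
                        amCorr = 0, aM = 0.5, aP = 0.5, bM = 0.05, bP = 0.05,
                        seed = 57)
  d <- scoreData(p)
  m <- fitMediation(d, outcome = "y", nBoot = 100, seed = 10)
  ## maternal-paternal score covariances
  crossCov <- m$scoreCov[c("maternal_T", "maternal_NT"),
                         c("paternal_T", "paternal_NT")]
  expect_lt(max(abs(crossCov)), 3 / sqrt(nrow(d)) + 0.02)
  expect_lt(abs(m$residCorMediators), 3 / sqrt(nrow(d)) + 0.02)
})

test_that("multi-group mediation contrasts separate designed sex differences", {
  mk <- function(bM, bP, sex, famPrefix, seed) {
    p <- generativeParams(nFamilies = 1500, fractionTrios = 1,
                          sibFraction = 0, aM = 0.5, aP = 0.5,
                          bM = bM, bP = bP, seed = seed)
    d <- scoreData(p)
    d$sex <- sex
    d$family_id <- paste0(famPrefix, d$family_id)
    d
  }
  ## daughters: strong maternal mediation; sons: none for either parent
  d <- rbind(mk(0.18, 0.02, "female", "D", 58), mk(0.02, 0.02, "male", "S", 59))
  mg <- multigroupMediation(d, groupCol = "sex", outcome = "y",
                            covariates = "age", nBoot = 150, seed = 11)
  daughters <- mg$groups[["female"]]
  sons <- mg$groups[["male"]]
  wd <- daughters$contrasts[daughters$contrasts$type == "transmitted", ]
  ws <- sons$contrasts[sons$contrasts$type == "transmitted", ]
  expect_true(wd$significant)
  expect_false(ws$significant)
  ## between-sex maternal contrast detects the designed difference
  bt <- mg$betweenContrasts
  expect_true(bt$significant[bt$term == "maternal_T"])
  expect_error(multigroupMediation(d[d$sex == "female", ], groupCol = "sex",
                                   outcome = "y"), "two groups")
})

test_that("identical groups give null between-group contrasts", {
  p <- generativeParams(nFamilies = 1200, fractionTrios = 1, sibFraction = 0,
                        aM = 0.5, aP = 0.5, bM = 0.08, bP = 0.08, seed = 60)
  d <- scoreData(p)
  set.seed(61)
  d$sex <- sample(c("female", "male"), nrow(d), replace = TRUE)
  mg <- multigroupMediation(d, groupCol = "sex", outcome = "y",
                            covariates = "age", nBoot = 120, seed = 12)
  bt <- mg$betweenContrasts
  expect_true(all(bt$ci_lo <= 0 & bt$ci_hi >= 0))
})
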