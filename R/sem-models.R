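## Parent-of-origin path models and mediation through parental phenotypes:
## four parental scores with FIML over missing non-transmitted scores,
## family-clustered robust SEs, Wald equality tests, and clustered-bootstrap
## mediation (single-group and multi-group by offspring sex).

.zscoreNA <- function(x) (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)

.sexToBinary <- function(x) {
  if (is.numeric(x)) return(x)
  as.numeric(x == "male")
}

.buildZX <- function(data, outcome, scoreCols, covariates, mediators = NULL) {
  Z <- list(outcome = .zscoreNA(data[[outcome]]))
  if (!is.null(mediators))
    for (nm in names(mediators)) Z[[nm]] <- .zscoreNA(data[[mediators[nm]]])
  for (nm in names(scoreCols)) {
    x <- data[[scoreCols[nm]]]
    if (all(is.na(x))) stop("score column '", scoreCols[nm],
                            "' is entirely missing")
    Z[[nm]] <- .zscoreNA(x)
  }
  Z <- do.call(cbind, Z)
  X <- list()
  for (cv in covariates) {
    x <- data[[cv]]
    X[[cv]] <- if (cv == "sex") .sexToBinary(x) else
      if (is.numeric(x) && length(unique(x)) > 2) .zscoreNA(x) else as.numeric(x)
  }
  X <- if (!length(X)) matrix(0, nrow(Z), 0) else do.call(cbind, X)
  if (anyNA(X)) stop("covariates must be complete")
  list(Z = Z, X = X)
}

#' Parent-of-origin effects via a FIML path model
#'
#' Regresses the offspring outcome jointly on the four parental scores
#' (maternal/paternal transmitted and non-transmitted), with covariates as
#' fixed regressors and the scores modeled as multivariate normal with free
#' means and covariances (so their mutual covariances absorb any genetic
#' assortative mating). Missing scores -- the non-transmitted score of the
#' ungenotyped parent in pairs -- are handled by full-information maximum
#' likelihood over missingness patterns; no record is discarded or imputed.
#' Standard errors are cluster-robust (sandwich) on the family.
#'
#' @param data data.frame with outcome, score, covariate and family columns.
#' @param outcome outcome column name (z-scored internally; `NA` allowed,
#'   FIML uses partial records).
#' @param scoreCols named character vector mapping the canonical terms
#'   `maternal_T`, `maternal_NT`, `paternal_T`, `paternal_NT` to columns.
#' @param covariates covariate columns (sex coded male = 1; continuous
#'   covariates z-scored).
#' @param familyCol family-id column for clustering.
#' @param forceFiml run the FIML optimizer even on complete data.
#' @return A `"PoeFit"`: `coef` table (standardized estimates, robust SEs,
#'   95% CIs, p), `robustVcov` of the four score coefficients, `scoreCov`
#'   (estimated score covariance matrix), `engine`, `n`.
#' @export
fitPoe <- function(data, outcome = "y",
                   scoreCols = c(maternal_T = "pgs_t_maternal",
                                 maternal_NT = "pgs_nt_maternal",
                                 paternal_T = "pgs_t_paternal",
                                 paternal_NT = "pgs_nt_paternal"),
                   covariates = c("age", "sex"), familyCol = "family_id",
                   forceFiml = FALSE) {
  stopifnot(all(c("maternal_T", "maternal_NT", "paternal_T", "paternal_NT")
                %in% names(scoreCols)))
  zx <- .buildZX(data, outcome, scoreCols, covariates)
  keep <- rowSums(!is.na(zx$Z)) > 0
  Z <- zx$Z[keep, , drop = FALSE]
  X <- zx$X[keep, , drop = FALSE]
  fam <- data[[familyCol]][keep]
  terms <- names(scoreCols)
  L <- .pathLayout(
    vars = c("outcome", terms),
    paths = data.frame(from = terms, to = "outcome",
                       stringsAsFactors = FALSE),
    exo = terms, residGroups = list("outcome"),
    covNames = covariates,
    covEq = list(outcome = covariates))
  fit <- pathFit(Z, X, L, forceFiml = forceFiml)
  V <- .clusterRobustVcov(fit, fam)
  pn <- paste0("outcome~", terms)
  est <- setNames(fit$A[1, match(terms, L$vars)], terms)
  se <- setNames(sqrt(diag(V)[pn]), terms)
  ci <- cbind(est - qnorm(0.975) * se, est + qnorm(0.975) * se)
  out <- list(
    coef = data.frame(term = terms, estimate = unname(est), se = unname(se),
                      ci_lo = ci[, 1], ci_hi = ci[, 2],
                      p = 2 * pnorm(-abs(unname(est / se))),
                      row.names = NULL),
    robustVcov = {
      Vp <- V[pn, pn]
      dimnames(Vp) <- list(terms, terms)
      Vp
    },
    scoreCov = {
      sc <- fit$Sigma[match(terms, L$vars), match(terms, L$vars)]
      dimnames(sc) <- list(terms, terms)
      sc
    },
    engine = fit$engine, converged = fit$converged,
    n = nrow(Z), nFamilies = length(unique(fam)),
    loglik = fit$loglik, fit = fit)
  class(out) <- "PoeFit"
  out
}

#' @method print PoeFit
#' @export
print.PoeFit <- function(x, ...) {
  cat(sprintf("PoeFit (%s), n = %d in %d families\n",
              x$engine, x$n, x$nFamilies))
  print(x$coef, digits = 3)
  invisible(x)
}

#' Wald test of coefficient equality
#'
#' Tests whether two (standardized) coefficients are equal using the
#' cluster-robust covariance: `delta_chi2 = (b1 - b2)^2 / Var(b1 - b2)`,
#' chi-square with 1 df per constraint.
#'
#' @param fit a `"PoeFit"`.
#' @param terms length-2 character vector of coefficient names to equate
#'   (e.g. `c("maternal_T", "paternal_T")`).
#' @return list: `delta_chi2`, `df`, `p`, `delta` (the difference) and
#'   `se_delta`.
#' @export
waldEquality <- function(fit, terms = c("maternal_T", "paternal_T")) {
  stopifnot(inherits(fit, "PoeFit"), length(terms) == 2)
  est <- setNames(fit$coef$estimate, fit$coef$term)
  if (!all(terms %in% names(est))) stop("unknown coefficient term(s)")
  V <- fit$robustVcov[terms, terms]
  d <- est[terms[1]] - est[terms[2]]
  vd <- V[1, 1] + V[2, 2] - 2 * V[1, 2]
  if (vd <= 0) stop("singular contrast covariance")
  chi2 <- unname(d^2 / vd)
  list(delta_chi2 = chi2, df = 1L,
       p = pchisq(chi2, 1L, lower.tail = FALSE),
       delta = unname(d), se_delta = sqrt(vd))
}

## ---- mediation ------------------------------------------------------------

.mediationLayout <- function(covariates) {
  terms <- c("maternal_T", "maternal_NT", "paternal_T", "paternal_NT")
  paths <- rbind(
    data.frame(from = c("maternal_T", "maternal_NT"), to = "Mm"),
    data.frame(from = c("paternal_T", "paternal_NT"), to = "Mp"),
    data.frame(from = c(terms, "Mm", "Mp"), to = "outcome"))
  .pathLayout(
    vars = c("outcome", "Mm", "Mp", terms),
    paths = paths, exo = terms,
    residGroups = list(c("Mm", "Mp"), "outcome"),
    covNames = covariates,
    covEq = list(Mm = character(), Mp = character(), outcome = covariates))
}

## effects table from a fitted mediation path model; total effects come from
## the path-tracing matrix (I - A)^-1, so total = direct + indirect exactly.
.mediationEffects <- function(fit) {
  L <- fit$layout
  terms <- c(maternal_T = "Mm", maternal_NT = "Mm",
             paternal_T = "Mp", paternal_NT = "Mp")
  out <- NULL
  for (t in names(terms)) {
    med <- terms[[t]]
    a <- pathCoef(fit, med, t)
    b <- pathCoef(fit, "outcome", med)
    cp <- pathCoef(fit, "outcome", t)
    tot <- fit$totalEffects[match("outcome", L$vars), match(t, L$vars)]
    out <- rbind(out, data.frame(
      term = t, parent = if (med == "Mm") "maternal" else "paternal",
      type = if (grepl("_T$", t)) "transmitted" else "non_transmitted",
      a = a, b = b, cprime = cp, indirect = a * b, total = tot))
  }
  rownames(out) <- NULL
  out
}

.resampleFamilies <- function(fam) {
  ids <- unique(fam)
  pick <- sample(ids, length(ids), replace = TRUE)
  rowsBy <- split(seq_along(fam), fam)
  unlist(rowsBy[as.character(pick)], use.names = FALSE)
}

#' Mediation of polygenic-score effects through parental phenotypes
#'
#' One joint path model: each parental phenotype is regressed on that
#' parent's transmitted and non-transmitted scores (paths `a`); the
#' offspring outcome is regressed on all four scores (direct paths
#' `c'`) plus both parental phenotypes (paths `b`) plus covariates; the
#' scores carry free covariances and the two parental-phenotype residuals a
#' free covariance (phenotypic assortative mating). Indirect effects are
#' `a x b` per parent and score type; total effects come from path tracing,
#' so `total = c' + indirect` holds within every replicate. Inference is by
#' clustered bootstrap: families are resampled with replacement and the
#' whole model refit; 95% percentile intervals are reported.
#'
#' @inheritParams fitPoe
#' @param mediators named character vector `c(Mm = ..., Mp = ...)` of the
#'   maternal and paternal phenotype columns.
#' @param nBoot bootstrap replications (default 1000; < 100 warns).
#' @param seed integer seed for the bootstrap.
#' @return A `"MediationResult"`: `effects` (a, b, c', indirect, total with
#'   bootstrap CIs and significance flags), `contrasts`
#'   (maternal - paternal indirect per score type, with CIs), `residCorMediators`
#'   (the assortative-mating residual correlation), bootstrap draws, and
#'   bookkeeping.
#' @export
fitMediation <- function(data, outcome = "y",
                         scoreCols = c(maternal_T = "pgs_t_maternal",
                                       maternal_NT = "pgs_nt_maternal",
                                       paternal_T = "pgs_t_paternal",
                                       paternal_NT = "pgs_nt_paternal"),
                         mediators = c(Mm = "maternal_pheno",
                                       Mp = "paternal_pheno"),
                         covariates = c("age", "sex"),
                         familyCol = "family_id",
                         nBoot = 1000L, seed = 1L) {
  if (nBoot < 100) warning("nBoot < 100: bootstrap CIs will be unstable")
  zx <- .buildZX(data, outcome, scoreCols, covariates, mediators = mediators)
  keep <- rowSums(!is.na(zx$Z)) > 0
  Z <- zx$Z[keep, , drop = FALSE]
  X <- zx$X[keep, , drop = FALSE]
  fam <- as.character(data[[familyCol]][keep])
  L <- .mediationLayout(covariates)
  point <- pathFit(Z, X, L)
  eff <- .mediationEffects(point)

  set.seed(seed)
  statNames <- c(paste0("ind_", eff$term), paste0("tot_", eff$term),
                 paste0("dir_", eff$term), "contrast_T", "contrast_NT")
  draws <- matrix(NA_real_, nBoot, length(statNames),
                  dimnames = list(NULL, statNames))
  nDiscarded <- 0L
  for (b in seq_len(nBoot)) {
    rows <- .resampleFamilies(fam)
    if (length(unique(fam[rows])) < 2L) {
      nDiscarded <- nDiscarded + 1L
      next
    }
    fb <- tryCatch(
      pathFit(Z[rows, , drop = FALSE], X[rows, , drop = FALSE], L,
              warmTheta = as.numeric(point$theta)),
      error = function(e) NULL)
    if (is.null(fb)) {
      nDiscarded <- nDiscarded + 1L
      next
    }
    eb <- .mediationEffects(fb)
    draws[b, ] <- c(eb$indirect, eb$total, eb$cprime,
                    eb$indirect[1] - eb$indirect[3],
                    eb$indirect[2] - eb$indirect[4])
  }
  ok <- stats::complete.cases(draws)
  ci <- t(apply(draws[ok, , drop = FALSE], 2, quantile,
                probs = c(0.025, 0.975)))
  eff$ci_lo <- ci[paste0("ind_", eff$term), 1]
  eff$ci_hi <- ci[paste0("ind_", eff$term), 2]
  eff$significant <- eff$ci_lo > 0 | eff$ci_hi < 0
  eff$total_ci_lo <- ci[paste0("tot_", eff$term), 1]
  eff$total_ci_hi <- ci[paste0("tot_", eff$term), 2]
  contr <- data.frame(
    type = c("transmitted", "non_transmitted"),
    delta_indirect = c(eff$indirect[1] - eff$indirect[3],
                       eff$indirect[2] - eff$indirect[4]),
    ci_lo = ci[c("contrast_T", "contrast_NT"), 1],
    ci_hi = ci[c("contrast_T", "contrast_NT"), 2])
  contr$significant <- contr$ci_lo > 0 | contr$ci_hi < 0
  residCov <- point$S[match("Mm", L$vars), match("Mp", L$vars)]
  residCor <- residCov / sqrt(point$S[match("Mm", L$vars), match("Mm", L$vars)] *
                              point$S[match("Mp", L$vars), match("Mp", L$vars)])
  out <- list(effects = eff, contrasts = contr,
              residCorMediators = residCor,
              scoreCov = {
                terms <- names(scoreCols)
                sc <- point$Sigma[match(terms, L$vars), match(terms, L$vars)]
                dimnames(sc) <- list(terms, terms)
                sc
              },
              draws = draws[ok, , drop = FALSE],
              nBoot = nBoot, nUsed = sum(ok), nDiscarded = nDiscarded,
              seed = seed, engine = point$engine, n = nrow(Z),
              nFamilies = length(unique(fam)), fit = point)
  class(out) <- "MediationResult"
  out
}

#' @method print MediationResult
#' @export
print.MediationResult <- function(x, ...) {
  cat(sprintf("MediationResult (%s), n = %d in %d families, %d bootstrap draws\n",
              x$engine, x$n, x$nFamilies, x$nUsed))
  print(x$effects[, c("term", "indirect", "ci_lo", "ci_hi", "significant",
                      "total")], digits = 3)
  cat("Maternal - paternal indirect contrasts:\n")
  print(x$contrasts, digits = 3)
  invisible(x)
}

#' Multi-group mediation by offspring sex
#'
#' Fits the mediation path model separately in each group (all paths free
#' across groups), with the clustered bootstrap resampling families within
#' group. Reports per-group effects, within-group maternal-vs-paternal
#' contrasts, and between-group contrasts of the same parent's indirect
#' effect (bootstrap draws paired across groups).
#'
#' @inheritParams fitMediation
#' @param groupCol grouping column (e.g. `"sex"`); both groups must be
#'   nonempty, groups under 50 families trigger a power warning.
#' @return A `"MultigroupMediation"` list: `groups` (named
#'   `"MediationResult"`s) and `betweenContrasts` (per term, difference of
#'   group-1 minus group-2 indirect effects with bootstrap CIs).
#' @export
multigroupMediation <- function(data, groupCol = "sex", outcome = "y",
                                scoreCols = c(maternal_T = "pgs_t_maternal",
                                              maternal_NT = "pgs_nt_maternal",
                                              paternal_T = "pgs_t_paternal",
                                              paternal_NT = "pgs_nt_paternal"),
                                mediators = c(Mm = "maternal_pheno",
                                              Mp = "paternal_pheno"),
                                covariates = c("age"),
                                familyCol = "family_id",
                                nBoot = 1000L, seed = 1L) {
  g <- data[[groupCol]]
  lev <- unique(g[!is.na(g)])
  if (length(lev) != 2) stop("grouping variable must have exactly two groups")
  fits <- list()
  for (k in 1:2) {
    dk <- data[g == lev[k] & !is.na(g), , drop = FALSE]
    nf <- length(unique(dk[[familyCol]]))
    if (nf == 0) stop("empty group: ", lev[k])
    if (nf < 50) warning("group '", lev[k], "' has ", nf,
                         " families; contrasts will be underpowered")
    fits[[as.character(lev[k])]] <-
      fitMediation(dk, outcome = outcome, scoreCols = scoreCols,
                   mediators = mediators, covariates = covariates,
                   familyCol = familyCol, nBoot = nBoot, seed = seed + k)
  }
  terms <- fits[[1]]$effects$term
  nPair <- min(fits[[1]]$nUsed, fits[[2]]$nUsed)
  between <- NULL
  for (t in terms) {
    d <- fits[[1]]$draws[seq_len(nPair), paste0("ind_", t)] -
         fits[[2]]$draws[seq_len(nPair), paste0("ind_", t)]
    q <- quantile(d, c(0.025, 0.975))
    between <- rbind(between, data.frame(
      term = t,
      delta = fits[[1]]$effects$indirect[fits[[1]]$effects$term == t] -
              fits[[2]]$effects$indirect[fits[[2]]$effects$term == t],
      ci_lo = q[1], ci_hi = q[2],
      significant = q[1] > 0 | q[2] < 0, row.names = NULL))
  }
  structure(list(groups = fits, groupLevels = as.character(lev),
                 betweenContrasts = between),
            class = "MultigroupMediation")
}

#' @method print MultigroupMediation
#' @export
print.MultigroupMediation <- function(x, ...) {
  cat("MultigroupMediation over groups:",
      paste(x$groupLevels, collapse = " vs "), "\n")
  cat("Between-group indirect-effect contrasts:\n")
  print(x$betweenContrasts, digits = 3)
  invisible(x)
}
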