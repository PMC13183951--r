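## Linear path-model engine with full-information maximum likelihood.
##
## Models are recursive linear path diagrams over observed variables:
## exogenous variables carry a free mean vector and a free (full) covariance
## block; each endogenous variable is a linear function of its path parents,
## optional fixed covariates (conditioned on, not modeled as normal), an
## intercept, and a residual; residuals are grouped into blocks with free
## within-block covariance. The implied joint distribution of the model
## variables given covariates is multivariate normal; the log-likelihood is
## accumulated pattern-wise over missing-data patterns (FIML). Complete data
## admit a closed-form ML fit (equation-wise OLS plus ML moment estimates)
## which also serves as the starting value -- and as an independent oracle --
## for the numerical FIML optimization. Cluster-robust (sandwich) covariances
## are computed from per-cluster score contributions.

## ---- model layout ---------------------------------------------------------

## vars: ordered variable names; paths: data.frame(from, to); exo: names of
## exogenous variables; residGroups: list of character vectors partitioning
## the endogenous variables; covEq: named list endo var -> covariate names.
.pathLayout <- function(vars, paths, exo, residGroups, covNames = character(),
                        covEq = list()) {
  endo <- setdiff(vars, exo)
  stopifnot(all(paths$from %in% vars), all(paths$to %in% endo),
            all(unlist(residGroups) %in% endo),
            setequal(unlist(residGroups), endo))
  nv <- length(vars)
  idx <- function(x) match(x, vars)
  pathIdx <- cbind(to = idx(paths$to), from = idx(paths$from))
  gEntries <- NULL
  for (v in endo) for (cv in covEq[[v]])
    gEntries <- rbind(gEntries, c(idx(v), match(cv, covNames)))
  nPath <- nrow(paths)
  nG <- if (is.null(gEntries)) 0L else nrow(gEntries)
  cholLen <- function(k) k * (k + 1L) / 2L
  blocks <- c(list(idx(exo)), lapply(residGroups, idx))
  nChol <- sum(vapply(blocks, function(b) cholLen(length(b)), numeric(1)))
  nTheta <- nPath + nG + nv + nChol
  names <- c(paste0(paths$to, "~", paths$from),
             if (nG) paste0(vars[gEntries[, 1]], "~", covNames[gEntries[, 2]]),
             paste0("mean_", vars),
             paste0("chol", seq_len(nChol)))
  list(vars = vars, nv = nv, exo = exo, endo = endo, covNames = covNames,
       pathIdx = pathIdx, pathNames = paste0(paths$to, "~", paths$from),
       gEntries = gEntries, blocks = blocks,
       iPath = seq_len(nPath), iG = nPath + seq_len(nG),
       iMean = nPath + nG + seq_len(nv),
       iChol = nPath + nG + nv + seq_len(nChol),
       nTheta = nTheta, thetaNames = names, covEq = covEq,
       residGroups = residGroups, paths = paths)
}

.cholToSigma <- function(th, k) {
  L <- matrix(0, k, k)
  L[lower.tri(L, diag = TRUE)] <- th
  diag(L) <- exp(diag(L))
  L %*% t(L)
}

.sigmaToChol <- function(S) {
  k <- nrow(S)
  L <- tryCatch(t(chol(S)), error = function(e)
    t(chol(S + diag(1e-8 + 1e-6 * mean(diag(S)), k))))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

.thetaToMats <- function(theta, L) {
  nv <- L$nv
  A <- matrix(0, nv, nv)
  if (length(L$iPath)) A[L$pathIdx] <- theta[L$iPath]
  G <- matrix(0, nv, length(L$covNames))
  if (length(L$iG)) G[L$gEntries] <- theta[L$iG]
  m <- theta[L$iMean]
  S <- matrix(0, nv, nv)
  pos <- 0L
  for (b in L$blocks) {
    k <- length(b)
    len <- k * (k + 1L) / 2L
    S[b, b] <- .cholToSigma(theta[L$iChol][pos + seq_len(len)], k)
    pos <- pos + len
  }
  list(A = A, G = G, m = m, S = S)
}

.matsToTheta <- function(mats, L) {
  theta <- numeric(L$nTheta)
  if (length(L$iPath)) theta[L$iPath] <- mats$A[L$pathIdx]
  if (length(L$iG)) theta[L$iG] <- mats$G[L$gEntries]
  theta[L$iMean] <- mats$m
  ch <- numeric(0)
  for (b in L$blocks) ch <- c(ch, .sigmaToChol(mats$S[b, b, drop = FALSE]))
  theta[L$iChol] <- ch
  theta
}

## ---- likelihood -----------------------------------------------------------

## Z: n x nv data matrix (model variables, NA allowed); X: n x ncov complete
## covariate matrix. Returns per-row log-likelihood.
.pathLoglikRows <- function(theta, L, Z, X, patterns) {
  mats <- .thetaToMats(theta, L)
  Binv <- solve(diag(L$nv) - mats$A)
  Sigma <- Binv %*% mats$S %*% t(Binv)
  lin <- matrix(mats$m, nrow(Z), L$nv, byrow = TRUE)
  if (length(L$covNames)) lin <- lin + X %*% t(mats$G)
  Mu <- lin %*% t(Binv)
  ll <- rep(NA_real_, nrow(Z))
  for (p in patterns) {
    o <- p$obs
    r <- p$rows
    So <- Sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(rep(-1e10, nrow(Z)))
    R <- Z[r, o, drop = FALSE] - Mu[r, o, drop = FALSE]
    V <- backsolve(ch, t(R), transpose = TRUE)     # solves t(ch) %*% V = t(R)
    quad <- colSums(V^2)
    ll[r] <- -0.5 * (length(o) * log(2 * pi) + 2 * sum(log(diag(ch))) + quad)
  }
  ll
}

.missingPatterns <- function(Z) {
  obs <- !is.na(Z)
  key <- apply(obs, 1L, function(x) paste(as.integer(x), collapse = ""))
  lapply(split(seq_len(nrow(Z)), key), function(r) {
    o <- which(obs[r[1], ])
    if (!length(o)) stop("row with all model variables missing")
    list(rows = r, obs = o)
  })
}

## ---- closed-form complete-data ML -----------------------------------------

.closedFormFit <- function(Z, X, L) {
  cc <- stats::complete.cases(Z)
  if (!any(cc)) stop("no complete cases available for starting values")
  Zc <- Z[cc, , drop = FALSE]
  Xc <- if (length(L$covNames)) X[cc, , drop = FALSE] else NULL
  nv <- L$nv
  n <- nrow(Zc)
  A <- matrix(0, nv, nv)
  G <- matrix(0, nv, length(L$covNames))
  m <- numeric(nv)
  S <- matrix(0, nv, nv)
  resids <- matrix(0, n, nv)
  exoIdx <- match(L$exo, L$vars)
  m[exoIdx] <- colMeans(Zc[, exoIdx, drop = FALSE])
  Sc <- crossprod(sweep(Zc[, exoIdx, drop = FALSE], 2, m[exoIdx])) / n
  S[exoIdx, exoIdx] <- Sc
  for (v in L$endo) {
    vi <- match(v, L$vars)
    parents <- L$paths$from[L$paths$to == v]
    pi <- match(parents, L$vars)
    covs <- L$covEq[[v]]
    D <- cbind(`(Intercept)` = 1,
               Zc[, pi, drop = FALSE],
               if (length(covs)) Xc[, match(covs, L$covNames), drop = FALSE])
    fit <- lm.fit(D, Zc[, vi])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    m[vi] <- cf[1]
    if (length(pi)) A[vi, pi] <- cf[1 + seq_along(pi)]
    if (length(covs))
      G[vi, match(covs, L$covNames)] <- cf[1 + length(pi) + seq_along(covs)]
    resids[, vi] <- fit$residuals
  }
  for (g in L$residGroups) {
    gi <- match(g, L$vars)
    S[gi, gi] <- crossprod(resids[, gi, drop = FALSE]) / n
  }
  list(A = A, G = G, m = m, S = S)
}

## ---- main fitter ----------------------------------------------------------

#' Fit a linear path model by maximum likelihood
#'
#' Internal engine behind [fitPoe()] and [fitMediation()]. Complete data
#' are fit in closed form (equation-wise OLS plus ML moments); data with
#' missing entries are fit by numerical maximization of the pattern-wise
#' multivariate-normal (FIML) log-likelihood, started at the complete-case
#' solution (or a supplied warm start).
#'
#' @param Z numeric matrix of model variables (columns named as in `vars`;
#'   `NA` allowed).
#' @param X numeric matrix of fixed covariates (complete).
#' @param layout model layout from `.pathLayout`.
#' @param warmTheta optional starting parameter vector.
#' @param forceFiml run the numerical FIML optimizer even when data are
#'   complete (used to verify it reproduces the closed form).
#' @return list with `theta`, implied matrices, `loglik`, `engine`,
#'   `converged`, and closures for downstream robust covariance.
#' @keywords internal
pathFit <- function(Z, X, layout, warmTheta = NULL, forceFiml = FALSE) {
  patterns <- .missingPatterns(Z)
  negll <- function(th) {
    v <- -sum(.pathLoglikRows(th, layout, Z, X, patterns))
    if (!is.finite(v)) 1e10 else v
  }
  complete <- !anyNA(Z)
  if (complete && !forceFiml) {
    theta <- .matsToTheta(.closedFormFit(Z, X, layout), layout)
    engine <- "closed-form ML"
    converged <- TRUE
  } else {
    theta0 <- if (is.null(warmTheta))
      .matsToTheta(.closedFormFit(Z, X, layout), layout) else warmTheta
    opt <- optim(theta0, negll, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-12))
    theta <- opt$par
    engine <- "FIML"
    converged <- opt$convergence == 0
    if (!converged)
      warning("FIML optimizer did not fully converge (code ",
              opt$convergence, "); gradient check advised")
  }
  mats <- .thetaToMats(theta, layout)
  Binv <- solve(diag(layout$nv) - mats$A)
  structure(list(
    theta = setNames(theta, layout$thetaNames),
    A = mats$A, S = mats$S, m = mats$m, G = mats$G,
    Sigma = Binv %*% mats$S %*% t(Binv),
    totalEffects = Binv,
    loglik = sum(.pathLoglikRows(theta, layout, Z, X, patterns)),
    engine = engine, converged = converged,
    layout = layout, Z = Z, X = X, patterns = patterns,
    negll = negll), class = "pathFit")
}

#' Path coefficient lookup
#' @param fit a `pathFit`.
#' @param to,from variable names of the directed path.
#' @return the estimated path coefficient.
#' @keywords internal
pathCoef <- function(fit, to, from) {
  L <- fit$layout
  fit$A[match(to, L$vars), match(from, L$vars)]
}

## ---- cluster-robust (sandwich) covariance ---------------------------------

## Per-row likelihood scores by central finite differences, summed within
## clusters; bread from the numerical Hessian of the total negative
## log-likelihood. Returns the robust covariance of the full theta vector.
.clusterRobustVcov <- function(fit, cluster) {
  L <- fit$layout
  theta <- as.numeric(fit$theta)
  p <- length(theta)
  n <- nrow(fit$Z)
  scores <- matrix(0, n, p)
  for (j in seq_len(p)) {
    h <- 1e-6 * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    scores[, j] <- (.pathLoglikRows(tp, L, fit$Z, fit$X, fit$patterns) -
                    .pathLoglikRows(tm, L, fit$Z, fit$X, fit$patterns)) / (2 * h)
  }
  cl <- rowsum(scores, group = cluster)
  meat <- crossprod(cl)
  H <- stats::optimHess(theta, fit$negll)
  bread <- tryCatch(solve(H), error = function(e)
    solve(H + diag(1e-8, p)))
  V <- bread %*% meat %*% bread
  dimnames(V) <- list(L$thetaNames, L$thetaNames)
  if (max(abs(V - t(V))) > 1e-6 * max(abs(V), 1))
    warning("robust covariance noticeably asymmetric; symmetrizing")
  (V + t(V)) / 2
}
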