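## Genetic nurture vs direct transmission: joint PGS_T / PGS_NT mixed models
## with a family random intercept, the beta_DGT subtraction, nurture ratios,
## BH-FDR over the outcome family, the longitudinal PGS-by-age model, and
## pair-vs-trio descriptive contrasts.

.zscore <- function(x) (x - mean(x)) / sd(x)

#' Joint transmitted / non-transmitted mixed model
#'
#' Fits `outcome ~ PGS_T + PGS_NT + covariates + (1 | family)` with both
#' polygenic scores entered jointly. Continuous outcomes use a linear mixed
#' model (REML); binary outcomes a mixed logistic model estimated by
#' adaptive Gauss-Hermite quadrature with a Laplace fallback. The outcome
#' (if continuous) and all continuous predictors are z-scored before
#' fitting so coefficients are standardized; binary outcomes report odds
#' ratios. Wald tests use a normal reference.
#'
#' @param data data.frame holding all columns.
#' @param outcome name of the outcome column (rows with `NA` dropped).
#' @param pgsT,pgsNT names of the score columns (standardized or raw; they
#'   are z-scored internally).
#' @param covariates covariate column names; numeric non-binary columns are
#'   z-scored, binary/factor columns enter untouched.
#' @param family `"gaussian"` or `"binomial"`.
#' @param familyCol name of the family-id column (random intercept).
#' @param nAGQ quadrature nodes for the binomial fit (1 = Laplace).
#' @return A `"JointFit"` list: `beta_t`, `se_t`, `p_t`, `beta_nt`,
#'   `se_nt`, `p_nt`, odds ratios for binomial fits, `beta_dgt` (gaussian
#'   only), `sigma_family`, sample sizes and the underlying `merMod`.
#' @export
fitJointTN <- function(data, outcome, pgsT = "pgs_t_std",
                       pgsNT = "pgs_nt_std", covariates = c("age", "sex"),
                       family = c("gaussian", "binomial"),
                       familyCol = "family_id", nAGQ = 7L) {
  family <- match.arg(family)
  cols <- c(outcome, pgsT, pgsNT, covariates, familyCol)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, cols]), cols]
  if (length(unique(d[[familyCol]])) < 2) stop("need at least 2 families")
  zT <- .zscore(d[[pgsT]])
  zNT <- .zscore(d[[pgsNT]])
  if (abs(cor(zT, zNT)) > 0.999)
    stop("PGS_T and PGS_NT are collinear; the joint model is not identified")
  md <- data.frame(.y = d[[outcome]], .zt = zT, .znt = zNT,
                   .fam = factor(d[[familyCol]]))
  for (cv in covariates) {
    x <- d[[cv]]
    if (is.numeric(x) && length(unique(x)) > 2) x <- .zscore(x)
    md[[cv]] <- x
  }
  if (family == "gaussian") md$.y <- .zscore(md$.y)
  rhs <- paste(c(".zt", ".znt", covariates, "(1 | .fam)"), collapse = " + ")
  fml <- as.formula(paste(".y ~", rhs))
  if (family == "gaussian") {
    fit <- lme4::lmer(fml, data = md, REML = TRUE)
  } else {
    if (!all(md$.y %in% c(0, 1))) stop("binomial outcome must be 0/1")
    fit <- tryCatch(
      lme4::glmer(fml, data = md, family = binomial(), nAGQ = nAGQ),
      error = function(e) lme4::glmer(fml, data = md, family = binomial(),
                                      nAGQ = 1L))
  }
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- fe / se
  p <- 2 * pnorm(-abs(z))
  vc <- lme4::VarCorr(fit)
  out <- list(
    outcome = outcome, family = family,
    beta_t = unname(fe[".zt"]), se_t = unname(se[".zt"]),
    p_t = unname(p[".zt"]),
    beta_nt = unname(fe[".znt"]), se_nt = unname(se[".znt"]),
    p_nt = unname(p[".znt"]),
    sigma_family = sqrt(vc$.fam[1, 1]),
    n = nrow(md), nFamilies = length(unique(md$.fam)),
    model = fit)
  if (family == "gaussian") {
    out$beta_dgt <- out$beta_t - out$beta_nt
  } else {
    out$or_t <- exp(out$beta_t)
    out$or_nt <- exp(out$beta_nt)
  }
  class(out) <- "JointFit"
  out
}

#' @method print JointFit
#' @export
print.JointFit <- function(x, ...) {
  cat(sprintf("JointFit (%s) on '%s', n = %d in %d families\n",
              x$family, x$outcome, x$n, x$nFamilies))
  if (x$family == "gaussian") {
    cat(sprintf("  beta_T  = %.3f (SE %.3f, p = %.3g)\n", x$beta_t, x$se_t, x$p_t))
    cat(sprintf("  beta_NT = %.3f (SE %.3f, p = %.3g)\n", x$beta_nt, x$se_nt, x$p_nt))
    cat(sprintf("  beta_DGT = %.3f\n", x$beta_dgt))
  } else {
    cat(sprintf("  OR_T  = %.3f (p = %.3g), OR_NT = %.3f (p = %.3g)\n",
                x$or_t, x$p_t, x$or_nt, x$p_nt))
  }
  invisible(x)
}

#' Direct genetic transmission effect
#'
#' `beta_DGT = beta_T - beta_NT`: the transmitted-score effect purged of the
#' genetic-nurture component. Defined for continuous outcomes only; for
#' binomial fits it is withheld.
#'
#' @param fit a `"JointFit"`.
#' @return numeric `beta_DGT`.
#' @export
dgt <- function(fit) {
  stopifnot(inherits(fit, "JointFit"))
  if (fit$family != "gaussian")
    stop("direct genetic transmission is reported for continuous outcomes only")
  fit$beta_t - fit$beta_nt
}

#' Genetic-nurture to direct-transmission ratio
#'
#' `beta_NT / beta_DGT`, reported as a percentage.
#'
#' @param fit a `"JointFit"` (gaussian).
#' @return percentage (numeric).
#' @export
nurtureRatio <- function(fit) {
  d <- dgt(fit)
  if (abs(d) < 1e-10)
    stop("beta_DGT is ~0; the nurture ratio is undefined")
  100 * fit$beta_nt / d
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate correction with enforced monotonicity;
#' input order is preserved. Thin wrapper over [stats::p.adjust()], kept as
#' the package's named operation for the five-outcome test family.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param nTests number of tests in the family (default `length(p)`).
#' @return adjusted p-values, same order as input.
#' @export
fdrAdjust <- function(p, nTests = length(p)) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH", n = nTests)
}

#' Apply FDR across a list of joint fits
#'
#' Adjusts the non-transmitted p-values as one family across outcomes, and
#' the transmitted p-values as a separate family of the same size.
#'
#' @param fits list of `"JointFit"` objects (one per outcome).
#' @return the list, each fit gaining `p_fdr_t` and `p_fdr_nt`.
#' @export
applyFdr <- function(fits) {
  pNT <- fdrAdjust(vapply(fits, `[[`, numeric(1), "p_nt"))
  pT <- fdrAdjust(vapply(fits, `[[`, numeric(1), "p_t"))
  for (i in seq_along(fits)) {
    fits[[i]]$p_fdr_nt <- pNT[i]
    fits[[i]]$p_fdr_t <- pT[i]
  }
  fits
}

#' Longitudinal PGS-by-age mixed model
#'
#' Repeated-measures model for current smoking quantity across waves:
#' fixed effects for PGS_T, PGS_NT, age (centered at the baseline mean),
#' their interactions `PGS_T x age` and `PGS_NT x age`, sex, birth year and
#' wave; random intercepts for person and family plus a person-level random
#' age slope orthogonal to (uncorrelated with) the intercept. Both
#' interactions are estimated within the single model, so no multiplicity
#' correction is applied to them. The outcome and scores are z-scored; age
#' stays in years so interaction coefficients are per year of age.
#'
#' @param data long-format data.frame (one row per person x wave).
#' @param outcome outcome column name.
#' @param pgsT,pgsNT score column names.
#' @param ageCol centered-age column (years since baseline mean age).
#' @param covariates additional covariate columns (z-scored if continuous).
#' @param personCol,familyCol grouping columns.
#' @return A `"LongitudinalFit"` list with the fixed-effect table
#'   (including `interaction_T_age`, `interaction_NT_age`), variance
#'   components, and sizes.
#' @export
fitLongitudinal <- function(data, outcome = "y", pgsT = "gen_score_t",
                            pgsNT = "gen_score_nt", ageCol = "age_c",
                            covariates = c("sex", "birth_year", "wave"),
                            personCol = "individual_id",
                            familyCol = "family_id") {
  cols <- c(outcome, pgsT, pgsNT, ageCol, covariates, personCol, familyCol)
  d <- data[stats::complete.cases(data[, cols]), cols]
  nWaves <- tapply(d[[ageCol]], d[[personCol]], function(a) length(unique(a)))
  if (max(nWaves) < 2)
    stop("a single wave per person: the PGS x age interaction is inestimable")
  if (var(d[[ageCol]]) == 0)
    stop("no variance in age: design is singular")
  md <- data.frame(.y = .zscore(d[[outcome]]),
                   .zt = .zscore(d[[pgsT]]), .znt = .zscore(d[[pgsNT]]),
                   .age = d[[ageCol]],
                   .per = factor(d[[personCol]]),
                   .fam = factor(d[[familyCol]]))
  for (cv in covariates) {
    x <- d[[cv]]
    if (cv == "wave") x <- factor(x)
    else if (is.numeric(x) && length(unique(x)) > 2) x <- .zscore(x)
    md[[cv]] <- x
  }
  rhs <- paste(c(".zt", ".znt", ".age", ".zt:.age", ".znt:.age", covariates,
                 "(1 | .fam)", "(1 | .per)", "(0 + .age | .per)"),
               collapse = " + ")
  fit <- lme4::lmer(as.formula(paste(".y ~", rhs)), data = md, REML = TRUE)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  p <- 2 * pnorm(-abs(fe / se))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvc <- function(grp) {
    v <- vc$vcov[vc$grp == grp & is.na(vc$var2)]
    if (length(v)) sum(v) else 0
  }
  coefTab <- data.frame(term = names(fe), estimate = unname(fe),
                        se = unname(se), p = unname(p))
  out <- list(
    coef = coefTab,
    beta_t = unname(fe[".zt"]), beta_nt = unname(fe[".znt"]),
    interaction_T_age = unname(fe[".zt:.age"]),
    se_interaction_T_age = unname(se[".zt:.age"]),
    p_interaction_T_age = unname(p[".zt:.age"]),
    interaction_NT_age = unname(fe[".znt:.age"]),
    se_interaction_NT_age = unname(se[".znt:.age"]),
    p_interaction_NT_age = unname(p[".znt:.age"]),
    var_person = getvc(".per"),
    var_family = getvc(".fam"),
    var_person_slope = sum(vc$vcov[vc$grp == ".per.1" & is.na(vc$var2)]),
    nObs = nrow(md), nPersons = length(unique(md$.per)),
    nFamilies = length(unique(md$.fam)),
    model = fit)
  class(out) <- "LongitudinalFit"
  out
}

#' @method print LongitudinalFit
#' @export
print.LongitudinalFit <- function(x, ...) {
  cat(sprintf("LongitudinalFit: %d obs, %d persons, %d families\n",
              x$nObs, x$nPersons, x$nFamilies))
  cat(sprintf("  PGS_T x age  = %.4f (SE %.4f, p = %.3g)\n",
              x$interaction_T_age, x$se_interaction_T_age,
              x$p_interaction_T_age))
  cat(sprintf("  PGS_NT x age = %.4f (SE %.4f, p = %.3g)\n",
              x$interaction_NT_age, x$se_interaction_NT_age,
              x$p_interaction_NT_age))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Pair-vs-trio descriptive contrasts
## ---------------------------------------------------------------------------

#' Welch contrast of a continuous characteristic from group summaries
#'
#' Welch (unequal-variance) two-sample t-test and absolute standardized
#' mean difference `|m1 - m2| / pooledSD`, computed from summary statistics
#' only.
#'
#' @param m1,s1,n1 mean, SD, size of group 1.
#' @param m2,s2,n2 mean, SD, size of group 2.
#' @return list: `t`, `df`, `p`, `smd`.
#' @export
contrastFromSummary <- function(m1, s1, n1, m2, s2, n2) {
  if (min(n1, n2) < 2) stop("empty or degenerate subgroup")
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  pooled <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df), smd = abs(m1 - m2) / pooled)
}

#' Chi-square contrast of a binary characteristic from counts
#'
#' Pearson chi-square (no continuity correction) for a 2x2 table built from
#' event counts, and SMD `|p1 - p2| / sqrt(pbar (1 - pbar))`.
#'
#' @param x1,n1 events and size of group 1.
#' @param x2,n2 events and size of group 2.
#' @return list: `chisq`, `df`, `p`, `smd`.
#' @export
contrastFromCounts <- function(x1, n1, x2, n2) {
  if (min(n1, n2) < 1) stop("empty subgroup")
  a <- x1; b <- n1 - x1; c <- x2; d <- n2 - x2
  n <- n1 + n2
  chisq <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  p1 <- x1 / n1; p2 <- x2 / n2
  pbar <- (x1 + x2) / n
  list(chisq = chisq, df = 1,
       p = pchisq(chisq, 1, lower.tail = FALSE),
       smd = abs(p1 - p2) / sqrt(pbar * (1 - pbar)))
}

#' Pair-vs-trio contrasts of cohort characteristics
#'
#' Compares offspring from complete trios against offspring with a single
#' genotyped parent on each characteristic: Welch t-test for continuous
#' columns, Pearson chi-square for binary ones, each with the absolute
#' standardized mean difference. All statistics are derived from group
#' summary statistics.
#'
#' @param phenotypes phenotype data.frame (wave-1 rows are used if a `wave`
#'   column is present).
#' @param pedigree pedigree data.frame defining the trio/pair split.
#' @param characteristics columns to compare.
#' @return A `"ContrastReport"` data.frame: per characteristic the group
#'   summaries, test statistic, `p`, and `smd`.
#' @export
subsampleContrasts <- function(phenotypes, pedigree,
                               characteristics = c("age", "smoking_initiation",
                                                   "cpd", "pack_years",
                                                   "alcohol_g_day",
                                                   "cannabis_initiation")) {
  fs <- familyStructure(pedigree)
  d <- phenotypes
  if ("wave" %in% names(d)) d <- d[d$wave == 1, ]
  d$structure <- fs$structure[match(d$individual_id, fs$individual_id)]
  d <- d[!is.na(d$structure), ]
  if (!all(c("pair", "trio") %in% d$structure)) stop("empty subgroup")
  rows <- list()
  for (ch in characteristics) {
    x <- d[[ch]]
    keep <- !is.na(x)
    xp <- x[keep & d$structure == "pair"]
    xt <- x[keep & d$structure == "trio"]
    if (!length(xp) || !length(xt)) stop("empty subgroup for ", ch)
    binary <- all(x[keep] %in% c(0, 1))
    if (binary) {
      ct <- contrastFromCounts(sum(xp), length(xp), sum(xt), length(xt))
      rows[[ch]] <- data.frame(
        characteristic = ch, type = "binary",
        pairs = sprintf("%d/%d (%.1f%%)", sum(xp), length(xp),
                        100 * mean(xp)),
        trios = sprintf("%d/%d (%.1f%%)", sum(xt), length(xt),
                        100 * mean(xt)),
        statistic = ct$chisq, df = ct$df, p = ct$p, smd = ct$smd)
    } else {
      ct <- contrastFromSummary(mean(xp), sd(xp), length(xp),
                                mean(xt), sd(xt), length(xt))
      rows[[ch]] <- data.frame(
        characteristic = ch, type = "continuous",
        pairs = sprintf("%.2f +/- %.2f (n=%d)", mean(xp), sd(xp), length(xp)),
        trios = sprintf("%.2f +/- %.2f (n=%d)", mean(xt), sd(xt), length(xt)),
        statistic = ct$t, df = ct$df, p = ct$p, smd = ct$smd)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ContrastReport", class(out))
  out
}
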