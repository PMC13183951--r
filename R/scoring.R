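## Polygenic-score decomposition: per-haplotype scores from a weight table,
## the four parent-specific PGS_T / PGS_NT values, imputation of missing
## non-transmitted scores in pairs, and within-batch standardization.

#' Score transmitted and non-transmitted haplotypes
#'
#' Raw weighted scores `sum_m weight_m * effect-allele dosage_m` over
#' non-missing markers (markers missing in a haplotype are skipped, never
#' mean-imputed; the used-marker count is reported) for the four parental
#' haplotype datasets of a [TransmissionMap-class]: maternal/paternal
#' transmitted and non-transmitted. The non-transmitted score of an
#' ungenotyped parent is `NA`.
#'
#' @param tm a [TransmissionMap-class].
#' @param weights weight table with columns `marker_id`, `effect_allele`,
#'   `weight` (see [simulateWeights()], or [readWeights()]).
#' @return data.frame: `offspring_id`, `pgs_t_maternal`, `pgs_t_paternal`,
#'   `pgs_nt_maternal`, `pgs_nt_paternal` and the four `used_*` marker
#'   counts.
#' @export
scoreHaplotypes <- function(tm, weights) {
  stopifnot(is(tm, "TransmissionMap"))
  map <- tm@map
  sc <- function(m) .scoreAlleleMatrix(m, weights, map)
  tmat <- sc(tm@tMaternal); tpat <- sc(tm@tPaternal)
  nmat <- sc(tm@ntMaternal); npat <- sc(tm@ntPaternal)
  zeroNA <- function(s) ifelse(s[, "used"] > 0, s[, "score"], NA_real_)
  data.frame(
    offspring_id = tm@offspring,
    pgs_t_maternal = zeroNA(tmat), pgs_t_paternal = zeroNA(tpat),
    pgs_nt_maternal = zeroNA(nmat), pgs_nt_paternal = zeroNA(npat),
    used_t_maternal = tmat[, "used"], used_t_paternal = tpat[, "used"],
    used_nt_maternal = nmat[, "used"], used_nt_paternal = npat[, "used"],
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Score full genotypes
#'
#' Raw weighted score of each person's genotype dosage; the decomposition
#' identity `transmitted + non-transmitted = full genotype score` holds for
#' every genotyped parent.
#'
#' @param haps a [HaplotypeSet-class].
#' @param weights weight table.
#' @return named numeric vector of raw scores.
#' @export
scoreGenotypes <- function(haps, weights) {
  s <- .scoreAlleleMatrix(dosage(haps), weights, haps@map, ploidy = 2L)
  setNames(s[, "score"], persons(haps))
}

#' Assemble a ScoreTable
#'
#' Combines the four per-parent scores into the summed transmitted and
#' non-transmitted scores (`pgs_t`, `pgs_nt`), with imputation flags and a
#' batch label. `pgs_nt` is `NA` for pairs until [imputeMissingNT()].
#'
#' @param hapScores output of [scoreHaplotypes()].
#' @param trait trait label.
#' @param batch batch label (scalar or per offspring).
#' @param familyId optional family ids aligned to rows.
#' @return a ScoreTable data.frame.
#' @export
buildScoreTable <- function(hapScores, trait = "CPD", batch = "batch1",
                            familyId = NULL) {
  out <- data.frame(
    offspring_id = hapScores$offspring_id, trait = trait,
    pgs_t_maternal = hapScores$pgs_t_maternal,
    pgs_t_paternal = hapScores$pgs_t_paternal,
    pgs_nt_maternal = hapScores$pgs_nt_maternal,
    pgs_nt_paternal = hapScores$pgs_nt_paternal,
    stringsAsFactors = FALSE)
  out$pgs_t <- out$pgs_t_maternal + out$pgs_t_paternal
  out$pgs_nt <- out$pgs_nt_maternal + out$pgs_nt_paternal
  out$nt_imputed_maternal <- FALSE
  out$nt_imputed_paternal <- FALSE
  out$batch <- batch
  if (!is.null(familyId)) out$family_id <- familyId
  out
}

#' Impute missing non-transmitted scores in pairs
#'
#' Replaces each missing parental non-transmitted score with the mean
#' non-transmitted score of the observed parents (computed per trait on the
#' raw scale, before standardization), sets the imputation flag, and
#' recomputes the combined `pgs_nt`.
#'
#' @param scores a ScoreTable (see [buildScoreTable()]).
#' @param perRole if `TRUE`, use the mothers-only mean for missing maternal
#'   scores and the fathers-only mean for paternal ones; default pools all
#'   observed parents.
#' @return the ScoreTable with imputed values and updated flags.
#' @export
imputeMissingNT <- function(scores, perRole = FALSE) {
  for (tr in unique(scores$trait)) {
    i <- scores$trait == tr
    obsM <- scores$pgs_nt_maternal[i]
    obsP <- scores$pgs_nt_paternal[i]
    if (all(is.na(obsM)) && all(is.na(obsP)))
      stop("no observed non-transmitted parental scores to impute from")
    pooled <- mean(c(obsM, obsP), na.rm = TRUE)
    mMean <- if (perRole && any(!is.na(obsM))) mean(obsM, na.rm = TRUE) else pooled
    pMean <- if (perRole && any(!is.na(obsP))) mean(obsP, na.rm = TRUE) else pooled
    mi <- i & is.na(scores$pgs_nt_maternal)
    pi <- i & is.na(scores$pgs_nt_paternal)
    scores$pgs_nt_maternal[mi] <- mMean
    scores$pgs_nt_paternal[pi] <- pMean
    scores$nt_imputed_maternal[mi] <- TRUE
    scores$nt_imputed_paternal[pi] <- TRUE
  }
  scores$pgs_nt <- scores$pgs_nt_maternal + scores$pgs_nt_paternal
  scores
}

## residualize-then-z-score one numeric vector within one batch
.stdVec <- function(x, covMat) {
  if (!is.null(covMat) && ncol(covMat) > 0) {
    fit <- lm.fit(cbind(1, covMat), x)
    r <- fit$residuals
    if (sd(r) < 1e-10 * max(1, sd(x)))
      stop("degenerate regression: covariates absorb the score entirely")
    x <- r
  }
  s <- sd(x)
  if (s == 0) stop("score has zero variance; cannot standardize")
  (x - mean(x)) / s
}

#' Standardize scores within batches
#'
#' Per batch: regress each score column on the supplied covariates (e.g.
#' ancestry principal components; possibly none), take residuals, and
#' z-score to mean 0 / SD 1. Applied consistently to all six score columns;
#' standardized versions are stored with suffix `_std`. Batches with fewer
#' than 3 members fall back to pooled standardization with a warning.
#' Standardization is idempotent: standardizing an already-standardized
#' column reproduces it.
#'
#' @param scores a ScoreTable.
#' @param covariates optional data.frame of numeric covariate columns
#'   aligned to `scores` rows.
#' @param batchCol name of the batch-label column.
#' @param columns score columns to standardize.
#' @return the ScoreTable with added `*_std` columns.
#' @export
standardizeScores <- function(scores, covariates = NULL, batchCol = "batch",
                              columns = c("pgs_t_maternal", "pgs_t_paternal",
                                          "pgs_nt_maternal", "pgs_nt_paternal",
                                          "pgs_t", "pgs_nt")) {
  batch <- scores[[batchCol]]
  if (is.null(batch)) stop("batch column '", batchCol, "' not found")
  small <- names(which(table(batch) < 3))
  if (length(small))
    warning("batch(es) with < 3 members standardized against the pooled ",
            "sample: ", paste(small, collapse = ", "))
  covMat <- if (is.null(covariates)) NULL else as.matrix(covariates)
  for (col in columns) {
    x <- scores[[col]]
    if (anyNA(x))
      stop("column ", col, " has missing values; impute before standardizing")
    out <- .stdVec(x, covMat)   # pooled fallback for undersized batches
    for (b in setdiff(unique(batch), small)) {
      i <- batch == b
      out[i] <- .stdVec(x[i], if (is.null(covMat)) NULL
                        else covMat[i, , drop = FALSE])
    }
    scores[[paste0(col, "_std")]] <- out
  }
  scores
}
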