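## Synthetic family cohort: founder couples, meiosis with recombination,
## pair/trio masking, phase-switch errors, and phenotypes under a known
## generative model. Everything downstream is validated against this truth.

#' Generative parameters for the synthetic cohort
#'
#' Bundles every knob of the simulator with defaults calibrated to the study
#' conditions the package is validated against: a cohort dominated by
#' parent-offspring pairs (trio fraction 3267/19233), transmitted effect
#' 0.202 and non-transmitted (genetic nurture) effect 0.037 on the
#' standardized quantitative outcome, assessment waves at mean ages
#' 33.0/38.9/44.8 years, 61.9% female offspring, smoking-initiation
#' prevalence 41.4%, and an age-attenuating transmitted effect
#' (-0.004 per year) with a stable nurture effect.
#'
#' @param nFamilies number of founder couples.
#' @param fractionTrios fraction of families keeping both parents genotyped.
#' @param nMarkersPerChrom,nChromosomes marker scaffold dimensions.
#' @param mafRange range of founder alt-allele frequencies (subset of
#'   (0, 0.5]).
#' @param crossoverRate expected crossovers per chromosome per meiosis
#'   (Poisson, no interference).
#' @param phaseErrorRate per-marker probability of a haplotype switch error.
#' @param deltaDirect effect of the offspring's standardized true
#'   transmitted score on the outcome (direct genetic effect).
#' @param betaNurture effect of the standardized true non-transmitted score
#'   (genetic nurture not mediated by the modeled parental phenotypes).
#' @param aM,aP loading of each parent's own standardized polygenic score on
#'   that parent's phenotype.
#' @param bM,bP effect of the maternal / paternal phenotype on the offspring
#'   outcome (the mediated nurture paths; both 0 by default so that
#'   `betaNurture` is the whole nurture effect).
#' @param amCorr mate-pair correlation of parental phenotypes (assortative
#'   mating); 0 by default, matching the negligible assortment observed.
#' @param sigmaFamily family random-intercept SD.
#' @param sigmaPerson person random-intercept SD (repeated measures).
#' @param sigmaAgeSlope person-level random age-slope SD (per year).
#' @param sigmaResid residual SD per assessment; `NULL` picks the value that
#'   makes the baseline outcome variance 1 so generative coefficients are on
#'   the standardized scale.
#' @param ageSlopeT,ageSlopeNT per-year change of the transmitted /
#'   non-transmitted effect (age centered at the baseline mean).
#' @param liabilityThreshold standard-normal threshold for smoking
#'   initiation; default `qnorm(1 - 0.414)` gives 41.4% prevalence.
#' @param waveAges mean ages (years) at the three assessment waves.
#' @param ageSD SD of baseline age.
#' @param propFemale proportion of female offspring.
#' @param maternalBias probability that the genotyped parent of a pair is
#'   the mother (more mothers than fathers are genotyped).
#' @param sibFraction fraction of families with two offspring.
#' @param parentEffects optional list `list(mT=, mNT=, pT=, pNT=)` of
#'   per-parent standardized effects (each on the z-scored per-parent
#'   haplotype score), overriding the symmetric split
#'   `deltaDirect/sqrt(2)` / `betaNurture/sqrt(2)`; used for
#'   parent-of-origin scenarios.
#' @param seed integer seed used by [simulateCohort()].
#' @return A classed list of parameters (`"GenerativeParams"`).
#' @export
generativeParams <- function(nFamilies = 2000,
                             fractionTrios = 3267 / 19233,
                             nMarkersPerChrom = 2500,
                             nChromosomes = 2,
                             mafRange = c(0.05, 0.5),
                             crossoverRate = 1.5,
                             phaseErrorRate = 0,
                             deltaDirect = 0.202,
                             betaNurture = 0.037,
                             aM = 0.4, aP = 0.4,
                             bM = 0, bP = 0,
                             amCorr = 0,
                             sigmaFamily = 0.2,
                             sigmaPerson = 0.3,
                             sigmaAgeSlope = 0.01,
                             sigmaResid = NULL,
                             ageSlopeT = -0.004, ageSlopeNT = 0,
                             liabilityThreshold = qnorm(1 - 0.414),
                             waveAges = c(33.0, 38.9, 44.8),
                             ageSD = 8.5,
                             propFemale = 0.619,
                             maternalBias = 0.66,
                             sibFraction = 0.3,
                             parentEffects = NULL,
                             seed = 1L) {
  p <- as.list(environment())
  if (p$nFamilies < 1 || p$nMarkersPerChrom < 1 || p$nChromosomes < 1)
    stop("dimensions must be positive")
  if (length(mafRange) != 2 || mafRange[1] <= 0 || mafRange[2] > 0.5 ||
      mafRange[1] > mafRange[2])
    stop("mafRange must lie in (0, 0.5]")
  if (fractionTrios < 0 || fractionTrios > 1)
    stop("fractionTrios must be in [0, 1]")
  if (phaseErrorRate < 0 || phaseErrorRate >= 1)
    stop("phaseErrorRate must be in [0, 1)")
  if (any(c(sigmaFamily, sigmaPerson, sigmaAgeSlope) < 0))
    stop("variance components must be non-negative")
  if (is.null(sigmaResid)) p$sigmaResid <- .autoSigmaResid(p)
  if (p$sigmaResid < 0) stop("sigmaResid must be non-negative")
  class(p) <- "GenerativeParams"
  p
}

## Residual SD completing the baseline outcome variance to 1. Uses the
## model-implied covariances: cov(zT, M_parent) = a/2 (each parent supplies
## half of the transmitted score), same for zNT, and cov(Mm, Mp) = amCorr.
.autoSigmaResid <- function(p) {
  covTM <- p$aM / 2 * p$bM + p$aP / 2 * p$bP
  v <- p$deltaDirect^2 + p$betaNurture^2 + p$bM^2 + p$bP^2 +
    2 * p$deltaDirect * covTM + 2 * p$betaNurture * covTM +
    2 * p$bM * p$bP * p$amCorr +
    p$sigmaFamily^2 + p$sigmaPerson^2
  if (v >= 1)
    stop("generative variance already exceeds 1; supply sigmaResid explicitly")
  sqrt(1 - v)
}

#' @method print GenerativeParams
#' @export
print.GenerativeParams <- function(x, ...) {
  cat("GenerativeParams:\n")
  cat(sprintf("  %d families (%.1f%% trios), %d x %d markers\n",
              x$nFamilies, 100 * x$fractionTrios, x$nChromosomes,
              x$nMarkersPerChrom))
  cat(sprintf("  deltaDirect = %.3f, betaNurture = %.3f, b paths = (%.3f, %.3f)\n",
              x$deltaDirect, x$betaNurture, x$bM, x$bP))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Founders
## ---------------------------------------------------------------------------

#' Simulate founder couples
#'
#' Draws `nFamilies` mother-father couples with independent biallelic
#' markers: per marker an alt-allele frequency from
#' `Uniform(mafRange)`, then haplotype alleles as independent Bernoulli
#' draws. Markers carry a uniform 1 cM spacing genetic map.
#'
#' @param params a [generativeParams()] object.
#' @return list with `haps` ([HaplotypeSet-class] of founders), `pedigree`
#'   (all parents and their offspring slots, everyone genotyped), `map`
#'   ([VariantMap-class]) and `maf` (the per-marker frequencies used).
#' @export
simulateFounders <- function(params) {
  stopifnot(inherits(params, "GenerativeParams"))
  m <- params$nMarkersPerChrom
  nc <- params$nChromosomes
  M <- m * nc
  chrom <- rep(seq_len(nc), each = m)
  map <- VariantMap(
    markerId = sprintf("chr%d_snp%d", chrom, rep(seq_len(m), nc)),
    chrom = chrom,
    physPos = rep(seq_len(m) * 10000L, nc),
    geneticPos = rep(seq_len(m) * 1.0, nc))
  maf <- runif(M, params$mafRange[1], params$mafRange[2])

  nf <- params$nFamilies
  mothers <- sprintf("F%d_M", seq_len(nf))
  fathers <- sprintf("F%d_P", seq_len(nf))
  nSibs <- 1L + rbinom(nf, 1L, params$sibFraction)
  offIds <- unlist(lapply(seq_len(nf), function(f)
    sprintf("F%d_O%d", f, seq_len(nSibs[f]))))
  offFam <- rep(seq_len(nf), nSibs)

  ids <- c(mothers, fathers)
  drawHap <- function() {
    h <- matrix(rbinom(length(ids) * M, 1L,
                       rep(maf, each = length(ids))),
                nrow = length(ids), ncol = M,
                dimnames = list(ids, map@markerId))
    storage.mode(h) <- "integer"
    h
  }
  haps <- HaplotypeSet(drawHap(), drawHap(), map)

  ped <- data.frame(
    family_id = c(sprintf("F%d", seq_len(nf)), sprintf("F%d", seq_len(nf)),
                  sprintf("F%d", offFam)),
    individual_id = c(mothers, fathers, offIds),
    father_id = c(rep(NA_character_, 2L * nf), fathers[offFam]),
    mother_id = c(rep(NA_character_, 2L * nf), mothers[offFam]),
    sex = c(rep("female", nf), rep("male", nf),
            ifelse(runif(length(offIds)) < params$propFemale,
                   "female", "male")),
    genotyped = TRUE,
    role = c(rep("mother", nf), rep("father", nf),
             rep("offspring", length(offIds))),
    stringsAsFactors = FALSE)
  validatePedigree(ped)
  list(haps = haps, pedigree = ped, map = map, maf = maf)
}

## ---------------------------------------------------------------------------
## Meiosis
## ---------------------------------------------------------------------------

## One gamete: per-marker source haplotype (1/2) for a single chromosome.
## Crossover count ~ Poisson(rate); breakpoint positions uniform on the
## genetic map; an even number of crossovers in one inter-marker interval
## cancels out.
.gameteSources <- function(nMark, cm, rate, forcedJunctions = NULL) {
  if (is.null(forcedJunctions)) {
    k <- rpois(1L, rate)
    junc <- integer(0)
    if (k > 0) {
      u <- runif(k, min = cm[1], max = cm[nMark])
      j <- findInterval(u, cm, rightmost.closed = FALSE)
      j <- j[j >= 1L & j < nMark]          # switch occurs after marker j
      tab <- table(j)
      junc <- sort(as.integer(names(tab)[tab %% 2L == 1L]))
    }
  } else {
    junc <- sort(unique(as.integer(forcedJunctions)))
  }
  s0 <- sample(1:2, 1L)
  src <- rep.int(s0, nMark)
  if (length(junc)) {
    flips <- cumsum(tabulate(junc + 1L, nbins = nMark))
    src <- 1L + (s0 - 1L + flips) %% 2L
  }
  list(src = src, junctions = junc)
}

#' Mate founder couples and simulate meioses
#'
#' For every offspring in the pedigree, draws one maternal and one paternal
#' gamete per chromosome (crossovers Poisson-distributed on the genetic
#' map), sets offspring haplotype 1 to the maternal gamete and haplotype 2
#' to the paternal gamete, and records the exact segment sources as
#' [TransmissionTruth-class].
#'
#' @param founders founder [HaplotypeSet-class] from [simulateFounders()].
#' @param pedigree pedigree data.frame (parents must be present in
#'   `founders`).
#' @param params a [generativeParams()] object.
#' @return list with `haps` (founders plus offspring) and `truth`.
#' @export
mateAndMeiose <- function(founders, pedigree, params) {
  validatePedigree(pedigree)
  map <- founders@map
  off <- pedigree[pedigree$role == "offspring", ]
  miss <- setdiff(c(off$mother_id, off$father_id), persons(founders))
  if (length(miss))
    stop("pedigree references founders absent from the haplotype set: ",
         paste(head(miss, 3), collapse = ", "))
  chroms <- unique(map@chrom)
  idx <- lapply(chroms, function(ch) which(map@chrom == ch))
  M <- nMarkers(map)
  nOff <- nrow(off)

  oh1 <- matrix(NA_integer_, nOff, M, dimnames = list(off$individual_id,
                                                      map@markerId))
  oh2 <- oh1
  segs <- vector("list", 4L * nOff * length(chroms))
  si <- 0L
  for (i in seq_len(nOff)) {
    for (side in 1:2) {
      par <- if (side == 1) off$mother_id[i] else off$father_id[i]
      p1 <- founders@hap1[par, ]
      p2 <- founders@hap2[par, ]
      lab <- if (side == 1) c("mat1", "mat2") else c("pat1", "pat2")
      gam <- integer(M)
      for (ci in seq_along(chroms)) {
        ix <- idx[[ci]]
        g <- .gameteSources(length(ix), map@geneticPos[ix],
                            params$crossoverRate)
        gam[ix] <- ifelse(g$src == 1L, p1[ix], p2[ix])
        bounds <- c(0L, g$junctions, length(ix))
        srcAt <- g$src[c(g$junctions, length(ix))]
        si <- si + 1L
        segs[[si]] <- data.frame(
          offspring = off$individual_id[i], chrom = chroms[ci], hap = side,
          start = ix[1] + bounds[-length(bounds)],
          end = ix[1] - 1L + bounds[-1],
          source = lab[srcAt], stringsAsFactors = FALSE)
      }
      if (side == 1) oh1[i, ] <- gam else oh2[i, ] <- gam
    }
  }
  truth <- new("TransmissionTruth", segments = do.call(rbind, segs[seq_len(si)]))
  allHaps <- HaplotypeSet(rbind(founders@hap1, oh1),
                          rbind(founders@hap2, oh2), map)
  list(haps = allHaps, truth = truth)
}

#' Expand truth segments into per-marker source matrices
#'
#' @param truth a [TransmissionTruth-class].
#' @param map the [VariantMap-class] the indices refer to.
#' @param offspringIds order of rows in the output.
#' @return list of two integer matrices `src1`, `src2` (offspring x
#'   markers) with codes 1:4 = mat1, mat2, pat1, pat2.
#' @export
truthSourceMatrices <- function(truth, map, offspringIds) {
  seg <- truth@segments
  codes <- c(mat1 = 1L, mat2 = 2L, pat1 = 3L, pat2 = 4L)
  M <- nMarkers(map)
  src1 <- matrix(NA_integer_, length(offspringIds), M,
                 dimnames = list(offspringIds, map@markerId))
  src2 <- src1
  rowOf <- match(seg$offspring, offspringIds)
  for (r in which(!is.na(rowOf))) {
    v <- codes[[seg$source[r]]]
    if (seg$hap[r] == 1L) src1[rowOf[r], seg$start[r]:seg$end[r]] <- v
    else                  src2[rowOf[r], seg$start[r]:seg$end[r]] <- v
  }
  list(src1 = src1, src2 = src2)
}

## ---------------------------------------------------------------------------
## Masking and phase errors
## ---------------------------------------------------------------------------

#' Mask one parent per family to create parent-offspring pairs
#'
#' Clears the `genotyped` flag of one randomly chosen parent in
#' `(1 - fractionTrios)` of the families; the genotype of a masked parent is
#' withheld from all downstream inference (its non-transmitted alleles
#' become missing) while the simulation truth retains full information.
#'
#' @param pedigree pedigree data.frame.
#' @param fractionTrios fraction of families left as complete trios.
#' @param maternalBias probability the *mother* remains genotyped in a
#'   masked family (more mothers than fathers are typically genotyped).
#' @param seed optional integer seed.
#' @return the pedigree with updated `genotyped` flags.
#' @export
maskParents <- function(pedigree, fractionTrios, maternalBias = 0.66,
                        seed = NULL) {
  if (fractionTrios < 0 || fractionTrios > 1)
    stop("fractionTrios must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  validatePedigree(pedigree)
  if (fractionTrios == 1) return(pedigree)
  fams <- unique(pedigree$family_id[pedigree$role == "offspring"])
  masked <- fams[runif(length(fams)) >= fractionTrios]
  for (f in masked) {
    keepMother <- runif(1) < maternalBias
    role <- if (keepMother) "father" else "mother"
    pedigree$genotyped[pedigree$family_id == f & pedigree$role == role] <- FALSE
  }
  pedigree
}

#' Inject haplotype switch errors
#'
#' Emulates imperfect statistical phasing: per person and marker, with
#' probability `rate` the haplotype assignment switches from that marker
#' onwards (within chromosome). Genotype dosages are unchanged.
#'
#' @param haps a [HaplotypeSet-class].
#' @param rate per-marker switch probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @return a new [HaplotypeSet-class] with toggled phase.
#' @export
injectPhaseErrors <- function(haps, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(haps)
  h1 <- haps@hap1; h2 <- haps@hap2
  n <- nrow(h1); M <- ncol(h1)
  sw <- matrix(rbinom(n * M, 1L, rate), n, M)
  state <- matrix(0L, n, M)
  for (ch in unique(haps@map@chrom)) {
    ix <- which(haps@map@chrom == ch)
    state[, ix] <- t(apply(sw[, ix, drop = FALSE], 1L, cumsum)) %% 2L
  }
  flip <- state == 1L
  new1 <- ifelse(flip, h2, h1)
  new2 <- ifelse(flip, h1, h2)
  dimnames(new1) <- dimnames(new2) <- dimnames(h1)
  HaplotypeSet(new1, new2, haps@map, haps@phaseKnown)
}

## ---------------------------------------------------------------------------
## Marker weights and true scores
## ---------------------------------------------------------------------------

#' Simulate a per-trait SNP weight table
#'
#' Gaussian weights scaled by `1/sqrt(M)` so raw scores have O(1) variance;
#' effect allele is the alt allele for every marker.
#'
#' @param map a [VariantMap-class].
#' @param trait trait label.
#' @return data.frame with columns `marker_id`, `effect_allele`, `weight`,
#'   `trait`.
#' @export
simulateWeights <- function(map, trait = "CPD") {
  M <- nMarkers(map)
  data.frame(marker_id = map@markerId,
             effect_allele = map@alt,
             weight = rnorm(M) / sqrt(M),
             trait = trait, stringsAsFactors = FALSE)
}

## Raw weighted score of an allele matrix (rows = people). NA alleles are
## skipped (contribute nothing, including any ref-orientation offset).
## ploidy = 1 for haplotype matrices (0/1), 2 for genotype dosages (0/1/2):
## a ref-oriented effect allele has dosage ploidy - a.
.scoreAlleleMatrix <- function(mat, weights, map, ploidy = 1L) {
  pos <- match(weights$marker_id, map@markerId)
  if (all(is.na(pos))) stop("no weight markers overlap the variant map")
  keep <- !is.na(pos)
  w <- weights$weight[keep]
  pos <- pos[keep]
  isAlt <- weights$effect_allele[keep] == map@alt[pos]
  isRef <- weights$effect_allele[keep] == map@ref[pos]
  if (any(!isAlt & !isRef))
    stop("effect alleles must match the ref or alt allele of the map")
  ## effect-allele dosage: a for alt-oriented, (1 - a) for ref-oriented
  signedW <- ifelse(isAlt, w, -w)
  sub <- mat[, pos, drop = FALSE]
  nas <- is.na(sub)
  sub[nas] <- 0L
  base <- sub %*% signedW
  ## per-row constant: ploidy x sum of ref-oriented weights over
  ## non-missing markers
  refW <- ifelse(isRef, ploidy * w, 0)
  const <- (1 - nas) %*% refW
  out <- cbind(as.numeric(base + const), rowSums(!nas))
  dimnames(out) <- list(rownames(mat), c("score", "used"))
  out
}

#' True transmitted and non-transmitted scores from simulation truth
#'
#' Computes, per offspring, the raw weighted scores of the truly transmitted
#' and non-transmitted parental haplotypes (per parent and combined) using
#' the simulator's [TransmissionTruth-class].
#'
#' @param haps complete [HaplotypeSet-class] (founders + offspring).
#' @param truth the [TransmissionTruth-class].
#' @param pedigree pedigree data.frame.
#' @param weights weight table (see [simulateWeights()]).
#' @return data.frame: `offspring_id`, `t_maternal`, `t_paternal`,
#'   `nt_maternal`, `nt_paternal`, `score_t`, `score_nt`.
#' @export
trueScores <- function(haps, truth, pedigree, weights) {
  off <- pedigree[pedigree$role == "offspring", ]
  map <- haps@map
  src <- truthSourceMatrices(truth, map, off$individual_id)
  mo1 <- haps@hap1[off$mother_id, , drop = FALSE]
  mo2 <- haps@hap2[off$mother_id, , drop = FALSE]
  fa1 <- haps@hap1[off$father_id, , drop = FALSE]
  fa2 <- haps@hap2[off$father_id, , drop = FALSE]
  tm <- ifelse(src$src1 == 1L, mo1, mo2)
  ntm <- ifelse(src$src1 == 1L, mo2, mo1)
  tp <- ifelse(src$src2 == 3L, fa1, fa2)
  ntp <- ifelse(src$src2 == 3L, fa2, fa1)
  sc <- function(m) .scoreAlleleMatrix(m, weights, map)[, "score"]
  out <- data.frame(offspring_id = off$individual_id,
                    t_maternal = sc(tm), t_paternal = sc(tp),
                    nt_maternal = sc(ntm), nt_paternal = sc(ntp),
                    stringsAsFactors = FALSE)
  out$score_t <- out$t_maternal + out$t_paternal
  out$score_nt <- out$nt_maternal + out$nt_paternal
  out
}

## ---------------------------------------------------------------------------
## Phenotypes
## ---------------------------------------------------------------------------

#' Assign phenotypes under the generative model
#'
#' Parental phenotype: `a * z(own full polygenic score) + noise`, with
#' mate-pair phenotype correlation `amCorr`. Offspring continuous outcome at
#' wave `w` (age centered at the wave-1 mean):
#' `y = (deltaDirect + ageSlopeT * ageC) * zT + (betaNurture + ageSlopeNT *
#' ageC) * zNT + bM * Mm + bP * Mp + familyEffect + personEffect +
#' personSlope * ageC + residual`. Binary outcomes threshold the
#' standardized baseline outcome. Realistic-scale substance-use columns
#' (lifetime CPD, pack-years `= amount/day x years / 20`, daily alcohol
#' grams, current CPD with former smokers coded 0) are derived from the same
#' latent outcome. Generative truth columns are carried with a `gen_`
#' prefix and the parameters are attached as attribute `genCoefs`.
#'
#' @param haps complete [HaplotypeSet-class].
#' @param truth [TransmissionTruth-class] from [mateAndMeiose()].
#' @param pedigree pedigree data.frame.
#' @param weights weight table.
#' @param params a [generativeParams()] object.
#' @return long-format data.frame, one row per offspring x wave.
#' @export
assignPhenotypes <- function(haps, truth, pedigree, weights, params) {
  off <- pedigree[pedigree$role == "offspring", ]
  n <- nrow(off)
  ts <- trueScores(haps, truth, pedigree, weights)
  zT <- as.numeric(scale(ts$score_t))
  zNT <- as.numeric(scale(ts$score_nt))

  ## parental phenotypes with assortative-mating correlation on the noise
  parents <- unique(rbind(
    data.frame(fam = off$family_id, mother = off$mother_id,
               father = off$father_id, stringsAsFactors = FALSE)))
  gsc <- .scoreAlleleMatrix(dosage(haps), weights, haps@map,
                            ploidy = 2L)[, "score"]
  zAll <- (gsc - mean(gsc[c(parents$mother, parents$father)])) /
    sd(gsc[c(parents$mother, parents$father)])
  eCorr <- 0
  if (params$amCorr != 0) {
    eCorr <- params$amCorr / sqrt((1 - params$aM^2) * (1 - params$aP^2))
    if (abs(eCorr) >= 1) stop("amCorr too large for the given a loadings")
  }
  nf <- nrow(parents)
  em <- rnorm(nf)
  ep <- eCorr * em + sqrt(1 - eCorr^2) * rnorm(nf)
  Mm <- params$aM * zAll[parents$mother] + sqrt(1 - params$aM^2) * em
  Mp <- params$aP * zAll[parents$father] + sqrt(1 - params$aP^2) * ep
  names(Mm) <- names(Mp) <- parents$fam
  MmO <- Mm[off$family_id]
  MpO <- Mp[off$family_id]

  uFam <- setNames(rnorm(nf, 0, params$sigmaFamily), parents$fam)[off$family_id]
  uPer <- rnorm(n, 0, params$sigmaPerson)
  uSlp <- rnorm(n, 0, params$sigmaAgeSlope)
  age1 <- pmin(67, pmax(18, rnorm(n, params$waveAges[1], params$ageSD)))
  sex <- off$sex
  birthYear <- 2010 - age1

  waves <- seq_along(params$waveAges)
  rows <- vector("list", length(waves))
  etaW <- matrix(0, n, length(waves))
  ## assessment dates vary between participants within a wave
  ageMat <- sapply(waves, function(w) {
    if (w == 1) age1 else
      age1 + (params$waveAges[w] - params$waveAges[1]) + rnorm(n, 0, 1.5)
  })
  for (w in waves) {
    ageC <- ageMat[, w] - params$waveAges[1]
    etaW[, w] <- (params$deltaDirect + params$ageSlopeT * ageC) * zT +
      (params$betaNurture + params$ageSlopeNT * ageC) * zNT +
      params$bM * MmO + params$bP * MpO +
      uFam + uPer + uSlp * ageC + rnorm(n, 0, params$sigmaResid)
  }
  y1 <- etaW[, 1]
  liab <- as.numeric(scale(y1))
  smkInit <- as.integer(liab > params$liabilityThreshold)
  liabCan <- 0.6 * liab + sqrt(1 - 0.36) * rnorm(n)
  canInit <- as.integer(liabCan > qnorm(1 - 0.227))
  cpd <- ifelse(smkInit == 1L, pmax(0, 10.24 + 6 * y1), NA_real_)
  yearsSmoked <- ifelse(smkInit == 1L,
                        pmax(1, (age1 - 17) * runif(n, 0.3, 0.9)), NA_real_)
  packYears <- cpd * yearsSmoked / 20
  alcohol <- pmax(0, 6.74 + 8.46 * (0.5 * liab + sqrt(0.75) * rnorm(n)))
  stillSmoking <- matrix(runif(n * length(waves)) <
                           rep(c(0.6, 0.5, 0.4)[waves], each = n),
                         n, length(waves))
  matCpd <- pmax(0, 10.24 + 6 * MmO)
  patCpd <- pmax(0, 10.24 + 6 * MpO)

  for (w in waves) {
    current <- smkInit == 1L & stillSmoking[, w]
    rows[[w]] <- data.frame(
      individual_id = off$individual_id,
      family_id = off$family_id,
      wave = w,
      age = ageMat[, w],
      age_c = ageMat[, w] - params$waveAges[1],
      sex = sex, birth_year = birthYear,
      y = etaW[, w],
      smoking_initiation = smkInit,
      cpd = cpd, pack_years = packYears,
      alcohol_g_day = alcohol,
      cannabis_initiation = canInit,
      current_cpd = ifelse(current, pmax(0, 8 + 5 * etaW[, w]), 0),
      maternal_cpd = matCpd, paternal_cpd = patCpd,
      gen_score_t = zT, gen_score_nt = zNT,
      gen_maternal_pheno = MmO, gen_paternal_pheno = MpO,
      gen_family_effect = uFam,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "genCoefs") <- params
  out
}

## ---------------------------------------------------------------------------
## One-stop cohort simulation
## ---------------------------------------------------------------------------

#' Simulate a complete synthetic family cohort
#'
#' Runs [simulateFounders()], [maskParents()], [mateAndMeiose()],
#' [injectPhaseErrors()] and [assignPhenotypes()] with a single seed.
#'
#' @param params a [generativeParams()] object.
#' @return list: `haps` (with phase errors injected, as seen by inference),
#'   `hapsTrue` (error-free, for validation), `pedigree`, `map`, `truth`,
#'   `weights`, `phenotypes`, `params`.
#' @export
simulateCohort <- function(params = generativeParams()) {
  set.seed(params$seed)
  f <- simulateFounders(params)
  ped <- maskParents(f$pedigree, params$fractionTrios, params$maternalBias)
  mm <- mateAndMeiose(f$haps, ped, params)
  haps <- injectPhaseErrors(mm$haps, params$phaseErrorRate)
  weights <- simulateWeights(f$map)
  phen <- assignPhenotypes(mm$haps, mm$truth, ped, weights, params)
  list(haps = haps, hapsTrue = mm$haps, pedigree = ped, map = f$map,
       truth = mm$truth, weights = weights, phenotypes = phen,
       params = params)
}

#' Simulate a cohort at the polygenic-score level
#'
#' Fast generator that skips markers entirely: per-parent transmitted and
#' non-transmitted haplotype scores are drawn directly (each `N(0, 1/2)`, so
#' parental full scores and offspring combined scores have unit variance,
#' and transmitted + non-transmitted equals the parent's full score
#' exactly), then phenotypes follow the same generative model as
#' [assignPhenotypes()] without any floor/threshold distortion of the
#' continuous outcome. Used for calibration and operating-characteristic
#' studies where marker-level detail is irrelevant.
#'
#' @param params a [generativeParams()] object.
#' @param seed optional seed overriding `params$seed`.
#' @return list: `scores` (one row per offspring, raw per-parent scores,
#'   with the non-transmitted score of the ungenotyped parent set `NA`),
#'   `phenotypes` (long format, one row per offspring x wave with column
#'   `y`, the continuous outcome), `params`.
#' @export
simulateScoreCohort <- function(params = generativeParams(), seed = NULL) {
  set.seed(if (is.null(seed)) params$seed else seed)
  nf <- params$nFamilies
  fam <- sprintf("F%d", seq_len(nf))
  motherScore <- rnorm(nf)
  fatherScore <- rnorm(nf)
  nSibs <- 1L + rbinom(nf, 1L, params$sibFraction)
  famOf <- rep(seq_len(nf), nSibs)
  n <- length(famOf)
  ids <- unlist(lapply(seq_len(nf), function(f)
    sprintf("F%d_O%d", f, seq_len(nSibs[f]))))

  tm <- motherScore[famOf] / 2 + rnorm(n, 0, 0.5)
  ntm <- motherScore[famOf] - tm
  tp <- fatherScore[famOf] / 2 + rnorm(n, 0, 0.5)
  ntp <- fatherScore[famOf] - tp
  zT <- tm + tp
  zNT <- ntm + ntp

  eCorr <- 0
  if (params$amCorr != 0)
    eCorr <- params$amCorr / sqrt((1 - params$aM^2) * (1 - params$aP^2))
  em <- rnorm(nf)
  ep <- eCorr * em + sqrt(1 - eCorr^2) * rnorm(nf)
  Mm <- params$aM * motherScore + sqrt(1 - params$aM^2) * em
  Mp <- params$aP * fatherScore + sqrt(1 - params$aP^2) * ep

  trio <- runif(nf) < params$fractionTrios
  motherKept <- runif(nf) < params$maternalBias
  ntmObs <- ifelse(trio[famOf] | motherKept[famOf], ntm, NA_real_)
  ntpObs <- ifelse(trio[famOf] | !motherKept[famOf], ntp, NA_real_)

  scores <- data.frame(
    offspring_id = ids, family_id = fam[famOf], trait = "CPD",
    pgs_t_maternal = tm, pgs_t_paternal = tp,
    pgs_nt_maternal = ntmObs, pgs_nt_paternal = ntpObs,
    pgs_t = zT, pgs_nt = ntmObs + ntpObs,
    nt_imputed_maternal = FALSE, nt_imputed_paternal = FALSE,
    batch = "sim", stringsAsFactors = FALSE)

  uFam <- rnorm(nf, 0, params$sigmaFamily)[famOf]
  uPer <- rnorm(n, 0, params$sigmaPerson)
  uSlp <- rnorm(n, 0, params$sigmaAgeSlope)
  age1 <- pmin(67, pmax(18, rnorm(n, params$waveAges[1], params$ageSD)))
  sex <- ifelse(runif(n) < params$propFemale, "female", "male")
  ## per-parent standardized effects (symmetric split unless overridden)
  pe <- params$parentEffects
  if (is.null(pe))
    pe <- list(mT = params$deltaDirect / sqrt(2),
               mNT = params$betaNurture / sqrt(2),
               pT = params$deltaDirect / sqrt(2),
               pNT = params$betaNurture / sqrt(2))
  s2 <- sqrt(2)  # per-parent haplotype scores have SD 1/sqrt(2)
  base <- s2 * (pe$mT * tm + pe$mNT * ntm + pe$pT * tp + pe$pNT * ntp)
  rows <- vector("list", length(params$waveAges))
  for (w in seq_along(params$waveAges)) {
    ## assessment dates vary between participants within a wave
    gap <- if (w == 1) 0 else
      (params$waveAges[w] - params$waveAges[1]) + rnorm(n, 0, 1.5)
    ageC <- age1 - params$waveAges[1] + gap
    yw <- base + params$ageSlopeT * ageC * zT +
      params$ageSlopeNT * ageC * zNT +
      params$bM * Mm[famOf] + params$bP * Mp[famOf] +
      uFam + uPer + uSlp * ageC + rnorm(n, 0, params$sigmaResid)
    rows[[w]] <- data.frame(
      individual_id = ids, family_id = fam[famOf], wave = w,
      age = ageC + params$waveAges[1], age_c = ageC,
      sex = sex, birth_year = 2010 - age1,
      y = yw,
      maternal_pheno = Mm[famOf], paternal_pheno = Mp[famOf],
      gen_score_t = zT, gen_score_nt = zNT,
      stringsAsFactors = FALSE)
  }
  phen <- do.call(rbind, rows)
  liab <- as.numeric(scale(phen$y[phen$wave == 1]))
  init <- as.integer(liab > params$liabilityThreshold)
  phen$smoking_initiation <- init[match(phen$individual_id,
                                        phen$individual_id[phen$wave == 1])]
  list(scores = scores, phenotypes = phen, params = params)
}
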