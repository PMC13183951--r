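## Haplotype-tile transmission inference: classify each offspring haplotype
## tile by Hamming distance to the available parental haplotypes, vote a
## parent per offspring haplotype genome-wide, refine crossover breakpoints,
## and extract the non-transmitted parental alleles.

#' Partition a variant map into tiles of adjacent markers
#'
#' Contiguous spans of `tileSize` adjacent markers per chromosome; a
#' trailing remainder shorter than `tileSize` is merged into the final tile
#' (avoiding short, noisy end tiles). A chromosome with fewer than
#' `tileSize` markers becomes a single whole-chromosome tile with a warning.
#'
#' @param map a [VariantMap-class].
#' @param tileSize markers per tile (default 150).
#' @return data.frame: `chrom`, `tile` (index within chromosome), `start`,
#'   `end` (global marker indices, 1-based inclusive).
#' @export
makeTiles <- function(map, tileSize = 150L) {
  if (tileSize < 2) stop("tileSize must be >= 2")
  out <- list()
  for (ch in unique(map@chrom)) {
    ix <- which(map@chrom == ch)
    m <- length(ix)
    if (m < tileSize) {
      warning(sprintf("chromosome %d has %d (< %d) markers: single tile",
                      ch, m, tileSize))
      starts <- 1L
      ends <- m
    } else {
      nT <- m %/% tileSize
      starts <- (seq_len(nT) - 1L) * tileSize + 1L
      ends <- c(starts[-1L] - 1L, m)   # remainder merged into final tile
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, tile = seq_along(starts),
      start = ix[1L] - 1L + starts, end = ix[1L] - 1L + ends)
  }
  do.call(rbind, out)
}

## Tile-summed mismatch and valid-marker counts between one offspring
## haplotype matrix and one parental haplotype matrix.
.tileMismatch <- function(offH, parH, ind) {
  valid <- (!is.na(offH)) & (!is.na(parH))
  mis <- (offH != parH) & valid
  mis[is.na(mis)] <- FALSE
  list(mis = mis %*% ind, valid = valid %*% ind)
}

#' Match offspring tiles against parental haplotypes
#'
#' Computes, per offspring haplotype and tile, the Hamming mismatch count
#' against each available parental haplotype (missing genotype calls are
#' excluded from both numerator and denominator), and assigns each tile a
#' best-match label by argmin mismatch fraction. Ties are broken by
#' continuity with the previous tile's label, else left unresolved; tiles
#' whose minimum mismatch fraction exceeds `tau` are unresolved. Haplotypes
#' of an ungenotyped parent are not candidates.
#'
#' @param haps [HaplotypeSet-class] holding offspring and genotyped parents.
#' @param pedigree pedigree data.frame; only parents flagged `genotyped`
#'   are used.
#' @param tiles tile table from [makeTiles()] (built from `haps`' map if
#'   omitted).
#' @param tileSize used when `tiles` is omitted.
#' @param tau unresolved threshold as a fraction of tile length
#'   (default 0.1).
#' @return A `"TileAssignment"` list: mismatch/valid count arrays
#'   (offspring x tile x offspring-haplotype x parental-haplotype, parental
#'   order mat1, mat2, pat1, pat2), per-tile argmin `labels`, parent
#'   availability, and the inputs needed by [resolveTransmission()].
#' @export
matchTiles <- function(haps, pedigree, tiles = NULL, tileSize = 150L,
                       tau = 0.1) {
  validatePedigree(pedigree)
  map <- haps@map
  if (is.null(tiles)) tiles <- makeTiles(map, tileSize)
  off <- pedigree[pedigree$role == "offspring", ]
  if (!nrow(off)) stop("no offspring in pedigree")
  gset <- pedigree$individual_id[pedigree$genotyped]
  motherG <- off$mother_id %in% gset
  fatherG <- off$father_id %in% gset
  if (any(!motherG & !fatherG))
    stop("offspring with no genotyped parent")

  M <- nMarkers(map)
  nT <- nrow(tiles)
  ind <- matrix(0, M, nT)
  for (t in seq_len(nT)) ind[tiles$start[t]:tiles$end[t], t] <- 1

  ## parental haplotype matrices aligned to offspring rows; ungenotyped -> NA
  alignPar <- function(ids, g, hap) {
    out <- matrix(NA_integer_, nrow(off), M)
    if (any(g)) {
      h <- if (hap == 1) haps@hap1 else haps@hap2
      out[g, ] <- h[ids[g], , drop = FALSE]
    }
    out
  }
  parMats <- list(alignPar(off$mother_id, motherG, 1),
                  alignPar(off$mother_id, motherG, 2),
                  alignPar(off$father_id, fatherG, 1),
                  alignPar(off$father_id, fatherG, 2))
  offMats <- list(haps@hap1[off$individual_id, , drop = FALSE],
                  haps@hap2[off$individual_id, , drop = FALSE])

  dnames <- list(off$individual_id, NULL, NULL,
                 c("mat1", "mat2", "pat1", "pat2"))
  mism <- array(NA_real_, c(nrow(off), nT, 2, 4), dimnames = dnames)
  valid <- mism
  for (h in 1:2) for (p in 1:4) {
    tm <- .tileMismatch(offMats[[h]], parMats[[p]], ind)
    mism[, , h, p] <- tm$mis
    valid[, , h, p] <- tm$valid
  }
  frac <- mism / ifelse(valid > 0, valid, NA)

  ## per-tile argmin label with continuity tie-break and tau threshold
  labels <- array(NA_integer_, c(nrow(off), nT, 2),
                  dimnames = list(off$individual_id, NULL, NULL))
  for (h in 1:2) {
    prev <- rep(NA_integer_, nrow(off))
    for (t in seq_len(nT)) {
      Fm <- frac[, t, h, , drop = TRUE]
      if (is.null(dim(Fm))) Fm <- matrix(Fm, nrow = 1)
      minv <- suppressWarnings(apply(Fm, 1L, min, na.rm = TRUE))
      minv[!is.finite(minv)] <- NA
      lab <- rep(NA_integer_, nrow(off))
      for (i in seq_len(nrow(off))) {
        if (is.na(minv[i]) || minv[i] > tau) next
        tied <- which(!is.na(Fm[i, ]) & Fm[i, ] <= minv[i] + 1e-12)
        if (length(tied) == 1L) lab[i] <- tied
        else if (!is.na(prev[i]) && prev[i] %in% tied) lab[i] <- prev[i]
        ## else unresolved
      }
      ## reset continuity at chromosome starts
      if (t > 1L && tiles$chrom[t] != tiles$chrom[t - 1L])
        prev <- rep(NA_integer_, nrow(off))
      labels[, t, h] <- lab
      prev <- ifelse(is.na(lab), prev, lab)
    }
  }
  structure(list(offspring = off$individual_id, tiles = tiles, tau = tau,
                 mism = mism, valid = valid, labels = labels,
                 motherGenotyped = motherG, fatherGenotyped = fatherG,
                 offMats = offMats, parMats = parMats, map = map),
            class = "TileAssignment")
}

#' @method print TileAssignment
#' @export
print.TileAssignment <- function(x, ...) {
  cat(sprintf("TileAssignment: %d offspring x %d tiles (tau = %.2f)\n",
              length(x$offspring), nrow(x$tiles), x$tau))
  invisible(x)
}

## Fill NA runs in a per-tile label vector where flanks agree; edge runs
## inherit their single flank.
.fillUnresolved <- function(lab) {
  if (all(is.na(lab)) || !anyNA(lab)) return(lab)
  r <- rle(is.na(lab))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    left <- if (starts[k] > 1L) lab[starts[k] - 1L] else NA_integer_
    right <- if (ends[k] < length(lab)) lab[ends[k] + 1L] else NA_integer_
    fill <- NA_integer_
    if (!is.na(left) && !is.na(right)) {
      if (left == right) fill <- left
    } else if (!is.na(left)) fill <- left
    else if (!is.na(right)) fill <- right
    if (!is.na(fill)) lab[starts[k]:ends[k]] <- fill
  }
  lab
}

#' Resolve transmission from tile assignments
#'
#' Three stages: (i) a genome-wide vote assigns each offspring haplotype to
#' the parent (mother/father) minimizing its total mismatch count, enforcing
#' one maternal and one paternal haplotype in trios (both haplotypes voting
#' for the same parent flags the offspring and excludes it); in pairs the
#' closer haplotype gets the genotyped parent and the other is labeled
#' `missing_parent`. (ii) Within the assigned parent, per-tile labels pick
#' the closer of the parent's two haplotypes (continuity tie-break, `tau`
#' threshold); label switches between adjacent same-parent tiles imply a
#' crossover whose breakpoint is refined to the marker minimizing the
#' cumulative left+right mismatch across the switch region. Unresolved
#' tiles inherit the flanking consensus when flanks agree, else their
#' markers are set missing. (iii) Per marker, the transmitted allele is the
#' parent's source-haplotype allele and the non-transmitted allele the
#' parent's other haplotype's allele; for an ungenotyped parent the
#' transmitted allele is read off the offspring haplotype and the
#' non-transmitted allele is missing.
#'
#' @param assign a `"TileAssignment"` from [matchTiles()].
#' @return A [TransmissionMap-class].
#' @export
resolveTransmission <- function(assign) {
  stopifnot(inherits(assign, "TileAssignment"))
  tiles <- assign$tiles
  map <- assign$map
  offIds <- assign$offspring
  nOff <- length(offIds)
  nT <- nrow(tiles)
  M <- nMarkers(map)

  ## stage (i): genome-wide parent vote per offspring haplotype
  totByParent <- function(h, p12) {  # p12: c(1,2) mother or c(3,4) father
    pmin(rowSums(assign$mism[, , h, p12[1], drop = FALSE], na.rm = TRUE),
         rowSums(assign$mism[, , h, p12[2], drop = FALSE], na.rm = TRUE))
  }
  mTot <- cbind(totByParent(1, 1:2), totByParent(2, 1:2))
  fTot <- cbind(totByParent(1, 3:4), totByParent(2, 3:4))
  hapParent <- matrix("missing_parent", nOff, 2,
                      dimnames = list(offIds, NULL))
  excluded <- character(0)
  for (i in seq_len(nOff)) {
    mg <- assign$motherGenotyped[i]
    fg <- assign$fatherGenotyped[i]
    if (mg && fg) {
      v1 <- if (mTot[i, 1] <= fTot[i, 1]) "mother" else "father"
      v2 <- if (mTot[i, 2] <= fTot[i, 2]) "mother" else "father"
      if (v1 == v2) { excluded <- c(excluded, offIds[i]); next }
      hapParent[i, ] <- c(v1, v2)
    } else if (mg) {
      own <- if (mTot[i, 1] <= mTot[i, 2]) 1L else 2L
      hapParent[i, own] <- "mother"
    } else {
      own <- if (fTot[i, 1] <= fTot[i, 2]) 1L else 2L
      hapParent[i, own] <- "father"
    }
  }

  source1 <- matrix(NA_integer_, nOff, M, dimnames = list(offIds, map@markerId))
  source2 <- source1
  xo <- list(offspring = character(0), chrom = integer(0), hap = integer(0),
             breakpoint = integer(0))
  chromTiles <- split(seq_len(nT), tiles$chrom)

  for (i in seq_len(nOff)) {
    if (offIds[i] %in% excluded) next
    for (h in 1:2) {
      par <- hapParent[i, h]
      if (par == "missing_parent") next
      p12 <- if (par == "mother") 1:2 else 3:4
      ## restricted per-tile labels within the assigned parent
      misA <- assign$mism[i, , h, p12[1]]
      misB <- assign$mism[i, , h, p12[2]]
      den <- assign$valid[i, , h, p12[1]]
      fa <- misA / ifelse(den > 0, den, NA)
      fb <- misB / ifelse(den > 0, den, NA)
      lab <- rep(NA_integer_, nT)
      prev <- NA_integer_
      for (t in seq_len(nT)) {
        if (t > 1L && tiles$chrom[t] != tiles$chrom[t - 1L]) prev <- NA_integer_
        ok <- !is.na(fa[t]) && !is.na(fb[t])
        if (!ok) next
        if (min(fa[t], fb[t]) > assign$tau) next
        if (abs(fa[t] - fb[t]) <= 1e-12) {
          if (!is.na(prev)) lab[t] <- prev
        } else lab[t] <- if (fa[t] < fb[t]) p12[1] else p12[2]
        if (!is.na(lab[t])) prev <- lab[t]
      }
      offV <- assign$offMats[[h]][i, ]
      mismRegion <- function(p, region) {
        pa <- assign$parMats[[p]][i, region]
        ov <- offV[region]
        as.integer(!is.na(ov) & !is.na(pa) & ov != pa)
      }
      for (ct in chromTiles) {
        lc <- .fillUnresolved(lab[ct])
        ## expand to markers
        srcV <- rep(NA_integer_, M)
        for (k in seq_along(ct)) {
          t <- ct[k]
          if (!is.na(lc[k])) srcV[tiles$start[t]:tiles$end[t]] <- lc[k]
        }
        runs <- rle(lc)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        res <- which(!is.na(runs$values))
        ## crossover refinement between consecutive resolved runs (any
        ## still-unresolved tiles in between are absorbed into the scan)
        if (length(res) > 1L) {
          for (q in seq_len(length(res) - 1L)) {
            a <- runs$values[res[q]]
            b <- runs$values[res[q + 1L]]
            if (a == b) next
            tl <- ct[ends[res[q]]]           # last tile with label a
            tr <- ct[starts[res[q + 1L]]]    # first tile with label b
            region <- tiles$start[tl]:tiles$end[tr]
            ma <- mismRegion(a, region)
            mb <- mismRegion(b, region)
            cost <- c(0, cumsum(ma)) + (sum(mb) - c(0, cumsum(mb)))
            k0 <- which.min(cost) - 1L       # markers 1..k0 keep label a
            if (k0 > 0L) srcV[region[seq_len(k0)]] <- a
            if (k0 < length(region)) srcV[region[(k0 + 1L):length(region)]] <- b
            xo$offspring <- c(xo$offspring, offIds[i])
            xo$chrom <- c(xo$chrom, tiles$chrom[tl])
            xo$hap <- c(xo$hap, h)
            xo$breakpoint <- c(xo$breakpoint, region[1] + k0)
          }
        }
        ## chromosome-edge scans: a crossover inside the first (last) tile
        ## leaves no flanking run boundary, so test a switch from (to) the
        ## parent's other haplotype within that tile
        if (length(res)) {
          other <- function(p) if (p == p12[1]) p12[2] else p12[1]
          t1 <- ct[1L]
          a <- lc[1L]
          if (!is.na(a)) {
            region <- tiles$start[t1]:tiles$end[t1]
            cur <- srcV[region]
            if (all(cur == a, na.rm = TRUE)) {   # not already refined
              mo <- mismRegion(other(a), region)
              ma <- mismRegion(a, region)
              cost <- c(0, cumsum(mo)) + (sum(ma) - c(0, cumsum(ma)))
              k0 <- which.min(cost) - 1L   # markers 1..k0 from the other hap
              if (k0 > 0L) {
                srcV[region[seq_len(k0)]] <- other(a)
                xo$offspring <- c(xo$offspring, offIds[i])
                xo$chrom <- c(xo$chrom, tiles$chrom[t1])
                xo$hap <- c(xo$hap, h)
                xo$breakpoint <- c(xo$breakpoint, region[1] + k0)
              }
            }
          }
          tn <- ct[length(ct)]
          a <- lc[length(ct)]
          if (!is.na(a)) {
            region <- tiles$start[tn]:tiles$end[tn]
            cur <- srcV[region]
            if (all(cur == a, na.rm = TRUE)) {
              ma <- mismRegion(a, region)
              mo <- mismRegion(other(a), region)
              cost <- c(0, cumsum(ma)) + (sum(mo) - c(0, cumsum(mo)))
              mn <- min(cost)
              k0 <- max(which(cost == mn)) - 1L  # prefer no trailing switch
              if (k0 < length(region)) {
                srcV[region[(k0 + 1L):length(region)]] <- other(a)
                xo$offspring <- c(xo$offspring, offIds[i])
                xo$chrom <- c(xo$chrom, tiles$chrom[tn])
                xo$hap <- c(xo$hap, h)
                xo$breakpoint <- c(xo$breakpoint, region[1] + k0)
              }
            }
          }
        }
        ## within-run double-crossover scan: two switches inside one tile
        ## (or straddling an adjacent tile pair) leave no run boundary, so
        ## test an interior segment copied from the parent's other
        ## haplotype, accepting it only if it removes >= 2 mismatches
        if (length(res)) {
          other <- function(p) if (p == p12[1]) p12[2] else p12[1]
          for (q in res) {
            a <- runs$values[q]
            rT <- ct[starts[q]:ends[q]]
            wins <- if (length(rT) == 1L) list(rT) else
              lapply(seq_len(length(rT) - 1L), function(j) rT[j:(j + 1L)])
            for (w in wins) {
              region <- tiles$start[w[1]]:tiles$end[w[length(w)]]
              if (!all(srcV[region] == a, na.rm = TRUE)) next
              len <- length(region)
              if (len < 4L) next
              ma <- mismRegion(a, region)
              if (sum(ma) < 2L) next
              mo <- mismRegion(other(a), region)
              f <- c(0, cumsum(ma)) - c(0, cumsum(mo))
              lead <- f[2:(len - 1L)]            # candidate segment starts
              cm <- cummin(lead)
              imp <- cm[seq_len(len - 2L)] - f[3:len]
              if (min(imp) <= -2) {
                i2 <- which.min(imp) + 2L
                i1 <- which.min(f[2:(i2 - 1L)]) + 1L
                seg <- region[i1:(i2 - 1L)]
                srcV[seg] <- other(a)
                xo$offspring <- c(xo$offspring, rep(offIds[i], 2L))
                xo$chrom <- c(xo$chrom, rep(tiles$chrom[w[1]], 2L))
                xo$hap <- c(xo$hap, rep(h, 2L))
                xo$breakpoint <- c(xo$breakpoint, region[i1], region[i2])
              }
            }
          }
        }
        ci <- tiles$start[ct[1]]:tiles$end[ct[length(ct)]]
        if (h == 1) source1[i, ci] <- srcV[ci] else source2[i, ci] <- srcV[ci]
      }
    }
  }

  ## stage (iii): transmitted / non-transmitted alleles per parent
  tM <- matrix(NA_integer_, nOff, M, dimnames = list(offIds, map@markerId))
  tP <- tM; ntM <- tM; ntP <- tM
  pm <- assign$parMats
  for (h in 1:2) {
    src <- if (h == 1) source1 else source2
    offH <- assign$offMats[[h]]
    isMat <- hapParent[, h] == "mother"
    isPat <- hapParent[, h] == "father"
    isMiss <- hapParent[, h] == "missing_parent"
    ## genotyped parent: transmitted = source-haplotype allele,
    ## non-transmitted = the parent's other haplotype's allele
    sel1 <- src == 1L; sel2 <- src == 2L
    sel3 <- src == 3L; sel4 <- src == 4L
    tM[isMat, ] <- ifelse(sel1[isMat, , drop = FALSE], pm[[1]][isMat, , drop = FALSE],
                   ifelse(sel2[isMat, , drop = FALSE], pm[[2]][isMat, , drop = FALSE], NA_integer_))
    ntM[isMat, ] <- ifelse(sel1[isMat, , drop = FALSE], pm[[2]][isMat, , drop = FALSE],
                    ifelse(sel2[isMat, , drop = FALSE], pm[[1]][isMat, , drop = FALSE], NA_integer_))
    tP[isPat, ] <- ifelse(sel3[isPat, , drop = FALSE], pm[[3]][isPat, , drop = FALSE],
                   ifelse(sel4[isPat, , drop = FALSE], pm[[4]][isPat, , drop = FALSE], NA_integer_))
    ntP[isPat, ] <- ifelse(sel3[isPat, , drop = FALSE], pm[[4]][isPat, , drop = FALSE],
                    ifelse(sel4[isPat, , drop = FALSE], pm[[3]][isPat, , drop = FALSE], NA_integer_))
    ## ungenotyped parent: transmitted read off the offspring haplotype
    if (any(isMiss)) {
      motherMissing <- isMiss & !assign$motherGenotyped
      fatherMissing <- isMiss & !assign$fatherGenotyped
      tM[motherMissing, ] <- offH[motherMissing, , drop = FALSE]
      tP[fatherMissing, ] <- offH[fatherMissing, , drop = FALSE]
    }
  }
  if (length(excluded)) {
    tM[excluded, ] <- NA_integer_; tP[excluded, ] <- NA_integer_
    ntM[excluded, ] <- NA_integer_; ntP[excluded, ] <- NA_integer_
  }
  unres <- rowMeans(is.na(source1) & is.na(source2)) # both haps unresolved
  names(unres) <- offIds

  new("TransmissionMap", offspring = offIds,
      source1 = source1, source2 = source2, hapParent = hapParent,
      tMaternal = tM, tPaternal = tP, ntMaternal = ntM, ntPaternal = ntP,
      crossovers = as.data.frame(xo, stringsAsFactors = FALSE),
      unresolvedFrac = unres, excluded = excluded, map = map)
}

#' Infer transmission end-to-end
#'
#' Convenience wrapper: [makeTiles()] + [matchTiles()] +
#' [resolveTransmission()].
#'
#' @inheritParams matchTiles
#' @return A [TransmissionMap-class].
#' @export
inferTransmission <- function(haps, pedigree, tileSize = 150L, tau = 0.1) {
  resolveTransmission(matchTiles(haps, pedigree, tileSize = tileSize,
                                 tau = tau))
}

#' Concordance of inferred vs true non-transmitted alleles
#'
#' Fraction of non-missing inferred non-transmitted alleles equal to the
#' simulation truth, overall and per parent role (and per chromosome).
#'
#' @param inferred a [TransmissionMap-class].
#' @param truth the matching [TransmissionTruth-class].
#' @param haps the complete (unmasked) [HaplotypeSet-class] holding the
#'   true parental haplotypes.
#' @param pedigree pedigree data.frame (pre-masking roles are used to find
#'   each offspring's parents).
#' @return list: `overall` concordance in `[0, 1]`, `byParent`,
#'   `byChromosome`, `nCompared`.
#' @export
concordance <- function(inferred, truth, haps, pedigree) {
  off <- pedigree[pedigree$role == "offspring", ]
  ids <- intersect(inferred@offspring, off$individual_id)
  if (!length(ids)) stop("no shared offspring between inference and truth")
  off <- off[match(ids, off$individual_id), ]
  map <- inferred@map
  src <- truthSourceMatrices(truth, map, ids)
  mo1 <- haps@hap1[off$mother_id, , drop = FALSE]
  mo2 <- haps@hap2[off$mother_id, , drop = FALSE]
  fa1 <- haps@hap1[off$father_id, , drop = FALSE]
  fa2 <- haps@hap2[off$father_id, , drop = FALSE]
  trueNtM <- ifelse(src$src1 == 1L, mo2, mo1)
  trueNtP <- ifelse(src$src2 == 3L, fa2, fa1)
  infM <- inferred@ntMaternal[ids, , drop = FALSE]
  infP <- inferred@ntPaternal[ids, , drop = FALSE]
  okM <- !is.na(infM)
  okP <- !is.na(infP)
  if (!any(okM) && !any(okP)) stop("no resolved non-transmitted alleles")
  eqM <- infM == trueNtM
  eqP <- infP == trueNtP
  byChrom <- vapply(unique(map@chrom), function(ch) {
    ix <- map@chrom == ch
    (sum(eqM[, ix][okM[, ix]]) + sum(eqP[, ix][okP[, ix]])) /
      max(1L, sum(okM[, ix]) + sum(okP[, ix]))
  }, numeric(1))
  list(
    overall = (sum(eqM[okM]) + sum(eqP[okP])) / (sum(okM) + sum(okP)),
    byParent = c(mother = sum(eqM[okM]) / max(1L, sum(okM)),
                 father = sum(eqP[okP]) / max(1L, sum(okP))),
    byChromosome = setNames(byChrom, unique(map@chrom)),
    nCompared = sum(okM) + sum(okP))
}
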