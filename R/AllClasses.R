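#' @import methods
#' @importFrom stats rbinom rpois rnorm runif complete.cases lm lm.fit resid
#'   sd var cov cor pnorm qnorm pchisq pt p.adjust optim rmultinom quantile
#'   as.formula model.matrix setNames binomial gaussian coef vcov na.omit
#' @importFrom utils read.table write.table head
NULL

## ---------------------------------------------------------------------------
## VariantMap: the marker scaffold shared by all haplotype containers
## ---------------------------------------------------------------------------

#' VariantMap: biallelic marker scaffold
#'
#' Ordered table of biallelic markers with chromosome, physical position (bp)
#' and genetic position (cM). Both position columns must be strictly
#' increasing within each chromosome; alleles are single characters. All
#' haplotype containers in the package are indexed against a `VariantMap`.
#'
#' @slot markerId character vector of unique marker names.
#' @slot chrom integer chromosome label per marker (markers grouped by
#'   chromosome, in order).
#' @slot physPos numeric physical positions in base pairs.
#' @slot geneticPos numeric genetic positions in centimorgans.
#' @slot ref,alt single-character reference / alternate alleles.
#'
#' @export
setClass("VariantMap",
  representation(
    markerId   = "character",
    chrom      = "integer",
    physPos    = "numeric",
    geneticPos = "numeric",
    ref        = "character",
    alt        = "character"
  )
)

setValidity("VariantMap", function(object) {
  n <- length(object@markerId)
  msg <- character()
  lens <- c(length(object@chrom), length(object@physPos),
            length(object@geneticPos), length(object@ref), length(object@alt))
  if (any(lens != n))
    msg <- c(msg, "all slots must have one entry per marker")
  if (anyDuplicated(object@markerId))
    msg <- c(msg, "marker ids must be unique")
  if (n > 0 && length(msg) == 0L) {
    if (is.unsorted(object@chrom))
      msg <- c(msg, "markers must be grouped by chromosome in ascending order")
    for (ch in unique(object@chrom)) {
      i <- object@chrom == ch
      if (any(diff(object@physPos[i]) <= 0))
        msg <- c(msg, sprintf("physical positions not strictly increasing on chromosome %d", ch))
      if (any(diff(object@geneticPos[i]) <= 0))
        msg <- c(msg, sprintf("genetic positions not strictly increasing on chromosome %d", ch))
    }
    if (any(nchar(object@ref) != 1L) || any(nchar(object@alt) != 1L))
      msg <- c(msg, "ref/alt alleles must be single characters (biallelic SNPs)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VariantMap
#'
#' @param markerId character marker names (unique).
#' @param chrom integer-like chromosome labels.
#' @param physPos physical positions (bp), strictly increasing per chromosome.
#' @param geneticPos genetic positions (cM), strictly increasing per
#'   chromosome.
#' @param ref,alt single-character alleles; defaults `"A"`/`"G"`.
#' @return A [VariantMap-class] object.
#' @export
VariantMap <- function(markerId, chrom, physPos, geneticPos,
                       ref = rep("A", length(markerId)),
                       alt = rep("G", length(markerId))) {
  new("VariantMap", markerId = as.character(markerId),
      chrom = as.integer(chrom), physPos = as.numeric(physPos),
      geneticPos = as.numeric(geneticPos),
      ref = as.character(ref), alt = as.character(alt))
}

#' Number of markers in a map or haplotype set
#' @param x a `VariantMap` or `HaplotypeSet`.
#' @return integer count of markers.
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname nMarkers
#' @export
setMethod("nMarkers", "VariantMap", function(x) length(x@markerId))

#' Chromosome labels of a VariantMap
#' @param x a `VariantMap`.
#' @return integer vector, one label per marker.
#' @export
chromOf <- function(x) {
  stopifnot(is(x, "VariantMap"))
  x@chrom
}

#' Marker ids of a VariantMap
#' @param x a `VariantMap`.
#' @return character vector of marker names.
#' @export
markerIds <- function(x) {
  stopifnot(is(x, "VariantMap"))
  x@markerId
}

setMethod("show", "VariantMap", function(object) {
  cat(sprintf("VariantMap: %d markers on %d chromosome(s)\n",
              nMarkers(object), length(unique(object@chrom))))
})

## ---------------------------------------------------------------------------
## HaplotypeSet: phased biallelic alleles per person
## ---------------------------------------------------------------------------

#' HaplotypeSet: phased biallelic haplotypes
#'
#' Phased alternate-allele indicators for a set of people: two
#' persons-by-markers matrices (`hap1`, `hap2`), entries 0/1 or `NA` for
#' missing calls. For simulated offspring, haplotype 1 is the maternal gamete
#' and haplotype 2 the paternal gamete before any phase errors are injected.
#'
#' @slot hap1,hap2 integer matrices (persons x markers) of alt-allele
#'   dosage per haplotype; rownames are person ids.
#' @slot map the [VariantMap-class] the columns are indexed against.
#' @slot phaseKnown named logical: whether each person's phase is trusted.
#' @export
setClass("HaplotypeSet",
  representation(
    hap1 = "matrix",
    hap2 = "matrix",
    map = "VariantMap",
    phaseKnown = "logical"
  )
)

setValidity("HaplotypeSet", function(object) {
  msg <- character()
  if (!identical(dim(object@hap1), dim(object@hap2)))
    msg <- c(msg, "hap1 and hap2 must have identical dimensions")
  if (ncol(object@hap1) != nMarkers(object@map))
    msg <- c(msg, "number of columns must equal the number of map markers")
  if (is.null(rownames(object@hap1)))
    msg <- c(msg, "hap matrices must carry person ids as rownames")
  bad <- function(m) any(!(m %in% c(0L, 1L, NA_integer_)))
  if (length(msg) == 0L && (bad(object@hap1) || bad(object@hap2)))
    msg <- c(msg, "haplotype entries must be 0, 1 or NA")
  if (length(object@phaseKnown) != nrow(object@hap1))
    msg <- c(msg, "phaseKnown must have one entry per person")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypeSet
#' @param hap1,hap2 integer matrices (persons x markers) with person-id
#'   rownames; entries 0/1/NA.
#' @param map the [VariantMap-class] for the columns.
#' @param phaseKnown logical per person (default all `TRUE`).
#' @return A [HaplotypeSet-class].
#' @export
HaplotypeSet <- function(hap1, hap2, map, phaseKnown = rep(TRUE, nrow(hap1))) {
  storage.mode(hap1) <- "integer"
  storage.mode(hap2) <- "integer"
  names(phaseKnown) <- rownames(hap1)
  new("HaplotypeSet", hap1 = hap1, hap2 = hap2, map = map,
      phaseKnown = phaseKnown)
}

#' @rdname nMarkers
#' @export
setMethod("nMarkers", "HaplotypeSet", function(x) nMarkers(x@map))

#' Person ids of a container
#' @param x a `HaplotypeSet` or `TransmissionMap`.
#' @return character vector of individual ids.
#' @export
setGeneric("persons", function(x) standardGeneric("persons"))

#' @rdname persons
#' @export
setMethod("persons", "HaplotypeSet", function(x) rownames(x@hap1))

#' Genotype dosage matrix
#'
#' Alt-allele dosage (0/1/2, `NA` where either haplotype call is missing).
#' @param x a `HaplotypeSet`.
#' @param ids optional subset of person ids.
#' @return integer matrix persons x markers.
#' @export
dosage <- function(x, ids = persons(x)) {
  stopifnot(is(x, "HaplotypeSet"))
  x@hap1[ids, , drop = FALSE] + x@hap2[ids, , drop = FALSE]
}

#' Extract haplotype matrices
#' @param x a `HaplotypeSet`.
#' @param which 1 or 2.
#' @param ids optional subset of person ids.
#' @return integer matrix persons x markers.
#' @export
haps <- function(x, which = 1, ids = persons(x)) {
  stopifnot(is(x, "HaplotypeSet"), which %in% c(1, 2))
  if (which == 1) x@hap1[ids, , drop = FALSE] else x@hap2[ids, , drop = FALSE]
}

setMethod("show", "HaplotypeSet", function(object) {
  cat(sprintf("HaplotypeSet: %d persons x %d markers (%d chromosome(s))\n",
              nrow(object@hap1), nMarkers(object),
              length(unique(object@map@chrom))))
})

## ---------------------------------------------------------------------------
## TransmissionTruth: simulator ground truth for every meiosis
## ---------------------------------------------------------------------------

#' TransmissionTruth: simulated meiosis ground truth
#'
#' Segment table recording, per offspring, gamete (1 = maternal, 2 =
#' paternal) and chromosome, which parental haplotype
#' (`mat1`/`mat2`/`pat1`/`pat2`) each marker segment was copied from.
#' Segments partition each chromosome; columns `start`/`end` are global
#' marker indices (1-based, inclusive).
#'
#' @slot segments data.frame with columns `offspring`, `chrom`, `hap`,
#'   `start`, `end`, `source`.
#' @export
setClass("TransmissionTruth", representation(segments = "data.frame"))

setValidity("TransmissionTruth", function(object) {
  seg <- object@segments
  need <- c("offspring", "chrom", "hap", "start", "end", "source")
  if (!all(need %in% names(seg)))
    return(paste("segments must have columns", paste(need, collapse = ", ")))
  if (nrow(seg) && !all(seg$source %in% c("mat1", "mat2", "pat1", "pat2")))
    return("source labels must be mat1/mat2/pat1/pat2")
  if (nrow(seg) && any(seg$end < seg$start))
    return("segment end must be >= start")
  ## adjacent segments of the same gamete must switch haplotype label
  key <- interaction(seg$offspring, seg$chrom, seg$hap, drop = TRUE)
  for (k in split(seq_len(nrow(seg)), key)) {
    o <- k[order(seg$start[k])]
    if (length(o) > 1L) {
      if (any(seg$start[o][-1] != seg$end[o][-length(o)] + 1L))
        return("segments must partition each chromosome without gaps")
      if (any(seg$source[o][-1] == seg$source[o][-length(o)]))
        return("adjacent segments of one gamete must differ in source haplotype")
    }
  }
  TRUE
})

setMethod("show", "TransmissionTruth", function(object) {
  seg <- object@segments
  cat(sprintf("TransmissionTruth: %d segments, %d offspring\n",
              nrow(seg), length(unique(seg$offspring))))
})

## ---------------------------------------------------------------------------
## TransmissionMap: inferred per-marker transmission + non-transmitted alleles
## ---------------------------------------------------------------------------

#' TransmissionMap: inferred transmission and non-transmitted alleles
#'
#' Result of [resolveTransmission()]: per offspring and marker, the inferred
#' source haplotype of each offspring haplotype (codes 1:4 =
#' mat1/mat2/pat1/pat2, `NA` = unresolved or missing parent), transmitted and
#' non-transmitted allele matrices per parent, inferred crossovers, and
#' offspring excluded for vote conflicts. Non-transmitted alleles of an
#' ungenotyped parent are all `NA`.
#'
#' @slot offspring character ids (rownames of all matrices).
#' @slot source1,source2 integer matrices offspring x markers, source codes.
#' @slot hapParent character matrix offspring x 2: which parent each
#'   offspring haplotype was voted to (`"mother"`, `"father"`,
#'   `"missing_parent"`).
#' @slot tMaternal,tPaternal,ntMaternal,ntPaternal integer matrices of
#'   transmitted / non-transmitted alleles (0/1/NA).
#' @slot crossovers data.frame: `offspring`, `chrom`, `hap`, `breakpoint`
#'   (global index of the first marker after the inferred crossover).
#' @slot unresolvedFrac named numeric, fraction of markers unresolved per
#'   offspring.
#' @slot excluded character ids of offspring dropped with a diagnostic.
#' @slot map the shared [VariantMap-class].
#' @export
setClass("TransmissionMap",
  representation(
    offspring = "character",
    source1 = "matrix", source2 = "matrix",
    hapParent = "matrix",
    tMaternal = "matrix", tPaternal = "matrix",
    ntMaternal = "matrix", ntPaternal = "matrix",
    crossovers = "data.frame",
    unresolvedFrac = "numeric",
    excluded = "character",
    map = "VariantMap"
  )
)

setValidity("TransmissionMap", function(object) {
  n <- length(object@offspring)
  m <- nMarkers(object@map)
  mats <- list(object@source1, object@source2, object@tMaternal,
               object@tPaternal, object@ntMaternal, object@ntPaternal)
  if (!all(vapply(mats, function(x) identical(dim(x), c(n, m)), logical(1))))
    return("all per-marker matrices must be offspring x markers")
  al <- c(object@tMaternal, object@tPaternal, object@ntMaternal, object@ntPaternal)
  if (!all(al %in% c(0L, 1L, NA_integer_)))
    return("allele matrices must contain 0, 1 or NA")
  ok <- c("mother", "father", "missing_parent")
  if (!all(object@hapParent %in% ok))
    return("hapParent entries must be mother/father/missing_parent")
  TRUE
})

#' @rdname persons
#' @export
setMethod("persons", "TransmissionMap", function(x) x@offspring)

setMethod("show", "TransmissionMap", function(object) {
  cat(sprintf(paste0(
    "TransmissionMap: %d offspring x %d markers\n",
    "  inferred crossovers: %d; excluded offspring: %d\n",
    "  mean unresolved fraction: %.4f\n"),
    length(object@offspring), nMarkers(object@map),
    nrow(object@crossovers), length(object@excluded),
    mean(object@unresolvedFrac)))
})

#' Non-transmitted allele matrix for one parent
#' @param x a `TransmissionMap`.
#' @param parent `"mother"` or `"father"`.
#' @return integer matrix offspring x markers (0/1/NA).
#' @export
nonTransmitted <- function(x, parent = c("mother", "father")) {
  stopifnot(is(x, "TransmissionMap"))
  parent <- match.arg(parent)
  if (parent == "mother") x@ntMaternal else x@ntPaternal
}

#' Transmitted allele matrix for one parent
#' @inheritParams nonTransmitted
#' @return integer matrix offspring x markers (0/1/NA).
#' @export
transmitted <- function(x, parent = c("mother", "father")) {
  stopifnot(is(x, "TransmissionMap"))
  parent <- match.arg(parent)
  if (parent == "mother") x@tMaternal else x@tPaternal
}
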