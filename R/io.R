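## Text-format interfaces: phased VCF, PED-like pedigree TSV, PRS weight
## tables, phenotype TSV, and truth segment tables.

#' Write a HaplotypeSet as a phased VCF
#'
#' Plain-text VCF v4.2 with phased GT fields (`0|1`; missing calls
#' `.|.`) and the genetic position stored in `INFO/CM`.
#'
#' @param haps a [HaplotypeSet-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writePhasedVcf <- function(haps, file) {
  map <- haps@map
  ids <- persons(haps)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic position in cM\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")), con)
  h1 <- t(haps@hap1)  # markers x persons
  h2 <- t(haps@hap2)
  gt <- matrix(paste0(ifelse(is.na(h1), ".", h1), "|",
                      ifelse(is.na(h2), ".", h2)),
               nrow = nrow(h1))
  fixed <- paste(map@chrom, map@physPos, map@markerId, map@ref, map@alt,
                 ".", "PASS", sprintf("CM=%g", map@geneticPos), "GT",
                 sep = "\t")
  writeLines(paste(fixed, apply(gt, 1, paste, collapse = "\t"), sep = "\t"),
             con)
  invisible(file)
}

#' Read a phased VCF into a HaplotypeSet
#'
#' Uses `vcfR` to parse the file; genotypes must be phased (`|` separator).
#' Genetic positions are taken from `INFO/CM` when present, else derived
#' from physical position at 1 cM/Mb.
#'
#' @param file path to a (plain or gzipped) VCF.
#' @return a [HaplotypeSet-class].
#' @export
readPhasedVcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  cm <- suppressWarnings(as.numeric(vcfR::extract.info(v, "CM")))
  if (all(is.na(cm))) cm <- as.numeric(fix[, "POS"]) / 1e6
  map <- VariantMap(markerId = fix[, "ID"], chrom = as.integer(fix[, "CHROM"]),
                    physPos = as.numeric(fix[, "POS"]),
                    geneticPos = cm, ref = fix[, "REF"], alt = fix[, "ALT"])
  gt <- vcfR::extract.gt(v)
  if (any(grepl("/", gt, fixed = TRUE), na.rm = TRUE))
    stop("unphased genotypes found; phased GT ('0|1') required")
  splitAllele <- function(k) {
    a <- substr(gt, k, k)
    a[a == "."] <- NA
    m <- matrix(as.integer(a), nrow = nrow(gt))
    dimnames(m) <- dimnames(gt)
    t(m)
  }
  HaplotypeSet(splitAllele(1L), splitAllele(3L), map)
}

#' Write / read a PED-like pedigree TSV
#'
#' Columns `FID`, `IID`, `PAT`, `MAT`, `SEX` (1 = male, 2 = female),
#' `GENOTYPED` (0/1), `ROLE`; missing parents coded `0`.
#'
#' @param pedigree pedigree data.frame.
#' @param file path.
#' @return `file` invisibly (write) or the pedigree data.frame (read).
#' @export
writePedigree <- function(pedigree, file) {
  validatePedigree(pedigree)
  out <- data.frame(
    FID = pedigree$family_id, IID = pedigree$individual_id,
    PAT = ifelse(is.na(pedigree$father_id), "0", pedigree$father_id),
    MAT = ifelse(is.na(pedigree$mother_id), "0", pedigree$mother_id),
    SEX = ifelse(pedigree$sex == "male", 1L, 2L),
    GENOTYPED = as.integer(pedigree$genotyped),
    ROLE = pedigree$role)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writePedigree
#' @export
readPedigree <- function(file) {
  d <- read.table(file, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE,
                  colClasses = c(FID = "character", IID = "character",
                                 PAT = "character", MAT = "character"))
  ped <- data.frame(
    family_id = d$FID, individual_id = d$IID,
    father_id = ifelse(d$PAT == "0", NA_character_, d$PAT),
    mother_id = ifelse(d$MAT == "0", NA_character_, d$MAT),
    sex = ifelse(d$SEX == 1L, "male", "female"),
    genotyped = d$GENOTYPED == 1L,
    role = d$ROLE, stringsAsFactors = FALSE)
  validatePedigree(ped)
  ped
}

#' Read / write a PRS weight table
#'
#' Tab-separated with columns `marker_id`, `effect_allele`, `weight` (and
#' optionally `trait`) -- the common PRS weight-file shape.
#'
#' @param file path.
#' @param weights weight data.frame.
#' @return the weight data.frame (read) or `file` invisibly (write).
#' @export
readWeights <- function(file) {
  w <- read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("marker_id", "effect_allele", "weight")
  if (!all(need %in% names(w)))
    stop("weight table must have columns ", paste(need, collapse = ", "))
  w
}

#' @rdname readWeights
#' @export
writeWeights <- function(weights, file) {
  write.table(weights, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write truth segments as a TSV
#'
#' Compact segment table (`offspring`, `chrom`, `hap`, `start`, `end`,
#' `source`) mirroring [TransmissionTruth-class].
#'
#' @param truth a [TransmissionTruth-class].
#' @param file path.
#' @return `file`, invisibly.
#' @export
writeTruthSegments <- function(truth, file) {
  write.table(truth@segments, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname writeTruthSegments
#' @export
readTruthSegments <- function(file) {
  seg <- read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  new("TransmissionTruth", segments = seg)
}
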