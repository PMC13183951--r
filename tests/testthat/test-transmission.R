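## helpers to build tiny deterministic families
.uniformMap <- function(m, nChrom = 1) {
  chrom <- rep(seq_len(nChrom), each = m)
  VariantMap(sprintf("c%d_s%d", chrom, rep(seq_len(m), nChrom)), chrom,
             rep(seq_len(m) * 1000L, nChrom), rep(seq_len(m) * 1.0, nChrom))
}

.trioPedigree <- function(fatherGenotyped = TRUE, motherGenotyped = TRUE) {
  data.frame(
    family_id = "F1",
    individual_id = c("M", "P", "O"),
    father_id = c(NA, NA, "P"), mother_id = c(NA, NA, "M"),
    sex = c("female", "male", "female"),
    genotyped = c(motherGenotyped, fatherGenotyped, TRUE),
    role = c("mother", "father", "offspring"), stringsAsFactors = FALSE)
}

test_that("makeTiles partitions chromosomes with remainder merging", {
  t1 <- makeTiles(.uniformMap(450), 150)
  expect_equal(nrow(t1), 3L)
  expect_equal(t1$end - t1$start + 1L, c(150L, 150L, 150L))
  t2 <- makeTiles(.uniformMap(460), 150)
  expect_equal(t2$end - t2$start + 1L, c(150L, 150L, 160L))
  expect_warning(t3 <- makeTiles(.uniformMap(149), 150), "single tile")
  expect_equal(nrow(t3), 1L)
  expect_equal(t3$end - t3$start + 1L, 149L)
  ## two chromosomes tile independently, global indices contiguous
  t4 <- makeTiles(.uniformMap(300, nChrom = 2), 150)
  expect_equal(t4$start, c(1L, 151L, 301L, 451L))
  expect_error(makeTiles(.uniformMap(10), 1), "tileSize")
})

test_that("an error-free trio without recombination resolves perfectly", {
  co <- smallTrioCohort(seed = 21, nFamilies = 15, nMarkers = 450,
                        nChrom = 1, crossoverRate = 0)
  ta <- matchTiles(co$haps, co$pedigree)
  tm <- resolveTransmission(ta)
  ## every assigned tile has zero mismatches for its chosen label
  expect_equal(length(tm@excluded), 0L)
  expect_equal(mean(tm@unresolvedFrac), 0)
  expect_equal(nrow(tm@crossovers), 0L)
  ## labels constant per chromosome: sources take a single value per row
  expect_true(all(apply(tm@source1, 1, function(s) length(unique(s)) == 1L)))
  cc <- concordance(tm, co$truth, co$hapsTrue, co$pedigree)
  expect_equal(cc$overall, 1.0)
})

test_that("a single crossover is localized to the true breakpoint", {
  m <- 600
  map <- .uniformMap(m)
  set.seed(22)
  mk <- function() rbinom(m, 1, runif(m, 0.2, 0.5))
  M1 <- mk(); M2 <- mk(); P1 <- mk(); P2 <- mk()
  ## maternal gamete: M1 up to marker 300, M2 after
  oh1 <- c(M1[1:300], M2[301:m])
  oh2 <- P1
  h1 <- rbind(M = M1, P = P1, O = oh1)
  h2 <- rbind(M = M2, P = P2, O = oh2)
  haps <- HaplotypeSet(h1, h2, map)
  ped <- .trioPedigree()
  tm <- inferTransmission(haps, ped, tileSize = 150)
  ## exactly one inferred crossover on the maternal haplotype, near 301
  xo <- tm@crossovers[tm@crossovers$hap == 1, ]
  expect_equal(nrow(xo), 1L)
  expect_lt(abs(xo$breakpoint - 301), 25)
  ## truth comparison: concordance 1 (ambiguity spans homozygous runs only)
  truth <- new("TransmissionTruth", segments = rbind(
    data.frame(offspring = "O", chrom = 1L, hap = 1L, start = 1L, end = 300L,
               source = "mat1", stringsAsFactors = FALSE),
    data.frame(offspring = "O", chrom = 1L, hap = 1L, start = 301L, end = m,
               source = "mat2", stringsAsFactors = FALSE),
    data.frame(offspring = "O", chrom = 1L, hap = 2L, start = 1L, end = m,
               source = "pat1", stringsAsFactors = FALSE)))
  cc <- concordance(tm, truth, haps, ped)
  expect_equal(cc$overall, 1.0)
})

test_that("a crossover inside a tile is assigned by mismatch minimization", {
  ## enumerate both single-tile assignments and check the argmin is chosen
  m <- 300
  map <- .uniformMap(m)
  set.seed(23)
  mk <- function() rbinom(m, 1, 0.4)
  M1 <- mk(); M2 <- mk(); P1 <- mk(); P2 <- mk()
  cut <- 180  # inside tile 2 (markers 151..300)
  oh1 <- c(M1[1:cut], M2[(cut + 1):m])
  haps <- HaplotypeSet(rbind(M = M1, P = P1, O = oh1),
                       rbind(M = M2, P = P2, O = P1), map)
  ta <- matchTiles(haps, .trioPedigree(), tileSize = 150, tau = 0.25)
  ## tile 2 mismatch counts against mat1 and mat2 for offspring hap 1
  misMat1 <- ta$mism["O", 2, 1, "mat1"]
  misMat2 <- ta$mism["O", 2, 1, "mat2"]
  expect_equal(unname(ta$labels["O", 2, 1]),
               which.min(c(misMat1, misMat2)))
  ## at the default tau the same tile (~50% crossover position) is close to
  ## the unresolved threshold; a stricter tau leaves it unresolved
  taStrict <- matchTiles(haps, .trioPedigree(), tileSize = 150, tau = 0.05)
  expect_true(is.na(taStrict$labels["O", 2, 1]))
})

test_that("pairs with one genotyped parent label the other haplotype missing", {
  co <- smallTrioCohort(seed = 24, nFamilies = 12, nMarkers = 450, nChrom = 1,
                        crossoverRate = 0.5)
  ped <- co$pedigree
  ped$genotyped[ped$role == "father"] <- FALSE
  tm <- inferTransmission(co$haps, ped)
  expect_true(all(tm@hapParent[, 1] == "mother"))
  expect_true(all(tm@hapParent[, 2] == "missing_parent"))
  ## non-transmitted alleles of the ungenotyped father are all missing
  expect_true(all(is.na(nonTransmitted(tm, "father"))))
  ## transmitted paternal alleles are read off the offspring haplotype
  off <- ped$individual_id[ped$role == "offspring"]
  expect_identical(transmitted(tm, "father"), co$haps@hap2[off, ])
  ## no genotyped parent at all errors out
  ped2 <- ped
  ped2$genotyped[ped2$role == "mother"] <- FALSE
  expect_error(matchTiles(co$haps, ped2), "genotyped parent")
})

test_that("transmitted + non-transmitted equals the parental dosage", {
  co <- smallTrioCohort(seed = 25, nFamilies = 25, nMarkers = 500, nChrom = 2,
                        crossoverRate = 1.5)
  tm <- inferTransmission(co$haps, co$pedigree)
  off <- co$pedigree[co$pedigree$role == "offspring", ]
  momDos <- dosage(co$haps, off$mother_id)
  dadDos <- dosage(co$haps, off$father_id)
  tMom <- transmitted(tm, "mother"); ntMom <- nonTransmitted(tm, "mother")
  ok <- !is.na(ntMom)
  expect_true(all((tMom + ntMom)[ok] == momDos[ok]))
  tDad <- transmitted(tm, "father"); ntDad <- nonTransmitted(tm, "father")
  ok <- !is.na(ntDad)
  expect_true(all((tDad + ntDad)[ok] == dadDos[ok]))
  ## homozygous parent: non-transmitted equals transmitted regardless of
  ## haplotype choice
  hom <- momDos %in% c(0L, 2L) & !is.na(ntMom)
  expect_true(all(ntMom[hom] == tMom[hom]))
})

test_that("masking one parent of a trio preserves the other parent's calls", {
  co <- smallTrioCohort(seed = 26, nFamilies = 30, nMarkers = 500, nChrom = 2,
                        crossoverRate = 1.5)
  tmTrio <- inferTransmission(co$haps, co$pedigree)
  ped <- co$pedigree
  ped$genotyped[ped$role == "father"] <- FALSE
  tmPair <- inferTransmission(co$haps, ped)
  bothResolved <- !is.na(tmTrio@ntMaternal) & !is.na(tmPair@ntMaternal)
  expect_gt(mean(bothResolved), 0.95)
  expect_true(all(tmTrio@ntMaternal[bothResolved] ==
                    tmPair@ntMaternal[bothResolved]))
})

test_that("concordance beats the frequency-matched random baseline", {
  co <- smallTrioCohort(seed = 27, nFamilies = 25, nMarkers = 500, nChrom = 1,
                        crossoverRate = 1.5)
  tm <- inferTransmission(co$haps, co$pedigree)
  cc <- concordance(tm, co$truth, co$hapsTrue, co$pedigree)
  ## random-guess oracle: picking a maternal haplotype uniformly at random
  ## is right whenever the mother is homozygous, else half the time
  off <- co$pedigree[co$pedigree$role == "offspring", ]
  momHet <- co$hapsTrue@hap1[off$mother_id, ] != co$hapsTrue@hap2[off$mother_id, ]
  chance <- mean(!momHet) + 0.5 * mean(momHet)
  set.seed(271)
  guess <- matrix(sample(1:2, length(momHet), replace = TRUE), nrow(momHet))
  src <- truthSourceMatrices(co$truth, co$map, off$individual_id)
  mo1 <- co$hapsTrue@hap1[off$mother_id, ]
  mo2 <- co$hapsTrue@hap2[off$mother_id, ]
  trueNt <- ifelse(src$src1 == 1L, mo2, mo1)
  guessNt <- ifelse(guess == 1L, mo2, mo1)
  randConc <- mean(guessNt == trueNt)
  expect_lt(abs(randConc - chance), 3 * sqrt(0.25 / length(momHet)) + 0.01)
  expect_gt(cc$overall, 0.99)
  expect_gt(cc$overall, randConc + 0.1)
})

test_that("concordance degrades monotonically with phase-error rate", {
  rates <- c(0, 0.001, 0.004)
  conc <- vapply(rates, function(r) {
    co <- smallTrioCohort(seed = 28, nFamilies = 30, nMarkers = 1000,
                          nChrom = 1, crossoverRate = 1, phaseErrorRate = r)
    tm <- inferTransmission(co$haps, co$pedigree)
    concordance(tm, co$truth, co$hapsTrue, co$pedigree)$overall
  }, numeric(1))
  expect_true(all(diff(conc) <= 0.005))
  expect_lt(conc[3], conc[1])
})

test_that("an unrelated 'offspring' cannot be resolved", {
  m <- 600
  map <- .uniformMap(m)
  set.seed(29)
  mk <- function() rbinom(m, 1, 0.5)
  haps <- HaplotypeSet(rbind(M = mk(), P = mk(), O = mk()),
                       rbind(M = mk(), P = mk(), O = mk()), map)
  ped <- .trioPedigree(fatherGenotyped = FALSE)
  tm <- inferTransmission(haps, ped, tau = 0.05)
  expect_true(all(is.na(nonTransmitted(tm, "mother")["O", ])) ||
                tm@unresolvedFrac["O"] > 0.5)
})
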