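test_that("founder allele frequencies match the sampled spectrum", {
  set.seed(1)
  p <- generativeParams(nFamilies = 1000, nMarkersPerChrom = 1000,
                        nChromosomes = 1, mafRange = c(0.5, 0.5))
  f <- simulateFounders(p)
  freq <- colMeans(rbind(f$haps@hap1, f$haps@hap2))
  sdBin <- sqrt(0.5 * 0.5 / (2 * 2 * 1000))
  expect_lt(max(abs(freq - 0.5)), 3 * sdBin + 3 * sdBin * 0.5)
  expect_true(all(abs(freq - 0.5) < 5 * sdBin))
})

test_that("same seed reproduces the cohort byte for byte", {
  p <- generativeParams(nFamilies = 30, nMarkersPerChrom = 200,
                        nChromosomes = 2, fractionTrios = 0.5, seed = 77)
  a <- simulateCohort(p)
  b <- simulateCohort(p)
  expect_identical(a$haps@hap1, b$haps@hap1)
  expect_identical(a$haps@hap2, b$haps@hap2)
  expect_identical(a$truth@segments, b$truth@segments)
  expect_identical(a$phenotypes, b$phenotypes)
})

test_that("founder genotypes are in Hardy-Weinberg equilibrium", {
  set.seed(2)
  p <- generativeParams(nFamilies = 2000, nMarkersPerChrom = 300,
                        nChromosomes = 1, mafRange = c(0.05, 0.5))
  f <- simulateFounders(p)
  dos <- dosage(f$haps)
  ## brute-force chi-square screen per marker against p^2 / 2pq / q^2
  pvals <- apply(dos, 2, function(g) {
    n <- length(g)
    q <- mean(g) / 2
    exp <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    obs <- tabulate(g + 1L, nbins = 3L)
    stat <- sum((obs - exp)^2 / exp)
    pchisq(stat, df = 1, lower.tail = FALSE)
  })
  ## ~0.1% failures expected at alpha = 0.001
  expect_lt(mean(pvals < 0.001), 0.01)
})

test_that("meiosis respects the crossover process", {
  ## zero rate: each offspring chromosome equals one intact parental haplotype
  p0 <- generativeParams(nFamilies = 15, nMarkersPerChrom = 300,
                         nChromosomes = 1, crossoverRate = 0,
                         sibFraction = 0, seed = 3)
  set.seed(3)
  f <- simulateFounders(p0)
  mm <- mateAndMeiose(f$haps, f$pedigree, p0)
  off <- f$pedigree[f$pedigree$role == "offspring", ]
  for (i in seq_len(nrow(off))) {
    h1 <- mm$haps@hap1[off$individual_id[i], ]
    m1 <- f$haps@hap1[off$mother_id[i], ]
    m2 <- f$haps@hap2[off$mother_id[i], ]
    expect_true(identical(h1, m1) || identical(h1, m2))
  }
  expect_true(all(table(mm$truth@segments$offspring) == 2L))

  ## Poisson moment check: mean crossovers per chromosome near the rate
  p1 <- generativeParams(nFamilies = 1250, nMarkersPerChrom = 250,
                         nChromosomes = 2, crossoverRate = 1.5,
                         sibFraction = 0, seed = 4)
  set.seed(4)
  f1 <- simulateFounders(p1)
  mm1 <- mateAndMeiose(f1$haps, f1$pedigree, p1)
  seg <- mm1$truth@segments
  nGam <- length(unique(seg$offspring)) * 2L * 2L  # 2 gametes x 2 chrom
  xo <- nrow(seg) - nGam
  ## crossovers landing between the same two markers cancel; the observable
  ## per-chromosome switch count is very slightly below the Poisson rate
  se <- sqrt(1.5 / nGam)
  expect_lt(abs(xo / nGam - 1.5), 3 * se + 0.02)
})

test_that("phenotypes reduce to the deterministic predictor without noise", {
  p <- generativeParams(nFamilies = 50, nMarkersPerChrom = 200,
                        nChromosomes = 1, sigmaFamily = 0, sigmaPerson = 0,
                        sigmaAgeSlope = 0, sigmaResid = 1e-12,
                        ageSlopeT = 0, ageSlopeNT = 0, bM = 0, bP = 0,
                        sibFraction = 0, seed = 5)
  co <- simulateCohort(p)
  w1 <- co$phenotypes[co$phenotypes$wave == 1, ]
  pred <- p$deltaDirect * w1$gen_score_t + p$betaNurture * w1$gen_score_nt
  expect_lt(max(abs(w1$y - pred)), 1e-6)
})

test_that("null nurture leaves the NT score uncorrelated with the outcome", {
  p <- generativeParams(nFamilies = 4000, betaNurture = 0, bM = 0, bP = 0,
                        amCorr = 0, sibFraction = 0, seed = 6)
  sc <- simulateScoreCohort(p)
  w1 <- sc$phenotypes[sc$phenotypes$wave == 1, ]
  r <- cor(w1$gen_score_nt, w1$y)
  expect_lt(abs(r), 3 / sqrt(nrow(w1)))
})

test_that("maskParents masks one parent of the right fraction of families", {
  p <- generativeParams(nFamilies = 3000, nMarkersPerChrom = 10,
                        nChromosomes = 1, sibFraction = 0, seed = 8)
  set.seed(8)
  f <- simulateFounders(p)
  ped <- maskParents(f$pedigree, fractionTrios = 0.17, seed = 9)
  fs <- familyStructure(ped)
  expect_lt(abs(mean(fs$structure == "trio") - 0.17),
            3 * sqrt(0.17 * 0.83 / 3000))
  ## audit: masked parents and genotyped parents are disjoint
  masked <- ped$individual_id[!ped$genotyped]
  expect_length(intersect(masked, ped$individual_id[ped$genotyped]), 0L)
  ## every masked family keeps exactly one genotyped parent
  par <- ped[ped$role != "offspring", ]
  kept <- tapply(par$genotyped, par$family_id, sum)
  expect_true(all(kept %in% c(1L, 2L)))
  ## identity and error cases
  expect_identical(maskParents(f$pedigree, 1), f$pedigree)
  expect_error(maskParents(f$pedigree, 1.2), "fractionTrios")
})

test_that("phase errors toggle haplotypes but never dosages", {
  p <- generativeParams(nFamilies = 100, nMarkersPerChrom = 2500,
                        nChromosomes = 2, sibFraction = 0, seed = 10)
  set.seed(10)
  f <- simulateFounders(p)
  expect_identical(injectPhaseErrors(f$haps, 0), f$haps)
  noisy <- injectPhaseErrors(f$haps, 0.001, seed = 11)
  expect_identical(dosage(noisy), dosage(f$haps))
  ## with ~Binomial(5000, 0.001) switches per person, roughly half of each
  ## chromosome-end haplotype ends up in the flipped state; flipped entries
  ## are visible at heterozygous markers (~38% here), so a sizable fraction
  ## of entries must differ while none of the dosages do
  flips <- rowMeans(noisy@hap1 != f$haps@hap1)
  expect_gt(mean(flips), 0.02)
  expect_lt(mean(flips), 0.5)
  expect_error(injectPhaseErrors(f$haps, 1.2), "rate")
})

test_that("no assortative mating means uncorrelated parental scores", {
  p <- generativeParams(nFamilies = 4000, amCorr = 0, sibFraction = 0,
                        seed = 12)
  sc <- simulateScoreCohort(p)
  s <- sc$scores
  trio <- !is.na(s$pgs_nt_maternal) & !is.na(s$pgs_nt_paternal)
  motherFull <- (s$pgs_t_maternal + s$pgs_nt_maternal)[trio]
  fatherFull <- (s$pgs_t_paternal + s$pgs_nt_paternal)[trio]
  expect_lt(abs(cor(motherFull, fatherFull)), 3 / sqrt(sum(trio)))
})

test_that("liability threshold yields the calibrated initiation prevalence", {
  p <- generativeParams(nFamilies = 6000, sibFraction = 0, seed = 13)
  sc <- simulateScoreCohort(p)
  w1 <- sc$phenotypes[sc$phenotypes$wave == 1, ]
  prev <- mean(w1$smoking_initiation)
  expect_lt(abs(prev - 0.414), 3 * sqrt(0.414 * 0.586 / nrow(w1)) + 0.005)
})

test_that("invalid generative parameters are rejected", {
  expect_error(generativeParams(mafRange = c(0, 0.5)), "mafRange")
  expect_error(generativeParams(mafRange = c(0.1, 0.6)), "mafRange")
  expect_error(generativeParams(nFamilies = 0), "positive")
  expect_error(generativeParams(fractionTrios = 2), "fractionTrios")
  expect_error(generativeParams(phaseErrorRate = 1), "phaseErrorRate")
  expect_error(generativeParams(sigmaFamily = -1), "non-negative")
})

test_that("offspring alleles always come from the designated parental haplotype", {
  co <- smallTrioCohort(seed = 14, nFamilies = 20, nMarkers = 300, nChrom = 2)
  src <- truthSourceMatrices(co$truth, co$map,
                             co$pedigree$individual_id[co$pedigree$role == "offspring"])
  off <- co$pedigree[co$pedigree$role == "offspring", ]
  hapOf <- function(code, i) {
    par <- if (code <= 2) off$mother_id[i] else off$father_id[i]
    h <- if (code %in% c(1, 3)) co$hapsTrue@hap1 else co$hapsTrue@hap2
    h[par, ]
  }
  for (i in seq_len(nrow(off))) {
    oh1 <- co$hapsTrue@hap1[off$individual_id[i], ]
    for (code in unique(src$src1[i, ])) {
      sel <- src$src1[i, ] == code
      expect_identical(oh1[sel], hapOf(code, i)[sel])
    }
  }
})
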