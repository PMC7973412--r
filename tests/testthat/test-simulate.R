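test_that("founder simulation respects SV carrier counts and determinism", {
  map <- tinyMap()
  svLoci <- data.frame(chrom = "A01", start = 4e6, end = 4e6 + 287,
                       svtype = "DEL", svlen = 288, nCarriers = 3)
  fs <- simulateFounders(7, map, svLoci, seed = 5)
  expect_s4_class(fs, "FounderSet")
  expect_identical(sum(svAlleles(fs)[1, ]), 3L)
  expect_true(all(founderHaplotypes(fs) %in% c(0L, 1L)))
  expect_identical(commonParent(fs), founderNames(fs)[1])

  fs2 <- simulateFounders(7, map, svLoci, seed = 5)
  expect_identical(fs, fs2)

  empty <- simulateFounders(2, map, seed = 5)
  expect_identical(nrow(svAlleles(empty)), 0L)
  expect_identical(length(svLoci(empty)), 0L)

  expect_error(
    simulateFounders(3, map, data.frame(chrom = "A01", start = 9e9,
                                        end = 9e9 + 50, svtype = "DEL",
                                        svlen = 51, nCarriers = 1), seed = 1),
    "outside the mapped extent")
})

test_that("DH lines are fully homozygous recombinants with 1:1 segregation", {
  pop <- tinyPop(seed = 3, sizes = c(40, 40))
  calls <- genotypeCalls(pop)
  expect_true(all(calls %in% c(0L, 1L)))   # doubled haploid: no hets, no NA
  expect_identical(ncol(pop), 80L)
  expect_setequal(unique(subfamily(pop)), c("FND2", "FND3"))

  ## empirical segregation near 1:1 at every marker within a subfamily
  freq <- rowMeans(calls[, subfamily(pop) == "FND2"])
  polym <- freq > 0 & freq < 1
  expect_gt(mean(abs(freq[polym] - 0.5) < 0.25), 0.95)
})

test_that("allele frequency at a segregating locus converges to 0.5", {
  ## one large subfamily: binomial(n, 0.5) sampling of parental alleles
  map <- tinyMap(n = 5)
  fs <- simulateFounders(2, map, seed = 7)
  ## force the two founders to differ at marker 3 so that it segregates
  fs@haplotypes[3, ] <- c(0L, 1L)
  pop <- makeDHPopulation(fs, sizes = 10000, seed = 8)
  f <- mean(genotypeCalls(pop)[3, ])
  expect_lt(abs(f - 0.5), 0.015)           # 3 binomial SEs at n = 10,000
})

test_that("recombination follows the Haldane map (expected crossovers)", {
  ## With markers every 1 cM, the summed adjacent recombination fractions
  ## approximate the expected crossover count: 1 per 100 cM gamete.
  map <- tinyMap(n = 101, lengthCM = 100)
  fs <- simulateFounders(2, map, seed = 21)
  fs@haplotypes[] <- cbind(rep(0L, 101), rep(1L, 101))  # fully informative
  pop <- makeDHPopulation(fs, sizes = 10000, seed = 22)
  calls <- genotypeCalls(pop)
  adjRec <- sapply(seq_len(100), function(i) mean(calls[i, ] != calls[i + 1, ]))
  expect_equal(sum(adjRec), 1.0, tolerance = 0.1)
  ## long-range recombination fraction: Haldane r = (1 - exp(-2d)) / 2
  rEnds <- mean(calls[1, ] != calls[101, ])
  expect_equal(rEnds, (1 - exp(-2)) / 2, tolerance = 0.03)
})

test_that("viability weights inject segregation distortion", {
  map <- tinyMap(n = 5)
  fs <- simulateFounders(2, map, seed = 7)
  fs@haplotypes[3, ] <- c(0L, 1L)
  mk <- rownames(fs@haplotypes)[3]
  pop <- makeDHPopulation(fs, sizes = 4000, seed = 9,
                          viability = setNames(0.3, mk))
  f <- mean(genotypeCalls(pop)[3, ])
  ## expected carrier fraction 0.3 / 1.3 = 0.231; 3 SE ~ 0.02 at n = 4000
  expect_lt(abs(f - 0.3 / 1.3), 0.02)
})

test_that("noise-free phenotypes reproduce the planted effect exactly", {
  pop <- tinyPop(seed = 13)
  model <- phenotypeModel(grandMean = 120, envEffects = c(-1, 0, 1),
                          qtlEffects = c(SV1 = -0.88), varG = 0, varGE = 0,
                          varE = 0, nReps = 1)
  ph <- simulatePhenotypes(pop, model, nEnv = 3, seed = 1)
  sv <- svGenotypes(pop)["SV1", ]
  for (ev in unique(ph$environment)) {
    d <- ph[ph$environment == ev, ]
    gg <- sv[d$individual]
    expect_equal(mean(d$days[gg == 1]) - mean(d$days[gg == 0]), -0.88)
  }
  ## determinism
  expect_identical(ph, simulatePhenotypes(pop, model, nEnv = 3, seed = 1))
})

test_that("closed-form H2 matches the variance-component formula", {
  m <- phenotypeModel(varG = 1.953, varGE = 1.0, varE = 2.0, nReps = 2)
  expect_equal(expectedH2(m, nEnv = 5), 1.953 / (1.953 + 0.2 + 0.2),
               tolerance = 1e-12)
  expect_error(phenotypeModel(varE = -1), "non-negative")
})

test_that("null phenotype variance matches the residual variance", {
  pop <- tinyPop(seed = 17, sizes = c(200, 200))
  ph <- simulatePhenotypes(pop, phenotypeModel(varE = 1, nReps = 1),
                           nEnv = 2, seed = 2)
  v <- tapply(ph$days, ph$environment, var)
  expect_true(all(abs(v - 1) < 0.15))
})

test_that("ANOVA H2 estimate recovers the closed-form expectation", {
  pop <- tinyPop(seed = 19, sizes = c(100, 100))
  m <- phenotypeModel(varG = 1.953, varGE = 1, varE = 2, nReps = 2)
  h2 <- mean(vapply(1:10, function(s)
    estimateH2(simulatePhenotypes(pop, m, nEnv = 5, seed = s))$H2, 0))
  expect_equal(h2, expectedH2(m, 5), tolerance = 0.03)
})

test_that("depth simulation follows the dosage model", {
  sv <- GenomicRanges::GRanges("A01", IRanges::IRanges(5001, 6000))
  spec <- depthSimSpec(meanDepth = 30, dropoutRate = 0.05)
  tracks <- simulateDepth(c(ref = 0L, het = 1L, hom = 2L), sv, spec,
                          flank = 2000, seed = 3)
  inIdx <- 2001:3000
  outIdx <- c(1:2000, 3001:5000)
  depthIn <- vapply(tracks, function(t) mean(t@depth[inIdx]), 0)
  depthOut <- vapply(tracks, function(t) mean(t@depth[outIdx]), 0)
  expect_equal(unname(depthIn[["hom"]]), 1.5, tolerance = 0.3)   # 30 x 0.05
  expect_equal(unname(depthIn[["het"]] / depthOut[["het"]]), 0.5,
               tolerance = 0.1)
  expect_equal(unname(depthIn[["ref"]] / depthOut[["ref"]]), 1,
               tolerance = 0.1)
  expect_error(depthSimSpec(dropoutRate = 0.6), "rate")
})

test_that("call failures are injected only in carriers, only inside the SV", {
  pop <- tinyPop(seed = 23, sizes = c(40, 40), nFounders = 3, nCarriers = 1)
  fs <- S4Vectors::metadata(pop)$founderSet
  del <- svLoci(fs)
  ## widen the deletion so that it spans some markers
  big <- GenomicRanges::resize(del, width = 2e6, fix = "center")
  pop2 <- injectCallFailures(pop, big)
  mm <- markerMap(pop2)
  inside <- mm$chrom == "A01" & mm$bp >= GenomicRanges::start(big) &
    mm$bp <= GenomicRanges::end(big)
  expect_true(any(inside))
  carriers <- svGenotypes(pop)["SV1", ] > 0
  f <- failedCalls(pop2)
  expect_true(all(f[inside, carriers]))
  expect_false(any(f[!inside, ]))
  expect_false(any(f[, !carriers]))
  ## carrier founder's subfamily is the only one affected
  carrierFnd <- colnames(svAlleles(fs))[svAlleles(fs)[1, ] == 1]
  if (carrierFnd != commonParent(fs))
    expect_true(all(subfamily(pop2)[carriers] == carrierFnd))
  ## construction: carrier fraction ~ 1/2 within the carrier subfamily
  inFam <- subfamily(pop2) == carrierFnd
  expect_equal(mean(colMeans(f[inside, inFam, drop = FALSE])),
               mean(carriers[inFam]), tolerance = 1e-12)
})

test_that("simulation outputs are reproducible and round-trip through TSV", {
  pop <- tinyPop(seed = 29, sizes = c(10, 10), nMarkers = 10)
  f <- tempfile(fileext = ".tsv")
  writeGenotypes(pop, f, seed = 29)
  back <- readGenotypes(f)
  expect_identical(genotypeCalls(back), genotypeCalls(pop))
  expect_identical(subfamily(back), subfamily(pop))
  expect_true(any(grepl("seed: 29", readLines(f))))
})
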