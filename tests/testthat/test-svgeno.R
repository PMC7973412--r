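test_that("amplicon prediction reproduces the documented product pairs", {
  ## P311-style: 1924 bp reference amplicon, 1361 bp internal deletion
  a311 <- pcrAssay("P311", "A02", fwd = c(1001, 1020), rev = c(2905, 2924))
  d311 <- svCatalog("A02", 1200, 2560, "DEL", 1361)
  expect_identical(predictAmplicons(a311, d311)$ref, 1924L)
  expect_identical(predictAmplicons(a311, d311)$alt, 563L)

  ## P133-style: 1130 bp amplicon, 373 bp deletion -> 757
  a133 <- pcrAssay("P133", "A02", fwd = c(501, 520), rev = c(1611, 1630))
  d133 <- svCatalog("A02", 700, 1072, "DEL", 373)
  expect_identical(predictAmplicons(a133, d133)$alt, 757L)

  ## P632-style: 667 bp amplicon, 35 bp deletion -> 632
  a632 <- pcrAssay("P632", "A02", fwd = c(101, 120), rev = c(748, 767))
  d632 <- svCatalog("A02", 300, 334, "DEL", 35)
  expect_identical(predictAmplicons(a632, d632)$alt, 632L)

  ## P732-style: 262 bp amplicon, 38 bp insertion -> 300
  a732 <- pcrAssay("P732", "C02", fwd = c(2001, 2020), rev = c(2243, 2262))
  i732 <- svCatalog("C02", 2100, 2100, "INS", 38)
  expect_identical(predictAmplicons(a732, i732)$alt, 300L)
  expect_identical(predictAmplicons(a732, i732)$label, "262 bp/300 bp")

  ## P513-style: deletion overlapping the reverse primer -> no product
  a513 <- pcrAssay("P513", "A02", fwd = c(5001, 5020), rev = c(5800, 5819))
  d513 <- svCatalog("A02", 5500, 6812, "DEL", 1313)
  res <- predictAmplicons(a513, d513)
  expect_true(is.na(res$alt))
  expect_identical(res$label, "819 bp/no product")
})

test_that("deletion-allele length conservation holds for internal deletions", {
  ## reference length - deletion size = deletion-allele length
  set.seed(501)
  for (rep in 1:10) {
    fstart <- sample(1000, 1)
    amp <- sample(500:3000, 1)
    a <- pcrAssay("X", "A02", fwd = c(fstart, fstart + 19),
                  rev = c(fstart + amp - 20, fstart + amp - 1))
    delLen <- sample(30:(amp - 60), 1)
    dstart <- fstart + 25
    d <- svCatalog("A02", dstart, dstart + delLen - 1, "DEL", delLen)
    out <- predictAmplicons(a, d)
    expect_identical(out$alt, out$ref - delLen)
  }
})

test_that("cross-chromosome SV leaves the assay unaffected with a warning", {
  a <- pcrAssay("P1", "A02", fwd = c(101, 120), rev = c(481, 500))
  d <- svCatalog("C02", 200, 299, "DEL", 100)
  expect_warning(out <- predictAmplicons(a, d), "chromosome")
  expect_identical(out$alt, out$ref)
})

test_that("segregation chi-square reproduces printed subfamily ratios", {
  ## representative printed cells; full table in the acceptance suite
  expect_equal(round(segregationTest(29, 31)$p, 3), 0.796)
  expect_equal(round(segregationTest(43, 17)$p, 3), 0.001)
  expect_identical(segregationTest(43, 17)$stars, "***")
  expect_equal(segregationTest(30, 30)$p, 1.0)
  ## independent tail oracle: chi2 = 5.0 at 50:30
  st <- segregationTest(50, 30)
  expect_equal(st$chi2, 5.0)
  expect_equal(st$p, pchisq(5, 1, lower.tail = FALSE))
  expect_equal(round(st$p, 4), 0.0253)
  ## no continuity correction: matches chisq.test(correct has no effect
  ## for goodness-of-fit) and differs from the Yates-corrected value
  expect_equal(st$chi2, unname(chisq.test(c(50, 30))$statistic))
  expect_error(segregationTest(0, 0), "zero")
  ## vectorized form returns a data.frame
  v <- segregationTest(c(29, 43), c(31, 17))
  expect_identical(nrow(v), 2L)
})

test_that("allelic effects match the pooled-variance t oracle", {
  ph <- data.frame(individual = sprintf("i%d", 1:6),
                   environment = "e1", replicate = 1L,
                   days = c(10, 11, 12, 13, 14, 15))
  sv <- setNames(c(1L, 1L, 1L, 0L, 0L, 0L), sprintf("i%d", 1:6))
  eff <- allelicEffects(sv, ph)
  expect_equal(eff$effect, -3.0)
  expect_equal(eff$t, -3.0 / (1 * sqrt(2 / 3)), tolerance = 1e-8)
  expect_equal(eff$p, 2 * pt(-abs(eff$t), df = 4), tolerance = 1e-8)
  expect_equal(round(eff$p, 3), 0.021)
  expect_identical(eff$signif, "*")

  ## identical class means -> effect 0, not significant
  ph0 <- ph; ph0$days <- c(1, 2, 3, 1, 2, 3)
  eff0 <- allelicEffects(sv, ph0)
  expect_equal(eff0$effect, 0)
  expect_identical(eff0$signif, "ns")

  ## empty class in an environment -> untestable
  ph2 <- rbind(ph, data.frame(individual = sprintf("i%d", 1:3),
                              environment = "e2", replicate = 1L,
                              days = c(9, 9, 9)))
  eff2 <- allelicEffects(sv, ph2)
  expect_false(eff2$testable[eff2$environment == "e2"])
  expect_true(eff2$testable[eff2$environment == "e1"])
})

test_that("planted effects are recovered without bias across seeds", {
  effs <- vapply(1:15, function(s) {
    pop <- tinyPop(seed = 600 + s, sizes = c(40, 40))
    model <- phenotypeModel(grandMean = 120, envEffects = c(-1, 0, 1),
                            qtlEffects = c(SV1 = -0.88), varE = 2,
                            nReps = 2)
    ph <- simulatePhenotypes(pop, model, nEnv = 3, seed = 700 + s)
    eff <- allelicEffects(svGenotypes(pop)["SV1", ], ph)
    mean(eff$effect, na.rm = TRUE)
  }, 0)
  expect_equal(mean(effs, na.rm = TRUE), -0.88, tolerance = 0.15)
})

test_that("NMC thresholds partition calls with boundary values ambiguous", {
  mkTrack <- function(inDepth, outDepth = 30) {
    depthTrack("A02", 1, c(rep(outDepth, 100), rep(inDepth, 50),
                           rep(outDepth, 100)))
  }
  iv <- c(101, 150)
  expect_identical(nmcGenotype(mkTrack(3), iv)$call, "deletion")
  expect_identical(nmcGenotype(mkTrack(30), iv)$call, "ambiguous")
  expect_identical(nmcGenotype(mkTrack(60), iv)$call, "reference")
  expect_equal(nmcGenotype(mkTrack(3), iv)$nmc, 0.1)
  ## boundary values are ambiguous, not called
  expect_identical(nmcGenotype(mkTrack(15), iv)$call, "ambiguous")   # 0.5
  expect_identical(nmcGenotype(mkTrack(45), iv)$call, "ambiguous")   # 1.5
  ## explicit baseline intervals
  out <- nmcGenotype(mkTrack(3), iv, baseline = list(c(1, 100)))
  expect_equal(out$nmc, 0.1)
  ## zero baseline -> uninformative sample
  zero <- depthTrack("A02", 1, c(rep(0, 100), rep(9, 50)))
  expect_error(nmcGenotype(zero, c(101, 150)), "uninformative")
  expect_error(nmcGenotype(mkTrack(3), c(500, 600)), "not covered")
})

test_that("simulated homozygous classes are called accurately, hets ambiguous", {
  sv <- GenomicRanges::GRanges("A02", IRanges::IRanges(2001, 2288))
  spec <- depthSimSpec(meanDepth = 30, dropoutRate = 0.05)
  geno <- setNames(rep(c(0L, 1L, 2L), each = 20),
                   sprintf("acc%02d", 1:60))
  tracks <- simulateDepth(geno, sv, spec, flank = 1500, seed = 77)
  ## panel genotyping uses the single-copy (relative copy number) baseline:
  ## reference ~2, het ~1, homozygous deletion ~0.1
  calls <- vapply(tracks, function(t)
    nmcGenotype(t, c(2001, 2288), singleCopyBaseline = TRUE)$call, "")
  expect_true(all(calls[geno == 0L] == "reference"))
  expect_true(all(calls[geno == 2L] == "deletion"))
  expect_true(all(calls[geno == 1L] == "ambiguous"))
  ## on the raw target/baseline ratio heterozygotes sit at one half
  nmcHet <- vapply(tracks[geno == 1L], function(t)
    nmcGenotype(t, c(2001, 2288))$nmc, 0)
  expect_equal(mean(nmcHet), 0.5, tolerance = 0.05)
})

test_that("concordance cross-tabulates and scores agreement", {
  ids <- sprintf("a%02d", 1:10)
  nmc <- setNames(rep("deletion", 10), ids)
  pcr <- setNames(rep("deletion", 10), ids)
  expect_equal(concordance(nmc, pcr)$agreement, 1.0)
  pcr[1] <- "reference"
  expect_equal(concordance(nmc, pcr)$agreement, 0.9)
  ## ambiguous NMC calls are excluded from the comparison
  nmc[2] <- "ambiguous"
  out <- concordance(nmc, pcr)
  expect_identical(out$n_compared, 9L)
  expect_equal(out$agreement, 8 / 9)
  expect_identical(sum(out$table), 10L)
  expect_error(concordance(setNames("deletion", "x"),
                           setNames("deletion", "y")), "shared")
})
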