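## Small builders shared across test files. Everything is generated in code;
## seeds are fixed so expectations are stable.

tinyMap <- function(chrom = "A01", n = 20L, lengthCM = 100)
  geneticMap(chrom, nMarkers = n, lengthCM = lengthCM)

## population of 2 subfamilies with one planted deletion carried by FND2
tinyPop <- function(seed = 11, sizes = c(30, 30), nFounders = 3,
                    nCarriers = 1, nMarkers = 30) {
  map <- tinyMap(n = nMarkers)
  svLoci <- data.frame(chrom = "A01", start = 4.1e6, end = 4.1e6 + 287,
                       svtype = "DEL", svlen = 288, nCarriers = nCarriers,
                       id = "SV1")
  fs <- simulateFounders(nFounders, map, svLoci, seed = seed)
  makeDHPopulation(fs, sizes = sizes, seed = seed + 1)
}

## genotype matrix built directly from a call matrix (markers x individuals)
gmFromMatrix <- function(calls, subfamily = NULL, failed = NULL,
                         chrom = "A01") {
  n <- nrow(calls)
  if (is.null(rownames(calls))) rownames(calls) <- sprintf("m%02d", seq_len(n))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("i%02d", seq_len(ncol(calls)))
  if (is.null(subfamily)) subfamily <- rep("SF1", ncol(calls))
  GenotypeMatrix(calls,
                 map = data.frame(chrom = chrom, bp = seq_len(n) * 1000L),
                 subfamily = subfamily, failed = failed)
}

## haplotype population matrix with planted LD blocks: markers in the same
## block share one of two complementary ancestral haplotypes per individual
plantedBlockHaplotypes <- function(nInd = 200, blockSizes = c(5, 5, 5),
                                   seed = 42) {
  set.seed(seed)
  m <- sum(blockSizes)
  X <- matrix(0L, m, nInd)
  row <- 0L
  for (b in seq_along(blockSizes)) {
    anc <- matrix(rbinom(2L * blockSizes[b], 1, 0.5), blockSizes[b], 2)
    ## force the two ancestral haplotypes to differ at every marker so that
    ## within-block |D'| = 1 exactly
    anc[, 2] <- 1L - anc[, 1]
    pick <- rbinom(nInd, 1, 0.5) + 1L
    X[row + seq_len(blockSizes[b]), ] <- anc[, pick]
    row <- row + blockSizes[b]
  }
  rownames(X) <- sprintf("m%02d", seq_len(m))
  X
}
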