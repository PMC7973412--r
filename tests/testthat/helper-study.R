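## shared drivers for the study-scale checks

## variance-component phenotype table: independent normal genotype, GxE and
## residual effects (no genetics), balanced G x E x R
vcPhenoTable <- function(seed, G = 354, E = 5, R = 2, s2G = 1.953,
                         s2GE = 1.0, s2e = 2.0) {
  set.seed(seed)
  ids <- sprintf("g%03d", seq_len(G))
  envs <- sprintf("e%d", seq_len(E))
  g <- rnorm(G, 0, sqrt(s2G))
  ge <- matrix(rnorm(G * E, 0, sqrt(s2GE)), G, E)
  tab <- expand.grid(individual = ids, environment = envs,
                     replicate = seq_len(R), stringsAsFactors = FALSE)
  i <- match(tab$individual, ids)
  j <- match(tab$environment, envs)
  tab$days <- 120 + g[i] + ge[cbind(i, j)] + rnorm(nrow(tab), 0, sqrt(s2e))
  tab
}

## one full study replicate: effect estimate (environment-adjusted class-mean
## difference averaged over environments) and whether the planted deletion is
## declared a QTL (significant in >= 2 of 5 environments)
studyReplicate <- function(seed, declare = TRUE) {
  st <- simulateStudy(seed = seed)
  pop <- st$population
  sv <- svGenotypes(pop)[st$svId, ]
  eff <- allelicEffects(sv, st$phenotypes)
  est <- mean(eff$effect, na.rm = TRUE)
  if (!declare) return(list(effect = est, declared = NA))
  qc <- qcFilter(pop)
  K <- kinshipMatrix(qc$genotypes)
  svM <- GenotypeMatrix(matrix(sv, 1, dimnames = list(st$svId, colnames(pop))),
                        map = data.frame(
                          chrom = as.character(GenomicRanges::seqnames(
                            svLoci(st$founders)))[1],
                          bp = GenomicRanges::start(svLoci(st$founders))[1]),
                        subfamily = subfamily(pop))
  entry <- aggregate(days ~ individual + environment, st$phenotypes, mean)
  scans <- lapply(split(entry, entry$environment), function(e) {
    y <- setNames(e$days, e$individual)
    s1 <- rbind(associationScan(qc$genotypes, y, K, nPcs = 2,
                                environment = e$environment[1]),
                associationScan(svM, y, K, nPcs = 2,
                                environment = e$environment[1]))
    ok <- !is.na(s1$p)
    s1$q <- NA_real_
    s1$q[ok] <- bhFDR(s1$p[ok])
    s1
  })
  svChrom <- as.character(GenomicRanges::seqnames(svLoci(st$founders)))[1]
  mm <- markerMap(qc$genotypes)
  ld <- pairwiseDprime(qc$genotypes, chrom = svChrom)
  blocks <- findBlocks(ld, mm[mm$chrom == svChrom, ])
  qtl <- suppressWarnings(declareQtl(scans, blocks))
  list(effect = est, declared = st$svId %in% qtl$peak_marker ||
         any(qtl$start <= GenomicRanges::start(svLoci(st$founders))[1] &
             qtl$end >= GenomicRanges::start(svLoci(st$founders))[1]))
}
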