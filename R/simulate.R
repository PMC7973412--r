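#' @include AllClasses.R
#' @importFrom GenomicRanges GRanges start end width seqnames
#' @importFrom IRanges IRanges
#' @importFrom stats rpois runif rbinom rnorm optimize pchisq qchisq
#'   p.adjust setNames median cor t.test chisq.test aggregate sd ave approx
NULL

#' Build a marker map
#'
#' A genetic/physical map: per chromosome, markers ordered by strictly
#' increasing physical position (bp, 1-based) with non-decreasing genetic
#' position (cM). The default layout places `nMarkers` equally spaced
#' markers per chromosome assuming 1 cM per `bpPerCM` bp, a desk-scale
#' stand-in for an anchored crop map.
#'
#' @param chroms chromosome names (A01... C09-style labels).
#' @param nMarkers markers per chromosome (recycled).
#' @param lengthCM chromosome lengths in cM (recycled).
#' @param bpPerCM physical bp per cM (constant recombination rate).
#' @return data.frame with columns `chrom`, `marker`, `bp`, `cM`.
#' @examples
#' head(geneticMap(c("A01", "A02"), nMarkers = 50, lengthCM = 100))
#' @export
geneticMap <- function(chroms = c("A01", "A02", "C02"), nMarkers = 100L,
                       lengthCM = 100, bpPerCM = 4e5) {
  nMarkers <- rep_len(as.integer(nMarkers), length(chroms))
  lengthCM <- rep_len(lengthCM, length(chroms))
  maps <- lapply(seq_along(chroms), function(i) {
    cm <- seq(0, lengthCM[i], length.out = nMarkers[i])
    data.frame(chrom = chroms[i],
               marker = sprintf("%s_m%04d", chroms[i], seq_len(nMarkers[i])),
               bp = as.integer(round(cm * bpPerCM)) + 1L,
               cM = cm, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  validateGeneticMap(map)
  map
}

validateGeneticMap <- function(map) {
  stopifnot(all(c("chrom", "marker", "bp", "cM") %in% colnames(map)))
  for (ch in unique(map$chrom)) {
    m <- map[map$chrom == ch, ]
    if (is.unsorted(m$bp, strictly = TRUE))
      stop("physical positions must be strictly increasing on ", ch)
    if (is.unsorted(m$cM))
      stop("genetic positions must be non-decreasing on ", ch)
  }
  if (anyDuplicated(map$marker)) stop("marker identifiers must be unique")
  invisible(map)
}

## linear bp -> cM interpolation within one chromosome's map
.bpToCM <- function(map1, bp) {
  stats::approx(map1$bp, map1$cM, xout = bp, rule = 2)$y
}

#' Simulate inbred founder lines
#'
#' Draws fully homozygous founder haplotypes at the mapped markers and
#' assigns presence/absence alleles at structural-variant loci. By default
#' haplotype alleles are i.i.d. Bernoulli(0.5) per marker; with
#' `blockCM > 0` each chromosome is partitioned into ancestral haplotype
#' blocks of that genetic length and every founder inherits one of two
#' ancestral haplotypes per block — the source of linkage disequilibrium
#' needed for LD-block detection.
#'
#' @param nFounders number of founders (>= 2); the first is the common
#'   parent to which all others are crossed.
#' @param map marker map as from [geneticMap()].
#' @param svLoci optional SV specification: a data.frame with columns
#'   `chrom`, `start`, `end` (1-based inclusive; for INS, `end = start`),
#'   `svtype` (`DEL`/`INS`), `svlen`, and optionally `nCarriers` (founders
#'   carrying the alternate allele; default 1) and `id`. Loci with
#'   `0 < nCarriers < nFounders` are polymorphic and guaranteed to carry
#'   both alleles. `carriers` may instead name founders explicitly
#'   (comma-separated).
#' @param seed integer seed; identical seeds give identical founder sets.
#' @param blockCM ancestral haplotype block length in cM (0 = no blocks).
#' @return A [FounderSet-class].
#' @examples
#' fs <- simulateFounders(7, geneticMap("A02", 40),
#'   svLoci = data.frame(chrom = "A02", start = 5e6, end = 5e6 + 287,
#'                       svtype = "DEL", svlen = 288, nCarriers = 3),
#'   seed = 1)
#' fs
#' @export
simulateFounders <- function(nFounders, map, svLoci = NULL, seed = 1,
                             blockCM = 0) {
  stopifnot(nFounders >= 2)
  validateGeneticMap(map)
  set.seed(seed)
  founders <- sprintf("FND%d", seq_len(nFounders))
  nm <- nrow(map)
  if (blockCM > 0) {
    hap <- matrix(0L, nm, nFounders)
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      blk <- floor(map$cM[idx] / blockCM)
      for (b in unique(blk)) {
        rows <- idx[blk == b]
        anc <- matrix(rbinom(2L * length(rows), 1L, 0.5), ncol = 2L)
        pick <- rbinom(nFounders, 1L, 0.5) + 1L
        hap[rows, ] <- anc[, pick, drop = FALSE]
      }
    }
  } else {
    hap <- matrix(rbinom(nm * nFounders, 1L, 0.5), nm, nFounders)
  }
  dimnames(hap) <- list(map$marker, founders)

  if (is.null(svLoci) || nrow(as.data.frame(svLoci)) == 0L) {
    gr <- GenomicRanges::GRanges()
    sva <- matrix(integer(), 0L, nFounders, dimnames = list(NULL, founders))
  } else {
    svLoci <- as.data.frame(svLoci)
    if (is.null(svLoci$id))
      svLoci$id <- sprintf("SV%d", seq_len(nrow(svLoci)))
    for (i in seq_len(nrow(svLoci))) {
      m <- map[map$chrom == svLoci$chrom[i], ]
      if (nrow(m) == 0L || svLoci$start[i] < min(m$bp) ||
          svLoci$end[i] > max(m$bp))
        stop("SV locus ", svLoci$id[i], " lies outside the mapped extent of ",
             svLoci$chrom[i])
    }
    gr <- GenomicRanges::GRanges(svLoci$chrom,
                                 IRanges::IRanges(svLoci$start, svLoci$end))
    names(gr) <- svLoci$id
    S4Vectors::mcols(gr)$svtype <- svLoci$svtype
    S4Vectors::mcols(gr)$svlen <- svLoci$svlen
    sva <- matrix(0L, nrow(svLoci), nFounders,
                  dimnames = list(svLoci$id, founders))
    for (i in seq_len(nrow(svLoci))) {
      if (!is.null(svLoci$carriers)) {
        who <- trimws(strsplit(svLoci$carriers[i], ",")[[1]])
        stopifnot(all(who %in% founders))
      } else {
        k <- if (is.null(svLoci$nCarriers)) 1L else svLoci$nCarriers[i]
        stopifnot(k >= 0, k <= nFounders)
        who <- sample(founders, k)
      }
      sva[i, who] <- 1L
    }
  }
  new("FounderSet", founders = founders, commonParent = founders[1],
      haplotypes = hap, map = map, svLoci = gr, svAlleles = sva)
}

## one meiotic gamete of the F1 (commonParent x founder): returns the
## parent-of-origin (0 = common parent, 1 = founder) at arbitrary cM
## positions, Haldane model: Poisson crossover count, uniform positions.
.gameteOrigin <- function(cmPositions, lengthCM) {
  nxo <- rpois(1L, lengthCM / 100)
  xo <- sort(runif(nxo, 0, lengthCM))
  phase <- rbinom(1L, 1L, 0.5)
  (phase + findInterval(cmPositions, xo)) %% 2L
}

#' Generate a multiparental DH population
#'
#' Each doubled-haploid (DH) line is a single recombinant gamete of the F1
#' between the common parent and one founder, doubled to full homozygosity.
#' Crossovers per chromosome are Poisson(length in Morgans) with positions
#' uniform on the cM scale (Haldane, no interference). Within a subfamily
#' every segregating locus therefore has expected 1:1 segregation; optional
#' per-locus viability weights inject segregation distortion (a DH carrying
#' the coded-1 allele at a weighted locus survives DH production with the
#' given probability).
#'
#' @param founders a [FounderSet-class].
#' @param sizes named (by non-common founder) or unnamed vector of
#'   subfamily sizes; default 60 per cross with the last cross 54,
#'   emulating a 354-line elite population.
#' @param seed integer seed.
#' @param viability optional named numeric in (0, 1]: survival probability
#'   of the allele-1 class at the named marker or SV locus.
#' @return A [GenotypeMatrix-class]; `metadata()` holds `founderSet`,
#'   `svGeno` (SV loci x individuals dosage in 0/1) and `seed`.
#' @examples
#' fs <- simulateFounders(3, geneticMap("A01", 20), seed = 1)
#' pop <- makeDHPopulation(fs, sizes = c(10, 10), seed = 2)
#' pop
#' @export
makeDHPopulation <- function(founders, sizes = NULL, seed = 1,
                             viability = NULL) {
  stopifnot(is(founders, "FounderSet"))
  others <- setdiff(founders@founders, founders@commonParent)
  if (is.null(sizes)) {
    sizes <- rep(60L, length(others))
    sizes[length(sizes)] <- 54L
  }
  sizes <- rep_len(as.integer(sizes), length(others))
  stopifnot(all(sizes > 0))
  names(sizes) <- others
  set.seed(seed)

  map <- founders@map
  chroms <- unique(map$chrom)
  chromIdx <- split(seq_len(nrow(map)), map$chrom)[chroms]
  chromLen <- vapply(chromIdx, function(i) max(map$cM[i]), 0)
  svGR <- founders@svLoci
  nSV <- length(svGR)
  svCM <- if (nSV) vapply(seq_len(nSV), function(i) {
    ch <- as.character(GenomicRanges::seqnames(svGR)[i])
    .bpToCM(map[map$chrom == ch, ], GenomicRanges::start(svGR)[i])
  }, 0) else numeric()
  svChrom <- as.character(GenomicRanges::seqnames(svGR))

  nInd <- sum(sizes)
  calls <- matrix(NA_integer_, nrow(map), nInd)
  svg <- matrix(NA_integer_, nSV, nInd)
  subf <- character(nInd)
  ids <- character(nInd)
  col <- 0L
  for (f in others) {
    hapC <- founders@haplotypes[, founders@commonParent]
    hapF <- founders@haplotypes[, f]
    svC <- if (nSV) founders@svAlleles[, founders@commonParent] else integer()
    svF <- if (nSV) founders@svAlleles[, f] else integer()
    made <- 0L
    while (made < sizes[[f]]) {
      g <- integer(nrow(map))
      svO <- integer(nSV)
      for (k in seq_along(chroms)) {
        idx <- chromIdx[[k]]
        svHere <- which(svChrom == chroms[k])
        ori <- .gameteOrigin(c(map$cM[idx], svCM[svHere]), chromLen[k])
        nm <- length(idx)
        g[idx] <- ori[seq_len(nm)]
        if (length(svHere)) svO[svHere] <- ori[-seq_len(nm)]
      }
      geno <- ifelse(g == 0L, hapC, hapF)
      svGeno <- if (nSV) ifelse(svO == 0L, svC, svF) else integer()
      if (!is.null(viability)) {
        w <- 1
        for (loc in names(viability)) {
          a <- if (loc %in% map$marker) geno[match(loc, map$marker)]
               else if (nSV && loc %in% names(svGR)) svGeno[match(loc, names(svGR))]
               else stop("viability locus not found: ", loc)
          if (!is.na(a) && a == 1L) w <- w * viability[[loc]]
        }
        if (runif(1) > w) next
      }
      made <- made + 1L; col <- col + 1L
      calls[, col] <- geno
      if (nSV) svg[, col] <- svGeno
      subf[col] <- f
      ids[col] <- sprintf("%s_DH%03d", f, made)
    }
  }
  dimnames(calls) <- list(map$marker, ids)
  if (nSV) dimnames(svg) <- list(names(svGR), ids)
  GenotypeMatrix(calls,
                 map = map[, c("chrom", "bp", "cM")],
                 subfamily = subf,
                 metadata = list(founderSet = founders, svGeno = svg,
                                 seed = seed))
}

#' Closed-form expected broad-sense heritability
#'
#' On an entry-mean basis over `nEnv` environments and `model@nReps`
#' replicates, `H2 = s2G / (s2G + s2GE/E + s2e/(E*R))`. The genotypic
#' variance `s2G` is `varG` plus the variance contributed by the explicit
#' QTL effects, `sum(effect^2 * p * (1 - p))` with allele frequency `p`
#' (0.5 for a locus segregating in all subfamilies).
#'
#' @param model a [PhenotypeModel-class].
#' @param nEnv number of environments.
#' @param alleleFreq frequency of the coded-1 allele at each QTL locus.
#' @return Expected H2 in [0, 1].
#' @examples
#' m <- phenotypeModel(varG = 1.953, varGE = 1, varE = 2, nReps = 2)
#' expectedH2(m, nEnv = 5)  # 0.830
#' @export
expectedH2 <- function(model, nEnv, alleleFreq = 0.5) {
  p <- rep_len(alleleFreq, length(model@qtlEffects))
  s2G <- model@varG + sum(model@qtlEffects^2 * p * (1 - p))
  E <- nEnv; R <- model@nReps
  s2G / (s2G + model@varGE / E + model@varE / (E * R))
}

#' Simulate multi-environment phenotypes
#'
#' Days to onset of flowering for each individual, environment and
#' replicate: `grand mean + env effect + sum(QTL effect x dose) + polygenic
#' N(0, varG) + GxE N(0, varGE) + residual N(0, varE)`. QTL effects are
#' looked up by name among the population's markers and simulated SV loci;
#' dose is the 0/1 DH allele code.
#'
#' @param pop a [GenotypeMatrix-class].
#' @param model a [PhenotypeModel-class]; `envEffects` must have length
#'   `nEnv` (or be empty, giving all-zero environment effects).
#' @param nEnv number of environments.
#' @param seed integer seed.
#' @return data.frame `individual`, `environment`, `replicate`, `days`.
#' @export
simulatePhenotypes <- function(pop, model, nEnv, seed = 1) {
  validObject(model)
  set.seed(seed)
  n <- ncol(pop)
  ids <- colnames(pop)
  envEff <- model@envEffects
  if (length(envEff) == 0L) envEff <- rep(0, nEnv)
  stopifnot(length(envEff) == nEnv)
  envs <- sprintf("env%d", seq_len(nEnv))

  genet <- rep(0, n)
  if (length(model@qtlEffects)) {
    svg <- svGenotypes(pop)
    for (loc in names(model@qtlEffects)) {
      dose <- if (loc %in% rownames(pop)) genotypeCalls(pop)[loc, ]
              else if (!is.null(svg) && loc %in% rownames(svg)) svg[loc, ]
              else stop("QTL effect locus not genotyped in population: ", loc)
      if (anyNA(dose)) stop("QTL effect locus has missing genotypes: ", loc)
      genet <- genet + model@qtlEffects[[loc]] * dose
    }
  }
  if (model@varG > 0) genet <- genet + rnorm(n, 0, sqrt(model@varG))

  R <- model@nReps
  ge <- matrix(if (model@varGE > 0) rnorm(n * nEnv, 0, sqrt(model@varGE))
               else 0, n, nEnv)
  out <- expand.grid(replicate = seq_len(R), individual = ids,
                     environment = envs, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)[, c(2, 3, 1)]
  i <- match(out$individual, ids)
  j <- match(out$environment, envs)
  resid <- if (model@varE > 0) rnorm(nrow(out), 0, sqrt(model@varE)) else 0
  out$days <- model@grandMean + envEff[j] + genet[i] + ge[cbind(i, j)] + resid
  out
}

#' Simulate per-base depth tracks around an SV
#'
#' Per-base read depth is Poisson with mean `meanDepth x dosage`:
#' dosage 1 outside the SV interval and, inside a deletion, 1 for
#' non-carriers, 0.5 for heterozygous carriers, and `dropoutRate` for
#' homozygous carriers (residual spurious mappings).
#'
#' @param svGeno named integer vector of deletion dosages per individual:
#'   0 (reference), 1 (heterozygous) or 2 (homozygous deletion).
#' @param sv a length-1 [GenomicRanges::GRanges] (the deletion interval).
#' @param spec a [DepthSimSpec-class].
#' @param flank bases of flanking sequence simulated on each side.
#' @param seed integer seed.
#' @return Named list of [DepthTrack-class], one per individual.
#' @export
simulateDepth <- function(svGeno, sv, spec = depthSimSpec(), flank = 1000L,
                          seed = 1) {
  stopifnot(is(sv, "GRanges"), length(sv) == 1L)
  validObject(spec)
  set.seed(seed)
  s <- GenomicRanges::start(sv); e <- GenomicRanges::end(sv)
  from <- max(1L, s - as.integer(flank)); to <- e + as.integer(flank)
  len <- to - from + 1L
  inside <- seq.int(s - from + 1L, e - from + 1L)
  dose <- c(`0` = 1, `1` = 0.5, `2` = spec@dropoutRate)
  lapply(setNames(names(svGeno), names(svGeno)), function(id) {
    mu <- rep(spec@meanDepth, len)
    mu[inside] <- spec@meanDepth * dose[[as.character(svGeno[[id]])]]
    depthTrack(as.character(GenomicRanges::seqnames(sv)), from,
               rpois(len, mu))
  })
}

#' Inject array call failures inside deletions
#'
#' Array probes whose physical position falls inside a deletion cannot
#' hybridize in carrier individuals: the corresponding calls are set to the
#' `failed` state (and `NA`). This is the signal SNaP calling recovers.
#'
#' @param pop a [GenotypeMatrix-class] with simulated SV truth
#'   (`svGenotypes(pop)`), or explicit `carriers`.
#' @param deletions [GenomicRanges::GRanges] of deletions; names must match
#'   rows of the carrier matrix.
#' @param carriers optional logical/integer matrix (deletions x
#'   individuals); defaults to `svGenotypes(pop)` rows for `deletions`.
#' @return The population with failures injected.
#' @export
injectCallFailures <- function(pop, deletions, carriers = NULL) {
  stopifnot(is(pop, "GenotypeMatrix"), is(deletions, "GRanges"))
  if (is.null(carriers)) {
    svg <- svGenotypes(pop)
    if (is.null(svg)) stop("no SV truth in population; supply 'carriers'")
    carriers <- svg[names(deletions), , drop = FALSE] > 0L
  }
  calls <- genotypeCalls(pop)
  failed <- failedCalls(pop)
  mm <- markerMap(pop)
  for (i in seq_along(deletions)) {
    ch <- as.character(GenomicRanges::seqnames(deletions)[i])
    hit <- mm$chrom == ch &
      mm$bp >= GenomicRanges::start(deletions)[i] &
      mm$bp <= GenomicRanges::end(deletions)[i]
    if (!any(hit)) next
    who <- which(carriers[i, ] > 0)
    failed[hit, who] <- TRUE
    calls[hit, who] <- NA_integer_
  }
  md <- S4Vectors::metadata(pop)
  GenotypeMatrix(calls, map = as.data.frame(SummarizedExperiment::rowData(pop)),
                 subfamily = subfamily(pop), failed = failed, metadata = md)
}

#' Simulate the full multiparental study design
#'
#' Convenience driver assembling the complete desk-scale study: a
#' seven-founder elite population (one common parent, six crosses of 60 DH
#' lines with the last cross 54; 354 lines total), a genetic map with
#' ancestral haplotype blocks, one planted 288 bp deletion carried by
#' `nCarriers` founders inside the mapped region, multi-environment
#' phenotypes with the deletion as a QTL, and the array call failures the
#' deletion causes.
#'
#' @param seed integer master seed (founders, meiosis and phenotypes draw
#'   from successive offsets).
#' @param effect allele-substitution effect of the deletion in days
#'   (negative = carriers flower earlier).
#' @param nEnv environments; @param nReps replicates per environment.
#' @param sdResid residual (plot) standard deviation in days.
#' @param varG polygenic variance (days^2); @param varGE GxE variance.
#' @param nCarriers founders carrying the deletion.
#' @param chroms,markersPerChrom,lengthCM,bpPerCM,blockCM map layout.
#' @param sizes subfamily sizes (default 5 x 60 + 54).
#' @return List: `population` (with call failures injected), `phenotypes`,
#'   `founders`, `svId`.
#' @export
simulateStudy <- function(seed = 1, effect = -0.88, nEnv = 5L, nReps = 2L,
                          sdResid = 2, varG = 0, varGE = 0, nCarriers = 3L,
                          chroms = c("A02", "C02"), markersPerChrom = 45L,
                          lengthCM = 100, bpPerCM = 4e5, blockCM = 10,
                          sizes = c(60, 60, 60, 60, 60, 54)) {
  map <- geneticMap(chroms, markersPerChrom, lengthCM, bpPerCM)
  m1 <- map[map$chrom == chroms[1], ]
  svStart <- m1$bp[floor(nrow(m1) / 2)] + 137L
  svLoci <- data.frame(chrom = chroms[1], start = svStart,
                       end = svStart + 287L, svtype = "DEL", svlen = 288L,
                       nCarriers = nCarriers, id = "SVq")
  founders <- simulateFounders(length(sizes) + 1L, map, svLoci, seed = seed,
                               blockCM = blockCM)
  pop <- makeDHPopulation(founders, sizes = sizes, seed = seed + 1L)
  pop <- injectCallFailures(pop, founders@svLoci)
  model <- phenotypeModel(grandMean = 120,
                          envEffects = seq(-2, 2, length.out = nEnv),
                          qtlEffects = c(SVq = effect), varG = varG,
                          varGE = varGE, varE = sdResid^2, nReps = nReps)
  pheno <- simulatePhenotypes(pop, model, nEnv = nEnv, seed = seed + 2L)
  list(population = pop, phenotypes = pheno, founders = founders,
       svId = "SVq")
}
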