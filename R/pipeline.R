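#' @include AllClasses.R
NULL

#' Pipeline configuration
#'
#' All stage toggles and thresholds of the SV-QTL inference chain, each
#' defaulting to the study's analysis settings: QC at 10% missingness and
#' 5% MAF, SNaP candidacy at a 10% failed-call rate with alpha 0.05,
#' association significance at BH-FDR 0.1 with a suggestive threshold of
#' -log10(p) = 3 and QTL support in at least 2 environments, Gabriel LD
#' blocks with Haploview bounds, a 10 kb promoter window, NMC call bounds
#' 0.5/1.5, and a 0.8 relative-score motif threshold. The configuration
#' (and seed) is serialized as YAML into every run directory.
#'
#' @param seed master seed for the simulation stage.
#' @param stages character vector of enabled stages, in dependency order
#'   from `simulate`, `qc`, `snap`, `gwas`, `blocks`, `svcat`, `svgeno`,
#'   `tfbs`.
#' @param ... overrides for any default listed above.
#' @return A list of class `svqtlConfig`.
#' @export
pipelineConfig <- function(seed = 1, stages = c("simulate", "qc", "snap",
                                                "gwas", "blocks", "svcat",
                                                "svgeno", "tfbs"), ...) {
  cfg <- list(
    seed = seed, stages = stages,
    sim = list(nFounders = 7L, markersPerChrom = 60L,
               chroms = c("A02", "C02", "C03"), lengthCM = 100,
               bpPerCM = 4e5, blockCM = 10, sizes = c(60, 60, 60, 60, 60, 54),
               nEnv = 5L, nReps = 2L, grandMean = 120,
               svEffect = -0.88, varG = 1.0, varGE = 0.5, varE = 2,
               meanDepth = 30, dropoutRate = 0.05),
    qc = list(maxMarkerMissing = 0.10, minMaf = 0.05,
              maxIndividualMissing = 0.10),
    snap = list(minFailRate = 0.10, alpha = 0.05, mode = "all"),
    gwas = list(nPcs = 2L, fdr = 0.1, suggestiveNeglog10p = 3.0,
                minEnvironments = 2L),
    blocks = list(minStrongFraction = 0.95),
    svcat = list(promoterBp = 10000),
    nmc = list(lower = 0.5, upper = 1.5),
    tfbs = list(minRelScore = 0.8))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && nm %in% names(cfg))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "svqtlConfig"
  cfg
}

#' Run the SV-QTL pipeline end to end
#'
#' Executes the enabled stages in dependency order — simulate a
#' multiparental DH population with one planted deletion QTL, marker QC,
#' SNaP calling, per-environment kinship+PC-adjusted association scans,
#' LD-block delineation, QTL declaration, SV-gene intersection with the
#' flowering filter, segregation and allelic-effect testing of the planted
#' SV, NMC genotyping on simulated depth, and a motif scan of the deleted
#' sequence — writing per-stage TSV outputs, the serialized configuration
#' and a summary into `outDir`. Identical configurations (same seed)
#' produce byte-identical outputs.
#'
#' @param config from [pipelineConfig()].
#' @param outDir run directory (created).
#' @return Invisibly, a list with the main in-memory results
#'   (`population`, `qc`, `snap`, `scans`, `blocks`, `qtl`, `svReport`,
#'   `segregation`, `effects`, `nmc`, `motifHits`) and `outDir`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run")) {
  stopifnot(inherits(config, "svqtlConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(outDir, "config.yaml"))
  log <- file.path(outDir, "manifest.tsv")
  manifest <- list()
  note <- function(stage, what, n)
    manifest[[length(manifest) + 1L]] <<- data.frame(stage = stage,
                                                     output = what, n = n)
  on.exit(if (length(manifest))
    .writeTSV(do.call(rbind, manifest), log), add = TRUE)
  res <- list(outDir = outDir)
  sc <- config$sim
  stageDir <- function(s) {
    d <- file.path(outDir, s)
    dir.create(d, showWarnings = FALSE)
    d
  }
  run <- function(s) s %in% config$stages

  if (!run("simulate"))
    stop("stage 'simulate' is required in this desk-scale configuration")
  d <- stageDir("simulate")
  map <- geneticMap(sc$chroms, sc$markersPerChrom, sc$lengthCM, sc$bpPerCM)
  svChrom <- sc$chroms[1]
  m1 <- map[map$chrom == svChrom, ]
  svStart <- m1$bp[floor(nrow(m1) / 2)] + 137L
  svLoci <- data.frame(chrom = svChrom, start = svStart,
                       end = svStart + 287L, svtype = "DEL", svlen = 288L,
                       nCarriers = 3L, id = "SVq")
  founders <- simulateFounders(sc$nFounders, map, svLoci, seed = config$seed,
                               blockCM = sc$blockCM)
  pop0 <- makeDHPopulation(founders, sizes = sc$sizes,
                           seed = config$seed + 1L)
  delGR <- founders@svLoci
  pop <- injectCallFailures(pop0, delGR)
  model <- phenotypeModel(grandMean = sc$grandMean,
                          envEffects = seq(-2, 2, length.out = sc$nEnv),
                          qtlEffects = c(SVq = sc$svEffect),
                          varG = sc$varG, varGE = sc$varGE, varE = sc$varE,
                          nReps = sc$nReps)
  pheno <- simulatePhenotypes(pop, model, nEnv = sc$nEnv,
                              seed = config$seed + 2L)
  writeGenotypes(pop, file.path(d, "genotypes.tsv"), seed = config$seed)
  writeGeneticMap(map, file.path(d, "map.tsv"), seed = config$seed)
  writePhenotypes(pheno, file.path(d, "phenotypes.tsv"), seed = config$seed)
  writeSVVcf(svCatalog(svLoci$chrom, svLoci$start, svLoci$end,
                       svLoci$svtype, svLoci$svlen,
                       founderAlleles = founders@svAlleles, id = svLoci$id),
             file.path(d, "sv_truth.vcf"), seed = config$seed)
  note("simulate", "genotypes.tsv", ncol(pop))
  res$population <- pop; res$phenotypes <- pheno; res$founders <- founders

  gmQC <- pop
  if (run("qc")) {
    d <- stageDir("qc")
    qc <- qcFilter(pop, config$qc$maxMarkerMissing, config$qc$minMaf,
                   config$qc$maxIndividualMissing)
    .writeTSV(qc$exclusions, file.path(d, "exclusions.tsv"))
    gmQC <- qc$genotypes
    note("qc", "markers retained", nrow(gmQC))
    res$qc <- qc
  }
  snapGeno <- NULL
  if (run("snap")) {
    d <- stageDir("snap")
    snap <- callSnap(pop, config$snap$minFailRate, config$snap$alpha,
                     config$snap$mode)
    .writeTSV(snap$report, file.path(d, "snap_report.tsv"))
    snapGeno <- snap$genotypes
    note("snap", "accepted SNaP markers",
         if (is.null(snapGeno)) 0L else nrow(snapGeno))
    res$snap <- snap
  }

  scans <- NULL
  if (run("gwas")) {
    d <- stageDir("gwas")
    K <- kinshipMatrix(gmQC)
    ## the SV presence/absence call enters the scan as an extra marker
    svMarker <- GenotypeMatrix(
      matrix(svGenotypes(pop)["SVq", ], 1,
             dimnames = list("SVq", colnames(pop))),
      map = data.frame(chrom = svLoci$chrom, bp = svLoci$start),
      subfamily = subfamily(pop))
    entry <- aggregate(days ~ individual + environment, pheno, mean)
    scans <- lapply(split(entry, entry$environment), function(e) {
      y <- setNames(e$days, e$individual)
      pieces <- list(gmQC, snapGeno, svMarker)
      scan <- do.call(rbind, lapply(Filter(Negate(is.null), pieces),
        function(gm) associationScan(gm, y, kinship = K,
                                     nPcs = config$gwas$nPcs,
                                     environment = e$environment[1])))
      ok <- !is.na(scan$p)             # joint BH across SNP + SNaP + SV
      scan$q <- NA_real_
      scan$q[ok] <- bhFDR(scan$p[ok])
      scan[order(scan$chrom, scan$bp), ]
    })
    all <- do.call(rbind, c(scans, make.row.names = FALSE))
    .writeTSV(all, file.path(d, "associations.tsv"))
    note("gwas", "marker-environment tests", nrow(all))
    res$scans <- scans
  }

  blocks <- NULL
  if (run("blocks")) {
    d <- stageDir("blocks")
    mmQC <- markerMap(gmQC)
    blocks <- do.call(rbind, lapply(unique(mmQC$chrom), function(ch) {
      ld <- pairwiseDprime(gmQC, chrom = ch)
      b <- findBlocks(ld, mmQC[mmQC$chrom == ch, ],
                      config$blocks$minStrongFraction)
      b$chrom <- ch
      b
    }))
    .writeTSV(blocks[, setdiff(colnames(blocks), "markers")],
              file.path(d, "blocks.tsv"))
    writeBed(data.frame(chrom = blocks$chrom, start = blocks$start,
                        end = blocks$end,
                        name = sprintf("block%d", seq_len(nrow(blocks)))),
             file.path(d, "blocks.bed"))
    note("blocks", "LD blocks", nrow(blocks))
    res$blocks <- blocks
  }

  qtl <- NULL
  if (run("gwas")) {
    d <- stageDir("qtl")
    qtl <- declareQtl(res$scans, blocks, fdr = config$gwas$fdr,
                      suggestiveNeglog10p = config$gwas$suggestiveNeglog10p,
                      minEnvironments = config$gwas$minEnvironments)
    .writeTSV(qtl, file.path(d, "qtl.tsv"))
    note("qtl", "declared QTL", nrow(qtl))
    res$qtl <- qtl
  }

  if (run("svcat")) {
    d <- stageDir("svcat")
    svs <- svCatalog(svLoci$chrom, svLoci$start, svLoci$end, svLoci$svtype,
                     svLoci$svlen, founderAlleles = founders@svAlleles,
                     id = svLoci$id)
    genes <- .demoGenes(svs, map)
    cls <- classifyPolymorphism(svs)
    intervals <- if (!is.null(qtl) && nrow(qtl)) qtl
      else if (!is.null(config$intervals)) config$intervals
      else data.frame(qtl = character(), chrom = character(),
                      start = integer(), end = integer())
    rep1 <- qtlSvReport(intervals, svs, genes, config$svcat$promoterBp)
    .writeTSV(rep1, file.path(d, "qtl_sv_report.tsv"))
    note("svcat", "polymorphic SV", length(cls$polymorphic))
    res$svReport <- rep1; res$genes <- genes; res$svs <- svs
  }

  if (run("svgeno")) {
    d <- stageDir("svgeno")
    svg <- svGenotypes(pop)["SVq", ]
    sf <- subfamily(pop)
    seg <- do.call(rbind, lapply(split(seq_along(svg), sf), function(ii) {
      c1 <- sum(svg[ii] == 1L); c2 <- sum(svg[ii] == 0L)
      if (c1 == 0L || c2 == 0L) return(NULL)
      st <- segregationTest(c1, c2)
      data.frame(subfamily = sf[ii[1]], carriers = c1, reference = c2,
                 chi2 = st$chi2, p = st$p, stars = st$stars)
    }))
    .writeTSV(seg, file.path(d, "segregation.tsv"))
    eff <- allelicEffects(svg, pheno)
    .writeTSV(eff, file.path(d, "allelic_effects.tsv"))
    dels <- svGenotypes(pop)["SVq", , drop = TRUE] * 2L  # DH: hom only
    panel <- dels[seq_len(min(24L, length(dels)))]
    tracks <- simulateDepth(panel, founders@svLoci["SVq"],
                            depthSimSpec(sc$meanDepth, sc$dropoutRate),
                            seed = config$seed + 3L)
    nmc <- vapply(tracks, function(tr)
      nmcGenotype(tr, founders@svLoci["SVq"],
                  singleCopyBaseline = TRUE)$call, "")
    .writeTSV(data.frame(individual = names(nmc), call = nmc),
              file.path(d, "nmc_calls.tsv"))
    note("svgeno", "segregation-tested subfamilies",
         if (is.null(seg)) 0L else nrow(seg))
    res$segregation <- seg; res$effects <- eff; res$nmc <- nmc
  }

  if (run("tfbs")) {
    d <- stageDir("tfbs")
    set.seed(config$seed + 4L)
    delSeq <- paste(sample(c("A", "C", "G", "T"), 288, replace = TRUE),
                    collapse = "")
    motif <- .eveningElementPFM()
    site <- consensusString(motif)
    substr(delSeq, 101, 100 + nchar(site)) <- site
    hits <- scanPFM(delSeq, motif, config$tfbs$minRelScore)
    .writeTSV(hits, file.path(d, "motif_hits.tsv"))
    note("tfbs", "motif hits in deleted sequence", nrow(hits))
    res$motifHits <- hits
  }
  invisible(res)
}

## toy annotation: one gene per map decile, the gene nearest the planted SV
## annotated as a flowering-time regulator
.demoGenes <- function(svs, map) {
  rows <- lapply(unique(map$chrom), function(ch) {
    m <- map[map$chrom == ch, ]
    at <- m$bp[seq(5, nrow(m), by = 10)]
    data.frame(chrom = ch, start = at - 1000L, end = at + 1000L)
  })
  g <- do.call(rbind, rows)
  g$start <- pmax(g$start, 1L)
  ids <- sprintf("GENE%03d", seq_len(nrow(g)))
  ann <- rep("ATP binding", nrow(g))
  svMid <- (GenomicRanges::start(svs)[1] + GenomicRanges::end(svs)[1]) / 2
  onChrom <- g$chrom == as.character(GenomicRanges::seqnames(svs))[1]
  near <- which(onChrom)[which.min(abs((g$start[onChrom] + g$end[onChrom]) / 2
                                       - svMid))]
  ann[near] <- "photoperiodism, positive regulation of flower development"
  g$end[near] <- max(g$end[near], GenomicRanges::end(svs)[1] + 100L)
  g$start[near] <- min(g$start[near], GenomicRanges::start(svs)[1] - 100L)
  geneModels(ids, g$chrom, g$start, g$end,
             strand = rep(c("+", "-"), length.out = nrow(g)), annotation = ann)
}

## a CCA1/LHY-class evening-element-like motif (synthetic counts shaped on
## the AAAATATCT core recognized by MYB-related circadian regulators)
.eveningElementPFM <- function() {
  cons <- c("A", "A", "A", "A", "T", "A", "T", "C", "T")
  cts <- matrix(2, 4, length(cons), dimnames = list(c("A", "C", "G", "T"),
                                                    NULL))
  for (j in seq_along(cons)) cts[cons[j], j] <- 24
  pfm(cts, id = "EE_synth", name = "evening-element-like (synthetic)")
}
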