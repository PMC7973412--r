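#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' GenotypeMatrix: marker-by-individual calls for a (multiparental) DH panel
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with two assays:
#' `calls`, an integer matrix of coded allele calls (`0` = allele A, `1` =
#' allele B, `NA` = not called), and `failed`, a logical matrix flagging
#' *systematic* call failures (as produced by array probes falling inside a
#' deletion). A failed cell is always also `NA` in `calls`; random
#' missingness is `NA` with `failed = FALSE`. The two states are kept apart
#' because quality control counts both as missing while SNaP calling uses
#' only the systematic failures.
#'
#' Row metadata carries the marker map (`chrom`, `bp`, and optionally `cM`);
#' column metadata carries the `subfamily` label (the non-common parent of
#' the cross each DH line descends from). For simulated populations,
#' `metadata()` additionally holds the founder set and the true SV genotype
#' matrix (see [svGenotypes()]).
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment]
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

.validGenotypeMatrix <- function(object) {
  msg <- NULL
  an <- names(SummarizedExperiment::assays(object))
  if (!all(c("calls", "failed") %in% an))
    msg <- c(msg, "assays must include 'calls' and 'failed'")
  else {
    calls <- SummarizedExperiment::assay(object, "calls")
    failed <- SummarizedExperiment::assay(object, "failed")
    if (!is.logical(failed))
      msg <- c(msg, "'failed' assay must be logical")
    bad <- calls[!is.na(calls)]
    if (length(bad) && !all(bad %in% c(0L, 1L)))
      msg <- c(msg, "'calls' must be coded 0/1/NA")
    if (any(failed & !is.na(calls)))
      msg <- c(msg, "failed cells must have NA calls")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chrom", "bp") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'chrom' and 'bp'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "marker identifiers must be unique")
  if (!"subfamily" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain 'subfamily'")
  if (is.null(msg)) TRUE else msg
}
setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix (markers x individuals), coded 0/1/NA.
#' @param map data.frame with one row per marker: columns `chrom`, `bp`
#'   (1-based physical position) and optionally `cM`.
#' @param subfamily character/factor of length `ncol(calls)`.
#' @param failed optional logical matrix of systematic call failures;
#'   defaults to all-`FALSE`.
#' @param metadata optional list stored in `metadata()`.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' gm <- GenotypeMatrix(
#'   calls = matrix(c(0L, 1L, 1L, 0L), 2, 2,
#'                  dimnames = list(c("m1", "m2"), c("i1", "i2"))),
#'   map = data.frame(chrom = "A01", bp = c(100L, 200L)),
#'   subfamily = c("FND2", "FND2"))
#' gm
#' @export
GenotypeMatrix <- function(calls, map, subfamily, failed = NULL,
                           metadata = list()) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(failed))
    failed <- matrix(FALSE, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  map <- as.data.frame(map)
  rownames(map) <- NULL
  stopifnot(nrow(map) == nrow(calls), length(subfamily) == ncol(calls))
  calls[failed] <- NA_integer_
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls, failed = failed),
    rowData = S4Vectors::DataFrame(map),
    colData = S4Vectors::DataFrame(subfamily = as.character(subfamily),
                                   row.names = colnames(calls)),
    metadata = metadata)
  rownames(se) <- rownames(calls)
  new("GenotypeMatrix", se)
}

#' FounderSet: inbred founder lines of a multiparental population
#'
#' Holds fully homozygous founder haplotypes at mapped marker positions and
#' founder presence/absence alleles at structural-variant loci. Exactly one
#' founder is flagged as the common parent to which all others are crossed.
#'
#' @slot founders character vector of founder identifiers.
#' @slot commonParent identifier of the common (recurrent) parent.
#' @slot haplotypes integer matrix (markers x founders) of 0/1 alleles.
#' @slot map data.frame marker map (`chrom`, `marker`, `bp`, `cM`).
#' @slot svLoci [GenomicRanges::GRanges] of SV loci with mcols `svtype`
#'   (`DEL`/`INS`) and `svlen`.
#' @slot svAlleles integer matrix (SV loci x founders), 0 = reference,
#'   1 = alternate (carrier).
#' @export
setClass("FounderSet",
  representation(founders = "character", commonParent = "character",
                 haplotypes = "matrix", map = "data.frame",
                 svLoci = "GRanges", svAlleles = "matrix"))

.validFounderSet <- function(object) {
  msg <- NULL
  if (length(object@commonParent) != 1L ||
      !object@commonParent %in% object@founders)
    msg <- c(msg, "exactly one common parent, drawn from the founders")
  if (!identical(colnames(object@haplotypes), object@founders))
    msg <- c(msg, "haplotype columns must match founders")
  h <- object@haplotypes
  if (length(h) && !all(h %in% c(0L, 1L)))
    msg <- c(msg, "founder haplotypes must be homozygous 0/1 (inbred lines)")
  if (nrow(object@svAlleles) != length(object@svLoci))
    msg <- c(msg, "one svAlleles row per SV locus")
  if (is.null(msg)) TRUE else msg
}
setValidity("FounderSet", .validFounderSet)

#' PhenotypeModel: additive multi-environment trait model
#'
#' Describes days-to-flowering (BBCH 61, days after sowing) as
#' `grand mean + environment effect + sum(QTL effect x allele dose) +
#' polygenic effect + GxE deviation + residual`, all noise Gaussian. On an
#' entry-mean basis over `E` environments and `R` replicates the expected
#' broad-sense heritability is
#' `H2 = s2G / (s2G + s2GE/E + s2e/(E*R))` — see [expectedH2()].
#'
#' @slot grandMean numeric, days.
#' @slot envEffects numeric vector, one additive shift (days) per environment.
#' @slot qtlEffects named numeric, allele-substitution effect in days per
#'   locus; names must match marker or SV identifiers in the population.
#'   Negative = carriers of the coded (1) allele flower earlier.
#' @slot varG numeric, variance of an i.i.d. polygenic genotype effect
#'   (days^2); contributes to s2G on top of the explicit QTL effects.
#' @slot varGE numeric, genotype-by-environment variance (days^2).
#' @slot varE numeric, residual (plot) variance (days^2).
#' @slot nReps integer, replicates per environment.
#' @export
setClass("PhenotypeModel",
  representation(grandMean = "numeric", envEffects = "numeric",
                 qtlEffects = "numeric", varG = "numeric", varGE = "numeric",
                 varE = "numeric", nReps = "integer"))

setValidity("PhenotypeModel", function(object) {
  if (object@varG < 0 || object@varGE < 0 || object@varE < 0)
    return("variance components must be non-negative")
  if (object@nReps < 1L) return("nReps must be >= 1")
  TRUE
})

#' @rdname PhenotypeModel-class
#' @param grandMean,envEffects,qtlEffects,varG,varGE,varE,nReps see slots.
#' @export
phenotypeModel <- function(grandMean = 120, envEffects = numeric(),
                           qtlEffects = numeric(), varG = 0, varGE = 0,
                           varE = 1, nReps = 2L) {
  new("PhenotypeModel", grandMean = grandMean, envEffects = envEffects,
      qtlEffects = qtlEffects, varG = varG, varGE = varGE, varE = varE,
      nReps = as.integer(nReps))
}

#' DepthSimSpec: read-depth simulation parameters
#'
#' Per-base depth is Poisson with mean `meanDepth x dosage`, where dosage is
#' 1 inside reference sequence, 0.5 inside a deletion for heterozygous
#' carriers, and `dropoutRate` (the residual rate of spurious short-read
#' mappings) for homozygous deletion carriers.
#'
#' @slot meanDepth numeric, baseline reads per base.
#' @slot dropoutRate numeric in [0, 0.5), residual in-deletion mapping rate.
#' @export
setClass("DepthSimSpec",
  representation(meanDepth = "numeric", dropoutRate = "numeric"))

setValidity("DepthSimSpec", function(object) {
  if (object@meanDepth < 0) return("meanDepth must be non-negative")
  if (object@dropoutRate < 0 || object@dropoutRate >= 0.5)
    return("dropoutRate must satisfy 0 <= rate < 0.5")
  TRUE
})

#' @rdname DepthSimSpec-class
#' @param meanDepth,dropoutRate see slots.
#' @export
depthSimSpec <- function(meanDepth = 30, dropoutRate = 0.05)
  new("DepthSimSpec", meanDepth = meanDepth, dropoutRate = dropoutRate)

#' DepthTrack: per-base read depth over one contiguous region
#'
#' @slot chrom chromosome name.
#' @slot start 1-based position of the first covered base.
#' @slot depth non-negative integer vector, one value per base.
#' @export
setClass("DepthTrack",
  representation(chrom = "character", start = "integer", depth = "integer"))

setValidity("DepthTrack", function(object) {
  if (any(object@depth < 0)) return("depth must be non-negative")
  if (object@start < 1L) return("start must be >= 1")
  TRUE
})

#' @rdname DepthTrack-class
#' @param chrom,start,depth see slots.
#' @export
depthTrack <- function(chrom, start, depth)
  new("DepthTrack", chrom = chrom, start = as.integer(start),
      depth = as.integer(round(depth)))

#' PCRAssay: a product-size PCR assay targeting a structural variant
#'
#' The reference-allele amplicon spans from the 5' end of the forward primer
#' footprint to the 3' end of the reverse primer footprint (1-based,
#' inclusive). Product sizes for SV alleles are predicted by
#' [predictAmplicons()].
#'
#' @slot id assay identifier (e.g. `"P311"`).
#' @slot chrom chromosome name.
#' @slot fwd,rev integer length-2 vectors `c(start, end)` of the two primer
#'   footprints on the reference (fwd upstream of rev).
#' @export
setClass("PCRAssay",
  representation(id = "character", chrom = "character",
                 fwd = "integer", rev = "integer"))

setValidity("PCRAssay", function(object) {
  f <- object@fwd; r <- object@rev
  if (length(f) != 2L || length(r) != 2L) return("primer footprints are c(start, end)")
  if (f[1] > f[2] || r[1] > r[2]) return("footprint start must not exceed end")
  if (f[2] >= r[1]) return("forward footprint must lie upstream of the reverse footprint")
  amp <- r[2] - f[1] + 1L
  if (amp < (f[2] - f[1] + 1L) + (r[2] - r[1] + 1L))
    return("amplicon shorter than the primers")
  TRUE
})

#' @rdname PCRAssay-class
#' @param id,chrom see slots.
#' @param fwd,rev primer footprints, `c(start, end)`, 1-based inclusive.
#' @export
pcrAssay <- function(id, chrom, fwd, rev)
  new("PCRAssay", id = id, chrom = chrom, fwd = as.integer(fwd),
      rev = as.integer(rev))

#' PFM: a position frequency matrix for one transcription-factor motif
#'
#' Counts are stored as a 4 x L matrix (rows A, C, G, T). The log-odds
#' (position weight) matrix is derived lazily by [logOdds()] from the
#' background frequencies and a total pseudocount distributed by background
#' (the JASPAR convention).
#'
#' @slot id motif identifier; @slot name motif name.
#' @slot counts numeric 4 x L matrix, rows named A/C/G/T.
#' @slot background length-4 background frequencies (A, C, G, T), sum 1.
#' @slot pseudocount total pseudocount added per column.
#' @export
setClass("PFM",
  representation(id = "character", name = "character", counts = "matrix",
                 background = "numeric", pseudocount = "numeric"))

setValidity("PFM", function(object) {
  cts <- object@counts
  if (!identical(rownames(cts), c("A", "C", "G", "T")))
    return("count rows must be named A, C, G, T")
  if (ncol(cts) < 1L) return("motif length must be >= 1")
  if (any(cts < 0)) return("counts must be non-negative")
  if (any(colSums(cts) <= 0)) return("every column must have a positive sum")
  if (length(object@background) != 4L || abs(sum(object@background) - 1) > 1e-6)
    return("background must be 4 frequencies summing to 1")
  TRUE
})

#' @rdname PFM-class
#' @param id,name,counts,background,pseudocount see slots.
#' @export
pfm <- function(counts, id = "motif", name = id,
                background = rep(0.25, 4), pseudocount = 0.8) {
  counts <- as.matrix(counts)
  rownames(counts) <- c("A", "C", "G", "T")
  new("PFM", id = id, name = name, counts = counts,
      background = background, pseudocount = pseudocount)
}
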