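#' @include AllClasses.R
NULL

#' Accessors for GenotypeMatrix and FounderSet objects
#'
#' @param x a [GenotypeMatrix-class] or [FounderSet-class] object.
#' @return `genotypeCalls`: the integer 0/1/NA call matrix.
#'   `failedCalls`: the logical matrix of systematic call failures.
#'   `markerMap`: the marker map as a data.frame (`marker`, `chrom`, `bp`,
#'   and `cM` when present). `subfamily`: per-individual subfamily labels.
#'   `svGenotypes`: the true SV dosage matrix (SV loci x individuals) for
#'   simulated populations, or `NULL`. `founderNames` / `commonParent` /
#'   `founderHaplotypes` / `svAlleles` / `svLoci`: the corresponding
#'   founder-set components.
#' @name accessors
NULL

#' @rdname accessors
#' @export
genotypeCalls <- function(x) SummarizedExperiment::assay(x, "calls")

#' @rdname accessors
#' @export
failedCalls <- function(x) SummarizedExperiment::assay(x, "failed")

#' @rdname accessors
#' @export
markerMap <- function(x) {
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  data.frame(marker = rownames(x), rd, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @export
subfamily <- function(x) SummarizedExperiment::colData(x)$subfamily

#' @rdname accessors
#' @export
svGenotypes <- function(x) S4Vectors::metadata(x)$svGeno

#' @rdname accessors
#' @export
founderNames <- function(x) x@founders

#' @rdname accessors
#' @export
commonParent <- function(x) x@commonParent

#' @rdname accessors
#' @export
founderHaplotypes <- function(x) x@haplotypes

#' @rdname accessors
#' @export
svAlleles <- function(x) x@svAlleles

#' @rdname accessors
#' @export
svLoci <- function(x) x@svLoci

#' @export
setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d markers x %d individuals\n",
              nrow(object), ncol(object)))
  sf <- table(subfamily(object))
  cat(sprintf("  subfamilies: %s\n",
              paste(sprintf("%s (%d)", names(sf), sf), collapse = ", ")))
  calls <- genotypeCalls(object)
  cat(sprintf("  missing: %.1f%%; failed: %.1f%%\n",
              100 * mean(is.na(calls)), 100 * mean(failedCalls(object))))
  chr <- unique(SummarizedExperiment::rowData(object)$chrom)
  cat(sprintf("  chromosomes: %s\n", paste(chr, collapse = ", ")))
  sv <- svGenotypes(object)
  if (!is.null(sv))
    cat(sprintf("  simulated SV loci: %d\n", nrow(sv)))
})

#' @export
setMethod("show", "FounderSet", function(object) {
  cat(sprintf("FounderSet: %d founders (common parent: %s)\n",
              length(object@founders), object@commonParent))
  cat(sprintf("  %d mapped markers on %s\n", nrow(object@haplotypes),
              paste(unique(object@map$chrom), collapse = ", ")))
  cat(sprintf("  %d SV loci\n", length(object@svLoci)))
})

#' @export
setMethod("show", "PFM", function(object) {
  cat(sprintf("PFM %s (%s): length %d, pseudocount %.2f\n",
              object@id, object@name, ncol(object@counts),
              object@pseudocount))
  cat(sprintf("  consensus: %s\n", consensusString(object)))
})

#' @export
setMethod("show", "DepthTrack", function(object) {
  cat(sprintf("DepthTrack %s:%d-%d, mean depth %.1f\n", object@chrom,
              object@start, object@start + length(object@depth) - 1L,
              mean(object@depth)))
})
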