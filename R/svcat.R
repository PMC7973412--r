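#' @include AllClasses.R
#' @importFrom GenomicRanges GRanges findOverlaps promoters strand trim
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Construct an SV catalog
#'
#' An SV catalog is a [GenomicRanges::GRanges] with metadata columns
#' `svtype` (`DEL`/`INS`), `svlen` (bp; for insertions the inserted
#' length), and `founderAlleles` (a matrix column, one column per founder:
#' 0 = reference, 1 = alternate, `NA` = unknown). Deletions span their
#' reference footprint (`width == svlen`); insertions are anchored at a
#' single reference base (`width == 1`).
#'
#' @param chrom,start,end 1-based inclusive reference coordinates.
#' @param svtype `"DEL"` or `"INS"`.
#' @param svlen SV size in bp (minimum detectable size 30 bp).
#' @param founderAlleles integer matrix (SV x founders) or `NULL`.
#' @param id SV names.
#' @return A `GRanges` SV catalog.
#' @export
svCatalog <- function(chrom, start, end, svtype, svlen,
                      founderAlleles = NULL, id = NULL) {
  stopifnot(all(svtype %in% c("DEL", "INS")), all(svlen >= 30))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  if (is.null(id)) id <- sprintf("SV%d", seq_along(gr))
  names(gr) <- id
  bad <- svtype == "DEL" & GenomicRanges::width(gr) != svlen
  if (any(bad))
    stop("deletion span must equal svlen: ", paste(id[bad], collapse = ", "))
  if (any(svtype == "INS" & GenomicRanges::width(gr) != 1L))
    stop("insertions must be anchored at a single base")
  S4Vectors::mcols(gr)$svtype <- svtype
  S4Vectors::mcols(gr)$svlen <- as.integer(svlen)
  if (!is.null(founderAlleles)) {
    founderAlleles <- as.matrix(founderAlleles)
    stopifnot(nrow(founderAlleles) == length(gr))
    S4Vectors::mcols(gr)$founderAlleles <- founderAlleles
  }
  gr
}

#' Partition an SV catalog into polymorphic and monomorphic calls
#'
#' An SV is *monomorphic* when all founders with a known allele agree —
#' including the all-alternate case, a shared difference from the
#' reference — and *polymorphic* otherwise. Records whose founder alleles
#' are all unknown cannot be classified and are returned separately.
#'
#' @param svs SV catalog from [svCatalog()] with `founderAlleles`.
#' @return List of `GRanges`: `polymorphic`, `monomorphic`, `unknown`.
#' @export
classifyPolymorphism <- function(svs) {
  fa <- S4Vectors::mcols(svs)$founderAlleles
  if (is.null(fa)) stop("founder alleles absent from the catalog")
  known <- rowSums(!is.na(fa))
  alt <- rowSums(fa == 1L, na.rm = TRUE)
  unknown <- known == 0L
  poly <- !unknown & alt > 0L & alt < known
  list(polymorphic = svs[poly],
       monomorphic = svs[!poly & !unknown],
       unknown = svs[unknown])
}

#' Tabulate SV sizes into the four standard classes
#'
#' Half-open, lower-inclusive bins: \[30, 100), \[100, 1000),
#' \[1000, 10000) and >= 10000 bp, counted per SV type.
#'
#' @param svs SV catalog.
#' @return Contingency table (type x size class); class counts sum to the
#'   number of records.
#' @export
sizeClasses <- function(svs) {
  svlen <- S4Vectors::mcols(svs)$svlen
  stopifnot(all(svlen >= 30))
  cls <- cut(svlen, breaks = c(30, 100, 1000, 10000, Inf), right = FALSE,
             labels = c("[30,100)", "[100,1000)", "[1000,10000)", ">=10000"))
  table(type = S4Vectors::mcols(svs)$svtype, class = cls)
}

#' Build a gene model GRanges
#'
#' @param id gene identifiers; @param chrom,start,end 1-based inclusive
#'   gene body coordinates; @param strand `"+"`/`"-"`;
#'   @param annotation free-text functional description (GO/Blast2GO).
#' @return `GRanges` with mcols `gene_id`, `annotation`.
#' @export
geneModels <- function(id, chrom, start, end, strand, annotation = "") {
  stopifnot(all(start < end), all(strand %in% c("+", "-")))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  names(gr) <- id
  S4Vectors::mcols(gr)$gene_id <- id
  S4Vectors::mcols(gr)$annotation <- rep_len(annotation, length(gr))
  gr
}

#' Intersect SV with gene bodies and promoter windows
#'
#' A hit is *intragenic* when the SV footprint overlaps the gene body, and
#' *promoter* when it overlaps the `promoterBp` window immediately
#' upstream of the gene start on the coding strand (anchored at the
#' annotated gene start, an approximation of the start codon). Insertions
#' intersect as their 1 bp anchor. An SV may hit several genes, and a gene
#' both ways.
#'
#' @param svs SV catalog; @param genes gene `GRanges` (see [geneModels()]
#'   or [readGenesGff()]); @param promoterBp promoter window length.
#' @return data.frame: `sv`, `gene_id`, `relation` in
#'   `{intragenic, promoter}`.
#' @export
intersectGenes <- function(svs, genes, promoterBp = 10000) {
  badChr <- !as.character(GenomicRanges::seqnames(svs)) %in%
    unique(as.character(GenomicRanges::seqnames(genes)))
  if (any(badChr))
    stop("SV on chromosome(s) absent from the annotation: ",
         paste(names(svs)[badChr], collapse = ", "))
  hitRows <- function(ov, relation) {
    if (length(ov) == 0L) return(NULL)
    data.frame(sv = names(svs)[S4Vectors::queryHits(ov)],
               gene_id = S4Vectors::mcols(genes)$gene_id[S4Vectors::subjectHits(ov)],
               relation = relation, stringsAsFactors = FALSE)
  }
  ovGene <- GenomicRanges::findOverlaps(svs, genes, ignore.strand = TRUE)
  prom <- suppressWarnings(
    GenomicRanges::trim(GenomicRanges::promoters(genes, upstream = promoterBp,
                                                 downstream = 0)))
  prom <- prom[GenomicRanges::width(prom) > 0]
  ovProm <- GenomicRanges::findOverlaps(svs, prom, ignore.strand = TRUE)
  out <- rbind(hitRows(ovGene, "intragenic"),
               if (length(ovProm))
                 data.frame(sv = names(svs)[S4Vectors::queryHits(ovProm)],
                            gene_id = S4Vectors::mcols(prom)$gene_id[S4Vectors::subjectHits(ovProm)],
                            relation = "promoter", stringsAsFactors = FALSE))
  if (is.null(out))
    out <- data.frame(sv = character(), gene_id = character(),
                      relation = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.floweringKeywords <- c("flower", "vernalization", "photoperiod", "circadian",
                        "floral", "vegetative to reproductive",
                        "vegetative phase change", "pollen", "carpel",
                        "sepal", "petal")

#' Flag flowering-time candidate genes by annotation keywords
#'
#' Case-insensitive substring match of the functional annotation against a
#' configurable keyword list covering flowering, vernalization,
#' photoperiod/circadian regulation, phase change and floral organ terms.
#'
#' @param genes gene `GRanges` with an `annotation` mcol.
#' @param keywords keyword list (defaults above).
#' @return The subset of `genes` whose annotation matches any keyword.
#' @export
floweringFilter <- function(genes, keywords = .floweringKeywords) {
  ann <- tolower(S4Vectors::mcols(genes)$annotation)
  ann[is.na(ann)] <- ""
  hit <- Reduce(`|`, lapply(tolower(keywords), function(k)
    grepl(k, ann, fixed = TRUE)))
  genes[hit]
}

#' Per-QTL gene / flowering-gene / SV intersection report
#'
#' For every QTL interval: the number of contained genes, the
#' flowering-annotated subset (with percentage), the SV-bearing subset
#' (intragenic or promoter hits, with percentage), and the SV-bearing
#' flowering genes listed with their SV name, size and type.
#'
#' @param qtls QTL data.frame from [declareQtl()] (needs `qtl`, `chrom`,
#'   `start`, `end`).
#' @param svs SV catalog; @param genes gene `GRanges`;
#' @param promoterBp promoter window passed to [intersectGenes()].
#' @return data.frame, one row per QTL: `qtl`, `size_kb`, `n_genes`,
#'   `n_flowering`, `pct_flowering`, `n_sv_genes`, `n_sv_flowering`,
#'   `sv_flowering_genes`, `sv_events` (dashes when empty).
#' @export
qtlSvReport <- function(qtls, svs, genes, promoterBp = 10000) {
  if (nrow(qtls) == 0L)
    return(data.frame(qtl = character(), size_kb = numeric(),
                      n_genes = integer(), n_flowering = integer(),
                      pct_flowering = numeric(), n_sv_genes = integer(),
                      n_sv_flowering = integer(),
                      sv_flowering_genes = character(),
                      sv_events = character(), stringsAsFactors = FALSE))
  flow <- names(floweringFilter(genes))
  hits <- intersectGenes(svs, genes, promoterBp = promoterBp)
  rows <- lapply(seq_len(nrow(qtls)), function(k) {
    qr <- GenomicRanges::GRanges(qtls$chrom[k],
                                 IRanges::IRanges(qtls$start[k], qtls$end[k]))
    inQ <- genes[IRanges::overlapsAny(genes, qr, ignore.strand = TRUE)]
    gid <- S4Vectors::mcols(inQ)$gene_id
    nG <- length(gid)
    fl <- intersect(gid, flow)
    svG <- intersect(gid, unique(hits$gene_id))
    svFl <- intersect(fl, svG)
    ev <- hits[hits$gene_id %in% svFl, , drop = FALSE]
    svDesc <- if (nrow(ev)) paste(sprintf(
      "%s: %d bp %s (%s)", ev$sv,
      S4Vectors::mcols(svs)$svlen[match(ev$sv, names(svs))],
      c(DEL = "deletion", INS = "insertion")[
        S4Vectors::mcols(svs)$svtype[match(ev$sv, names(svs))]],
      ev$relation), collapse = "; ") else "-"
    data.frame(qtl = qtls$qtl[k],
               size_kb = (qtls$end[k] - qtls$start[k]) / 1000,
               n_genes = nG, n_flowering = length(fl),
               pct_flowering = if (nG) round(100 * length(fl) / nG, 1) else NA,
               n_sv_genes = length(svG), n_sv_flowering = length(svFl),
               sv_flowering_genes = if (length(svFl)) paste(svFl, collapse = ";")
                                    else "-",
               sv_events = svDesc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
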