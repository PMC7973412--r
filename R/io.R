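#' @include AllClasses.R
#' @importFrom utils read.delim write.table
NULL

## TSV with '#'-prefixed header comments (used to embed the seed)
.writeTSV <- function(df, file, comments = character()) {
  con <- file(file, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Tabular writers for pipeline outputs
#'
#' All writers emit TSV with optional `#` header comments; by convention
#' the simulation seed is embedded as a comment so every output is
#' traceable to its generating configuration.
#'
#' @param pop,map,pheno,blocks,results objects to serialize.
#' @param file output path.
#' @param seed optional seed recorded in the header.
#' @name writers
NULL

#' @rdname writers
#' @export
writeGenotypes <- function(pop, file, seed = NULL) {
  calls <- genotypeCalls(pop)
  st <- matrix("A", nrow(calls), ncol(calls))
  st[calls == 1L] <- "B"
  st[is.na(calls)] <- "NA"
  st[failedCalls(pop)] <- "FAIL"
  df <- data.frame(marker = rownames(pop), markerMap(pop)[c("chrom", "bp")],
                   st, check.names = FALSE)
  colnames(df)[-(1:3)] <- colnames(pop)
  cm <- c(sprintf("subfamily: %s", paste(subfamily(pop), collapse = ",")),
          if (!is.null(seed)) sprintf("seed: %d", seed))
  .writeTSV(df, file, cm)
}

#' Read a tabular genotype matrix written by [writeGenotypes()]
#' @param file path.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(file) {
  hdr <- grep("^#", readLines(file, n = 20L), value = TRUE)
  df <- read.delim(file, comment.char = "#", check.names = FALSE,
                   colClasses = "character")
  st <- as.matrix(df[, -(1:3), drop = FALSE])
  calls <- matrix(NA_integer_, nrow(st), ncol(st), dimnames = dimnames(st))
  calls[st == "A"] <- 0L
  calls[st == "B"] <- 1L
  failed <- st == "FAIL"
  rownames(calls) <- rownames(failed) <- df$marker
  sfLine <- sub("^# subfamily: ", "", grep("subfamily:", hdr, value = TRUE))
  subf <- if (length(sfLine)) strsplit(sfLine, ",")[[1]]
          else rep(NA_character_, ncol(calls))
  GenotypeMatrix(calls,
                 map = data.frame(chrom = df$chrom, bp = as.integer(df$bp)),
                 subfamily = subf, failed = failed)
}

#' @rdname writers
#' @export
writeGeneticMap <- function(map, file, seed = NULL)
  .writeTSV(map[, c("chrom", "marker", "bp", "cM")], file,
            if (!is.null(seed)) sprintf("seed: %d", seed))

#' @rdname writers
#' @export
writePhenotypes <- function(pheno, file, seed = NULL)
  .writeTSV(pheno, file, if (!is.null(seed)) sprintf("seed: %d", seed))

#' Write a depth track as bedGraph (0-based half-open intervals)
#'
#' Consecutive equal-depth bases are collapsed into one interval.
#'
#' @param track a [DepthTrack-class]; @param file path;
#' @param seed optional seed comment.
#' @export
writeBedGraph <- function(track, file, seed = NULL) {
  d <- track@depth
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  df <- data.frame(chrom = track@chrom,
                   start = track@start - 1L + starts,  # 0-based
                   end = track@start - 1L + ends,      # half-open
                   depth = r$values)
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  writeLines("track type=bedGraph", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Read a bedGraph depth track (one contiguous region)
#' @param file path.
#' @return A [DepthTrack-class].
#' @export
readBedGraph <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^(#|track)", lines)]
  df <- read.delim(text = lines, header = FALSE,
                   col.names = c("chrom", "start", "end", "depth"))
  depth <- rep(df$depth, df$end - df$start)
  depthTrack(df$chrom[1], df$start[1] + 1L, depth)
}

#' Write an SV catalog as a minimal VCF (DEL/INS with SVTYPE/SVLEN/END)
#'
#' Deletions use `POS = start - 1` padding-base convention with `END` the
#' last deleted base and negative `SVLEN`; insertions anchor at `POS` with
#' positive `SVLEN`.
#'
#' @param svs SV catalog ([svCatalog()]); @param file path;
#' @param seed optional seed comment.
#' @export
writeSVVcf <- function(svs, file, seed = NULL) {
  mc <- S4Vectors::mcols(svs)
  del <- mc$svtype == "DEL"
  pos <- ifelse(del, pmax(GenomicRanges::start(svs) - 1L, 1L),
                GenomicRanges::start(svs))
  info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", mc$svtype,
                  ifelse(del, -mc$svlen, mc$svlen),
                  GenomicRanges::end(svs))
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(seed)) sprintf("##seed=%d", seed),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\t%s",
                  as.character(GenomicRanges::seqnames(svs)), pos,
                  names(svs), mc$svtype, info)
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Read DEL/INS records from a VCF into an SV catalog
#'
#' Uses symbolic-allele records with `SVTYPE`, `SVLEN` and `END` INFO
#' fields; other record types are ignored.
#'
#' @param file VCF path.
#' @return An SV-catalog `GRanges` (no founder alleles).
#' @export
readSVVcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  svtype <- vcfR::extract.info(v, "SVTYPE")
  svlen <- suppressWarnings(abs(as.integer(vcfR::extract.info(v, "SVLEN"))))
  endp <- suppressWarnings(as.integer(vcfR::extract.info(v, "END")))
  keep <- svtype %in% c("DEL", "INS")
  pos <- as.integer(fix$POS)[keep]
  svtype <- svtype[keep]; svlen <- svlen[keep]; endp <- endp[keep]
  start <- ifelse(svtype == "DEL", pos + 1L, pos)  # undo padding base
  end <- ifelse(svtype == "DEL", endp, pos)
  svCatalog(fix$CHROM[keep], start, end, svtype, svlen,
            id = fix$ID[keep])
}

#' Write LD blocks / SV as BED (0-based half-open)
#'
#' @param x data.frame with `chrom`, `start`, `end` (1-based inclusive)
#'   and optionally a name column, or a `GRanges`.
#' @param file path; @param seed optional seed comment.
#' @export
writeBed <- function(x, file, seed = NULL) {
  if (is(x, "GRanges"))
    x <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                    start = GenomicRanges::start(x),
                    end = GenomicRanges::end(x),
                    name = if (!is.null(names(x))) names(x) else ".")
  nm <- if ("name" %in% colnames(x)) x$name
        else if ("qtl" %in% colnames(x)) x$qtl else "."
  df <- data.frame(x$chrom, x$start - 1L, x$end, nm)
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Read gene models from GFF3
#'
#' Imports `gene`-type features; the functional annotation is taken from
#' the `description` or `Note` attribute when present.
#'
#' @param file GFF3 path.
#' @return Gene `GRanges` with mcols `gene_id`, `annotation`.
#' @export
readGenesGff <- function(file) {
  gff <- rtracklayer::import(file, format = "gff3")
  genes <- gff[gff$type == "gene"]
  ann <- if ("description" %in% colnames(S4Vectors::mcols(genes)))
    genes$description
  else if ("Note" %in% colnames(S4Vectors::mcols(genes)))
    vapply(genes$Note, function(x) paste(x, collapse = "; "), "")
  else ""
  ids <- if (!is.null(genes$ID)) genes$ID else genes$Name
  geneModels(ids, as.character(GenomicRanges::seqnames(genes)),
             GenomicRanges::start(genes), GenomicRanges::end(genes),
             as.character(GenomicRanges::strand(genes)),
             as.character(ann))
}
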