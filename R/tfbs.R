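#' @include AllClasses.R
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   consensusString readDNAStringSet writeXStringSet
NULL

#' Log-odds (position weight) matrix of a PFM
#'
#' Column counts are converted to corrected probabilities with a total
#' pseudocount distributed by the background frequencies (the JASPAR
#' convention), then to base-2 log-odds against the background.
#'
#' @param x a [PFM-class].
#' @return 4 x L numeric matrix (rows A, C, G, T).
#' @export
logOdds <- function(x) {
  stopifnot(is(x, "PFM"))
  cts <- x@counts
  bg <- x@background
  q <- sweep(cts + x@pseudocount * bg, 2, colSums(cts) + x@pseudocount, "/")
  log2(q / bg)
}

#' @exportMethods consensusString
setMethod(Biostrings::consensusString, "PFM", function(x, ...) {
  paste(rownames(x@counts)[apply(x@counts, 2, which.max)], collapse = "")
})

#' Read motifs in JASPAR format
#'
#' Parses the JASPAR .jaspar/.pfm text format: a `>ID NAME` header
#' followed by four count rows, either bare numbers or the bracketed
#' `A [ 4 19 0 ]` style. Row-length mismatches and negative counts raise
#' a parse error naming the offending line.
#'
#' @param file path to a JASPAR file, or a character vector of lines via
#'   `text`.
#' @param text character vector of lines (alternative to `file`).
#' @param background,pseudocount stored into each [PFM-class].
#' @return A named list of [PFM-class] objects.
#' @export
readJaspar <- function(file = NULL, text = NULL, background = rep(0.25, 4),
                       pseudocount = 0.8) {
  lines <- if (!is.null(text)) text else readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no JASPAR header ('>') found")
  motifs <- list()
  for (s in seq_along(starts)) {
    from <- starts[s]
    to <- if (s < length(starts)) starts[s + 1] - 1L else length(lines)
    hdr <- strsplit(sub("^>\\s*", "", lines[from]), "\\s+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else id
    body <- lines[seq.int(from + 1L, to)]
    if (length(body) != 4L)
      stop("motif ", id, ": expected 4 count rows, got ", length(body),
           " (line ", from, ")")
    rows <- lapply(seq_along(body), function(k) {
      ln <- gsub("^[ACGTacgt]\\s*", "", trimws(body[k]))
      ln <- gsub("[][]", " ", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (anyNA(vals))
        stop("motif ", id, ": unparseable counts on line ", from + k)
      if (any(vals < 0))
        stop("motif ", id, ": negative count on line ", from + k)
      vals
    })
    L <- lengths(rows)
    if (length(unique(L)) != 1L)
      stop("motif ", id, ": row-length mismatch (line ", from + which(L != L[1])[1],
           ")")
    cts <- do.call(rbind, rows)
    motifs[[id]] <- pfm(cts, id = id, name = name, background = background,
                        pseudocount = pseudocount)
  }
  motifs
}

#' Write motifs in JASPAR format
#'
#' @param motifs a [PFM-class] or list thereof.
#' @param file output path.
#' @export
writeJaspar <- function(motifs, file) {
  if (is(motifs, "PFM")) motifs <- list(motifs)
  out <- unlist(lapply(motifs, function(m) {
    c(sprintf(">%s %s", m@id, m@name),
      vapply(rownames(m@counts), function(r)
        sprintf("%s [ %s ]", r,
                paste(format(m@counts[r, ], trim = TRUE), collapse = " ")),
        ""))
  }))
  writeLines(out, file)
  invisible(file)
}

.BASES <- c("A", "C", "G", "T")

#' Scan a sequence for motif hits on both strands
#'
#' Every window of motif length is scored with the log-odds matrix on the
#' plus strand and on the reverse complement; windows containing `N` (or
#' any non-ACGT base) are skipped. Scores are reported relative to the
#' motif's attainable range: `rel = (score - min) / (max - min)`, where
#' min/max are the column-wise extremes of the log-odds matrix, so a
#' motif's consensus sequence scores exactly 1.
#'
#' @param seq nucleotide string (or `DNAString`) over A/C/G/T/N.
#' @param motif a [PFM-class].
#' @param minRelScore minimum relative score of a reported hit.
#' @return data.frame sorted by position: `motif`, `position` (0-based
#'   offset of the window on the query), `strand`, `score` (log-odds),
#'   `relScore`. Empty when the sequence is shorter than the motif.
#' @examples
#' m <- pfm(rbind(c(9, 9, 9), c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)))
#' scanPFM("GGAAAGG", m)       # plus-strand hit at offset 2
#' scanPFM("CCTTTCC", m)       # minus-strand hit
#' @export
scanPFM <- function(seq, motif, minRelScore = 0.8) {
  stopifnot(is(motif, "PFM"))
  seq <- toupper(as.character(seq))
  pwm <- logOdds(motif)
  L <- ncol(pwm)
  empty <- data.frame(motif = character(), position = integer(),
                      strand = character(), score = numeric(),
                      relScore = numeric(), stringsAsFactors = FALSE)
  n <- nchar(seq)
  if (n < L) return(empty)
  minS <- sum(apply(pwm, 2, min))
  maxS <- sum(apply(pwm, 2, max))
  chars <- strsplit(seq, "")[[1]]
  code <- match(chars, .BASES)          # NA for N or other symbols
  rcseq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    gsub("[^ACGT]", "N", seq))))
  codeRC <- match(strsplit(rcseq, "")[[1]], .BASES)

  scoreStrand <- function(cd) {
    nw <- n - L + 1L
    sc <- rep(0, nw)
    okAll <- rep(TRUE, nw)
    for (k in seq_len(L)) {
      ck <- cd[seq.int(k, k + nw - 1L)]
      ok <- !is.na(ck)
      okAll <- okAll & ok
      ckf <- ifelse(ok, ck, 1L)
      sc <- sc + pwm[cbind(ckf, k)]
    }
    sc[!okAll] <- NA_real_
    sc
  }
  plus <- scoreStrand(code)
  minusRC <- scoreStrand(codeRC)
  ## window at RC offset i (0-based) covers query offset n - L - i
  minus <- rev(minusRC)

  mk <- function(sc, strand) {
    rel <- (sc - minS) / (maxS - minS)
    keep <- !is.na(rel) & rel >= minRelScore
    if (!any(keep)) return(NULL)
    data.frame(motif = motif@id, position = which(keep) - 1L,
               strand = strand, score = sc[keep], relScore = rel[keep],
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(plus, "+"), mk(minus, "-"))
  if (is.null(out)) return(empty)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
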