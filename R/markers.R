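#' @include AllClasses.R
NULL

#' Marker and individual quality control
#'
#' Applies the standard array-QC cascade: individuals with more than
#' `maxIndividualMissing` missing data are removed first; then markers with
#' more than `maxMarkerMissing` missing data or a minor allele frequency
#' below `minMaf` are excluded. "Missing" counts both random missingness
#' and systematic call failures. MAF is computed on the retained
#' individuals. The filter is idempotent.
#'
#' @param g a [GenotypeMatrix-class].
#' @param maxMarkerMissing,maxIndividualMissing maximum tolerated missing
#'   fraction (exclusive thresholds: a marker at exactly the threshold is
#'   kept).
#' @param minMaf minimum minor allele frequency (exclusive: MAF exactly at
#'   the threshold is kept).
#' @return List with `genotypes` (the filtered [GenotypeMatrix-class]) and
#'   `exclusions` (data.frame `id`, `type`, `reason`, `value`).
#' @examples
#' fs <- simulateFounders(3, geneticMap("A01", 30), seed = 1)
#' pop <- makeDHPopulation(fs, sizes = c(20, 20), seed = 2)
#' qc <- qcFilter(pop)
#' nrow(qc$genotypes); nrow(qc$exclusions)
#' @export
qcFilter <- function(g, maxMarkerMissing = 0.10, minMaf = 0.05,
                     maxIndividualMissing = 0.10) {
  stopifnot(is(g, "GenotypeMatrix"), nrow(g) > 0L, ncol(g) > 0L)
  calls0 <- genotypeCalls(g)
  keepInd <- rep(TRUE, ncol(calls0))
  keepMk <- rep(TRUE, nrow(calls0))
  excl <- list()
  ## iterate to a fixed point: removing a marker changes individual
  ## missingness and vice versa; at convergence the filter is idempotent
  repeat {
    calls <- calls0[keepMk, keepInd, drop = FALSE]
    if (ncol(calls) == 0L) stop("no individuals survive quality control")

    indMiss <- colMeans(is.na(calls))
    badInd <- indMiss > maxIndividualMissing
    if (any(badInd)) {
      excl[[length(excl) + 1L]] <- data.frame(
        id = colnames(calls)[badInd], type = "individual",
        reason = "missingness", value = unname(indMiss[badInd]))
      keepInd[match(colnames(calls)[badInd], colnames(calls0))] <- FALSE
      calls <- calls[, !badInd, drop = FALSE]
      if (ncol(calls) == 0L) stop("no individuals survive quality control")
    }
    mkMiss <- rowMeans(is.na(calls))
    badMiss <- mkMiss > maxMarkerMissing
    if (any(badMiss))
      excl[[length(excl) + 1L]] <- data.frame(
        id = rownames(calls)[badMiss], type = "marker",
        reason = "missingness", value = unname(mkMiss[badMiss]))
    p <- rowMeans(calls, na.rm = TRUE)
    maf <- pmin(p, 1 - p)
    maf[is.nan(maf)] <- 0
    badMaf <- !badMiss & maf < minMaf
    if (any(badMaf))
      excl[[length(excl) + 1L]] <- data.frame(
        id = rownames(calls)[badMaf], type = "marker", reason = "maf",
        value = unname(maf[badMaf]))
    badMk <- badMiss | badMaf
    keepMk[match(rownames(calls)[badMk], rownames(calls0))] <- FALSE
    if (!any(keepMk)) stop("no markers survive quality control")
    if (!any(badInd) && !any(badMk)) break
  }
  exclusions <- if (length(excl))
    do.call(rbind, c(excl, make.row.names = FALSE))
  else data.frame(id = character(), type = character(),
                  reason = character(), value = numeric())
  list(genotypes = g[keepMk, keepInd], exclusions = exclusions)
}

#' Call SNaP markers from systematic array failure
#'
#' A SNaP (single nucleotide absence polymorphism) marker is an array locus
#' whose probe site is deleted in part of the population: calls fail
#' systematically in carriers. Candidates are markers whose failed-call
#' fraction is at least `minFailRate`. Within each subfamily where both
#' states occur (a polymorphic subfamily), presence (successful call) vs
#' absence (failed call) counts are tested against the 1:1 DH expectation
#' with a one-df chi-square goodness-of-fit test (no continuity
#' correction). A candidate is accepted when at least one subfamily is
#' polymorphic and the 1:1 test is not rejected (`p >= alpha`) in all
#' polymorphic subfamilies (`mode = "all"`) or in at least one
#' (`mode = "any"`). Accepted markers are recoded as dominant
#' presence/absence calls: 1 = absence (deleted probe site), 0 = presence;
#' random missingness stays `NA`.
#'
#' @param g a [GenotypeMatrix-class] with `failed` states.
#' @param minFailRate minimum overall failed-call fraction for candidacy.
#' @param alpha significance level of the per-subfamily 1:1 test.
#' @param mode acceptance rule across polymorphic subfamilies.
#' @return List with `report` (data.frame: `marker`, `subfamily`,
#'   `presence`, `absence`, `chi2`, `p`, `accepted`) and `genotypes`
#'   (a [GenotypeMatrix-class] of accepted markers, dominant-coded, with
#'   marker ids suffixed `_SNaP`).
#' @export
callSnap <- function(g, minFailRate = 0.10, alpha = 0.05,
                     mode = c("all", "any")) {
  mode <- match.arg(mode)
  stopifnot(is(g, "GenotypeMatrix"))
  failed <- failedCalls(g)
  calls <- genotypeCalls(g)
  sf <- subfamily(g)
  cand <- which(rowMeans(failed) >= minFailRate)

  rows <- list()
  accepted <- character()
  for (i in cand) {
    fi <- failed[i, ]
    typed <- fi | !is.na(calls[i, ])   # untyped = random missing
    pres <- tapply(!fi & typed, sf, sum)
    abs_ <- tapply(fi, sf, sum)
    poly <- pres > 0 & abs_ > 0
    if (!any(poly)) next               # monomorphic everywhere: nothing to map
    chi2 <- p <- rep(NA_real_, length(pres))
    for (k in which(poly)) {
      tst <- segregationTest(pres[[k]], abs_[[k]])
      chi2[k] <- tst$chi2; p[k] <- tst$p
    }
    ok <- if (mode == "all") all(p[poly] >= alpha) else any(p[poly] >= alpha)
    if (ok) accepted <- c(accepted, rownames(g)[i])
    rows[[length(rows) + 1L]] <- data.frame(
      marker = rownames(g)[i], subfamily = names(pres),
      presence = as.integer(pres), absence = as.integer(abs_),
      chi2 = chi2, p = p, accepted = ok, row.names = NULL)
  }
  report <- if (length(rows)) do.call(rbind, rows)
            else data.frame(marker = character(), subfamily = character(),
                            presence = integer(), absence = integer(),
                            chi2 = numeric(), p = numeric(),
                            accepted = logical())
  geno <- NULL
  if (length(accepted)) {
    idx <- match(accepted, rownames(g))
    rec <- ifelse(failed[idx, , drop = FALSE], 1L,
                  ifelse(is.na(calls[idx, , drop = FALSE]), NA_integer_, 0L))
    rownames(rec) <- paste0(accepted, "_SNaP")
    colnames(rec) <- colnames(g)
    mp <- as.data.frame(SummarizedExperiment::rowData(g))[idx, , drop = FALSE]
    geno <- GenotypeMatrix(rec, map = mp, subfamily = sf)
  }
  list(report = report, genotypes = geno)
}
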