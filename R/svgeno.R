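#' @include AllClasses.R
NULL

#' Predict PCR product sizes for the reference and SV alleles
#'
#' The reference allele always yields the reference amplicon length. For
#' the alternate allele: a deletion lying strictly between the two primer
#' footprints shortens the product by its size; an insertion anchored
#' strictly between the footprints lengthens it by the inserted length; an
#' SV overlapping either primer footprint abolishes primer binding and
#' gives no product. An SV on another chromosome (or entirely outside the
#' amplicon) leaves both alleles at the reference length, with a warning.
#'
#' @param assay a [PCRAssay-class].
#' @param sv a length-1 SV catalog entry ([svCatalog()]), or a list with
#'   `chrom`, `start`, `end`, `svtype`, `svlen`.
#' @return List: `ref` (bp), `alt` (bp, or `NA` for "no product") and
#'   `label` (`"1130 bp/757 bp"`-style string, `"no product"` for `NA`).
#' @examples
#' a <- pcrAssay("P311", "A02", fwd = c(1001, 1020), rev = c(2905, 2924))
#' sv <- svCatalog("A02", 1200, 2560, "DEL", 1361)
#' predictAmplicons(a, sv)$alt  # 563
#' @export
predictAmplicons <- function(assay, sv) {
  stopifnot(is(assay, "PCRAssay"))
  if (is(sv, "GRanges")) {
    stopifnot(length(sv) == 1L)
    sv <- list(chrom = as.character(GenomicRanges::seqnames(sv)),
               start = GenomicRanges::start(sv),
               end = GenomicRanges::end(sv),
               svtype = S4Vectors::mcols(sv)$svtype,
               svlen = S4Vectors::mcols(sv)$svlen)
  }
  refLen <- assay@rev[2] - assay@fwd[1] + 1L
  fmt <- function(ref, alt)
    sprintf("%d bp/%s", ref, if (is.na(alt)) "no product"
            else sprintf("%d bp", alt))
  if (!identical(sv$chrom, assay@chrom)) {
    warning("SV on another chromosome; assay unaffected")
    return(list(ref = refLen, alt = refLen, label = fmt(refLen, refLen)))
  }
  s <- sv$start; e <- sv$end
  hitsPrimer <- (e >= assay@fwd[1] && s <= assay@fwd[2]) ||
                (e >= assay@rev[1] && s <= assay@rev[2])
  between <- s > assay@fwd[2] && e < assay@rev[1]
  alt <- if (hitsPrimer) NA_integer_
         else if (!between) refLen
         else if (sv$svtype == "DEL") refLen - sv$svlen
         else refLen + sv$svlen
  if (!hitsPrimer && !between)
    warning("SV outside the amplicon; both alleles at reference length")
  list(ref = refLen, alt = alt, label = fmt(refLen, alt))
}

#' Chi-square test of 1:1 segregation
#'
#' One-df goodness-of-fit chi-square of two allele-class counts against
#' the 1:1 DH expectation, without continuity correction:
#' `chi2 = (c1 - c2)^2 / (c1 + c2)`. Stars mark p < 0.05 / 0.01 / 0.001.
#'
#' @param count1,count2 non-negative class counts (vectorized).
#' @return For scalar input a list `count1`, `count2`, `chi2`, `p`,
#'   `stars`; for vector input a data.frame of the same columns.
#' @examples
#' segregationTest(29, 31)$p  # 0.796
#' segregationTest(43, 17)$p  # 0.00079 -> prints as 0.001
#' @export
segregationTest <- function(count1, count2) {
  stopifnot(length(count1) == length(count2), all(count1 >= 0),
            all(count2 >= 0))
  n <- count1 + count2
  if (any(n == 0)) stop("both counts zero")
  chi2 <- (count1 - count2)^2 / n
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  stars <- ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
           ifelse(p < 0.05, "*", "")))
  if (length(n) == 1L)
    list(count1 = count1, count2 = count2, chi2 = chi2, p = p, stars = stars)
  else
    data.frame(count1 = count1, count2 = count2, chi2 = chi2, p = p,
               stars = stars, stringsAsFactors = FALSE)
}

#' Per-environment allelic effect of an SV with Student's t test
#'
#' For each environment, individuals are collapsed to entry means over
#' replicates and the effect is `mean(days | carrier) - mean(days |
#' reference)` — negative meaning carriers flower earlier — tested with a
#' two-sided pooled-variance (Student's) t test. Environments where a
#' genotype class is empty are marked untestable.
#'
#' @param svGeno named 0/1 vector: 1 = carrier of the SV allele.
#' @param pheno phenotype data.frame (`individual`, `environment`,
#'   `replicate`, `days`).
#' @param alpha significance level for the `signif` flag.
#' @return data.frame: `environment`, `n_carrier`, `n_reference`,
#'   `effect` (days), `t`, `df`, `p`, `signif` (stars or `"ns"`),
#'   `testable`.
#' @export
allelicEffects <- function(svGeno, pheno, alpha = 0.05) {
  envs <- unique(pheno$environment)
  entry <- aggregate(days ~ individual + environment, data = pheno,
                     FUN = mean)
  rows <- lapply(envs, function(ev) {
    d <- entry[entry$environment == ev, ]
    gg <- svGeno[d$individual]
    carrier <- d$days[!is.na(gg) & gg == 1]
    refcls <- d$days[!is.na(gg) & gg == 0]
    if (length(carrier) == 0L || length(refcls) == 0L)
      return(data.frame(environment = ev, n_carrier = length(carrier),
                        n_reference = length(refcls), effect = NA_real_,
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        signif = NA_character_, testable = FALSE))
    eff <- mean(carrier) - mean(refcls)
    if (length(carrier) > 1L && length(refcls) > 1L &&
        (sd(carrier) > 0 || sd(refcls) > 0)) {
      tt <- t.test(carrier, refcls, var.equal = TRUE)
      tstat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
    } else {
      tstat <- if (eff == 0) 0 else NA_real_
      df <- length(carrier) + length(refcls) - 2
      p <- if (eff == 0) 1 else NA_real_
    }
    stars <- if (is.na(p) || p >= alpha) "ns"
             else if (p < 0.001) "***" else if (p < 0.01) "**" else "*"
    data.frame(environment = ev, n_carrier = length(carrier),
               n_reference = length(refcls), effect = eff, t = tstat,
               df = df, p = p, signif = stars, testable = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normalized-mean-coverage (NMC) deletion genotyping
#'
#' `nmc = mean depth over the target interval / mean depth over the
#' baseline interval(s)`. An NMC below 0.5 calls a homozygous deletion,
#' above 1.5 the reference state, and the closed interval \[0.5, 1.5\] is
#' ambiguous (heterozygotes are expected near 0.5-1.0 and are not callable
#' from coverage alone).
#'
#' For genotyping inbred/diploid panels the baseline should be expressed
#' per single copy: with `singleCopyBaseline = TRUE` the baseline mean is
#' halved (its haploid equivalent), putting a two-copy reference individual
#' near 2 and a heterozygote near 1 — the relative-copy-number convention
#' under which the three call classes separate cleanly.
#'
#' @param depth a [DepthTrack-class].
#' @param interval `c(start, end)` (1-based inclusive) of the putative
#'   deletion, or a length-1 `GRanges`.
#' @param baseline list of `c(start, end)` baseline intervals; default is
#'   the covered track minus the target interval (the flanking sequence).
#' @param singleCopyBaseline normalize the baseline to its single-copy
#'   (haploid) equivalent before forming the ratio.
#' @return List: `nmc`, `call` in `{deletion, reference, ambiguous}`,
#'   `meanTarget`, `meanBaseline`.
#' @export
nmcGenotype <- function(depth, interval, baseline = NULL,
                        singleCopyBaseline = FALSE) {
  stopifnot(is(depth, "DepthTrack"))
  if (is(interval, "GRanges"))
    interval <- c(GenomicRanges::start(interval), GenomicRanges::end(interval))
  from <- depth@start; to <- depth@start + length(depth@depth) - 1L
  if (interval[1] < from || interval[2] > to)
    stop("target interval not covered by the depth track")
  idx <- seq.int(interval[1] - from + 1L, interval[2] - from + 1L)
  if (is.null(baseline)) {
    bidx <- setdiff(seq_along(depth@depth), idx)
  } else {
    bidx <- unlist(lapply(baseline, function(b) {
      if (b[1] < from || b[2] > to) stop("baseline interval not covered")
      seq.int(b[1] - from + 1L, b[2] - from + 1L)
    }))
    bidx <- setdiff(bidx, idx)
  }
  if (length(bidx) == 0L) stop("empty baseline")
  mB <- mean(depth@depth[bidx])
  if (mB == 0) stop("uninformative sample: zero baseline coverage")
  mT <- mean(depth@depth[idx])
  nmc <- mT / (if (singleCopyBaseline) mB / 2 else mB)
  call <- if (nmc < 0.5) "deletion" else if (nmc > 1.5) "reference"
          else "ambiguous"
  list(nmc = nmc, call = call, meanTarget = mT, meanBaseline = mB)
}

#' Concordance between NMC and PCR deletion calls
#'
#' Cross-tabulates coverage-based calls (`deletion` / `reference` /
#' `ambiguous`) against PCR calls (`deletion` / `reference` /
#' `heterozygous`) over shared individuals and reports the agreement
#' fraction among non-ambiguous NMC calls.
#'
#' @param nmcCalls,pcrCalls named character vectors of calls.
#' @return List: `table` (3 x 3 contingency), `agreement`, `n_compared`.
#' @export
concordance <- function(nmcCalls, pcrCalls) {
  ids <- intersect(names(nmcCalls), names(pcrCalls))
  if (length(ids) == 0L) stop("no shared individual identifiers")
  nm <- factor(nmcCalls[ids], levels = c("deletion", "reference", "ambiguous"))
  pc <- factor(pcrCalls[ids], levels = c("deletion", "reference", "heterozygous"))
  tab <- table(nmc = nm, pcr = pc)
  use <- nm != "ambiguous"
  agreement <- if (any(use))
    mean(as.character(nm[use]) == as.character(pc[use])) else NA_real_
  list(table = tab, agreement = agreement, n_compared = sum(use))
}
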