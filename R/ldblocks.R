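#' @include AllClasses.R
NULL

#' Pairwise D' with a likelihood-grid confidence interval
#'
#' From two-locus haplotype counts (`AB`, `Ab`, `aB`, `ab`), computes the
#' raw disequilibrium coefficient `D = pAB - pA pB`, the normalized
#' `D' = D / Dmax` (with `Dmax` the sign-dependent allele-frequency bound),
#' and a two-sided 90% confidence interval on `|D'|` from the multinomial
#' likelihood of the counts evaluated over a grid of `|D'|` values with
#' allele frequencies fixed at their sample estimates (the
#' Wall-Pritchard/Haploview approach). The pair is classified *strong LD*
#' when `ci_low >= 0.70` and `ci_high >= 0.98`, *strong recombination*
#' when `ci_high < 0.90`, otherwise *uninformative*. A monomorphic locus
#' yields an uninformative classification (no error).
#'
#' @param counts numeric length-4 vector of haplotype counts
#'   `c(AB, Ab, aB, ab)` (first locus allele then second).
#' @param conf CI mass (0.90 = the Haploview default).
#' @param gridStep grid resolution on `|D'|`.
#' @return List: `D`, `Dprime` (|D'|), `ciLow`, `ciHigh`, `classification`.
#' @examples
#' dprime(c(40, 10, 10, 40))  # D = 0.15, D' = 0.6
#' @export
dprime <- function(counts, conf = 0.90, gridStep = 0.001) {
  stopifnot(length(counts) == 4L, all(counts >= 0))
  n <- sum(counts)
  uninf <- list(D = NA_real_, Dprime = NA_real_, ciLow = NA_real_,
                ciHigh = NA_real_, classification = "uninformative")
  if (n == 0L) return(uninf)
  pAB <- counts[1] / n
  pA <- (counts[1] + counts[2]) / n
  pB <- (counts[1] + counts[3]) / n
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(uninf)
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dp <- if (dmax == 0) 0 else abs(D) / dmax
  sgn <- if (D >= 0) 1 else -1

  grid <- seq(0, 1, by = gridStep)
  Dg <- sgn * grid * dmax
  p11 <- pA * pB + Dg
  p12 <- pA * (1 - pB) - Dg
  p21 <- (1 - pA) * pB - Dg
  p22 <- (1 - pA) * (1 - pB) + Dg
  eps <- 1e-12
  ll <- counts[1] * log(pmax(p11, eps)) + counts[2] * log(pmax(p12, eps)) +
    counts[3] * log(pmax(p21, eps)) + counts[4] * log(pmax(p22, eps))
  bad <- p11 < -eps | p12 < -eps | p21 < -eps | p22 < -eps
  ll[bad] <- -Inf
  lik <- exp(ll - max(ll))
  cum <- cumsum(lik) / sum(lik)
  tail <- (1 - conf) / 2
  ciLow <- grid[which(cum >= tail)[1]]
  ciHigh <- grid[which(cum >= 1 - tail)[1]]
  cls <- if (ciLow >= 0.70 && ciHigh >= 0.98) "strong LD"
         else if (ciHigh < 0.90) "strong recombination"
         else "uninformative"
  list(D = unname(D), Dprime = unname(min(dp, 1)), ciLow = ciLow,
       ciHigh = ciHigh, classification = cls)
}

#' All-pairs D' for map-ordered markers on one chromosome
#'
#' For fully homozygous (DH/inbred) genotypes, haplotypes are observed
#' directly and two-locus haplotype counts are tallied over individuals
#' non-missing at both markers. For heterozygous (0/1/2-coded diploid)
#' input, haplotype frequencies are estimated by an EM fallback and scaled
#' to pseudo-counts.
#'
#' @param g a [GenotypeMatrix-class], or a 0/1 (haploid) or 0/1/2 (diploid)
#'   marker-by-individual matrix.
#' @param chrom chromosome to analyze (required for a GenotypeMatrix with
#'   several chromosomes).
#' @param diploid treat the matrix input as diploid 0/1/2 genotypes.
#' @param maxPairs optional cap on marker distance (in markers) between
#'   pair members.
#' @return data.frame: `i`, `j` (map-order indices), `marker1`, `marker2`,
#'   `D`, `Dprime`, `ciLow`, `ciHigh`, `classification`.
#' @export
pairwiseDprime <- function(g, chrom = NULL, diploid = FALSE,
                           maxPairs = Inf) {
  if (is(g, "GenotypeMatrix")) {
    mm <- markerMap(g)
    if (is.null(chrom)) {
      stopifnot(length(unique(mm$chrom)) == 1L)
      chrom <- mm$chrom[1]
    }
    keep <- mm$chrom == chrom
    X <- genotypeCalls(g)[keep, , drop = FALSE]
    X <- X[order(mm$bp[keep]), , drop = FALSE]
  } else {
    X <- as.matrix(g)
  }
  m <- nrow(X)
  rows <- vector("list", m * (m - 1L) / 2L)
  k <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, min(m, i + maxPairs))) {
      cts <- if (diploid) .emHaplotypeCounts(X[i, ], X[j, ])
             else .haploCounts(X[i, ], X[j, ])
      ld <- dprime(cts)
      k <- k + 1L
      rows[[k]] <- data.frame(i = i, j = j, marker1 = rownames(X)[i],
                              marker2 = rownames(X)[j], D = ld$D,
                              Dprime = ld$Dprime, ciLow = ld$ciLow,
                              ciHigh = ld$ciHigh,
                              classification = ld$classification,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

.haploCounts <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  c(sum(a == 0 & b == 0), sum(a == 0 & b == 1),
    sum(a == 1 & b == 0), sum(a == 1 & b == 1))
}

## EM estimate of two-locus haplotype frequencies from diploid 0/1/2 dosages;
## returns pseudo-counts on 2n gametes. Only the double heterozygote is
## phase-ambiguous.
.emHaplotypeCounts <- function(a, b, iter = 50L, tol = 1e-8) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n2 <- 2 * length(a)
  cnt2 <- function(x, y) sum(a == x & b == y)
  ## unambiguous gamete contributions, haplotype order (00, 01, 10, 11)
  base <- c(2 * cnt2(0, 0) + cnt2(0, 1) + cnt2(1, 0),
            2 * cnt2(0, 2) + cnt2(0, 1) + cnt2(1, 2),
            2 * cnt2(2, 0) + cnt2(1, 0) + cnt2(2, 1),
            2 * cnt2(2, 2) + cnt2(2, 1) + cnt2(1, 2))
  nDH <- cnt2(1, 1)   # double heterozygotes: phase unknown
  f <- rep(0.25, 4)
  for (it in seq_len(iter)) {
    cis <- f[1] * f[4]; trans <- f[2] * f[3]
    pc <- if (cis + trans == 0) 0.5 else cis / (cis + trans)
    cnt <- base + nDH * c(pc, 1 - pc, 1 - pc, pc)
    fn <- cnt / n2
    if (max(abs(fn - f)) < tol) { f <- fn; break }
    f <- fn
  }
  f * n2
}

#' Gabriel-style LD blocks from pairwise D' confidence intervals
#'
#' A candidate span of consecutive map-ordered markers is a block when at
#' least `minStrongFraction` of its *informative* pairs (pairs classified
#' strong LD or strong recombination) are strong LD. Maximal
#' non-overlapping spans are returned with longest-first greedy
#' resolution (span length in markers, ties to the leftmost).
#'
#' @param pairLD output of [pairwiseDprime()] for one chromosome.
#' @param map map for the same markers, ordered as in `pairLD` (data.frame
#'   with `marker`, `bp`; optional `chrom`).
#' @param minStrongFraction minimum strong-LD fraction among informative
#'   pairs (0.95 = the Haploview default).
#' @return data.frame of blocks: `chrom`, `start`, `end` (bp of the first
#'   and last member marker), `first`, `last` (map indices), `n_markers`,
#'   `size_kb`, `markers` (comma-separated ids).
#' @export
findBlocks <- function(pairLD, map, minStrongFraction = 0.95) {
  m <- max(pairLD$j)
  stopifnot(nrow(map) >= m)
  S <- matrix(0L, m, m)   # strong LD indicator
  I <- matrix(0L, m, m)   # informative indicator
  idx <- cbind(pairLD$i, pairLD$j)
  S[idx] <- as.integer(pairLD$classification == "strong LD")
  I[idx] <- as.integer(pairLD$classification != "uninformative")
  cs <- apply(apply(S, 1, cumsum), 1, cumsum)  # 2-D prefix sums, cs[j,i] ...
  ci <- apply(apply(I, 1, cumsum), 1, cumsum)
  sumIn <- function(M2, a, b) {
    tot <- M2[b, b] - (if (a > 1) M2[a - 1, b] + M2[b, a - 1] - M2[a - 1, a - 1] else 0)
    tot
  }
  cand <- list()
  for (a in seq_len(m - 1L)) {
    for (b in seq.int(a + 1L, m)) {
      ninf <- sumIn(ci, a, b)
      if (ninf == 0L) next
      frac <- sumIn(cs, a, b) / ninf
      if (frac >= minStrongFraction)
        cand[[length(cand) + 1L]] <- c(a, b)
    }
  }
  chrom <- if ("chrom" %in% colnames(map)) map$chrom[1] else NA_character_
  if (!length(cand))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), first = integer(), last = integer(),
                      n_markers = integer(), size_kb = numeric(),
                      markers = character(), stringsAsFactors = FALSE))
  cand <- cand[order(vapply(cand, function(x) x[2] - x[1], 0L),
                     -vapply(cand, `[`, 0L, 1L), decreasing = TRUE)]
  taken <- rep(FALSE, m)
  rows <- list()
  for (span in cand) {
    rng <- seq.int(span[1], span[2])
    if (any(taken[rng])) next
    taken[rng] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = map$bp[span[1]], end = map$bp[span[2]],
      first = span[1], last = span[2], n_markers = length(rng),
      size_kb = (map$bp[span[2]] - map$bp[span[1]]) / 1000,
      markers = paste(map$marker[rng], collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$first), , drop = FALSE]
}
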