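#' @include AllClasses.R
NULL

#' Allele-sharing (IBS) kinship matrix
#'
#' Pairwise identity-by-state similarity between fully homozygous
#' individuals: the proportion of markers (non-missing in both) at which
#' the two carry the same allele. Values lie in [0, 1] with a unit
#' diagonal.
#'
#' @param g a [GenotypeMatrix-class] (QC-filtered).
#' @return Symmetric individual-by-individual numeric matrix.
#' @export
kinshipMatrix <- function(g) {
  X <- genotypeCalls(g)
  if (any(colSums(!is.na(X)) == 0L))
    stop("individual(s) with all-missing genotypes: ",
         paste(colnames(X)[colSums(!is.na(X)) == 0L], collapse = ", "))
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0L
  ## shared = both 1 or both 0 (among jointly observed markers)
  both1 <- crossprod(X0)
  both0 <- crossprod((1L - X0) * obs)
  nObs <- crossprod(obs * 1L)
  if (any(nObs == 0L)) stop("individual pair with no jointly typed marker")
  K <- (both1 + both0) / nObs
  dimnames(K) <- list(colnames(X), colnames(X))
  K
}

## REML profile log-likelihood of delta = s2e/s2g on the kinship eigenbasis,
## for the null model y = X b + u + e, var(u) = s2g K. EMMA-style: K is
## eigendecomposed once; the 1-D profile over delta is optimized numerically.
.remlDelta <- function(yr, Xr, lambda) {
  n <- length(yr); p <- ncol(Xr)
  obj <- function(logDelta) {
    d <- lambda + exp(logDelta)
    w <- 1 / d
    XtWX <- crossprod(Xr, Xr * w)
    XtWy <- crossprod(Xr, yr * w)
    b <- solve(XtWX, XtWy)
    r <- yr - Xr %*% b
    rss <- sum(r^2 * w)
    ## restricted likelihood (up to a constant)
    -0.5 * ((n - p) * log(rss) + sum(log(d)) + determinant(XtWX)$modulus[1])
  }
  opt <- optimize(obj, c(-12, 12), maximum = TRUE)
  exp(opt$maximum)
}

#' Kinship- and structure-adjusted single-marker association scan
#'
#' For one environment's trait values, fits the null polygenic model
#' `y = covariates + u + e` with `var(u)` proportional to the kinship
#' matrix (variance ratio estimated by REML on the kinship eigenbasis) and
#' then score-tests each marker: `chi = (g' P y)^2 / (g' P g)` with `P` the
#' generalized-least-squares projection under the fitted null covariance.
#' Covariates are an intercept plus the leading `nPcs` principal components
#' of the kinship matrix. With an identity kinship and `nPcs = 0` the
#' statistic reduces to the classic marker-regression score chi-square.
#'
#' Missing genotypes are mean-imputed for the score (they contribute no
#' association signal); the `n` entering the explained-variance formula
#' `R2 = chi / (n - 2 + chi)` is the number of non-missing
#' phenotype-genotype pairs for that marker.
#'
#' @param g a [GenotypeMatrix-class] of markers to test.
#' @param phenotype named numeric vector of per-individual trait values
#'   (one environment); names matched against individuals.
#' @param kinship kinship matrix from [kinshipMatrix()]; `NULL` for an
#'   unadjusted scan (identity covariance).
#' @param nPcs number of kinship principal components used as covariates.
#' @param environment label stored in the result.
#' @return data.frame: `marker`, `chrom`, `bp`, `environment`, `n`, `chi2`,
#'   `p`, `q` (Benjamini-Hochberg within the scan), `R2`, sorted by genome
#'   coordinate.
#' @export
associationScan <- function(g, phenotype, kinship = NULL, nPcs = 2,
                            environment = "env1") {
  stopifnot(is(g, "GenotypeMatrix"))
  ids <- intersect(colnames(g), names(phenotype))
  if (!is.null(kinship) && !is.null(rownames(kinship)))
    ids <- intersect(ids, rownames(kinship))
  y <- phenotype[ids]
  y <- y[!is.na(y)]
  ids <- names(y)
  if (length(unique(y)) < 2L) stop("phenotype is constant")
  n <- length(ids)
  if (!is.null(kinship) && is.null(rownames(kinship))) {
    stopifnot(nrow(kinship) == n)        # unnamed kinship: population order
    dimnames(kinship) <- list(ids, ids)
  }
  X <- matrix(1, n, 1, dimnames = list(ids, "intercept"))
  useK <- !is.null(kinship)
  if (useK) {
    K <- kinship[ids, ids]
    eK <- eigen(K, symmetric = TRUE)
    if (nPcs > 0) {
      pcs <- eK$vectors[, seq_len(nPcs), drop = FALSE]
      colnames(pcs) <- sprintf("PC%d", seq_len(nPcs))
      X <- cbind(X, pcs)
    }
  } else if (nPcs > 0) {
    stop("principal-component covariates require a kinship matrix")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("singular covariate matrix; collinear columns: ",
         paste(colnames(X)[-seq_len(qrX$rank)], collapse = ", "))

  if (useK) {
    U <- eK$vectors
    lambda <- pmax(eK$values, 0)
    yr <- crossprod(U, y)
    Xr <- crossprod(U, X)
    delta <- .remlDelta(yr, Xr, lambda)
    w <- 1 / (lambda + delta)          # V^-1 = U diag(w) U', up to scale
  } else {
    U <- diag(n); yr <- y; Xr <- X
    w <- rep(1, n)
  }
  ## P y and the machinery for g' P g on the rotated basis
  XtWX <- crossprod(Xr, Xr * w)
  A <- solve(XtWX)
  py <- w * (yr - Xr %*% (A %*% crossprod(Xr, yr * w)))  # rotated P y
  ## residual variance scale under the null (REML)
  sigma2 <- sum(yr * py) / (n - ncol(Xr))

  calls <- genotypeCalls(g)[, ids, drop = FALSE]
  mm <- markerMap(g)
  chi2 <- nUsed <- rep(NA_real_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    gi <- calls[i, ]
    miss <- is.na(gi)
    nUsed[i] <- n - sum(miss)
    if (nUsed[i] == 0L || length(unique(gi[!miss])) < 2L) next
    if (any(miss)) gi[miss] <- mean(gi[!miss])
    gr <- if (useK) crossprod(U, gi)[, 1] else gi
    pg <- w * (gr - Xr %*% (A %*% crossprod(Xr, gr * w)))
    denom <- sum(gr * pg) * sigma2
    if (denom <= 0) next
    chi2[i] <- sum(gr * py)^2 / denom
  }
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  res <- data.frame(marker = rownames(calls), chrom = mm$chrom, bp = mm$bp,
                    environment = environment, n = as.integer(nUsed),
                    chi2 = chi2, p = p, q = NA_real_,
                    R2 = chi2 / (nUsed - 2 + chi2),
                    stringsAsFactors = FALSE)
  ok <- !is.na(res$p)
  res$q[ok] <- bhFDR(res$p[ok])
  res[order(res$chrom, res$bp), , drop = FALSE]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values (BH-adjusted p-values), same order as the input.
#' @examples
#' bhFDR(c(0.001, 0.02, 0.03, 0.5))  # 0.004 0.040 0.040 0.500
#' @export
bhFDR <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Genomic inflation factor
#'
#' `lambda = median(chi2) / qchisq(0.5, 1)`; 1 under a calibrated null.
#'
#' @param chi2 one-df chi-square statistics (or a scan result data.frame).
#' @return lambda.
#' @export
genomicInflation <- function(chi2) {
  if (is.data.frame(chi2)) chi2 <- chi2$chi2
  median(chi2, na.rm = TRUE) / qchisq(0.5, df = 1)
}

#' Declare QTL from per-environment scans
#'
#' A marker is *significant* in an environment when its BH q-value is at
#' most `fdr` and *suggestive* when `-log10(p)` reaches
#' `suggestiveNeglog10p`. A QTL is an LD block containing at least one
#' marker significant in at least `minEnvironments` environments; it is
#' reported with the block's coordinates and size in kb. A qualifying
#' marker that falls outside every supplied block (e.g. a presence/absence
#' SV call in a recombination gap) is reported as a point QTL of size 0.
#' Without any blocks, all qualifying markers are reported as point QTL
#' with a warning.
#'
#' @param results list (or rbind) of per-environment [associationScan()]
#'   data.frames covering at least `minEnvironments` environments.
#' @param blocks LD blocks from [findBlocks()] (data.frame with `chrom`,
#'   `start`, `end`), or `NULL`.
#' @param fdr,suggestiveNeglog10p,minEnvironments significance rule.
#' @return data.frame of QTL: `qtl`, `chrom`, `start`, `end`, `size_kb`,
#'   `n_markers`, `peak_marker`, `min_p`, `n_env`.
#' @export
declareQtl <- function(results, blocks = NULL, fdr = 0.1,
                       suggestiveNeglog10p = 3.0, minEnvironments = 2L) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, results)
  stopifnot(fdr > 0, suggestiveNeglog10p > 0)
  if (length(unique(results$environment)) < minEnvironments)
    stop("results must cover at least ", minEnvironments, " environments")
  results$significant <- !is.na(results$q) & results$q <= fdr
  results$suggestive <- !is.na(results$p) & -log10(results$p) >= suggestiveNeglog10p

  empty <- data.frame(qtl = character(), chrom = character(),
                      start = integer(), end = integer(),
                      size_kb = numeric(), n_markers = integer(),
                      peak_marker = character(), min_p = numeric(),
                      n_env = integer(), stringsAsFactors = FALSE)
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0L) return(empty)
  perMarker <- aggregate(environment ~ marker + chrom + bp, data = sig,
                         FUN = function(e) length(unique(e)))
  names(perMarker)[4] <- "n_env"
  hits <- perMarker[perMarker$n_env >= minEnvironments, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)

  if (is.null(blocks) || nrow(blocks) == 0L) {
    warning("no LD blocks supplied; reporting point QTL")
    out <- data.frame(qtl = sprintf("%s_%d", hits$chrom,
                                    as.integer(ave(hits$bp, hits$chrom,
                                                   FUN = seq_along))),
                      chrom = hits$chrom, start = hits$bp, end = hits$bp,
                      size_kb = 0, n_markers = 1L, peak_marker = hits$marker,
                      min_p = vapply(hits$marker, function(m)
                        min(results$p[results$marker == m], na.rm = TRUE), 0),
                      n_env = hits$n_env, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  rows <- list()
  cnt <- integer()
  assigned <- rep(FALSE, nrow(hits))
  for (b in seq_len(nrow(blocks))) {
    inb <- hits$chrom == blocks$chrom[b] & hits$bp >= blocks$start[b] &
      hits$bp <= blocks$end[b]
    assigned <- assigned | inb
    if (!any(inb)) next
    ch <- blocks$chrom[b]
    cnt[ch] <- if (ch %in% names(cnt)) cnt[[ch]] + 1L else 1L
    mk <- hits$marker[inb]
    ps <- results$p[results$marker %in% mk]
    peak <- results$marker[results$marker %in% mk][which.min(ps)]
    rows[[length(rows) + 1L]] <- data.frame(
      qtl = sprintf("%s_%d", ch, cnt[[ch]]), chrom = ch,
      start = blocks$start[b], end = blocks$end[b],
      size_kb = (blocks$end[b] - blocks$start[b]) / 1000,
      n_markers = sum(inb), peak_marker = peak,
      min_p = min(ps, na.rm = TRUE), n_env = max(hits$n_env[inb]),
      stringsAsFactors = FALSE)
  }
  for (k in which(!assigned)) {         # qualifying markers in block gaps
    ch <- hits$chrom[k]
    cnt[ch] <- if (ch %in% names(cnt)) cnt[[ch]] + 1L else 1L
    rows[[length(rows) + 1L]] <- data.frame(
      qtl = sprintf("%s_%d", ch, cnt[[ch]]), chrom = ch,
      start = hits$bp[k], end = hits$bp[k], size_kb = 0,
      n_markers = 1L, peak_marker = hits$marker[k],
      min_p = min(results$p[results$marker == hits$marker[k]], na.rm = TRUE),
      n_env = hits$n_env[k], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Entry-mean broad-sense heritability from a balanced trial
#'
#' Two-way genotype-by-environment ANOVA on a balanced phenotype table
#' (every genotype in every environment with a constant number of
#' replicates). Variance components come from the expected mean squares —
#' `s2e = MSE`, `s2GE = (MS_GE - MSE) / R`, `s2G = (MS_G - MS_GE) / (E R)`
#' — and `H2 = s2G / (s2G + s2GE/E + s2e/(E R))` on the entry-mean basis.
#'
#' @param pheno data.frame from [simulatePhenotypes()] (`individual`,
#'   `environment`, `replicate`, `days`).
#' @return List: `H2`, `s2G`, `s2GE`, `s2e`, `nEnv`, `nReps`.
#' @export
estimateH2 <- function(pheno) {
  G <- length(unique(pheno$individual))
  E <- length(unique(pheno$environment))
  R <- nrow(pheno) / (G * E)
  if (R != round(R)) stop("unbalanced phenotype table")
  y <- pheno$days
  gm <- mean(y)
  mG <- tapply(y, pheno$individual, mean)
  mE <- tapply(y, pheno$environment, mean)
  mGE <- tapply(y, list(pheno$individual, pheno$environment), mean)
  ssG <- E * R * sum((mG - gm)^2)
  ssGE <- R * sum((sweep(sweep(mGE, 1, mG), 2, mE) + gm)^2)
  ssErr <- sum((y - mGE[cbind(pheno$individual, pheno$environment)])^2)
  msG <- ssG / (G - 1)
  msGE <- ssGE / ((G - 1) * (E - 1))
  mse <- if (R > 1) ssErr / (G * E * (R - 1)) else 0
  s2e <- mse
  s2GE <- max(0, (msGE - mse) / R)
  s2G <- max(0, (msG - msGE) / (E * R))
  list(H2 = s2G / (s2G + s2GE / E + s2e / (E * R)),
       s2G = s2G, s2GE = s2GE, s2e = s2e, nEnv = E, nReps = R)
}
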