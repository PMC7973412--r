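founderMat <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("FND%d", seq_len(ncol(m)))
  m
}

test_that("polymorphism classification partitions the catalog", {
  fa <- founderMat(c(1L, 1L, 1L, 0L, 0L, 0L, 0L),   # 3/7 carriers
                   rep(1L, 7),                      # all-alt: monomorphic
                   rep(0L, 7),                      # reference-like
                   rep(NA_integer_, 7))             # unknown everywhere
  svs <- svCatalog("A02", c(100, 5000, 9000, 12000),
                   c(387, 5099, 9099, 12099), rep("DEL", 4),
                   c(288, 100, 100, 100), founderAlleles = fa)
  cls <- classifyPolymorphism(svs)
  expect_identical(names(cls$polymorphic), "SV1")
  expect_setequal(names(cls$monomorphic), c("SV2", "SV3"))
  expect_identical(names(cls$unknown), "SV4")
  ## partition property
  expect_identical(length(cls$polymorphic) + length(cls$monomorphic) +
                     length(cls$unknown), length(svs))

  ## unknown alleles in some founders are ignored
  fa2 <- founderMat(c(1L, NA, 1L, NA, 0L, 0L, 0L))
  svs2 <- svCatalog("A02", 100, 387, "DEL", 288, founderAlleles = fa2)
  expect_identical(length(classifyPolymorphism(svs2)$polymorphic), 1L)
})

test_that("size classes use half-open lower-inclusive bins", {
  sizes <- c(30, 99, 100, 429, 999, 1000, 9999, 10000, 26000)
  svs <- svCatalog("A02", seq(1e5, by = 1e5, length.out = 9) + 1,
                   seq(1e5, by = 1e5, length.out = 9) + sizes,
                   rep("DEL", 9), sizes,
                   founderAlleles = matrix(rep(c(1L, 0L), c(9, 9 * 6)), 9))
  tab <- sizeClasses(svs)
  expect_equal(unname(tab["DEL", ]), c(2, 3, 2, 2))
  expect_identical(sum(tab), length(svs))
  ## invariant under shuffling
  set.seed(7)
  expect_equal(unname(sizeClasses(svs[sample(9)])["DEL", ]), c(2, 3, 2, 2))
  expect_error(svCatalog("A02", 1, 20, "DEL", 20), "svlen|30")
})

test_that("gene-body intersection uses exclusive boundaries", {
  genes <- geneModels(c("g1", "g2"), "A02", c(101, 201), c(500, 300),
                      strand = c("+", "+"), annotation = "ATP binding")
  ## DEL spanning [401, 900] overlaps g1 (101-500)
  svIn <- svCatalog("A02", 401, 900, "DEL", 500)
  hits <- intersectGenes(svIn, genes, promoterBp = 50)
  expect_true(any(hits$gene_id == "g1" & hits$relation == "intragenic"))
  ## a deletion of bases [101, 200] does not touch a gene starting at 201
  ## (the half-open [100, 200) vs [200, 300) boundary case in 1-based form)
  svOut <- svCatalog("A02", 101, 200, "DEL", 100)
  h2 <- intersectGenes(svOut, genes, promoterBp = 0)
  expect_false(any(h2$gene_id == "g2" & h2$relation == "intragenic"))
  ## unknown chromosome errors with the offending record
  svBad <- svCatalog("Z99", 101, 200, "DEL", 100)
  expect_error(intersectGenes(svBad, genes), "SV1")
})

test_that("promoter windows are strand-aware", {
  genes <- geneModels(c("plus", "minus"), "A02", c(50000, 30000),
                      c(60000, 49999), strand = c("+", "-"),
                      annotation = "")
  ## DEL at [41001, 42000]: inside the 10 kb window upstream of the
  ## plus-strand gene start (40000-49999), but downstream of the
  ## minus-strand gene end -> not its promoter
  sv <- svCatalog("A02", 41001, 42000, "DEL", 1000)
  hits <- intersectGenes(sv, genes, promoterBp = 10000)
  prom <- hits[hits$relation == "promoter", ]
  expect_true("plus" %in% prom$gene_id)
  expect_false("minus" %in% prom$gene_id)
  ## the minus-strand promoter lies right of its end coordinate
  svRight <- svCatalog("A02", 55001, 55100, "DEL", 100)
  hitsR <- intersectGenes(svRight, genes, promoterBp = 10000)
  promR <- hitsR[hitsR$relation == "promoter", ]
  expect_true("minus" %in% promR$gene_id)
})

test_that("SV-major and gene-major sweeps give identical hit sets", {
  set.seed(401)
  n <- 40
  starts <- sort(sample(1e6, n))
  svs <- svCatalog("A02", starts, starts + 99, rep("DEL", n), rep(100, n))
  gs <- sort(sample(1e6, 25))
  genes <- geneModels(sprintf("g%02d", 1:25), "A02", gs, gs + 4999,
                      strand = sample(c("+", "-"), 25, TRUE),
                      annotation = "")
  hits <- intersectGenes(svs, genes, promoterBp = 2000)
  ## quadratic all-pairs oracle
  oracle <- list()
  for (i in seq_len(n)) for (j in 1:25) {
    s1 <- starts[i]; e1 <- starts[i] + 99
    gS <- gs[j]; gE <- gs[j] + 4999
    if (s1 <= gE && e1 >= gS)
      oracle[[length(oracle) + 1L]] <- c(names(svs)[i], sprintf("g%02d", j),
                                         "intragenic")
    st <- as.character(GenomicRanges::strand(genes))[j]
    pr <- if (st == "+") c(gS - 2000, gS - 1) else c(gE + 1, gE + 2000)
    if (s1 <= pr[2] && e1 >= pr[1])
      oracle[[length(oracle) + 1L]] <- c(names(svs)[i], sprintf("g%02d", j),
                                         "promoter")
  }
  om <- do.call(rbind, oracle)
  key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
  expect_identical(key(as.matrix(hits)), key(om))
})

test_that("flowering keyword filter matches the documented terms", {
  genes <- geneModels(sprintf("g%d", 1:5), "A02",
                      c(1, 1001, 2001, 3001, 4001),
                      c(900, 1901, 2901, 3901, 4901),
                      strand = rep("+", 5),
                      annotation = c("regulation of flower development",
                                     "entrainment of circadian clock",
                                     "ATP binding",
                                     "VERNALIZATION insensitive 3",
                                     "pollen tube growth"))
  fl <- floweringFilter(genes)
  expect_setequal(names(fl), c("g1", "g2", "g4", "g5"))
  ## configurable keyword list
  expect_identical(names(floweringFilter(genes, "atp")), "g3")
})

test_that("QTL report aggregates genes, flowering genes and SV", {
  ## 92 genes in one block, 10 flowering -> 10.9%
  starts <- seq(1000, by = 3000, length.out = 92)
  ann <- rep("unknown protein", 92)
  ## flowering genes: the SV host plus nine genes far from the SV, so that
  ## only one flowering gene carries the SV (promoter windows included)
  ann[c(1, 40:48)] <- "floral organ development"
  genes <- geneModels(sprintf("g%02d", 1:92), "A02", starts, starts + 2000,
                      strand = rep("+", 92), annotation = ann)
  sv <- svCatalog("A02", starts[1] + 100, starts[1] + 487, "DEL", 388)
  qtls <- data.frame(qtl = "A02_1", chrom = "A02", start = 1L,
                     end = max(starts) + 2500L)
  rep1 <- qtlSvReport(qtls, sv, genes)
  expect_identical(rep1$n_genes, 92L)
  expect_identical(rep1$n_flowering, 10L)
  expect_equal(rep1$pct_flowering, 10.9)
  expect_identical(rep1$n_sv_flowering, 1L)
  expect_match(rep1$sv_events, "388 bp deletion \\(intragenic\\)")
  ## a QTL without SV-bearing genes yields a dashes row
  qtls2 <- data.frame(qtl = "C02_1", chrom = "A02", start = 200000L,
                      end = 250000L)
  rep2 <- qtlSvReport(qtls2, sv, genes)
  expect_identical(rep2$sv_events, "-")
  expect_identical(rep2$sv_flowering_genes, "-")
})

test_that("SV catalogs round-trip through VCF", {
  fa <- founderMat(c(1L, 0L, 1L, 0L, 0L, 0L, 0L))
  svs <- svCatalog(c("A02", "C02"), c(5001, 9001), c(5388, 9001),
                   c("DEL", "INS"), c(388, 57),
                   founderAlleles = rbind(fa, fa))
  f <- tempfile(fileext = ".vcf")
  writeSVVcf(svs, f, seed = 99)
  back <- readSVVcf(f)
  expect_identical(length(back), 2L)
  expect_identical(GenomicRanges::start(back),
                   GenomicRanges::start(svs))
  expect_identical(S4Vectors::mcols(back)$svlen,
                   S4Vectors::mcols(svs)$svlen)
  expect_identical(S4Vectors::mcols(back)$svtype,
                   S4Vectors::mcols(svs)$svtype)
  expect_true(any(grepl("##seed=99", readLines(f))))
})

test_that("gene models round-trip through GFF3", {
  genes <- geneModels(c("gA", "gB"), "A02", c(1000, 9000), c(3000, 12000),
                      strand = c("+", "-"),
                      annotation = c("regulation of flower development",
                                     "ATP binding"))
  f <- tempfile(fileext = ".gff3")
  df <- data.frame(seqid = "A02", source = "test", type = "gene",
                   start = c(1000, 9000), end = c(3000, 12000), score = ".",
                   strand = c("+", "-"), phase = ".",
                   attributes = sprintf("ID=%s;description=%s", c("gA", "gB"),
                                        c("regulation of flower development",
                                          "ATP binding")))
  writeLines(c("##gff-version 3",
               apply(df, 1, paste, collapse = "\t")), f)
  back <- readGenesGff(f)
  expect_identical(names(back), c("gA", "gB"))
  expect_identical(S4Vectors::mcols(back)$annotation[1],
                   "regulation of flower development")
  expect_identical(names(floweringFilter(back)), "gA")
})
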