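test_that("variant-to-gene distance follows the gene-body convention", {
  g <- geneAnnotation("G1", "chr1", 1200, 2000)
  expect_equal(distanceToGene(1500, "chr1", g), 0)
  expect_equal(distanceToGene(1000, "chr1", g), 200)
  expect_equal(distanceToGene(2000, "chr1", g), 0)   # boundary inclusive
  expect_equal(distanceToGene(1200, "chr1", g), 0)
  expect_equal(distanceToGene(2600, "chr1", g), 600)
  expect_equal(distanceToGene(1500, "chr2", g), Inf)
})

test_that("closest-gene search returns all ties and respects the mode", {
  genes <- geneAnnotation(c("A", "B"), "chr1", c(1000, 16000),
                          c(4000, 20000))
  # lead inside gene A
  expect_equal(closestGenes(2000, "chr1", genes), "A")
  # exactly equidistant (6 kb from each edge): both tied genes returned
  expect_setequal(closestGenes(10000, "chr1", genes), c("A", "B"))
  # non-coding genes are excluded
  genes2 <- geneAnnotation(c("A", "B"), "chr1", c(1000, 16000),
                           c(4000, 20000),
                           gene_type = c("lincRNA", "protein_coding"))
  expect_equal(closestGenes(2000, "chr1", genes2), "B")

  # gene_body and tss modes disagree for a lead inside a long gene
  long <- geneAnnotation(c("LONG", "NEAR"), "chr1", c(1000, 52000),
                         c(50000, 53000), strand = "+")
  expect_equal(closestGenes(49000, "chr1", long, "gene_body"), "LONG")
  expect_equal(closestGenes(49000, "chr1", long, "tss"), "NEAR")
})

test_that("precision and recall follow their counting definitions", {
  truth <- data.frame(protein_id = c("P1", "P2", "P3"),
                      gene_id = c("G1", "G2", "G3"))
  tested <- c("P1", "P2", "P3")
  preds <- data.frame(
    protein_id = c("P1", "P1", "P2", "P2"),
    gene_id = c("G1", "GX", "G2", "G2"),   # duplicate pair collapses
    out_signal = c(1L, 1L, 1L, 2L)
  )
  rep <- scoreMethod(preds, truth, tested, method = "m")
  expect_equal(rep$tp, 2)
  expect_equal(rep$fp, 1)
  expect_equal(rep$fn, 1)
  expect_equal(rep$precision, 2 / 3)
  expect_equal(rep$recall, 2 / 3)
  # accounting identities
  expect_equal(rep$tp + rep$fp,
               nrow(unique(preds[, c("protein_id", "gene_id")])))
  expect_equal(rep$tp + rep$fn, length(tested))
})

test_that("no predictions gives undefined precision and zero recall", {
  truth <- data.frame(protein_id = "P1", gene_id = "G1")
  rep <- scoreMethod(data.frame(protein_id = character(),
                                gene_id = character()),
                     truth, "P1")
  expect_true(is.na(rep$precision))
  expect_equal(rep$recall, 0)
})

test_that("predictions for untested proteins are an accounting error", {
  truth <- data.frame(protein_id = "P1", gene_id = "G1")
  expect_error(
    scoreMethod(data.frame(protein_id = "P9", gene_id = "G1"),
                truth, "P1"),
    "untested"
  )
})

test_that("signal restriction and stratification behave consistently", {
  truth <- data.frame(protein_id = c("P1", "P2"),
                      gene_id = c("G1", "G2"))
  tested <- c("P1", "P2")
  preds <- data.frame(
    protein_id = c("P1", "P2", "P2"),
    gene_id = c("G1", "G2", "GX"),
    out_signal = c(1L, 2L, 2L)
  )
  first <- scoreMethod(preds, truth, tested,
                       restriction = "first_signal_only")
  expect_equal(first$tp, 1)
  expect_equal(first$fp, 0)

  strata <- scoreMethod(preds, truth, tested, restriction = "by_cs_index")
  expect_named(strata, c("cs1", "cs2"))
  # strata aggregate back to the pooled report (pairs unique per stratum)
  pooled <- scoreMethod(preds, truth, tested)
  expect_equal(strata$cs1$tp + strata$cs2$tp, pooled$tp)
  expect_equal(strata$cs1$fp + strata$cs2$fp, pooled$fp)
})

test_that("stored ratios always reproduce from the stored counts", {
  set.seed(21)
  for (i in 1:10) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1)
    tested <- tp + sample(0:100, 1)
    r <- benchmarkReport("m", tp, fp, tested)
    if (tp + fp > 0) expect_equal(r$precision, r$tp / (r$tp + r$fp))
    expect_equal(r$recall, r$tp / r$tested)
    expect_equal(r$fn, r$tested - r$tp)
  }
})

test_that("slope-sign concordance splits by TP/FP labels", {
  est <- data.frame(
    alphaHat = c(1, 2, -1, 0, 3, -2),
    label = c("TP", "TP", "TP", "FP", "FP", "FP")
  )
  sc <- signConcordance(est)
  expect_equal(sc$TP$positive, 2)
  expect_equal(sc$TP$total, 3)
  expect_equal(sc$FP$positive, 1)   # alphaHat exactly 0 is non-positive
  expect_equal(sc$FP$total, 3)
  # all positive slopes -> fraction 1
  all1 <- signConcordance(data.frame(alphaHat = c(1, 2), label = "TP"))
  expect_equal(all1$TP$fraction, 1)
})

test_that("a small end-to-end run is deterministic and self-consistent", {
  cfg <- locusConfig(m = 80L, nExp = 500L, nOut = 2000L)
  ct <- suppressWarnings(simulateBenchmarkCatalog(
    nProteins = 4L, genesPerLocus = 2L, pleiotropyRate = 0.5,
    multiSignalRate = 0.5, config = cfg, seed = 77
  ))
  res1 <- runEndToEnd(ct)
  res2 <- runEndToEnd(ct)
  expect_identical(res1$reports, res2$reports)
  expect_identical(res1$mr, res2$mr)
  for (r in res1$reports) {
    expect_equal(r$tp + r$fn, length(res1$testedProteins))
  }
})

test_that("zero pleiotropy leaves colocalization no false-positive room", {
  cfg <- locusConfig(m = 80L, nExp = 500L, nOut = 2000L)
  ct <- suppressWarnings(simulateBenchmarkCatalog(
    nProteins = 5L, genesPerLocus = 3L, pleiotropyRate = 0,
    multiSignalRate = 0, config = cfg, seed = 78
  ))
  res <- runEndToEnd(ct)
  for (m in c("abf", "bf_bf", "clpp")) {
    r <- res$reports[[m]]
    if (r$tp + r$fp > 0) expect_equal(r$precision, 1)
  }
  # zero multi-signal rate shuts the multi-signal MR route entirely
  expect_equal(res$reports$multi_coloc$recall, 0)
})

test_that("proteins flagged as complexes are excluded from the universe", {
  cfg <- locusConfig(m = 60L, nExp = 400L, nOut = 1000L)
  ct <- suppressWarnings(simulateBenchmarkCatalog(
    nProteins = 3L, genesPerLocus = 2L, pleiotropyRate = 0.5,
    multiSignalRate = 0.5, config = cfg, seed = 79
  ))
  res <- runEndToEnd(ct)
  ct@proteins$complex <- c(TRUE, FALSE, FALSE)
  res2 <- runEndToEnd(ct)
  expect_false("P001" %in% res2$testedProteins)
  expect_true(length(res2$testedProteins) <= length(res$testedProteins))
})

test_that("the pipeline writer emits reproducible artifacts and a manifest", {
  cfg <- runConfig(seed = 9L, nProteins = 3L, genesPerLocus = 2L,
                   pleiotropyRate = 0.5, multiSignalRate = 0.5,
                   locus = locusConfig(m = 60L, nExp = 400L, nOut = 1000L))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- suppressWarnings(runAll(cfg, d1))
  m2 <- suppressWarnings(runAll(cfg, d2))
  expect_identical(m1$md5, m2$md5)
  expect_true(all(file.exists(file.path(d1, m1$file))))
  expect_true(file.exists(file.path(d1, "manifest.tsv")))
  rep <- read.delim(file.path(d1, "report.tsv"))
  expect_true(all(c("method", "tp", "fp", "fn", "precision_pct",
                    "recall_pct") %in% names(rep)))
})
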