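# Hand-built tissue fixture: 10 samples, wiring fully known.
.pairFixture <- function() {
  s <- paste0("s", 1:10)
  base <- seq(10, 100, by = 10)
  circ <- rbind(circ1 = base, circ2 = c(30, 10, 50, 20, 80, 40, 90, 60, 100, 70))
  mrna <- rbind(gene1 = base + 5, gene2 = rev(base))
  mir <- rbind(mir1 = rev(base), mir2 = c(55, 45, 65, 35, 75, 25, 85, 15, 95, 5))
  colnames(circ) <- colnames(mrna) <- colnames(mir) <- s
  de <- function(ids) data.frame(feature_id = ids, log2fc = 2,
                                 pvalue = 0.001, fdr = 0.001,
                                 significant = TRUE, direction = "up",
                                 stringsAsFactors = FALSE)
  list(expr = list(circRNA = circ, miRNA = mir, mRNA = mrna),
       deTables = list(circRNA = de(rownames(circ)),
                       miRNA = de(rownames(mir)),
                       mRNA = de(rownames(mrna))))
}

test_that("negative pairs require DE membership and a strict threshold", {
  fx <- .pairFixture()
  inter <- data.frame(mirna_id = c("mir1", "mir1"),
                      target_id = c("circ1", "gene1"),
                      target_type = c("circRNA", "mRNA"),
                      stringsAsFactors = FALSE)
  got <- filterMirnaTargetPairs(fx$deTables, inter, fx$expr)
  expect_equal(nrow(got), 2L)          # mir1 is perfectly antitone to both
  expect_equal(got$coefficient, c(-1, -1))
  expect_setequal(got$pair_type, c("mirna_circ", "mirna_mrna"))

  # miRNA not DE -> excluded even at SCC -1
  deT <- fx$deTables
  deT$miRNA$significant <- FALSE
  expect_equal(nrow(filterMirnaTargetPairs(deT, inter, fx$expr)), 0L)

  # a pair sitting exactly at the threshold is excluded (strict <)
  rho <- spearmanCor(fx$expr$miRNA["mir2", ], fx$expr$circRNA["circ2", ])
  inter2 <- data.frame(mirna_id = "mir2", target_id = "circ2",
                       target_type = "circRNA", stringsAsFactors = FALSE)
  atBoundary <- filterMirnaTargetPairs(fx$deTables, inter2, fx$expr,
                                       sccThreshold = rho)
  expect_equal(nrow(atBoundary), 0L)
  justBelow <- filterMirnaTargetPairs(fx$deTables, inter2, fx$expr,
                                      sccThreshold = rho + 1e-9)
  expect_equal(nrow(justBelow), as.integer(rho < rho + 1e-9))
})

test_that("unknown features are skipped with a warning and counted", {
  fx <- .pairFixture()
  inter <- data.frame(mirna_id = c("mir1", "ghost"),
                      target_id = c("circ1", "circ1"),
                      target_type = "circRNA", stringsAsFactors = FALSE)
  expect_warning(got <- filterMirnaTargetPairs(fx$deTables, inter, fx$expr),
                 "unknown")
  expect_equal(nrow(got), 1L)
  expect_equal(unname(attr(got, "skipped")["unknown"]), 1L)
})

test_that("ceRNA candidates need a shared miRNA and strict PCC", {
  fx <- .pairFixture()
  retained <- data.frame(
    id_a = c("mir1", "mir1", "mir2"),
    id_b = c("circ1", "gene1", "circ2"),
    pair_type = c("mirna_circ", "mirna_mrna", "mirna_circ"),
    method = "spearman", coefficient = -0.9, n_samples = 10L,
    stringsAsFactors = FALSE)
  got <- filterCernaPairs(fx$deTables, retained, fx$expr)
  # circ1-gene1 share mir1 and are near-perfectly correlated
  expect_equal(got$id_a, "circ1")
  expect_equal(got$id_b, "gene1")
  expect_equal(got$common_mirnas, "mir1")
  # circ2 shares no miRNA with any mRNA: never tested, even though
  # circ2-gene1 could be correlated
  expect_false("circ2" %in% got$id_a)

  # exact-threshold PCC is excluded
  pcc <- pearsonCor(log2(fx$expr$circRNA["circ1", ] + 1),
                    log2(fx$expr$mRNA["gene1", ] + 1))
  atBoundary <- filterCernaPairs(fx$deTables, retained, fx$expr,
                                 pccThreshold = pcc)
  expect_equal(nrow(atBoundary), 0L)
})

test_that("duplicated expression profiles give PCC 1 and are kept", {
  fx <- .pairFixture()
  fx$expr$mRNA <- rbind(fx$expr$mRNA,
                        geneDup = fx$expr$circRNA["circ1", ])
  fx$deTables$mRNA <- rbind(fx$deTables$mRNA,
                            data.frame(feature_id = "geneDup", log2fc = 2,
                                       pvalue = 0.001, fdr = 0.001,
                                       significant = TRUE, direction = "up"))
  retained <- data.frame(
    id_a = c("mir1", "mir1"), id_b = c("circ1", "geneDup"),
    pair_type = c("mirna_circ", "mirna_mrna"),
    method = "spearman", coefficient = -0.9, n_samples = 10L,
    stringsAsFactors = FALSE)
  got <- filterCernaPairs(fx$deTables, retained, fx$expr)
  expect_equal(got$id_b, "geneDup")
  expect_equal(got$coefficient, 1)
})

test_that("every emitted pair references only DE-significant features", {
  d <- generateDesign(tissues = "hypothalamus", replicates = 5L)
  cfg <- simulationConfig(nCirc = 60L, nMirna = 20L, nMrna = 80L,
                          nTriads = 5L, seed = 19L)
  sim <- simulateCounts(d, cfg)
  inter <- generateInteractions(sim$truth, cfg)
  mats <- lapply(sim$counts, SummarizedExperiment::assay)
  cond <- SummarizedExperiment::colData(sim$counts[[1]])$condition
  de <- lapply(setNames(names(mats), names(mats)), function(cl)
    callDE(mats[[cl]], cond, cl, control = "NHS"))
  expr <- lapply(mats, normalizeCPM)
  got <- filterMirnaTargetPairs(de, inter, expr)
  sig <- lapply(de, function(x) x$feature_id[x$significant])
  expect_true(all(got$id_a %in% sig$miRNA))
  tgt <- ifelse(got$pair_type == "mirna_circ", "circRNA", "mRNA")
  expect_true(all(mapply(function(id, cl) id %in% sig[[cl]], got$id_b, tgt)))
})

test_that("null pairs pass the SCC filter at the exhaustive n=6 null rate", {
  null6 <- spearmanNull6()
  expected <- mean(abs(null6) > 0.7)
  set.seed(77)
  nPairs <- 4000L
  hits <- mean(replicate(nPairs, {
    abs(spearmanCor(rnorm(6), rnorm(6))) > 0.7
  }))
  se <- sqrt(expected * (1 - expected) / nPairs)
  expect_lt(abs(hits - expected), 4 * se)
})
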