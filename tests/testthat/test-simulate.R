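smallDesign <- generateDesign(tissues = "hypothalamus")

test_that("null configuration plants nothing", {
  cfg <- simulationConfig(nCirc = 20L, nMirna = 10L, nMrna = 30L,
                          deFraction = 0, nTriads = 0L, seed = 3L)
  sim <- simulateCounts(smallDesign, cfg)
  expect_equal(nrow(sim$truth@plantedDE), 0L)
  expect_equal(nrow(sim$truth@plantedTriads), 0L)
  expect_equal(nrow(sim$truth@plantedInteractions), 0L)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- simulationConfig(nCirc = 30L, nMirna = 10L, nMrna = 40L,
                          nTriads = 3L, seed = 9L)
  a <- simulateCounts(smallDesign, cfg)
  b <- simulateCounts(smallDesign, cfg)
  for (cl in names(a$counts))
    expect_identical(SummarizedExperiment::assay(a$counts[[cl]]),
                     SummarizedExperiment::assay(b$counts[[cl]]))
  expect_identical(a$truth@plantedDE, b$truth@plantedDE)
  expect_identical(generateInteractions(a$truth, cfg),
                   generateInteractions(b$truth, cfg))
})

test_that("counts are nonnegative integers and ground truth is consistent", {
  cfg <- simulationConfig(nCirc = 30L, nMirna = 10L, nMrna = 40L,
                          nTriads = 5L, seed = 2L)
  sim <- simulateCounts(smallDesign, cfg)
  m <- SummarizedExperiment::assay(sim$counts$circRNA)
  expect_true(all(m >= 0))
  expect_true(is.integer(m))
  expect_true(validObject(sim$truth))
  # triad circRNA and mRNA are planted DE, miRNA opposes their direction
  de <- sim$truth@plantedDE
  tri <- sim$truth@plantedTriads
  expect_true(all(tri$circ_id %in% de$feature_id[de$class == "circRNA"]))
  expect_true(all(tri$mrna_id %in% de$feature_id[de$class == "mRNA"]))
  dirOf <- setNames(de$direction, de$feature_id)
  expect_true(all(dirOf[tri$mirna_id] != dirOf[tri$circ_id]))
})

test_that("over-planting triads is a configuration error", {
  expect_error(simulationConfig(nCirc = 5L, nMirna = 5L, nMrna = 5L,
                                nTriads = 6L), "nTriads")
})

test_that("interaction table contains planted edges plus unique decoys", {
  cfg <- simulationConfig(nCirc = 30L, nMirna = 10L, nMrna = 40L,
                          nTriads = 5L, interactionDensity = 0.1, seed = 4L)
  sim <- simulateCounts(smallDesign, cfg)
  tab <- generateInteractions(sim$truth, cfg)
  key <- paste(tab$mirna_id, tab$target_id, tab$target_type)
  expect_false(anyDuplicated(key) > 0)
  pk <- with(sim$truth@plantedInteractions,
             paste(mirna_id, target_id, target_type))
  expect_true(all(pk %in% key))
  expect_gte(nrow(tab), 10L)  # two edges per planted triad

  cfg0 <- simulationConfig(nCirc = 30L, nMirna = 10L, nMrna = 40L,
                           nTriads = 5L, interactionDensity = 0, seed = 4L)
  sim0 <- simulateCounts(smallDesign, cfg0)
  tab0 <- generateInteractions(sim0$truth, cfg0)
  expect_equal(nrow(tab0), nrow(sim0$truth@plantedInteractions))
})

test_that("planted coupling produces the intended correlation signs", {
  # at full coupling with many replicates, nearly every planted pair should
  # show strongly negative miRNA-target and positive circRNA-mRNA rank
  # correlation
  d <- generateDesign(tissues = "hypothalamus", replicates = 50L)
  cfg <- simulationConfig(nTriads = 20L, couplingStrength = 1,
                          seed = 21L)
  sim <- simulateCounts(d, cfg)
  tri <- sim$truth@plantedTriads
  cpm <- lapply(sim$counts, normalizeCPM)
  sccMC <- mapply(function(a, b) spearmanCor(cpm$miRNA[a, ], cpm$circRNA[b, ]),
                  tri$mirna_id, tri$circ_id)
  sccMG <- mapply(function(a, b) spearmanCor(cpm$miRNA[a, ], cpm$mRNA[b, ]),
                  tri$mirna_id, tri$mrna_id)
  pccCG <- mapply(function(a, b) pearsonCor(log2(cpm$circRNA[a, ] + 1),
                                            log2(cpm$mRNA[b, ] + 1)),
                  tri$circ_id, tri$mrna_id)
  expect_gte(mean(sccMC < -0.7), 0.95)
  expect_gte(mean(sccMG < -0.7), 0.95)
  expect_gte(mean(pccCG > 0), 0.95)
})

test_that("planted DE features carry the configured mean ratio", {
  d <- generateDesign(tissues = "hypothalamus", replicates = 50L)
  cfg <- simulationConfig(nCirc = 200L, nMirna = 50L, nMrna = 200L,
                          nTriads = 0L, deFraction = 0.2, deLog2FC = 2,
                          seed = 6L)
  sim <- simulateCounts(d, cfg)
  de <- sim$truth@plantedDE
  up <- de$feature_id[de$class == "mRNA" & de$direction == "up"]
  m <- SummarizedExperiment::assay(sim$counts$mRNA)
  cond <- SummarizedExperiment::colData(sim$counts$mRNA)$condition
  ratio <- rowMeans(m[up, cond == "HS"]) / rowMeans(m[up, cond == "NHS"])
  expect_equal(median(log2(ratio)), 2, tolerance = 0.15)
})
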