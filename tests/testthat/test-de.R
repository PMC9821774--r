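test_that("BH adjustment matches hand-calculated values", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(-0.1)), "\\[0, 1\\]")
})

# fixture with a strong planted effect in a sea of nulls
.deFixture <- function(seed = 23) {
  set.seed(seed)
  n <- 300L
  m <- matrix(rnbinom(n * 6, mu = 200, size = 1 / 0.05), n, 6,
              dimnames = list(sprintf("f%03d", 1:n), paste0("s", 1:6)))
  m[1, 4:6] <- m[1, 4:6] * 8L   # clear DE feature
  m
}

test_that("significance requires both the fold-change and probability gate", {
  m <- .deFixture()
  cond <- rep(c("NHS", "HS"), each = 3)
  de <- callDE(m, cond, "circRNA", control = "NHS")
  expect_true(de$significant[1])
  expect_equal(de$direction[1], "up")
  # gate soundness: every significant row satisfies the printed thresholds
  sig <- de[de$significant, ]
  expect_true(all(abs(sig$log2fc) >= 1 & sig$pvalue < 0.05))
  notsig <- de[!de$significant, ]
  expect_true(all(abs(notsig$log2fc) < 1 | notsig$pvalue >= 0.05))
})

test_that("the mRNA class gates on FDR where circRNA gates on p", {
  # find a feature that passes the raw-p gate but not BH: moderate shift
  set.seed(41)
  n <- 400L
  m <- matrix(rnbinom(n * 6, mu = 150, size = 1 / 0.05), n, 6,
              dimnames = list(sprintf("f%03d", 1:n), paste0("s", 1:6)))
  m[1, 4:6] <- as.integer(round(m[1, 4:6] * 2.6))
  cond <- rep(c("NHS", "HS"), each = 3)
  deC <- callDE(m, cond, "circRNA", control = "NHS")
  deM <- callDE(m, cond, "mRNA", control = "NHS")
  # identical statistics, different gates
  expect_equal(deC$pvalue, deM$pvalue)
  expect_equal(deC$log2fc, deM$log2fc)
  borderline <- deC$significant & !deM$significant
  if (any(borderline)) {
    i <- which(borderline)[1]
    expect_lt(deC$pvalue[i], 0.05)
    expect_gte(deM$fdr[i], 0.05)
  }
  expect_true(all(deM$fdr[deM$significant] < 0.05))
})

test_that("a strong p-value cannot rescue a weak fold change", {
  m <- .deFixture()
  cond <- rep(c("NHS", "HS"), each = 3)
  de <- callDE(m, cond, "miRNA", control = "NHS")
  weak <- abs(de$log2fc) < 1
  expect_false(any(de$significant[weak]))
})

test_that("unknown RNA class is rejected", {
  m <- .deFixture()
  expect_error(callDE(m, rep(c("A", "B"), each = 3), "lncRNA"),
               "unknown rnaClass")
})

test_that("label swap negates fold changes and keeps p-values", {
  m <- .deFixture()
  cond <- rep(c("NHS", "HS"), each = 3)
  a <- callDE(m, cond, "circRNA", control = "NHS", pseudocount = 0)
  b <- callDE(m, cond, "circRNA", control = "HS", pseudocount = 0)
  expect_equal(a$log2fc, -b$log2fc)
  # exact up to floating-point asymmetry of the tie-tolerant two-sided sum
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-6)
})

test_that("null data keep mRNA calls at or below the FDR level", {
  set.seed(57)
  n <- 2000L
  m <- matrix(rnbinom(n * 6, mu = 120, size = 1 / 0.1), n, 6,
              dimnames = list(sprintf("f%04d", 1:n), paste0("s", 1:6)))
  de <- callDE(m, rep(c("NHS", "HS"), each = 3), "mRNA", control = "NHS")
  expect_lte(sum(de$significant), 0.05 * n)
})

test_that("callDE on an RNACountSet uses its colData and class", {
  d <- generateDesign(tissues = "hypothalamus")
  cfg <- simulationConfig(nCirc = 40L, nMirna = 10L, nMrna = 40L,
                          nTriads = 2L, seed = 8L)
  sim <- simulateCounts(d, cfg)
  de <- callDE(sim$counts$circRNA, tissue = "hypothalamus")
  expect_equal(nrow(de), 40L)
  expect_true(all(c("feature_id", "log2fc", "pvalue", "fdr", "significant",
                    "direction") %in% names(de)))
})
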