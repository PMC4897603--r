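## Splicing entropy, correlation diagnostics, pathway-input transform,
## rank concordance and the wild-type control permutation.

test_that("Shannon entropy closed forms", {
  expect_equal(shannonEntropy(rep(1, 4)), 2)
  expect_equal(shannonEntropy(1), 0)
  expect_equal(shannonEntropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(shannonEntropy(c(2, 1, 1)), 1.5) # renormalized internally
  expect_equal(shannonEntropy(c(1, 0, 0)), 0)
  expect_error(shannonEntropy(c(0, 0)), "positive sum")
  expect_error(shannonEntropy(c(0.5, -0.1)), "non-negative")
})

test_that("per-gene splicing entropy over isoform abundances", {
  iso <- matrix(c(30, 30, 100, 0, 0, 50, 25, 25,
                  10, 10, 0, 0, 0, 0, 0, 0),
                ncol = 2L,
                dimnames = list(c("A.1", "A.2", "B.1", "B.2", "B.3",
                                  "C.1", "C.2", "C.3"), c("S1", "S2")))
  map <- c(A.1 = "A", A.2 = "A", B.1 = "B", B.2 = "B", B.3 = "B",
           C.1 = "C", C.2 = "C", C.3 = "C")
  e <- geneSplicingEntropy(iso, map, "S1")
  expect_equal(unname(e["A"]), 1)
  expect_equal(unname(e["B"]), 0)
  expect_equal(unname(e["C"]), 1.5)
  ## zero-expression genes are omitted, not zero
  e2 <- geneSplicingEntropy(iso, map, "S2")
  expect_identical(names(e2), "A")
  expect_error(geneSplicingEntropy(iso, map[-1L], "S1"), "A.1")
})

test_that("sample-level entropy pools all isoforms of all genes", {
  iso <- matrix(rep(5, 8), ncol = 1L,
                dimnames = list(paste0("I", 1:8), "S1"))
  expect_equal(sampleSplicingEntropy(iso, "S1"), 3)
  iso2 <- iso
  iso2[, 1L] <- c(40, rep(0, 7))
  expect_equal(sampleSplicingEntropy(iso2, "S1"), 0)
  ## concentrating mass on the same support strictly lowers entropy
  iso3 <- iso
  iso3[, 1L] <- c(20, rep(20 / 7, 7))
  expect_lt(sampleSplicingEntropy(iso3, "S1"),
            sampleSplicingEntropy(iso, "S1"))
  iso0 <- iso
  iso0[, 1L] <- 0
  expect_error(sampleSplicingEntropy(iso0, "S1"), "no expressed isoform")
})

test_that("entropy is additive for equal-weight uniform genes", {
  G <- 4L
  k <- 4L
  iso <- matrix(rep(1, G * k), ncol = 1L,
                dimnames = list(sprintf("G%d.%d", rep(1:G, each = k),
                                        rep(1:k, G)), "S1"))
  expect_equal(sampleSplicingEntropy(iso, "S1"), log2(G * k),
               tolerance = 1e-12)
})

test_that("entropy-expression correlation: exact, null, leave-one-out", {
  x <- setNames(1:10, paste0("S", 1:10))
  expect_equal(entropyExpressionCorrelation(x, 2 * x + 1)$r, 1)
  expect_equal(entropyExpressionCorrelation(x, -x)$r, -1)
  set.seed(4)
  xs <- setNames(rnorm(1000), paste0("S", 1:1000))
  ys <- setNames(rnorm(1000), paste0("S", 1:1000))
  expect_lt(abs(entropyExpressionCorrelation(xs, ys)$r), 0.1)
  expect_warning(res <- entropyExpressionCorrelation(
    x, setNames(rep(1, 10), names(x))), "zero variance")
  expect_true(is.na(res$r))
  ## one outlier masks a strong association; the diagnostic exposes it
  xo <- setNames(c(1:7, 4), paste0("S", 1:8))
  yo <- setNames(c(1:7 * 0.5 + 0.1 * c(1, -1, 1, -1, 1, -1, 1), -10),
                 paste0("S", 1:8))
  res <- entropyExpressionCorrelation(xo, yo)
  best <- max(res$loo$r, na.rm = TRUE)
  expect_gt(best, res$r + 0.2)
  expect_gte(res$looMaxDelta, best - res$r)
  expect_error(entropyExpressionCorrelation(x[1:2], (2 * x)[1:2]),
               "at least 3")
})

test_that("pathway-input transform v = s(1-p)", {
  expect_equal(ipageTransform(0, 1), 1)
  expect_equal(ipageTransform(1, 1), 0)
  expect_equal(ipageTransform(1, -1), 0)
  expect_equal(ipageTransform(0.05, -1), -0.95)
  expect_equal(ipageTransform(c(0.2, 0.4), c(1, -1)), c(0.8, -0.6))
  expect_error(ipageTransform(1.2, 1), "0, 1")
  expect_error(ipageTransform(0.5, 2), "\\+1 or -1")
})

test_that("gene direction vector finds planted shifts and stays bounded", {
  set.seed(9)
  samples <- paste0("S", 1:55)
  mut <- samples[1:5]
  expr <- matrix(rnorm(20 * 55), nrow = 20L,
                 dimnames = list(paste0("G", 1:20), samples))
  expr["G1", mut] <- expr["G1", mut] + 3 # +3 SD shift
  expr["G2", mut] <- expr["G2", mut] - 3
  expr["G20", ] <- 7 # zero variance everywhere
  v <- geneDirectionVector(expr, mut)
  expect_gt(v$v[v$gene == "G1"], 0.95)
  expect_lt(v$v[v$gene == "G2"], -0.95)
  expect_equal(v$v[v$gene == "G20"], 0)
  expect_true(all(abs(v$v) <= 1))
  ## null genes average near zero
  expect_lt(abs(mean(v$v[3:19])), 0.35)
  expect_error(geneDirectionVector(expr, samples[1L]), "at least 2")
})

test_that("swapping the group labels negates the direction vector", {
  set.seed(10)
  samples <- paste0("S", 1:20)
  expr <- matrix(rnorm(5 * 20), nrow = 5L,
                 dimnames = list(paste0("G", 1:5), samples))
  a <- geneDirectionVector(expr, samples[1:10])
  b <- geneDirectionVector(expr, samples[11:20])
  expect_equal(a$v, -b$v, tolerance = 1e-9)
})

test_that("rank concordance detects a monotone repressed target", {
  x <- setNames(c(1, 2, 3, 4, 5), paste0("S", 1:5))
  y <- setNames(c(9, 7, 5, 3, 1), paste0("S", 1:5))
  res <- rankConcordance(x, y, expectedSign = -1)
  expect_equal(res$rho, -1)
  expect_true(res$concordant)
  res2 <- rankConcordance(x, setNames(c(1, 3, 5, 7, 9), names(x)),
                          expectedSign = -1)
  expect_false(res2$concordant)
  expect_true(rankConcordance(x, setNames(c(1, 3, 5, 7, 9), names(x)),
                              expectedSign = 1)$concordant)
  flat <- rankConcordance(x, setNames(rep(2, 5), names(x)), -1)
  expect_true(is.na(flat$rho))
  expect_error(rankConcordance(x[1:2], y[1:2], -1), "at least 3")
})

test_that("wild-type control permutation behaves as an empirical null", {
  pool <- paste0("S", 1:30)
  cst <- wildtypeControlPermutation(pool, function(s) 0.2, subsetSize = 5L,
                                    nIter = 50L, seed = 2, observed = 0.9)
  expect_equal(cst$p, 0) # constant null, more extreme observation
  expect_equal(cst$null, rep(0.2, 50L))
  ## deterministic given the seed, p on the 1/nIter grid
  set.seed(1)
  vals <- setNames(rnorm(30), pool)
  stat <- function(s) mean(vals[s])
  a <- wildtypeControlPermutation(pool, stat, 8L, nIter = 100L, seed = 5,
                                  observed = 0.1)
  b <- wildtypeControlPermutation(pool, stat, 8L, nIter = 100L, seed = 5,
                                  observed = 0.1)
  expect_identical(a$null, b$null)
  expect_true(a$p %in% ((0:100) / 100))
  expect_error(wildtypeControlPermutation(pool, stat, 31L, 10L),
               "exceeds")
})

test_that("control-permutation p is calibrated when the observation is null", {
  set.seed(6)
  pool <- paste0("S", 1:40)
  vals <- setNames(rnorm(40), pool)
  stat <- function(s) mean(vals[s])
  ps <- vapply(1:120, function(i) {
    obs <- stat(sample(pool, 8L))
    wildtypeControlPermutation(pool, stat, 8L, nIter = 60L,
                               observed = obs)$p
  }, numeric(1L))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("entropy coupling slope is recovered from a generated cohort", {
  duon <- DuonSpec(expressionLog2fc = 0, allelicSkew = 0.8,
                   motifEffect = "none", entropyCoupling = 0.02,
                   entropyNoiseSd = 0.1, nMutantSamples = 8L)
  cfg <- simulationConfig(seed = 61L, nSamples = 50L, nGenes = 20L,
                          nBackgroundRecurrent = 3L,
                          nBackgroundPrivate = 0L, nKnownContaminants = 0L,
                          exprMeanLog2Range = c(5, 5.2),
                          plantedDuons = list(duon))
  sim <- generateCohort(cfg)
  iso <- isoformExpression(sim$cohort)
  h <- vapply(colnames(iso), function(s) sampleSplicingEntropy(iso, s),
              numeric(1L))
  x <- expressionMatrix(sim$cohort)[sim$truth$gene[1L], ]
  fit <- coef(lm(h ~ x))[["x"]]
  expect_lt(abs(fit - 0.02) / 0.02, 0.5) # within 50% relative error
})

test_that("mutant-allele expression combines RNA fraction and expression", {
  sim <- smallPlantedSim(seed = 604L, nDuons = 1L, nBackground = 3L)
  tr <- sim$truth[1L, ]
  mae <- mutantAllelicExpression(sim$cohort, tr$chrom, tr$pos, tr$ref,
                                 tr$alt, tr$gene)
  carriers <- strsplit(tr$samples, ",")[[1]]
  expect_setequal(names(mae), carriers)
  expr <- expressionMatrix(sim$cohort)[tr$gene, carriers]
  expect_true(all(mae <= expr[names(mae)] + 1e-9))
  expect_true(all(mae >= 0))
})
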