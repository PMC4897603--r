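## The synthetic cohort generator: validity, planted construction,
## determinism, null calibration and the expected-score oracle.

test_that("a cohort with no planted duons is valid with an empty truth", {
  sim <- generateCohort(simulationConfig(seed = 701L, nSamples = 20L,
                                         nGenes = 10L,
                                         nBackgroundRecurrent = 5L,
                                         nBackgroundPrivate = 2L,
                                         nKnownContaminants = 2L))
  expect_true(validObject(sim$cohort))
  expect_equal(nrow(sim$truth), 0L)
  expect_equal(cohortSize(sim$cohort), 20L)
  expect_equal(nrow(mutations(sim$cohort)), 9L)
})

test_that("planted regulatory overlap flags are realized in the tracks", {
  duons <- list(
    DuonSpec(inDnase = TRUE, inChip = FALSE, motifEffect = "none"),
    DuonSpec(inDnase = FALSE, inChip = TRUE, motifEffect = "none"))
  sim <- smallPlantedSim(seed = 702L, duons = duons, nBackground = 3L)
  dn <- tracksOfKind(sim$cohort, "dnase")
  ch <- tracksOfKind(sim$cohort, "chip")
  tr <- sim$truth
  expect_true(overlapTrack(tr$chrom[1], tr$pos[1], tr$ref[1], tr$alt[1], dn))
  expect_false(overlapTrack(tr$chrom[1], tr$pos[1], tr$ref[1], tr$alt[1], ch))
  expect_false(overlapTrack(tr$chrom[2], tr$pos[2], tr$ref[2], tr$alt[2], dn))
  expect_true(overlapTrack(tr$chrom[2], tr$pos[2], tr$ref[2], tr$alt[2], ch))
})

test_that("planted motif effects are reproduced by the production scanner", {
  sim <- smallPlantedSim(seed = 703L, nDuons = 10L, nBackground = 2L)
  models <- geneModels(sim$cohort)
  seqs <- geneSequences(sim$cohort)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    mp <- scanMotifPerturbation(tr$pos, tr$ref, tr$alt, models[[tr$gene]],
                                seqs[[tr$gene]], pwms(sim$cohort))
    expect_identical(mp@effect, tr$motif_effect,
                     label = paste("duon", tr$gene))
  }
})

test_that("the same seed reproduces a byte-identical serialized cohort", {
  cfg <- function() simulationConfig(seed = 704L, nSamples = 15L,
                                     nGenes = 12L,
                                     nBackgroundRecurrent = 4L,
                                     plantedDuons = defaultDuonSpecs(2L))
  d1 <- tempfile()
  d2 <- tempfile()
  writeCohort(generateCohort(cfg())$cohort, d1)
  writeCohort(generateCohort(cfg())$cohort, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  ## and a different seed does not
  d3 <- tempfile()
  writeCohort(generateCohort(simulationConfig(seed = 705L, nSamples = 15L,
                                              nGenes = 12L,
                                              nBackgroundRecurrent = 4L,
                                              plantedDuons =
                                                defaultDuonSpecs(2L)))$cohort,
              d3)
  expect_false(identical(readLines(file.path(d1, "expression.tsv")),
                         readLines(file.path(d3, "expression.tsv"))))
})

test_that("expectedRedact encodes planted effects and disabled layers", {
  cfg <- simulationConfig(seed = 1, nSamples = 100L)
  allOn <- DuonSpec(expressionLog2fc = 1.5, allelicSkew = 0.8,
                    inDnase = TRUE, inChip = TRUE, motifEffect = "gain")
  expect_identical(expectedRedact(allOn, cfg), "REDACT")

  cfgNoA <- simulationConfig(seed = 1, nSamples = 100L,
                             layersEnabled = c(dnase = TRUE, chip = TRUE,
                                               allelic = FALSE))
  noC <- DuonSpec(expressionLog2fc = 1.5, allelicSkew = 0.8,
                  inDnase = TRUE, inChip = FALSE, motifEffect = "gain")
  expect_identical(expectedRedact(noC, cfgNoA), "RED*cT")

  ## no expression effect can never qualify as a pDM
  noE <- DuonSpec(expressionLog2fc = 0, allelicSkew = 0.8,
                  inDnase = TRUE, inChip = TRUE, motifEffect = "gain")
  s <- expectedRedact(noE, cfg)
  expect_identical(substr(s, 2L, 2L), "e")
  ## skew opposing the expression direction is expected lowercase
  contra <- DuonSpec(expressionLog2fc = 1.5, allelicSkew = 0.2,
                     inDnase = TRUE, inChip = TRUE, motifEffect = "none")
  expect_identical(expectedRedact(contra, cfg), "REDaCt")
  ## below the recurrence floor
  rare <- DuonSpec(nMutantSamples = 2L)
  expect_identical(substr(expectedRedact(rare, cfg), 1L, 1L), "r")
})

test_that("exome allele fractions follow the purity mixture model", {
  p <- 0.6
  duon <- DuonSpec(nMutantSamples = 50L, motifEffect = "none")
  cfg <- simulationConfig(seed = 706L, nSamples = 60L, nGenes = 8L,
                          nBackgroundRecurrent = 0L,
                          nBackgroundPrivate = 0L, nKnownContaminants = 0L,
                          purityRange = c(p, p), exomeDepth = 80L,
                          plantedDuons = list(duon))
  sim <- generateCohort(cfg)
  ac <- allelicCounts(sim$cohort)
  vaf <- ac$exome_alt / (ac$exome_alt + ac$exome_ref)
  expected <- p * 0.5 / (p * 0.5 + (1 - p))
  se <- sd(vaf) / sqrt(length(vaf))
  expect_lt(abs(mean(vaf) - expected), 3 * se + 1e-3)
})

test_that("E-layer p-values are uniform on a null cohort of 500 genes", {
  cfg <- simulationConfig(seed = 707L, nSamples = 60L, nGenes = 500L,
                          nBackgroundRecurrent = 200L,
                          nBackgroundPrivate = 0L, nKnownContaminants = 0L)
  sim <- generateCohort(cfg)
  muts <- mutations(sim$cohort)
  expr <- expressionMatrix(sim$cohort)
  ps <- vapply(seq_len(nrow(muts)), function(i)
    testExpressionChange(muts$gene[i], muts$samples[[i]], expr)@pValue,
    numeric(1L))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("entropy coupling with a planted target correlation is realized", {
  duon <- DuonSpec(expressionLog2fc = 0.5, allelicSkew = 0.8,
                   nMutantSamples = 8L, motifEffect = "none",
                   entropyTargetR = 0.8, entropyNoiseSd = 0.1)
  cfg <- simulationConfig(seed = 708L, nSamples = 50L, nGenes = 25L,
                          nBackgroundRecurrent = 2L,
                          plantedDuons = list(duon))
  sim <- generateCohort(cfg)
  iso <- isoformExpression(sim$cohort)
  h <- vapply(colnames(iso), function(s) sampleSplicingEntropy(iso, s),
              numeric(1L))
  x <- expressionMatrix(sim$cohort)[sim$truth$gene[1L], ]
  expect_lt(abs(cor(x, h) - 0.8), 0.15)
})

test_that("configuration validity catches infeasible requests", {
  expect_error(simulationConfig(seed = NA), "seed")
  expect_error(simulationConfig(seed = 1, nSamples = 1L), "nSamples")
  expect_error(simulationConfig(seed = 1, purityRange = c(0, 0.5)),
               "purityRange")
  expect_error(
    simulationConfig(seed = 1, nSamples = 10L,
                     plantedDuons = list(DuonSpec(nMutantSamples = 11L))),
    "more carriers")
  expect_error(DuonSpec(allelicSkew = 1.2), "allelicSkew")
  expect_error(DuonSpec(consequence = "inframe_del", motifEffect = "gain"),
               "gain")
  twoCoupled <- list(DuonSpec(entropyCoupling = 0.1),
                     DuonSpec(entropyCoupling = 0.2))
  expect_error(simulationConfig(seed = 1, plantedDuons = twoCoupled),
               "entropy coupling")
})
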