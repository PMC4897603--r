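## Evidence layers: recurrence, expression change, allelic imbalance,
## track overlap and the permutation null, motif perturbation.

test_that("recurrence requires the 3-sample floor and >1% jointly", {
  expect_identical(assessRecurrence(3, 200)@status, "consistent")
  expect_identical(assessRecurrence(5, 500)@status, "inconsistent") # ==1%
  expect_identical(assessRecurrence(2, 50)@status, "inconsistent")
  expect_identical(assessRecurrence(6, 500)@status, "consistent")
  expect_true(is.na(assessRecurrence(3, 200)@pValue))
  expect_error(assessRecurrence(3, 0), "positive")
})

test_that("expression change matches the exact U distribution", {
  expr <- rbind(GENE = c(10, 11, 12, 1, 2, 3, 4, 5))
  colnames(expr) <- paste0("S", 1:8)
  res <- testExpressionChange("GENE", c("S1", "S2", "S3"), expr)
  expect_equal(res@pValue, 2 / 56, tolerance = 1e-12)
  expect_equal(res@pValue, enumWilcoxP(c(10, 11, 12), 1:5),
               tolerance = 1e-12)
  expect_identical(res@status, "consistent")
  expect_identical(res@direction, "up")
})

test_that("expression change handles null shifts and absent data", {
  expr <- rbind(GENE = c(1, 2, 3, 4, 1, 2, 3, 4))
  colnames(expr) <- paste0("S", 1:8)
  res <- testExpressionChange("GENE", paste0("S", 1:4), expr)
  expect_identical(res@status, "inconsistent")
  expect_gt(res@pValue, 0.9)

  expect_identical(testExpressionChange("NOPE", "S1", expr)@status, "absent")
  expect_identical(
    testExpressionChange("GENE", paste0("S", 1:8), expr)@status, "absent")
})

test_that("Mann-Whitney agrees with enumeration for small groups", {
  set.seed(42)
  for (rep in 1:15) {
    n1 <- sample(2:6, 1L)
    n2 <- sample(2:(12 - n1), 1L)
    vals <- sample(seq_len(100), n1 + n2) # distinct => no ties
    x <- vals[seq_len(n1)]
    y <- vals[-seq_len(n1)]
    expect_equal(wilcox.test(x, y)$p.value, enumWilcoxP(x, y),
                 tolerance = 1e-10)
  }
})

test_that("allelic imbalance reproduces the exact binomial case", {
  counts <- data.frame(chrom = "chr1", pos = 1L, ref = "C", alt = "A",
                       sample = "S1", exome_ref = 10L, exome_alt = 10L,
                       rna_ref = 5L, rna_alt = 15L, stringsAsFactors = FALSE)
  res <- testAllelicImbalance(counts) # no purity: p0 = raw exome VAF = 0.5
  expect_equal(res@pValue, enumBinomP(15, 20, 0.5), tolerance = 1e-10)
  expect_equal(res@pValue, 0.0413894653, tolerance = 1e-8)
  expect_identical(res@direction, "up")
  expect_identical(res@status, "consistent")
})

test_that("allelic imbalance: modal counts are null, zero coverage absent", {
  counts <- data.frame(chrom = "chr1", pos = 1L, ref = "C", alt = "A",
                       sample = c("S1", "S2"), exome_ref = 20L,
                       exome_alt = 20L, rna_ref = 15L, rna_alt = 15L,
                       stringsAsFactors = FALSE)
  res <- testAllelicImbalance(counts)
  expect_identical(res@status, "inconsistent")
  expect_gt(res@pValue, 0.5)

  dry <- transform(counts, rna_ref = 0L, rna_alt = 0L)
  expect_identical(testAllelicImbalance(dry)@status, "absent")
  expect_identical(testAllelicImbalance(NULL)@status, "absent")
})

test_that("purity adjustment caps the null at the het expectation", {
  ## exome VAF 0.3 at purity 0.6: corrected 0.5 => null 0.5
  counts <- data.frame(chrom = "chr1", pos = 1L, ref = "C", alt = "A",
                       sample = "S1", exome_ref = 56L, exome_alt = 24L,
                       rna_ref = 30L, rna_alt = 30L, stringsAsFactors = FALSE)
  res <- testAllelicImbalance(counts, purity = c(S1 = 0.6))
  expect_equal(res@pValue, enumBinomP(30, 60, 0.5), tolerance = 1e-9)
  ## VAF beyond the clonal-het dose (corrected > 1) relaxes the cap
  loh <- transform(counts, exome_ref = 20L, exome_alt = 60L) # VAF 0.75
  res2 <- testAllelicImbalance(loh, purity = c(S1 = 0.6))
  expect_equal(res2@pValue, enumBinomP(30, 60, 0.625), tolerance = 1e-9)
})

test_that("binomial test agrees with pmf enumeration on a grid", {
  for (n in c(7L, 18L, 30L)) {
    for (p0 in seq(0.1, 0.9, by = 0.2)) {
      for (x in unique(c(0L, 3L, n %/% 2L, n))) {
        expect_equal(binom.test(x, n, p0)$p.value, enumBinomP(x, n, p0),
                     tolerance = 1e-9,
                     label = sprintf("binom x=%d n=%d p0=%.1f", x, n, p0))
      }
    }
  }
})

test_that("track overlap uses the changed-base footprint", {
  tr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 20)) # BED [10,20)
  expect_true(overlapTrack("chr1", 15, "C", "A", tr))
  expect_false(overlapTrack("chr1", 21, "C", "A", tr))
  ## 3-bp deletion starting at pos 19: first deleted base inside
  expect_true(overlapTrack("chr1", 19, "CATG", "C", tr))
  ## insertion anchored at base 20 (inside), written MAF-style
  expect_true(overlapTrack("chr1", 20, "A", "AGGG", tr))
  expect_false(overlapTrack("chr1", 2, "C", "A", tr))
  expect_false(overlapTrack("chr1", 15, "C", "A", NULL))
})

test_that("permutation overlap p hits the forced and calibrated cases", {
  gm <- singleExonModel(1000L)
  full <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  none <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 6000))
  half <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500))
  expect_identical(permutationOverlapP(gm, full, 2000L, seed = 1), 1)
  expect_identical(permutationOverlapP(gm, none, 2000L, seed = 1), 0)
  p <- permutationOverlapP(gm, half, 10000L, seed = 7)
  expect_lt(abs(p - 0.5), 0.02) # 3*SE bound at nPerm = 10,000
  ## deterministic given the seed
  expect_identical(p, permutationOverlapP(gm, half, 10000L, seed = 7))
  ## add-one estimator is strictly positive
  expect_gt(permutationOverlapP(gm, none, 100L, seed = 1,
                                estimator = "add-one"), 0)
  empty <- list(chrom = "chr1", strand = "+",
                exons = matrix(integer(), 0L, 2L))
  expect_error(permutationOverlapP(empty, full, 10L), "empty exon")
})

test_that("permutation overlap p is monotone in track coverage", {
  gm <- singleExonModel(1000L)
  covs <- c(0.2, 0.5, 0.8)
  ps <- vapply(covs, function(f) {
    tr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000 * f))
    permutationOverlapP(gm, tr, 4000L, seed = 11)
  }, numeric(1L))
  expect_true(all(diff(ps) > 0))
  expect_equal(ps, covs, tolerance = 0.05)
})

test_that("permutation p under a uniform planted position matches coverage", {
  ## the null estimator depends only on the track's exonic coverage, so
  ## its expectation over uniformly planted positions equals the coverage
  gm <- singleExonModel(800L)
  tr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 420)) # 40%
  set.seed(99)
  ps <- vapply(1:50, function(i)
    permutationOverlapP(gm, tr, 2000L), numeric(1L))
  expect_lt(abs(mean(ps) - 0.4), 3 * sd(ps) / sqrt(50) + 1e-3)
})

test_that("motif scan detects an engineered gain and its loss mirror", {
  pwm <- makeTestPwm("TATAAT")
  ## wild-type window: consensus with position 3 broken (T->G)
  seqWt <- paste0("CCCCCCCCCC", "TAGAAT", "CCCCCCCCCC")
  gm <- singleExonModel(nchar(seqWt))
  res <- scanMotifPerturbation(13, "G", "T", gm, seqWt,
                               list(TST = pwm))
  expect_identical(res@effect, "gain")
  expect_identical(res@gainTfs, "TFX")
  ## the mutant sequence scanned with swapped alleles shows the loss
  seqMut <- paste0("CCCCCCCCCC", "TATAAT", "CCCCCCCCCC")
  res2 <- scanMotifPerturbation(13, "T", "G", gm, seqMut, list(TST = pwm))
  expect_identical(res2@effect, "loss")
  expect_identical(res2@lossTfs, "TFX")
  ## a neutral edit far from any motif
  res3 <- scanMotifPerturbation(3, "C", "A", gm, seqWt, list(TST = pwm))
  expect_identical(res3@effect, "none")
})

test_that("motif scan is allele-symmetric on random substitutions", {
  pwms <- syntheticPwmLibrary()
  set.seed(21)
  gm <- singleExonModel(120L)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:12) {
    seqChars <- sample(bases, 120L, TRUE)
    ## sometimes embed a consensus so losses occur too
    if (rep %% 2L == 0L) seqChars[41:46] <- strsplit("TATAAT", "")[[1]]
    pos <- sample(20:100, 1L)
    ref <- seqChars[pos]
    alt <- sample(setdiff(bases, ref), 1L)
    fwd <- scanMotifPerturbation(pos, ref, alt, gm,
                                 paste(seqChars, collapse = ""), pwms)
    mutChars <- seqChars
    mutChars[pos] <- alt
    rev <- scanMotifPerturbation(pos, alt, ref, gm,
                                 paste(mutChars, collapse = ""), pwms)
    swap <- c(gain = "loss", loss = "gain", none = "none")
    expect_identical(rev@effect, unname(swap[fwd@effect]))
  }
})

test_that("motif scan detects loss from an in-frame deletion", {
  seqWt <- paste0("CCCCCCCCCC", "TATAAT", "CCCCCCCCCC")
  gm <- singleExonModel(nchar(seqWt))
  res <- scanMotifPerturbation(12, "ATA", "-", gm, seqWt,
                               list(TST = makeTestPwm("TATAAT")))
  expect_identical(res@effect, "loss")
  expect_error(scanMotifPerturbation(500, "C", "A", gm, seqWt,
                                     list(TST = makeTestPwm("TATAAT"))),
               "outside")
})

test_that("SNV motif permutation agrees with exhaustive window rescans", {
  pwms <- syntheticPwmLibrary()
  set.seed(33)
  seqChars <- sample(c("A", "C", "G", "T"), 90L, TRUE)
  seqChars[31:36] <- strsplit("CACGTG", "")[[1]]
  s <- paste(seqChars, collapse = "")
  gm <- singleExonModel(90L)
  alt <- "A"
  ## brute force: effect of editing every position to the same alt base
  eff <- vapply(1:90, function(pos) {
    if (seqChars[pos] == alt) return(FALSE)
    scanMotifPerturbation(pos, seqChars[pos], alt, gm, s, pwms)@effect !=
      "none"
  }, logical(1L))
  exact <- mean(eff)
  p <- permutationMotifP(31, seqChars[31], alt, gm, s, pwms,
                         nPerm = 4000L, seed = 13)
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(p - exact), 3 * se + 1e-3)
  ## deterministic given the seed
  expect_identical(p, permutationMotifP(31, seqChars[31], alt, gm, s, pwms,
                                        nPerm = 4000L, seed = 13))
})

test_that("direction consistency is vacuous for absent or undirected layers", {
  up <- ev("E", "consistent", 0.01, "up")
  expect_true(directionConsistency(up, ev("A", "consistent", 0.01, "up")))
  expect_false(directionConsistency(up, ev("A", "consistent", 0.01, "down")))
  expect_true(directionConsistency(up, ev("A", "absent")))
  expect_true(directionConsistency(ev("E", "absent"),
                                   ev("A", "consistent", 0.01, "down")))
})
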