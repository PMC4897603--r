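## REDACT evidence layers R, E, A and the D/C overlap machinery.

#' R layer: recurrence
#'
#' A mutation counts as recurrent when it is carried by at least 3 samples
#' AND by more than 1\% of the cohort - the two conditions act jointly, so
#' the effective floor is whichever is greater. No p-value is attached; the
#' layer is a filter.
#'
#' @param nCarriers number of carrier samples.
#' @param cohortSize total cohort size.
#' @param minSamples recurrence floor (default 3).
#' @param minFraction cohort fraction that must be strictly exceeded
#'   (default 0.01).
#' @return An \linkS4class{EvidenceResult} for layer "R".
#' @examples
#' assessRecurrence(3, 200)  # consistent: 3 >= 3 and 1.5% > 1%
#' assessRecurrence(5, 500)  # inconsistent: 5/500 is not > 1%
#' @export
assessRecurrence <- function(nCarriers, cohortSize, minSamples = 3L,
                             minFraction = 0.01) {
  if (length(cohortSize) != 1L || is.na(cohortSize) || cohortSize <= 0) {
    .stopf("cohortSize must be a positive integer")
  }
  ok <- nCarriers >= minSamples && nCarriers / cohortSize > minFraction
  EvidenceResult("R", if (ok) "consistent" else "inconsistent")
}

#' E layer: cohort-level mRNA expression change
#'
#' Compares the gene's expression in carrier samples against all other
#' samples with a two-sided Mann-Whitney U test (exact when feasible, the
#' usual tie-corrected normal approximation otherwise). Direction is "up"
#' when the carrier median exceeds the non-carrier median.
#'
#' @param gene gene id.
#' @param mutantSamples character vector of carrier sample ids.
#' @param expression gene x sample matrix.
#' @param alpha significance threshold (default 0.05).
#' @return An \linkS4class{EvidenceResult} for layer "E"; status is
#'   "absent" when the gene is missing from the matrix or either group is
#'   empty.
#' @export
testExpressionChange <- function(gene, mutantSamples, expression,
                                 alpha = 0.05) {
  if (!gene %in% rownames(expression)) {
    return(EvidenceResult("E", "absent"))
  }
  mutantSamples <- intersect(mutantSamples, colnames(expression))
  others <- setdiff(colnames(expression), mutantSamples)
  x <- expression[gene, mutantSamples]
  y <- expression[gene, others]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 1L || length(y) < 1L) {
    return(EvidenceResult("E", "absent"))
  }
  p <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))$p.value
  dir <- if (median(x) > median(y)) "up" else "down"
  EvidenceResult("E", if (p < alpha) "consistent" else "inconsistent",
                 pValue = p, direction = dir)
}

## Null RNA alt-allele proportion for one sample: the exome VAF corrected
## for tumor purity (c = VAF/purity). While c stays within what a fully
## clonal heterozygous mutation can produce (c <= 1) the null is capped at
## the het expectation 0.5; beyond that the DNA itself indicates loss of
## the wild-type allele and the cap relaxes continuously (c/2) up to 1.
.allelicNullP0 <- function(exomeVaf, sPurity, purityAdjust = TRUE) {
  if (!purityAdjust || is.na(sPurity)) {
    return(exomeVaf)
  }
  corrected <- exomeVaf / sPurity
  min(max(corrected / 2, min(corrected, 0.5)), 1)
}

#' A layer: allelic expression imbalance
#'
#' Per carrier sample, tests the RNA-seq alt read count against a null
#' proportion derived from the exome allelic fraction (purity-adjusted)
#' with an exact two-sided binomial test; per-sample p-values are combined
#' with Fisher's method. Direction is "up" when a read-count-weighted
#' majority of samples expresses the mutant allele above its DNA-level
#' expectation. The layer is consistent when the combined p-value is below
#' \code{alpha} and all individually significant samples agree in
#' direction.
#'
#' @param counts data.frame with one row per carrier sample and columns
#'   sample, exome_ref, exome_alt, rna_ref, rna_alt.
#' @param purity named numeric vector of per-sample tumor purity (entries
#'   may be missing; those samples fall back to the raw exome VAF).
#' @param alpha significance threshold (default 0.05).
#' @param purityAdjust divide exome VAF by purity when forming the null
#'   (default TRUE).
#' @return An \linkS4class{EvidenceResult} for layer "A"; "absent" when no
#'   sample has both RNA and exome coverage.
#' @export
testAllelicImbalance <- function(counts, purity = numeric(), alpha = 0.05,
                                 purityAdjust = TRUE) {
  if (is.null(counts) || nrow(counts) == 0L) {
    return(EvidenceResult("A", "absent"))
  }
  rnaTot <- counts$rna_ref + counts$rna_alt
  exoTot <- counts$exome_ref + counts$exome_alt
  use <- which(rnaTot >= 1L & exoTot >= 1L)
  if (!length(use)) {
    return(EvidenceResult("A", "absent"))
  }
  ps <- numeric(length(use))
  signs <- numeric(length(use))
  weights <- numeric(length(use))
  for (i in seq_along(use)) {
    r <- use[i]
    vaf <- counts$exome_alt[r] / exoTot[r]
    sPur <- if (counts$sample[r] %in% names(purity))
      purity[[counts$sample[r]]] else NA_real_
    p0 <- .allelicNullP0(vaf, sPur, purityAdjust)
    p0 <- min(max(p0, 1e-9), 1 - 1e-9)
    ps[i] <- binom.test(counts$rna_alt[r], rnaTot[r], p = p0,
                        alternative = "two.sided")$p.value
    signs[i] <- sign(counts$rna_alt[r] / rnaTot[r] - p0)
    weights[i] <- rnaTot[r]
  }
  combined <- fisherCombine(pmin(ps, 1))
  dirScore <- sum(weights * signs)
  dir <- if (dirScore > 0) "up" else if (dirScore < 0) "down" else "none"
  sig <- ps < alpha
  oneDirection <- !any(sig) || length(unique(signs[sig])) == 1L
  status <- if (combined < alpha && oneDirection) "consistent" else
    "inconsistent"
  EvidenceResult("A", status, pValue = combined, direction = dir,
                 detail = sprintf("%d informative sample(s)", length(use)))
}

#' Does a mutation overlap a regulatory track?
#'
#' The mutation footprint is the set of changed reference bases: any
#' deleted base suffices for a deletion, and an insertion is anchored to
#' the base to its left. A substitution overlaps when its (1-based)
#' position falls inside an interval.
#'
#' @param chrom,pos,ref,alt the mutation (1-based position).
#' @param track \code{GRanges} regulatory track.
#' @return TRUE/FALSE.
#' @examples
#' tr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 20))
#' overlapTrack("chr1", 15, "C", "A", tr)  # TRUE
#' overlapTrack("chr1", 21, "C", "A", tr)  # FALSE
#' @export
overlapTrack <- function(chrom, pos, ref, alt, track) {
  if (is.null(track) || length(track) == 0L) {
    return(FALSE)
  }
  fp <- mutationFootprint(pos, ref, alt)
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(fp["start"], fp["end"]))
  GenomicRanges::countOverlaps(q, track) > 0L
}

#' Permutation p-value for regulatory-track overlap
#'
#' The null model shuffles the mutation uniformly over the gene's exonic
#' bases \code{nPerm} times and counts the shuffles (n) whose footprint
#' overlaps the track; the returned p-value is the plain permutation
#' estimator n/nPerm (optionally the strictly positive (n+1)/(nPerm+1)).
#' Note the estimator depends only on the track's exonic coverage, not on
#' the observed position: it measures how surprising any overlap within
#' this gene would be.
#'
#' @param geneModel gene model (\code{list(chrom, strand, exons)}).
#' @param track \code{GRanges} track (may be NULL/empty: p = 0).
#' @param nPerm number of shuffles (default 10000).
#' @param seed RNG seed.
#' @param footprintWidth width (in exonic bases) of the shuffled footprint;
#'   use the mutation's changed-base count (default 1).
#' @param estimator "n/N" or "add-one".
#' @return Permutation p-value in [0,1].
#' @export
permutationOverlapP <- function(geneModel, track, nPerm = 10000L,
                                seed = NULL, footprintWidth = 1L,
                                estimator = c("n/N", "add-one")) {
  estimator <- match.arg(estimator)
  if (nPerm < 1L) .stopf("nPerm must be >= 1")
  L <- splicedLength(geneModel$exons)
  if (L < 1L) .stopf("gene model has an empty exon set")
  footprintWidth <- max(1L, min(as.integer(footprintWidth), L))
  cov <- if (is.null(track)) logical(L) else
    splicedCoverage(geneModel$exons, geneModel$chrom, track)
  if (!is.null(seed)) set.seed(.assertSeed(seed))
  nStart <- L - footprintWidth + 1L
  draws <- sample.int(nStart, nPerm, replace = TRUE)
  if (footprintWidth == 1L) {
    n <- sum(cov[draws])
  } else {
    cs <- cumsum(c(0L, as.integer(cov)))
    n <- sum((cs[draws + footprintWidth] - cs[draws]) > 0L)
  }
  if (estimator == "n/N") n / nPerm else (n + 1) / (nPerm + 1)
}

#' Direction consistency between the E and A layers
#'
#' TRUE when both layers carry a defined direction and agree, or when
#' either layer is absent (vacuously consistent).
#'
#' @param eResult,aResult \linkS4class{EvidenceResult}s for E and A.
#' @return TRUE/FALSE.
#' @export
directionConsistency <- function(eResult, aResult) {
  if (eResult@status == "absent" || aResult@status == "absent") {
    return(TRUE)
  }
  if (eResult@direction == "none" || aResult@direction == "none") {
    return(TRUE)
  }
  eResult@direction == aResult@direction
}
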