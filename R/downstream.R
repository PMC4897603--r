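## Downstream consequences of a potential duon mutation: splicing entropy,
## entropy-expression correlation, the pathway-input transform, target
## concordance and wild-type control permutations.

#' Shannon entropy of a proportion vector
#'
#' H = -sum p_i log2 p_i with 0 log 0 := 0, in bits (base-2 logarithm).
#' Inputs are renormalized internally, so raw abundances are accepted.
#'
#' @param proportions non-negative numeric vector with a positive sum.
#' @return Entropy in bits.
#' @examples
#' shannonEntropy(rep(1, 4))        # 2 bits
#' shannonEntropy(c(0.5, 0.25, 0.25))  # 1.5 bits
#' @export
shannonEntropy <- function(proportions) {
  if (any(is.na(proportions)) || any(proportions < 0)) {
    .stopf("proportions must be non-negative and non-missing")
  }
  s <- sum(proportions)
  if (s <= 0) .stopf("proportions must have a positive sum")
  p <- proportions[proportions > 0] / s
  -sum(p * log2(p))
}

#' Per-gene splicing entropy in one sample
#'
#' Shannon entropy of the relative abundances of each gene's expressed
#' isoforms in the given sample. Genes whose isoforms are all zero in this
#' sample have undefined entropy and are omitted.
#'
#' @param isoformExpression isoform x sample matrix.
#' @param isoformToGene named character map isoform -> gene.
#' @param sample sample id (column name).
#' @return Named numeric vector, gene -> entropy in bits.
#' @export
geneSplicingEntropy <- function(isoformExpression, isoformToGene, sample) {
  if (!sample %in% colnames(isoformExpression)) {
    .stopf("sample '%s' not found in the isoform matrix", sample)
  }
  iso <- rownames(isoformExpression)
  unmapped <- setdiff(iso, names(isoformToGene))
  if (length(unmapped)) {
    .stopf("isoform(s) without a gene mapping: %s",
           paste(head(unmapped, 3L), collapse = ", "))
  }
  v <- isoformExpression[, sample]
  genes <- isoformToGene[iso]
  tot <- tapply(v, genes, sum)
  out <- vapply(names(tot)[tot > 0], function(g) {
    shannonEntropy(v[genes == g])
  }, numeric(1L))
  out[order(names(out))]
}

#' Sample-level splicing entropy
#'
#' Shannon entropy of the relative abundances of all expressed isoforms
#' across all genes in one sample - a single pooled distribution, not an
#' average of per-gene entropies.
#'
#' @inheritParams geneSplicingEntropy
#' @return Entropy in bits.
#' @export
sampleSplicingEntropy <- function(isoformExpression, sample) {
  if (!sample %in% colnames(isoformExpression)) {
    .stopf("sample '%s' not found in the isoform matrix", sample)
  }
  v <- isoformExpression[, sample]
  if (sum(v) <= 0) .stopf("sample '%s' has no expressed isoform", sample)
  shannonEntropy(v)
}

#' Correlation between a gene's expression and splicing entropy
#'
#' Pearson (default) or Spearman correlation between per-sample expression
#' of a gene of interest and per-sample splicing entropy, with an optional
#' leave-one-out diagnostic reporting how much the coefficient moves when
#' any single sample is dropped (a single outlying sample can mask a
#' strong association).
#'
#' @param expressionValues named numeric vector (per-sample expression).
#' @param entropies named numeric vector (per-sample entropy) on the same
#'   samples.
#' @param method "pearson" or "spearman".
#' @param leaveOneOut compute the leave-one-out diagnostic (default TRUE).
#' @return List with \code{r}, \code{n}, and (when requested) \code{loo}, a
#'   data.frame of per-dropped-sample coefficients, plus
#'   \code{looMaxDelta}, the largest absolute change in r from dropping a
#'   single sample. \code{r} is NA (with a warning) when either vector has
#'   zero variance.
#' @export
entropyExpressionCorrelation <- function(expressionValues, entropies,
                                         method = c("pearson", "spearman"),
                                         leaveOneOut = TRUE) {
  method <- match.arg(method)
  samples <- intersect(names(expressionValues), names(entropies))
  if (length(samples) < 3L) {
    .stopf("need at least 3 samples with both expression and entropy")
  }
  x <- expressionValues[samples]
  h <- entropies[samples]
  if (sd(x) == 0 || sd(h) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(list(r = NA_real_, n = length(samples)))
  }
  r <- cor(x, h, method = method)
  out <- list(r = r, n = length(samples))
  if (leaveOneOut && length(samples) > 3L) {
    rs <- vapply(seq_along(samples), function(i) {
      if (sd(x[-i]) == 0 || sd(h[-i]) == 0) NA_real_
      else cor(x[-i], h[-i], method = method)
    }, numeric(1L))
    out$loo <- data.frame(dropped = samples, r = rs,
                          stringsAsFactors = FALSE)
    out$looMaxDelta <- max(abs(rs - r), na.rm = TRUE)
  }
  out
}

#' Signed pathway-input transform
#'
#' Maps a per-gene differential-expression p-value and direction onto
#' v = s (1 - p), the bounded score in [-1, 1] used as input for
#' information-theoretic pathway enrichment: |v| approaches 1 as the
#' change becomes certain, and the sign carries the direction.
#'
#' @param p p-value(s) in [0, 1].
#' @param s direction sign(s), +1 or -1.
#' @return v = s * (1 - p).
#' @examples
#' ipageTransform(0.05, -1)  # -0.95
#' @export
ipageTransform <- function(p, s) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    .stopf("p must lie in [0, 1]")
  }
  if (!all(s %in% c(-1, 1))) .stopf("s must be +1 or -1")
  s * (1 - p)
}

#' Per-gene direction vector for pathway analysis
#'
#' For every gene, a two-sample t-test (Welch by default) compares carrier
#' samples against the rest of the cohort; the signed score
#' v = sign(mean difference) * (1 - p) summarizes direction and strength.
#' Genes with zero variance in both groups get v = 0.
#'
#' @param expression gene x sample matrix.
#' @param mutantSamples carrier sample ids (>= 2; the remainder must also
#'   be >= 2).
#' @param varEqual use the pooled-variance (classic) t-test instead of
#'   Welch (default FALSE).
#' @return data.frame with columns gene, p, s, v.
#' @export
geneDirectionVector <- function(expression, mutantSamples,
                                varEqual = FALSE) {
  mutantSamples <- intersect(mutantSamples, colnames(expression))
  others <- setdiff(colnames(expression), mutantSamples)
  if (length(mutantSamples) < 2L || length(others) < 2L) {
    .stopf("both groups need at least 2 samples")
  }
  res <- lapply(rownames(expression), function(g) {
    x <- expression[g, mutantSamples]
    y <- expression[g, others]
    if (sd(x) == 0 && sd(y) == 0) {
      return(data.frame(gene = g, p = 1, s = 1, v = 0,
                        stringsAsFactors = FALSE))
    }
    tt <- tryCatch(t.test(x, y, var.equal = varEqual),
                   error = function(e) NULL)
    if (is.null(tt)) {
      return(data.frame(gene = g, p = 1, s = 1, v = 0,
                        stringsAsFactors = FALSE))
    }
    s <- if (mean(x) >= mean(y)) 1 else -1
    data.frame(gene = g, p = tt$p.value, s = s,
               v = ipageTransform(tt$p.value, s), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Rank concordance between mutant-allele expression and a target gene
#'
#' Ranks carrier samples by the expression of the mutant allele and asks
#' whether a downstream target moves in the expected direction: the
#' Spearman rank correlation between mutant-allele expression and target
#' expression is computed, and concordance holds when its sign matches
#' \code{expectedSign}.
#'
#' @param mutantAllelicExpression named numeric vector over carrier
#'   samples.
#' @param targetExpression named numeric vector over the same samples.
#' @param expectedSign +1 or -1.
#' @return List with \code{rho} and \code{concordant}; \code{rho} is NA
#'   (undefined) when either vector is constant.
#' @export
rankConcordance <- function(mutantAllelicExpression, targetExpression,
                            expectedSign) {
  if (!expectedSign %in% c(-1, 1)) .stopf("expectedSign must be +1 or -1")
  samples <- intersect(names(mutantAllelicExpression),
                       names(targetExpression))
  if (length(samples) < 3L) .stopf("need at least 3 carrier samples")
  x <- mutantAllelicExpression[samples]
  y <- targetExpression[samples]
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, concordant = NA))
  }
  rho <- cor(x, y, method = "spearman")
  list(rho = rho, concordant = sign(rho) == expectedSign)
}

#' Wild-type control permutation
#'
#' Draws \code{subsetSize} wild-type samples without replacement
#' \code{nIter} times and evaluates a user-supplied statistic on each draw,
#' building the null distribution of the statistic among samples that do
#' not carry the mutation. The empirical p-value of an observed value is
#' the fraction of null draws at least as extreme (two-sided on the
#' absolute value).
#'
#' @param wildtypeSamples pool of wild-type sample ids.
#' @param statistic function taking a character vector of sample ids and
#'   returning one number (typically a closure over the cohort's data,
#'   e.g. an expression-entropy correlation).
#' @param subsetSize samples per draw.
#' @param nIter number of draws (default 1000).
#' @param seed RNG seed.
#' @param observed observed value of the statistic (optional; p is NA
#'   without it).
#' @return List with \code{null} (numeric vector of length nIter) and
#'   \code{p}.
#' @export
wildtypeControlPermutation <- function(wildtypeSamples, statistic,
                                       subsetSize, nIter = 1000L,
                                       seed = NULL, observed = NULL) {
  if (subsetSize > length(wildtypeSamples)) {
    .stopf("subsetSize (%d) exceeds the wild-type pool (%d)",
           subsetSize, length(wildtypeSamples))
  }
  if (nIter < 1L) .stopf("nIter must be >= 1")
  if (!is.null(seed)) set.seed(.assertSeed(seed))
  null <- vapply(seq_len(nIter), function(i) {
    statistic(sample(wildtypeSamples, subsetSize))
  }, numeric(1L))
  p <- if (is.null(observed)) NA_real_ else
    mean(abs(null) >= abs(observed), na.rm = TRUE)
  list(null = null, p = p)
}

#' Mutant-allele expression of a mutation's carriers
#'
#' Combines the RNA alt-allele fraction with overall gene expression:
#' the mutant gene copy's expression in a carrier is
#' (rna_alt / (rna_ref + rna_alt)) * expression.
#'
#' @param cohort a \linkS4class{DuonCohort}.
#' @param chrom,pos,ref,alt,gene the mutation.
#' @return Named numeric vector over carrier samples with RNA coverage.
#' @export
mutantAllelicExpression <- function(cohort, chrom, pos, ref, alt, gene) {
  ac <- allelicCounts(cohort)
  sub <- ac[ac$chrom == chrom & ac$pos == pos & ac$ref == ref &
              ac$alt == alt, , drop = FALSE]
  sub <- sub[sub$rna_ref + sub$rna_alt >= 1L, , drop = FALSE]
  if (!nrow(sub)) {
    return(setNames(numeric(0L), character(0L)))
  }
  expr <- expressionMatrix(cohort)
  frac <- sub$rna_alt / (sub$rna_ref + sub$rna_alt)
  setNames(frac * expr[gene, sub$sample], sub$sample)
}
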