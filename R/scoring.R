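## REDACT score assembly, combined p-values, FDR, cohort-level scoring.

#' Assemble the six-letter REDACT string
#'
#' Encodes per-layer evidence into the composite score: uppercase letter =
#' consistent evidence, lowercase = data present but inconsistent, '*' =
#' data layer absent. The potential-duon-mutation flag requires uppercase R
#' and E plus at least one uppercase regulatory letter (D, C or T).
#'
#' @param perLayer named list of \linkS4class{EvidenceResult}s covering all
#'   six layers R, E, D, A, C, T.
#' @return A \linkS4class{RedactScore} (combined p-values unfilled).
#' @examples
#' res <- list(
#'   R = EvidenceResult("R", "consistent"),
#'   E = EvidenceResult("E", "consistent", 0.01, "up"),
#'   D = EvidenceResult("D", "inconsistent", 0.4),
#'   A = EvidenceResult("A", "absent"),
#'   C = EvidenceResult("C", "consistent", 0.02),
#'   T = EvidenceResult("T", "inconsistent", 0.9))
#' assembleRedact(res)@scoreString  # "REd*Ct"
#' @export
assembleRedact <- function(perLayer) {
  missingLayers <- setdiff(.LAYERS, names(perLayer))
  if (length(missingLayers)) {
    .stopf("perLayer is missing layer(s): %s",
           paste(missingLayers, collapse = ", "))
  }
  chars <- vapply(.LAYERS, function(l) {
    r <- perLayer[[l]]
    switch(r@status,
           consistent = l,
           inconsistent = tolower(l),
           absent = "*")
  }, character(1L))
  s <- paste(chars, collapse = "")
  isPdm <- chars[1L] == "R" && chars[2L] == "E" &&
    any(chars[c(3L, 5L, 6L)] %in% c("D", "C", "T"))
  new("RedactScore", scoreString = s, perLayer = perLayer[.LAYERS],
      isPdm = isPdm)
}

#' Parse a REDACT string back into per-layer statuses
#'
#' Inverse of the \code{\link{assembleRedact}} encoding.
#'
#' @param scoreString a 6-character REDACT string.
#' @return Named character vector (R,E,D,A,C,T) of statuses.
#' @export
parseRedactString <- function(scoreString) {
  if (nchar(scoreString) != 6L) .stopf("REDACT strings have 6 characters")
  chars <- strsplit(scoreString, "")[[1]]
  out <- character(6L)
  for (i in seq_len(6L)) {
    out[i] <- if (chars[i] == "*") "absent"
      else if (chars[i] == .LAYERS[i]) "consistent"
      else if (chars[i] == tolower(.LAYERS[i])) "inconsistent"
      else .stopf("character %d ('%s') does not encode layer %s", i,
                  chars[i], .LAYERS[i])
  }
  setNames(out, .LAYERS)
}

#' Fisher's method for combining independent p-values
#'
#' X = -2 * sum(log p) is referred to the upper tail of a chi-squared
#' distribution with 2k degrees of freedom.
#'
#' @param pValues numeric vector of p-values in (0, 1].
#' @return Combined p-value; NA for an empty input.
#' @examples
#' fisherCombine(c(0.01, 0.02, 0.03))
#' fisherCombine(0.2)  # k = 1 returns the input exactly
#' @export
fisherCombine <- function(pValues) {
  if (!length(pValues)) {
    return(NA_real_)
  }
  if (any(is.na(pValues)) || any(pValues <= 0) || any(pValues > 1)) {
    .stopf("fisherCombine needs p-values in (0, 1]")
  }
  x <- -2 * sum(log(pValues))
  pchisq(x, df = 2 * length(pValues), lower.tail = FALSE)
}

#' Hartung's method for combining (possibly correlated) p-values
#'
#' Probit-based combination: with t_i the standard-normal quantiles of the
#' p-values, the inter-test correlation is estimated as
#' rho = 1 - var(t), truncated below at -1/(k-1) and regularized upward by
#' Hartung's kappa term, rho~ = rho* + kappa sqrt(2/(k+1)) (1 - rho*). The
#' statistic T = sum(w t) / sqrt((1 - rho~) sum(w^2) + rho~ (sum w)^2) is
#' referred to the lower tail of the standard normal, so that small
#' p-values yield a small combined p-value. When all inputs are equal the
#' method returns that common value for any kappa. The regularization
#' (default kappa = 0.2, Hartung's recommendation) keeps the variance term
#' positive when the correlation estimate hits the truncation boundary,
#' where the unregularized formula (kappa = 0) degenerates to a zero
#' variance; with kappa = 0 a degenerate boundary case returns 0.5 for
#' balanced evidence and the limiting 0/1 otherwise.
#'
#' @param pValues numeric vector (k >= 2) of p-values strictly inside
#'   (0, 1).
#' @param weights optional positive weights (default all 1).
#' @param kappa non-negative regularization constant (default 0.2; 0 gives
#'   the bare truncated-correlation formula).
#' @return Combined p-value.
#' @export
hartungCombine <- function(pValues, weights = NULL, kappa = 0.2) {
  k <- length(pValues)
  if (k < 2L) .stopf("hartungCombine needs at least 2 p-values")
  if (any(is.na(pValues)) || any(pValues <= 0) || any(pValues >= 1)) {
    .stopf("hartungCombine needs p-values strictly inside (0, 1)")
  }
  if (is.null(weights)) weights <- rep(1, k)
  if (length(weights) != k || any(weights <= 0)) {
    .stopf("weights must be positive and match the p-values in length")
  }
  if (kappa < 0) .stopf("kappa must be non-negative")
  t <- qnorm(pValues)
  rhoHat <- 1 - sum((t - mean(t))^2) / (k - 1)
  rhoStar <- max(-1 / (k - 1), rhoHat)
  rhoTilde <- rhoStar + kappa * sqrt(2 / (k + 1)) * (1 - rhoStar)
  denomSq <- (1 - rhoTilde) * sum(weights^2) + rhoTilde * sum(weights)^2
  num <- sum(weights * t)
  if (denomSq <= 1e-12 * sum(weights^2)) {
    ## variance degenerates exactly at the truncation boundary (possible
    ## with strongly anti-correlated probits, e.g. equal weights and
    ## k = 1 + 1/var(t)); perfectly balanced evidence combines to 0.5
    if (abs(num) < 1e-8 * sum(weights)) {
      return(0.5)
    }
    return(if (num < 0) 0 else 1)
  }
  pnorm(num / sqrt(denomSq))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; a thin wrapper over
#' \code{stats::p.adjust(method = "BH")} kept as the package's single FDR
#' entry point.
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @return q-values in input order; q >= p elementwise.
#' @export
bhFdr <- function(pValues) {
  p.adjust(pValues, method = "BH")
}

## Clamp permutation p-values away from {0,1} so that the log/probit
## transforms of the combination methods are defined. The half-width
## 1/(2 nPerm) sits below the estimator's resolution 1/nPerm.
.clampPermP <- function(p, nPerm) {
  min(max(p, 1 / (2 * nPerm)), 1 - 1 / (2 * nPerm))
}

## Evidence layers for one mutation row against the cohort.
.evaluateLayers <- function(cohort, row, carriers, config, dnaseTrack,
                            chipTrack) {
  gene <- row$gene
  gm <- geneModels(cohort)[[gene]]
  res <- list()
  res$R <- assessRecurrence(length(carriers), cohortSize(cohort),
                            config@recurrenceMin, config@recurrenceFrac)
  res$E <- tryCatch(
    testExpressionChange(gene, carriers, expressionMatrix(cohort),
                         alpha = config@alphaE),
    error = function(e) EvidenceResult("E", "absent"))
  ac <- allelicCounts(cohort)
  sub <- ac[ac$chrom == row$chrom & ac$pos == row$pos & ac$ref == row$ref &
              ac$alt == row$alt & ac$sample %in% carriers, , drop = FALSE]
  res$A <- tryCatch(
    testAllelicImbalance(sub, purity(cohort), alpha = config@alphaE,
                         purityAdjust = config@purityAdjust),
    error = function(e) EvidenceResult("A", "absent"))
  fp <- mutationFootprint(row$pos, row$ref, row$alt)
  fpWidth <- fp["end"] - fp["start"] + 1L
  for (layer in c("D", "C")) {
    track <- if (layer == "D") dnaseTrack else chipTrack
    if (is.null(track)) {
      res[[layer]] <- EvidenceResult(layer, "absent")
      next
    }
    res[[layer]] <- tryCatch({
      hit <- overlapTrack(row$chrom, row$pos, row$ref, row$alt, track)
      p <- permutationOverlapP(gm, track, nPerm = config@nPerm,
                               footprintWidth = fpWidth,
                               estimator = config@permEstimator)
      EvidenceResult(layer, if (hit) "consistent" else "inconsistent",
                     pValue = p)
    }, error = function(e) EvidenceResult(layer, "absent"))
  }
  seqs <- geneSequences(cohort)
  if (!length(pwms(cohort)) || !gene %in% names(seqs)) {
    res$T <- EvidenceResult("T", "absent")
  } else {
    res$T <- tryCatch({
      mp <- scanMotifPerturbation(row$pos, row$ref, row$alt, gm,
                                  seqs[[gene]], pwms(cohort),
                                  scoreFraction = config@motifScoreFraction)
      p <- permutationMotifP(row$pos, row$ref, row$alt, gm, seqs[[gene]],
                             pwms(cohort),
                             scoreFraction = config@motifScoreFraction,
                             nPerm = config@nPermMotif,
                             estimator = config@permEstimator)
      detail <- if (mp@effect == "gain") {
        paste0("gain:", paste(mp@gainTfs, collapse = ","))
      } else if (mp@effect == "loss") {
        paste0("loss:", paste(mp@lossTfs, collapse = ","))
      } else ""
      EvidenceResult("T",
                     if (mp@effect != "none") "consistent" else
                       "inconsistent",
                     pValue = p, detail = detail)
    }, error = function(e) EvidenceResult("T", "absent"))
  }
  res
}

#' Score every mutation in a cohort
#'
#' Runs the full REDACT pipeline: known-variant exclusion, consequence
#' restriction to protein-altering classes, recurrence filter, per-layer
#' evidence evaluation, direction-consistency downgrade of A when it
#' contradicts E, copy-number-confound annotation, Fisher (and, when at
#' least two layer p-values exist, Hartung) combination over the configured
#' layers, and Benjamini-Hochberg FDR across all scored mutations. A layer
#' failure for one mutation marks that layer absent rather than aborting.
#' Results are ordered by (q, combined p, descending carrier count, gene).
#'
#' @param cohort a \linkS4class{DuonCohort}.
#' @param config a \linkS4class{RedactConfig}.
#' @return List with elements \code{scores} (list of
#'   \linkS4class{RedactScore}), \code{report} (the result data.frame, see
#'   \code{\link{redactReport}}) and \code{stageCounts} (named integer
#'   vector: input, post_known_filter, protein_altering, recurrent, pdm).
#' @export
scoreCohort <- function(cohort, config) {
  set.seed(config@seed)
  muts <- mutations(cohort)
  counts <- c(input = nrow(muts))
  flt <- filterKnownVariants(muts, knownVariants(cohort))
  muts <- flt$kept
  counts["post_known_filter"] <- nrow(muts)
  muts <- muts[muts$consequence %in% config@keepConsequences, , drop = FALSE]
  counts["protein_altering"] <- nrow(muts)
  if (nrow(muts)) {
    rec <- vapply(seq_len(nrow(muts)), function(i) {
      assessRecurrence(length(muts$samples[[i]]), cohortSize(cohort),
                       config@recurrenceMin,
                       config@recurrenceFrac)@status == "consistent"
    }, logical(1L))
    muts <- muts[rec, , drop = FALSE]
  }
  counts["recurrent"] <- nrow(muts)
  if (nrow(muts) == 0L) {
    counts["pdm"] <- 0L
    return(list(scores = list(), report = .emptyReport(),
                stageCounts = counts))
  }
  dnaseTrack <- tracksOfKind(cohort, "dnase")
  chipTrack <- tracksOfKind(cohort, "chip")
  cna <- cnaFlags(cohort)
  scores <- vector("list", nrow(muts))
  for (i in seq_len(nrow(muts))) {
    row <- muts[i, , drop = FALSE]
    carriers <- muts$samples[[i]]
    layers <- .evaluateLayers(cohort, row, carriers, config, dnaseTrack,
                              chipTrack)
    if (!directionConsistency(layers$E, layers$A) &&
        layers$A@status == "consistent") {
      layers$A <- EvidenceResult("A", "inconsistent",
                                 pValue = layers$A@pValue,
                                 direction = layers$A@direction,
                                 detail = "direction contradicts E")
    }
    sc <- assembleRedact(layers)
    sc@gene <- row$gene
    sc@chrom <- row$chrom
    sc@pos <- as.integer(row$pos)
    sc@ref <- row$ref
    sc@alt <- row$alt
    sc@consequence <- row$consequence
    sc@nSamples <- length(carriers)
    sc@cnaFlagged <- nrow(cna) > 0L &&
      any(cna$gene == row$gene & cna$sample %in% carriers)
    ps <- vapply(config@combineLayers, function(l) {
      r <- layers[[l]]
      if (r@status == "absent" || is.na(r@pValue)) NA_real_ else r@pValue
    }, numeric(1L))
    ps <- ps[!is.na(ps)]
    nPermFor <- function(l) if (l == "T") config@nPermMotif else config@nPerm
    if (length(ps)) {
      ## permutation p-values can be exactly 0 or 1; clamp them (only) so
      ## the log/probit transforms are defined
      clamped <- vapply(names(ps), function(l) {
        if (l %in% c("D", "C", "T")) .clampPermP(ps[[l]], nPermFor(l))
        else ps[[l]]
      }, numeric(1L))
      sc@pFisher <- fisherCombine(clamped)
      if (length(clamped) >= 2L) {
        sc@pHartung <- hartungCombine(pmin(pmax(clamped, 1e-12), 1 - 1e-12))
      }
    }
    scores[[i]] <- sc
  }
  pf <- vapply(scores, function(s) s@pFisher, numeric(1L))
  q <- rep(NA_real_, length(pf))
  q[!is.na(pf)] <- bhFdr(pf[!is.na(pf)])
  for (i in seq_along(scores)) scores[[i]]@qValue <- q[i]
  ord <- order(q, pf, -vapply(scores, function(s) s@nSamples, integer(1L)),
               vapply(scores, function(s) s@gene, character(1L)))
  scores <- scores[ord]
  counts["pdm"] <- sum(vapply(scores, function(s) s@isPdm, logical(1L)))
  list(scores = scores, report = redactReport(scores), stageCounts = counts)
}

.emptyReport <- function() {
  data.frame(gene = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), consequence = character(),
             n_samples = integer(), redact = character(), p_E = numeric(),
             p_A = numeric(), p_D = numeric(), p_C = numeric(),
             p_T = numeric(), p_fisher = numeric(), p_hartung = numeric(),
             q_value = numeric(), is_pdm = logical(), cna_flagged = logical(),
             motif_detail = character(), stringsAsFactors = FALSE)
}

#' Tabulate RedactScore objects
#'
#' @param scores list of \linkS4class{RedactScore}.
#' @return data.frame with one row per scored mutation: identity fields,
#'   carrier count, REDACT string, per-layer p-values, combined p-values,
#'   q-value, pDM and CNA flags, and motif detail.
#' @export
redactReport <- function(scores) {
  if (!length(scores)) {
    return(.emptyReport())
  }
  layerP <- function(s, l) {
    r <- s@perLayer[[l]]
    if (r@status == "absent") NA_real_ else r@pValue
  }
  data.frame(
    gene = vapply(scores, function(s) s@gene, character(1L)),
    chrom = vapply(scores, function(s) s@chrom, character(1L)),
    pos = vapply(scores, function(s) s@pos, integer(1L)),
    ref = vapply(scores, function(s) s@ref, character(1L)),
    alt = vapply(scores, function(s) s@alt, character(1L)),
    consequence = vapply(scores, function(s) s@consequence, character(1L)),
    n_samples = vapply(scores, function(s) s@nSamples, integer(1L)),
    redact = vapply(scores, function(s) s@scoreString, character(1L)),
    p_E = vapply(scores, layerP, numeric(1L), l = "E"),
    p_A = vapply(scores, layerP, numeric(1L), l = "A"),
    p_D = vapply(scores, layerP, numeric(1L), l = "D"),
    p_C = vapply(scores, layerP, numeric(1L), l = "C"),
    p_T = vapply(scores, layerP, numeric(1L), l = "T"),
    p_fisher = vapply(scores, function(s) s@pFisher, numeric(1L)),
    p_hartung = vapply(scores, function(s) s@pHartung, numeric(1L)),
    q_value = vapply(scores, function(s) s@qValue, numeric(1L)),
    is_pdm = vapply(scores, function(s) s@isPdm, logical(1L)),
    cna_flagged = vapply(scores, function(s) s@cnaFlagged, logical(1L)),
    motif_detail = vapply(scores, function(s) s@perLayer$T@detail,
                          character(1L)),
    stringsAsFactors = FALSE)
}

#' Write a REDACT report TSV
#'
#' @param report data.frame from \code{\link{redactReport}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRedactReport <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
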