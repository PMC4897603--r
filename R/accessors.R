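## Generics, accessors and show methods.

#' Accessors for DuonCohort slots
#'
#' Accessor functions are the supported way to reach the components of a
#' \linkS4class{DuonCohort}; slot access is an implementation detail.
#'
#' @param x a \linkS4class{DuonCohort}.
#' @return The corresponding component (see \linkS4class{DuonCohort}).
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))
#' @rdname cohort-accessors
#' @export
setMethod("mutations", "DuonCohort", function(x) x@mutations)

#' @rdname cohort-accessors
#' @export
setGeneric("expressionMatrix", function(x) standardGeneric("expressionMatrix"))
#' @rdname cohort-accessors
#' @export
setMethod("expressionMatrix", "DuonCohort", function(x) x@expression)

#' @rdname cohort-accessors
#' @export
setGeneric("isoformExpression",
           function(x) standardGeneric("isoformExpression"))
#' @rdname cohort-accessors
#' @export
setMethod("isoformExpression", "DuonCohort", function(x) x@isoformExpression)

#' @rdname cohort-accessors
#' @export
setGeneric("isoformToGene", function(x) standardGeneric("isoformToGene"))
#' @rdname cohort-accessors
#' @export
setMethod("isoformToGene", "DuonCohort", function(x) x@isoformToGene)

#' @rdname cohort-accessors
#' @export
setGeneric("allelicCounts", function(x) standardGeneric("allelicCounts"))
#' @rdname cohort-accessors
#' @export
setMethod("allelicCounts", "DuonCohort", function(x) x@allelicCounts)

#' @rdname cohort-accessors
#' @export
setGeneric("purity", function(x) standardGeneric("purity"))
#' @rdname cohort-accessors
#' @export
setMethod("purity", "DuonCohort", function(x) x@purity)

#' @rdname cohort-accessors
#' @export
setGeneric("cnaFlags", function(x) standardGeneric("cnaFlags"))
#' @rdname cohort-accessors
#' @export
setMethod("cnaFlags", "DuonCohort", function(x) x@cnaFlags)

#' @rdname cohort-accessors
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))
#' @rdname cohort-accessors
#' @export
setMethod("tracks", "DuonCohort", function(x) x@tracks)

#' @rdname cohort-accessors
#' @export
setGeneric("pwms", function(x) standardGeneric("pwms"))
#' @rdname cohort-accessors
#' @export
setMethod("pwms", "DuonCohort", function(x) x@pwms)

#' @rdname cohort-accessors
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))
#' @rdname cohort-accessors
#' @export
setMethod("geneModels", "DuonCohort", function(x) x@geneModels)

#' @rdname cohort-accessors
#' @export
setGeneric("geneSequences", function(x) standardGeneric("geneSequences"))
#' @rdname cohort-accessors
#' @export
setMethod("geneSequences", "DuonCohort", function(x) x@sequences)

#' @rdname cohort-accessors
#' @export
setGeneric("knownVariants", function(x) standardGeneric("knownVariants"))
#' @rdname cohort-accessors
#' @export
setMethod("knownVariants", "DuonCohort", function(x) x@knownVariants)

#' Number of samples in a cohort
#'
#' @param x a \linkS4class{DuonCohort}.
#' @return Integer cohort size (number of expression columns).
#' @export
setGeneric("cohortSize", function(x) standardGeneric("cohortSize"))
#' @rdname cohortSize
#' @export
setMethod("cohortSize", "DuonCohort", function(x) ncol(x@expression))

#' Tracks of one kind, merged into a single GRanges
#'
#' @param x a \linkS4class{DuonCohort}.
#' @param kind "dnase" or "chip".
#' @return A \code{GRanges} concatenating all tracks of the requested kind,
#'   or NULL when the cohort carries no track of that kind (data layer
#'   absent).
#' @export
tracksOfKind <- function(x, kind) {
  sel <- Filter(function(tr) identical(metadata(tr)$kind, kind), tracks(x))
  if (!length(sel)) {
    return(NULL)
  }
  do.call(c, unname(sel))
}

setMethod("show", "DuonCohort", function(object) {
  cat("DuonCohort with", nrow(object@mutations), "mutations across",
      ncol(object@expression), "samples\n")
  cat("  genes:", nrow(object@expression),
      "| isoforms:", nrow(object@isoformExpression), "\n")
  kinds <- vapply(object@tracks, function(tr) {
    k <- metadata(tr)$kind
    if (is.null(k)) "?" else k
  }, character(1L))
  cat("  tracks:", if (length(kinds)) paste(kinds, collapse = ", ") else
      "none", "| PWMs:", length(object@pwms), "\n")
  cat("  allelic-count rows:", nrow(object@allelicCounts),
      "| known variants:", length(object@knownVariants), "\n")
})

setMethod("show", "EvidenceResult", function(object) {
  cat(sprintf("EvidenceResult [%s] %s", object@layer, object@status))
  if (!is.na(object@pValue)) cat(sprintf(", p = %.4g", object@pValue))
  if (object@direction != "none") cat(", direction", object@direction)
  if (nzchar(object@detail)) cat(" (", object@detail, ")", sep = "")
  cat("\n")
})

setMethod("show", "RedactScore", function(object) {
  cat("RedactScore", object@scoreString)
  if (!is.na(object@gene))
    cat(sprintf("  %s %s:%d %s>%s", object@gene, object@chrom, object@pos,
                object@ref, object@alt))
  cat("\n")
  if (!is.na(object@pFisher))
    cat(sprintf("  p(Fisher) = %.3g, p(Hartung) = %.3g, q = %.3g\n",
                object@pFisher, object@pHartung, object@qValue))
  cat("  potential duon mutation:", object@isPdm, "\n")
})

setMethod("show", "MotifPerturbation", function(object) {
  cat("MotifPerturbation:", object@effect, "\n")
  if (length(object@gainTfs))
    cat("  gained:", paste(object@gainTfs, collapse = ", "), "\n")
  if (length(object@lossTfs))
    cat("  lost:", paste(object@lossTfs, collapse = ", "), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSamples, "samples,", object@nGenes,
      "genes,", length(object@plantedDuons), "planted duons, seed",
      object@seed, "\n")
})

setMethod("show", "RedactConfig", function(object) {
  cat("RedactConfig: alphaE", object@alphaE, "| recurrence >=",
      object@recurrenceMin, "and >", object@recurrenceFrac * 100,
      "% | nPerm", object@nPerm, "| seed", object@seed, "\n")
})
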