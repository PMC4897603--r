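## S4 classes for the REDACT pipeline.

#' EvidenceResult: outcome of one REDACT evidence layer
#'
#' One layer's verdict for one mutation: the layer letter, whether the
#' evidence is consistent with a regulatory duon effect, the layer's p-value
#' (when the layer performs a test), and the direction of change where
#' meaningful (E and A layers).
#'
#' @slot layer one of "R","E","D","A","C","T".
#' @slot status "consistent", "inconsistent" or "absent" (data layer not
#'   available for this mutation).
#' @slot pValue numeric p-value in [0,1], or NA. Always NA when status is
#'   "absent".
#' @slot direction "up", "down" or "none".
#' @slot detail free-text annotation (e.g. TF names for the T layer).
#' @exportClass EvidenceResult
setClass("EvidenceResult",
  representation(layer = "character", status = "character",
                 pValue = "numeric", direction = "character",
                 detail = "character"),
  prototype(pValue = NA_real_, direction = "none", detail = ""))

setValidity("EvidenceResult", function(object) {
  msg <- character()
  if (length(object@layer) != 1L || !object@layer %in% .LAYERS)
    msg <- c(msg, "layer must be one of R,E,D,A,C,T")
  if (length(object@status) != 1L ||
      !object@status %in% c("consistent", "inconsistent", "absent"))
    msg <- c(msg, "status must be consistent/inconsistent/absent")
  if (identical(object@status, "absent") && !is.na(object@pValue))
    msg <- c(msg, "absent layers must not carry a p-value")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0,1]")
  if (!object@direction %in% c("up", "down", "none"))
    msg <- c(msg, "direction must be up/down/none")
  if (length(msg)) msg else TRUE
})

#' Construct an EvidenceResult
#'
#' @param layer layer letter ("R","E","D","A","C","T").
#' @param status "consistent", "inconsistent" or "absent".
#' @param pValue layer p-value or NA.
#' @param direction "up", "down" or "none".
#' @param detail free-text annotation.
#' @return An \linkS4class{EvidenceResult}.
#' @examples
#' EvidenceResult("E", "consistent", 0.01, "up")
#' @export
EvidenceResult <- function(layer, status, pValue = NA_real_,
                           direction = "none", detail = "") {
  new("EvidenceResult", layer = layer, status = status,
      pValue = as.numeric(pValue), direction = direction, detail = detail)
}

#' MotifPerturbation: TF binding-site gain/loss caused by a mutation
#'
#' @slot effect "gain", "loss" or "none".
#' @slot gainTfs TF names whose motif passes threshold only in the mutant
#'   allele.
#' @slot lossTfs TF names whose motif passes threshold only in the wild-type
#'   allele.
#' @slot wtBestScore best log-odds score in the wild-type window.
#' @slot mutBestScore best log-odds score in the mutant window.
#' @exportClass MotifPerturbation
setClass("MotifPerturbation",
  representation(effect = "character", gainTfs = "character",
                 lossTfs = "character", wtBestScore = "numeric",
                 mutBestScore = "numeric"),
  prototype(effect = "none", gainTfs = character(), lossTfs = character(),
            wtBestScore = -Inf, mutBestScore = -Inf))

#' RedactScore: the assembled six-letter score for one mutation
#'
#' Character i of \code{scoreString} (layer order R,E,D,A,C,T) is uppercase
#' when the layer is consistent, lowercase when data are present but
#' inconsistent, and '*' when the data layer is absent. \code{isPdm} is TRUE
#' when R and E are uppercase and at least one of D, C, T is uppercase.
#'
#' @slot gene,chrom,ref,alt,consequence mutation identity fields.
#' @slot pos 1-based genomic position.
#' @slot nSamples number of carrier samples.
#' @slot scoreString the 6-character REDACT string.
#' @slot perLayer named list of \linkS4class{EvidenceResult} (names
#'   R,E,D,A,C,T).
#' @slot pFisher,pHartung,qValue combined p-values and BH q-value (NA until
#'   filled by \code{\link{scoreCohort}}).
#' @slot isPdm potential-duon-mutation flag.
#' @slot cnaFlagged TRUE when a carrier sample has a detectable copy-number
#'   alteration at the locus (annotation, not an exclusion).
#' @exportClass RedactScore
setClass("RedactScore",
  representation(gene = "character", chrom = "character", pos = "integer",
                 ref = "character", alt = "character",
                 consequence = "character", nSamples = "integer",
                 scoreString = "character", perLayer = "list",
                 pFisher = "numeric", pHartung = "numeric",
                 qValue = "numeric", isPdm = "logical",
                 cnaFlagged = "logical"),
  prototype(gene = NA_character_, chrom = NA_character_, pos = NA_integer_,
            ref = NA_character_, alt = NA_character_,
            consequence = NA_character_, nSamples = NA_integer_,
            pFisher = NA_real_, pHartung = NA_real_, qValue = NA_real_,
            cnaFlagged = FALSE))

setValidity("RedactScore", function(object) {
  msg <- character()
  if (nchar(object@scoreString) != 6L)
    msg <- c(msg, "scoreString must have exactly 6 characters")
  if (!identical(sort(names(object@perLayer)), sort(.LAYERS)))
    msg <- c(msg, "perLayer must hold all six layers R,E,D,A,C,T")
  if (isTRUE(object@isPdm)) {
    ch <- strsplit(object@scoreString, "")[[1]]
    if (!(ch[1L] == "R" && ch[2L] == "E" && any(ch[c(3L, 5L, 6L)] %in%
                                                c("D", "C", "T"))))
      msg <- c(msg, "isPdm requires uppercase R, E and one of D/C/T")
  }
  if (length(msg)) msg else TRUE
})

#' DuonCohort: the joined multi-omic cohort bundle
#'
#' The central data container: somatic mutations with their carrier samples,
#' normalized gene- and isoform-level expression, per-mutation allelic read
#' counts from exome and RNA-seq, tumor purity, copy-number flags,
#' regulatory tracks (DNase hypersensitivity and ChIP peaks), transcription
#' factor PWMs, gene models and spliced coding sequences, and the catalog of
#' known (common) variants used for exclusion.
#'
#' @slot mutations data.frame with columns chrom, pos (1-based integer),
#'   ref, alt, gene, consequence, protein_change and a list-column
#'   \code{samples} of carrier sample ids (one row per distinct variant).
#' @slot expression gene x sample matrix of non-negative normalized
#'   expression values.
#' @slot isoformExpression isoform x sample matrix.
#' @slot isoformToGene named character vector mapping isoform ids to gene
#'   ids.
#' @slot allelicCounts data.frame with columns chrom, pos, ref, alt, sample,
#'   exome_ref, exome_alt, rna_ref, rna_alt.
#' @slot purity named numeric vector in (0,1], one entry per sample with
#'   purity data.
#' @slot cnaFlags data.frame with columns gene, sample listing loci with a
#'   detectable copy-number alteration.
#' @slot tracks named list of \code{GRanges}; each has
#'   \code{metadata()$kind} equal to "dnase" or "chip".
#' @slot pwms named list of 4 x L probability matrices (rownames A,C,G,T,
#'   columns sum to 1) with attributes \code{tf_name} and \code{motif_id}.
#' @slot geneModels named list; each element is
#'   \code{list(chrom, strand, exons)} with \code{exons} a 0-based half-open
#'   integer matrix (columns start, end), sorted and non-overlapping.
#' @slot sequences \code{DNAStringSet} of spliced (concatenated-exon) coding
#'   sequences on the + strand, named by gene.
#' @slot knownVariants character vector of "chrom:pos:ref:alt" keys.
#' @exportClass DuonCohort
setClass("DuonCohort",
  representation(mutations = "data.frame", expression = "matrix",
                 isoformExpression = "matrix", isoformToGene = "character",
                 allelicCounts = "data.frame", purity = "numeric",
                 cnaFlags = "data.frame", tracks = "list", pwms = "list",
                 geneModels = "list", sequences = "DNAStringSet",
                 knownVariants = "character"))

setValidity("DuonCohort", function(object) {
  msg <- character()
  mut <- object@mutations
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "samples")
  if (!all(need %in% names(mut)))
    msg <- c(msg, paste("mutations must contain columns:",
                        paste(need, collapse = ", ")))
  if (ncol(object@expression) < 2L)
    msg <- c(msg, "cohort needs at least 2 expression samples")
  if (nrow(mut) > 0L && all(need %in% names(mut))) {
    if (any(lengths(mut$samples) == 0L))
      msg <- c(msg, "every mutation needs at least one carrier sample")
    if (any(mut$ref == mut$alt))
      msg <- c(msg, "ref and alt alleles must differ")
    if (any(mut$pos < 1L))
      msg <- c(msg, "positions must be >= 1")
    if (!all(mut$consequence %in% .CONSEQUENCES))
      msg <- c(msg, "consequence outside {missense, inframe_del, inframe_ins, other}")
    missingModel <- setdiff(unique(mut$gene), names(object@geneModels))
    if (length(missingModel))
      msg <- c(msg, paste("mutated genes without a gene model:",
                          paste(head(missingModel, 3L), collapse = ", ")))
  }
  if (nrow(object@allelicCounts) > 0L) {
    extra <- setdiff(unique(object@allelicCounts$sample),
                     colnames(object@expression))
    if (length(extra))
      msg <- c(msg, "allelic-count samples missing from expression columns")
  }
  if (any(object@expression < 0, na.rm = TRUE))
    msg <- c(msg, "expression values must be non-negative")
  for (g in names(object@geneModels)) {
    gm <- object@geneModels[[g]]
    ex <- gm$exons
    if (is.unsorted(ex[, 1L]) || any(ex[, 1L] >= ex[, 2L]) ||
        (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))) {
      msg <- c(msg, paste0("gene model ", g,
                           ": exons must be sorted, non-empty, non-overlapping"))
      break
    }
    if (g %in% names(object@sequences) &&
        splicedLength(ex) != length(object@sequences[[g]])) {
      msg <- c(msg, paste0("gene ", g,
                           ": total exon length != sequence length"))
      break
    }
  }
  for (m in object@pwms) {
    if (!is.matrix(m) || nrow(m) != 4L ||
        any(abs(colSums(m) - 1) > 1e-6) || any(m < 0)) {
      msg <- c(msg, "each PWM must be a 4-row non-negative matrix with columns summing to 1")
      break
    }
  }
  if (length(object@purity) &&
      (any(object@purity <= 0) || any(object@purity > 1)))
    msg <- c(msg, "purity values must lie in (0,1]")
  if (length(msg)) msg else TRUE
})

#' Construct a DuonCohort
#'
#' @param mutations mutation data.frame (see \linkS4class{DuonCohort}).
#' @param expression gene x sample matrix.
#' @param isoformExpression isoform x sample matrix.
#' @param isoformToGene named character map isoform -> gene.
#' @param allelicCounts per (mutation, sample) read-count data.frame.
#' @param purity named numeric vector in (0,1].
#' @param cnaFlags data.frame(gene, sample) of flagged loci.
#' @param tracks named list of GRanges with \code{metadata()$kind}.
#' @param pwms named list of PWM probability matrices.
#' @param geneModels named list of gene models.
#' @param sequences DNAStringSet of spliced coding sequences.
#' @param knownVariants character vector of "chrom:pos:ref:alt" keys.
#' @return A validated \linkS4class{DuonCohort}.
#' @export
DuonCohort <- function(mutations, expression,
                       isoformExpression = matrix(0, 0, ncol(expression),
                         dimnames = list(NULL, colnames(expression))),
                       isoformToGene = character(),
                       allelicCounts = .emptyAllelicCounts(),
                       purity = numeric(), cnaFlags = .emptyCnaFlags(),
                       tracks = list(), pwms = list(), geneModels = list(),
                       sequences = Biostrings::DNAStringSet(),
                       knownVariants = character()) {
  new("DuonCohort", mutations = mutations, expression = expression,
      isoformExpression = isoformExpression, isoformToGene = isoformToGene,
      allelicCounts = allelicCounts, purity = purity, cnaFlags = cnaFlags,
      tracks = tracks, pwms = pwms, geneModels = geneModels,
      sequences = sequences, knownVariants = knownVariants)
}

.emptyAllelicCounts <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), sample = character(), exome_ref = integer(),
             exome_alt = integer(), rna_ref = integer(), rna_alt = integer(),
             stringsAsFactors = FALSE)
}

.emptyCnaFlags <- function() {
  data.frame(gene = character(), sample = character(),
             stringsAsFactors = FALSE)
}

.emptyMutations <- function() {
  df <- data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), gene = character(),
                   consequence = character(), protein_change = character(),
                   stringsAsFactors = FALSE)
  df$samples <- list()
  df
}

#' DuonSpec: one planted duon mutation for the synthetic cohort generator
#'
#' Encodes the effect classes observed for real potential duon mutations:
#' a cohort-level expression shift, an allelic skew of the mutant copy in
#' RNA, regulatory-track overlap, motif creation/destruction, coupling of
#' sample splicing entropy to the mutant gene's expression, and an optional
#' repressed/activated target gene.
#'
#' @slot gene gene id; "" lets the generator assign one.
#' @slot nMutantSamples number of carrier samples.
#' @slot expressionLog2fc planted log2 fold-change of the gene's expression
#'   in carrier samples (E effect; 0 = none).
#' @slot allelicSkew true RNA alt-allele fraction in carriers (A effect;
#'   0.5 is neutral relative to a pure het).
#' @slot inDnase,inChip whether the mutation site is covered by the DNase /
#'   ChIP track.
#' @slot motifEffect "gain", "loss" or "none" (T effect). "gain" requires a
#'   substitution; indels support "loss"/"none".
#' @slot consequence "missense", "inframe_del" or "inframe_ins".
#' @slot entropyCoupling slope linking sample splicing entropy (bits) to the
#'   gene's expression (linear expression units); 0 = uncoupled.
#' @slot entropyNoiseSd SD (bits) of the entropy noise around the coupling
#'   line.
#' @slot entropyTargetR optional target Pearson correlation between the
#'   gene's expression and sample entropy; when set (non-NA) the coupling
#'   slope is derived from the realized expression SD so the true r equals
#'   this value.
#' @slot targetGene optional downstream target gene id ("" = none; "auto"
#'   lets the generator assign one).
#' @slot targetSign expected sign (+1/-1) of the association between mutant
#'   allelic expression and target expression.
#' @exportClass DuonSpec
setClass("DuonSpec",
  representation(gene = "character", nMutantSamples = "integer",
                 expressionLog2fc = "numeric", allelicSkew = "numeric",
                 inDnase = "logical", inChip = "logical",
                 motifEffect = "character", consequence = "character",
                 entropyCoupling = "numeric", entropyNoiseSd = "numeric",
                 entropyTargetR = "numeric", targetGene = "character",
                 targetSign = "numeric"),
  prototype(gene = "", nMutantSamples = 5L, expressionLog2fc = 1.5,
            allelicSkew = 0.8, inDnase = TRUE, inChip = TRUE,
            motifEffect = "none", consequence = "missense",
            entropyCoupling = 0, entropyNoiseSd = 0.1,
            entropyTargetR = NA_real_, targetGene = "", targetSign = -1))

setValidity("DuonSpec", function(object) {
  msg <- character()
  if (object@nMutantSamples < 1L)
    msg <- c(msg, "nMutantSamples must be >= 1")
  if (object@allelicSkew <= 0 || object@allelicSkew >= 1)
    msg <- c(msg, "allelicSkew must lie in (0,1)")
  if (!object@motifEffect %in% c("gain", "loss", "none"))
    msg <- c(msg, "motifEffect must be gain/loss/none")
  if (!object@consequence %in% c("missense", "inframe_del", "inframe_ins"))
    msg <- c(msg, "consequence must be missense/inframe_del/inframe_ins")
  if (object@consequence != "missense" && object@motifEffect == "gain")
    msg <- c(msg, "motif gain is only supported for substitutions")
  if (!object@targetSign %in% c(-1, 1))
    msg <- c(msg, "targetSign must be -1 or +1")
  if (length(msg)) msg else TRUE
})

#' Construct a DuonSpec
#'
#' @param gene gene id ("" = auto-assign).
#' @param nMutantSamples carrier count.
#' @param expressionLog2fc planted expression log2 fold-change.
#' @param allelicSkew true RNA alt fraction in carriers.
#' @param inDnase,inChip regulatory-track overlap flags.
#' @param motifEffect "gain", "loss" or "none".
#' @param consequence "missense", "inframe_del" or "inframe_ins".
#' @param entropyCoupling entropy-vs-expression slope (bits per expression
#'   unit).
#' @param entropyNoiseSd entropy noise SD in bits.
#' @param entropyTargetR optional target Pearson r for the entropy coupling.
#' @param targetGene optional target gene ("auto" to let the generator pick).
#' @param targetSign expected association sign for the target gene.
#' @return A validated \linkS4class{DuonSpec}.
#' @export
DuonSpec <- function(gene = "", nMutantSamples = 5L, expressionLog2fc = 1.5,
                     allelicSkew = 0.8, inDnase = TRUE, inChip = TRUE,
                     motifEffect = "none", consequence = "missense",
                     entropyCoupling = 0, entropyNoiseSd = 0.1,
                     entropyTargetR = NA_real_, targetGene = "",
                     targetSign = -1) {
  new("DuonSpec", gene = gene, nMutantSamples = as.integer(nMutantSamples),
      expressionLog2fc = expressionLog2fc, allelicSkew = allelicSkew,
      inDnase = inDnase, inChip = inChip, motifEffect = motifEffect,
      consequence = consequence, entropyCoupling = entropyCoupling,
      entropyNoiseSd = entropyNoiseSd, entropyTargetR = entropyTargetR,
      targetGene = targetGene, targetSign = targetSign)
}

#' SimulationConfig: study conditions for the synthetic cohort generator
#'
#' Defaults emulate a mid-sized tumor cohort with normalized (level-3 style)
#' expression, moderate sequencing depth, and typical tumor purity.
#'
#' @slot nSamples cohort size (number of tumor samples).
#' @slot nGenes number of genes.
#' @slot isoformRange inclusive range of isoforms per gene.
#' @slot nBackgroundRecurrent number of background recurrent mutations with
#'   no planted effects.
#' @slot nBackgroundPrivate number of single-sample mutations (removed by
#'   the recurrence filter).
#' @slot backgroundRecurrenceRange carrier-count range for background
#'   recurrent mutations.
#' @slot nKnownContaminants number of mutations also present in the known
#'   (common) variant catalog, removed by the exclusion filter.
#' @slot exprMeanLog2Range per-gene baseline log2-expression range.
#' @slot exprSdLog2 log2-expression noise SD across samples.
#' @slot rnaDepth,exomeDepth read depth at mutation sites.
#' @slot purityRange tumor purity range.
#' @slot trackCoverage background fraction of each gene's exonic bases
#'   covered by each regulatory track.
#' @slot cnaRate fraction of background carrier (gene, sample) pairs flagged
#'   with a copy-number alteration.
#' @slot layersEnabled named logical vector with entries dnase, chip,
#'   allelic; FALSE disables generation of that data layer (score letter
#'   becomes '*').
#' @slot plantedDuons list of \linkS4class{DuonSpec}.
#' @slot seed mandatory RNG seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nSamples = "integer", nGenes = "integer",
                 isoformRange = "integer", nBackgroundRecurrent = "integer",
                 nBackgroundPrivate = "integer",
                 backgroundRecurrenceRange = "integer",
                 nKnownContaminants = "integer",
                 exprMeanLog2Range = "numeric", exprSdLog2 = "numeric",
                 rnaDepth = "integer", exomeDepth = "integer",
                 purityRange = "numeric", trackCoverage = "numeric",
                 cnaRate = "numeric", layersEnabled = "logical",
                 plantedDuons = "list", seed = "integer"),
  prototype(nSamples = 100L, nGenes = 300L, isoformRange = c(2L, 5L),
            nBackgroundRecurrent = 100L, nBackgroundPrivate = 10L,
            backgroundRecurrenceRange = c(3L, 8L), nKnownContaminants = 10L,
            exprMeanLog2Range = c(3, 8), exprSdLog2 = 0.5, rnaDepth = 60L,
            exomeDepth = 80L, purityRange = c(0.4, 0.7),
            trackCoverage = 0.2, cnaRate = 0.05,
            layersEnabled = c(dnase = TRUE, chip = TRUE, allelic = TRUE),
            plantedDuons = list(), seed = NA_integer_))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (is.na(object@seed)) msg <- c(msg, "seed is mandatory")
  if (object@nSamples < 2L) msg <- c(msg, "nSamples must be >= 2")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@trackCoverage < 0 || object@trackCoverage > 1)
    msg <- c(msg, "trackCoverage must lie in [0,1]")
  if (any(object@purityRange <= 0) || any(object@purityRange > 1))
    msg <- c(msg, "purityRange must lie in (0,1]")
  if (!all(c("dnase", "chip", "allelic") %in% names(object@layersEnabled)))
    msg <- c(msg, "layersEnabled needs entries dnase, chip, allelic")
  for (d in object@plantedDuons) {
    if (!is(d, "DuonSpec")) {
      msg <- c(msg, "plantedDuons must be a list of DuonSpec objects")
      break
    }
    if (d@nMutantSamples > object@nSamples)
      msg <- c(msg, "a DuonSpec plants more carriers than there are samples")
  }
  nCoupled <- sum(vapply(object@plantedDuons, function(d)
    d@entropyCoupling != 0 || !is.na(d@entropyTargetR), logical(1L)))
  if (nCoupled > 1L)
    msg <- c(msg, "at most one planted duon may carry entropy coupling")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param seed mandatory RNG seed (integer).
#' @param ... slot overrides; see \linkS4class{SimulationConfig}.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 1, nSamples = 20L, nGenes = 10L,
#'                         nBackgroundRecurrent = 5L)
#' @export
simulationConfig <- function(seed, ...) {
  args <- list(...)
  intSlots <- c("nSamples", "nGenes", "isoformRange", "nBackgroundRecurrent",
                "nBackgroundPrivate", "backgroundRecurrenceRange",
                "nKnownContaminants", "rnaDepth", "exomeDepth")
  for (s in intersect(names(args), intSlots)) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("SimulationConfig", seed = .assertSeed(seed)), args))
}

#' RedactConfig: thresholds and estimator choices for scoring
#'
#' @slot alphaE significance threshold for the E and A layers.
#' @slot recurrenceMin minimum carrier count (recurrence floor).
#' @slot recurrenceFrac carrier fraction that must be exceeded (strictly).
#' @slot motifScoreFraction fraction of a PWM's maximum log-odds score a
#'   site must reach to count as a predicted binding site.
#' @slot nPerm permutations for the D/C overlap null.
#' @slot nPermMotif permutations for the T (motif) null.
#' @slot permEstimator "n/N" (the plain permutation estimator) or "add-one"
#'   ((n+1)/(N+1), strictly positive).
#' @slot combineLayers layers whose p-values enter the combined statistic.
#' @slot keepConsequences consequence classes retained for scoring.
#' @slot tTestVariant "welch" or "pooled" (downstream direction vector).
#' @slot purityAdjust logical; divide the exome VAF by purity when forming
#'   the allelic-imbalance null.
#' @slot seed RNG seed for the permutation layers.
#' @exportClass RedactConfig
setClass("RedactConfig",
  representation(alphaE = "numeric", recurrenceMin = "integer",
                 recurrenceFrac = "numeric", motifScoreFraction = "numeric",
                 nPerm = "integer", nPermMotif = "integer",
                 permEstimator = "character", combineLayers = "character",
                 keepConsequences = "character", tTestVariant = "character",
                 purityAdjust = "logical", seed = "integer"),
  prototype(alphaE = 0.05, recurrenceMin = 3L, recurrenceFrac = 0.01,
            motifScoreFraction = 0.8, nPerm = 10000L, nPermMotif = 1000L,
            permEstimator = "n/N",
            combineLayers = c("E", "A", "D", "C", "T"),
            keepConsequences = c("missense", "inframe_del", "inframe_ins"),
            tTestVariant = "welch", purityAdjust = TRUE, seed = NA_integer_))

setValidity("RedactConfig", function(object) {
  msg <- character()
  if (object@nPerm < 100L) msg <- c(msg, "nPerm must be >= 100")
  if (object@nPermMotif < 100L) msg <- c(msg, "nPermMotif must be >= 100")
  if (object@alphaE <= 0 || object@alphaE >= 1)
    msg <- c(msg, "alphaE must lie in (0,1)")
  if (is.na(object@seed)) msg <- c(msg, "seed is mandatory")
  if (!object@permEstimator %in% c("n/N", "add-one"))
    msg <- c(msg, "permEstimator must be 'n/N' or 'add-one'")
  if (!all(object@combineLayers %in% c("E", "A", "D", "C", "T")))
    msg <- c(msg, "combineLayers must be a subset of E,A,D,C,T")
  if (!object@tTestVariant %in% c("welch", "pooled"))
    msg <- c(msg, "tTestVariant must be 'welch' or 'pooled'")
  if (length(msg)) msg else TRUE
})

#' Construct a RedactConfig
#'
#' @param seed mandatory RNG seed for the permutation layers.
#' @param ... slot overrides; see \linkS4class{RedactConfig}.
#' @return A validated \linkS4class{RedactConfig}.
#' @examples
#' redactConfig(seed = 1, nPerm = 2000L)
#' @export
redactConfig <- function(seed, ...) {
  args <- list(...)
  for (s in intersect(names(args), c("recurrenceMin", "nPerm", "nPermMotif")))
    args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("RedactConfig", seed = .assertSeed(seed)), args))
}
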