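## End-to-end entry points: simulate, score, downstream. Each writes its
## outputs plus a JSON run manifest (config hash, seed, stage counts) so a
## run is auditable. A thin command-line wrapper over these functions ships
## in inst/scripts/duonscan.

#' Read a simulation configuration file
#'
#' YAML key-value file mirroring the slots of
#' \linkS4class{SimulationConfig}; planted duons are given under
#' \code{plantedDuons} as a list of key-value maps with DuonSpec fields, or
#' as the string \code{"default"} for \code{\link{defaultDuonSpecs}}.
#'
#' @param path YAML file.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
readSimulationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) .stopf("config %s: seed is mandatory", path)
  duons <- list()
  if (!is.null(y$plantedDuons)) {
    if (identical(y$plantedDuons, "default")) {
      duons <- defaultDuonSpecs()
    } else {
      duons <- lapply(y$plantedDuons, function(d) do.call(DuonSpec, d))
    }
  }
  y$plantedDuons <- NULL
  seed <- y$seed
  y$seed <- NULL
  for (k in c("isoformRange", "backgroundRecurrenceRange", "purityRange",
              "exprMeanLog2Range")) {
    if (!is.null(y[[k]])) y[[k]] <- unlist(y[[k]])
  }
  if (!is.null(y$layersEnabled)) y$layersEnabled <- unlist(y$layersEnabled)
  do.call(simulationConfig,
          c(list(seed = seed, plantedDuons = duons), y))
}

#' Read a scoring (run) configuration file
#'
#' YAML key-value file mirroring the slots of \linkS4class{RedactConfig}.
#'
#' @param path YAML file.
#' @return A validated \linkS4class{RedactConfig}.
#' @export
readRedactConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) .stopf("config %s: seed is mandatory", path)
  seed <- y$seed
  y$seed <- NULL
  if (!is.null(y$combineLayers)) y$combineLayers <- unlist(y$combineLayers)
  if (!is.null(y$keepConsequences))
    y$keepConsequences <- unlist(y$keepConsequences)
  do.call(redactConfig, c(list(seed = seed), y))
}

## Stable hash of an arbitrary R object via its deparsed form.
.configHash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(x, control = c("exact")), tf)
  unname(tools::md5sum(tf))
}

.writeManifest <- function(outDir, command, seed, extra = list()) {
  manifest <- c(list(command = command, seed = seed,
                     package_version = as.character(
                       utils::packageVersion("duonscan"))),
                extra)
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.slotList <- function(obj) {
  sn <- methods::slotNames(class(obj))
  setNames(lapply(sn, function(s) methods::slot(obj, s)), sn)
}

#' Simulate a cohort and write it to disk
#'
#' @param config a \linkS4class{SimulationConfig}, or the path of a YAML
#'   configuration file.
#' @param outDir output directory; receives the cohort files, the truth
#'   table and a JSON run manifest recording the seed and a configuration
#'   hash (identical config => identical hash).
#' @return Invisibly, \code{list(cohort, truth, manifest)}.
#' @export
runSimulate <- function(config, outDir) {
  if (is.character(config)) config <- readSimulationConfig(config)
  validObject(config)
  sim <- generateCohort(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeCohort(sim$cohort, outDir)
  f <- .cohortFiles(outDir)
  write.table(sim$truth, f$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- .writeManifest(outDir, "simulate", config@seed,
                             list(config_hash = .configHash(
                               .slotList(config)[setdiff(
                                 methods::slotNames("SimulationConfig"),
                                 "plantedDuons")]),
                               n_planted = length(config@plantedDuons)))
  invisible(list(cohort = sim$cohort, truth = sim$truth,
                 manifest = manifest))
}

#' Score a cohort directory and write the pDM report
#'
#' Loads a cohort from disk, runs \code{\link{scoreCohort}} and writes
#' \code{pdm_report.tsv}, a stage-count log and a run manifest. The stage
#' counts record the mutation totals entering each pipeline stage (input,
#' after known-variant exclusion, protein-altering, recurrent, pDM).
#'
#' @param cohortDir cohort directory (see \code{\link{readCohort}}).
#' @param config a \linkS4class{RedactConfig} or YAML path.
#' @param outDir output directory.
#' @return Invisibly, the \code{\link{scoreCohort}} result.
#' @export
runScore <- function(cohortDir, config, outDir) {
  if (is.character(config)) config <- readRedactConfig(config)
  validObject(config)
  cohort <- readCohort(cohortDir)
  res <- scoreCohort(cohort, config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeRedactReport(res$report, file.path(outDir, "pdm_report.tsv"))
  counts <- res$stageCounts
  write.table(data.frame(stage = names(counts), n = as.integer(counts)),
              file.path(outDir, "stage_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf(
    "scored cohort: %d input, %d after known-variant filter, %d protein-altering, %d recurrent, %d pDM",
    counts["input"], counts["post_known_filter"],
    counts["protein_altering"], counts["recurrent"], counts["pdm"]))
  .writeManifest(outDir, "score", config@seed,
                 list(config_hash = .configHash(.slotList(config)),
                      stage_counts = as.list(counts)))
  invisible(res)
}

#' Downstream analysis for one scored gene
#'
#' For a gene of interest from a pDM report, computes and writes: the
#' splicing-entropy profile (per sample, and per gene within carrier
#' samples), the correlation between the gene's expression and sample
#' entropy with a leave-one-out diagnostic, the signed per-gene direction
#' vector (v = s(1-p)) ready for pathway-enrichment input, the carrier
#' rank-concordance against an optional target gene, and a wild-type
#' control permutation of the expression-entropy correlation.
#'
#' @param cohortDir cohort directory.
#' @param reportFile pDM report TSV written by \code{\link{runScore}}.
#' @param gene gene of interest (must appear in the report).
#' @param outDir output directory.
#' @param targetGene optional target gene for the concordance analysis.
#' @param expectedSign expected association sign for the target (+1/-1).
#' @param subsetSize wild-type samples per control draw (default: number
#'   of carriers).
#' @param nIter control-permutation draws (default 1000).
#' @param seed RNG seed (default 1).
#' @return Invisibly, a list with the computed results.
#' @export
runDownstream <- function(cohortDir, reportFile, gene, outDir,
                          targetGene = NULL, expectedSign = -1,
                          subsetSize = NULL, nIter = 1000L, seed = 1L) {
  cohort <- readCohort(cohortDir)
  report <- read.delim(reportFile, stringsAsFactors = FALSE)
  hit <- report[report$gene == gene, , drop = FALSE]
  if (!nrow(hit)) .stopf("gene '%s' does not appear in %s", gene, reportFile)
  hit <- hit[1L, ]
  muts <- mutations(cohort)
  idx <- which(muts$gene == gene & muts$pos == hit$pos &
                 muts$ref == hit$ref & muts$alt == hit$alt)
  if (!length(idx)) .stopf("reported mutation not found in the cohort")
  carriers <- muts$samples[[idx[1L]]]
  wildtype <- setdiff(colnames(expressionMatrix(cohort)), carriers)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  iso <- isoformExpression(cohort)
  sampEnt <- vapply(colnames(iso), function(s)
    sampleSplicingEntropy(iso, s), numeric(1L))
  write.table(data.frame(sample = names(sampEnt), entropy = sampEnt),
              file.path(outDir, "sample_entropy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  geneEnt <- do.call(rbind, lapply(carriers, function(s) {
    e <- geneSplicingEntropy(iso, isoformToGene(cohort), s)
    data.frame(gene = names(e), sample = s, entropy = unname(e),
               stringsAsFactors = FALSE)
  }))
  write.table(geneEnt, file.path(outDir, "gene_entropy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  expr <- expressionMatrix(cohort)
  entCor <- entropyExpressionCorrelation(expr[gene, carriers],
                                         sampEnt[carriers])
  statistic <- function(ss) {
    if (sd(expr[gene, ss]) == 0 || sd(sampEnt[ss]) == 0) return(0)
    cor(expr[gene, ss], sampEnt[ss])
  }
  ctrl <- wildtypeControlPermutation(
    wildtype, statistic,
    subsetSize = if (is.null(subsetSize)) length(carriers) else subsetSize,
    nIter = nIter, seed = seed, observed = entCor$r)

  vvec <- geneDirectionVector(expr, carriers)
  write.table(vvec[, c("gene", "v")], file.path(outDir, "v_vector.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## per-gene entropy-vs-expression correlation across carriers (pathway
  ## input for splicing-factor style mutations)
  entMat <- vapply(carriers, function(s) {
    e <- geneSplicingEntropy(iso, isoformToGene(cohort), s)
    e[rownames(expr)]
  }, numeric(nrow(expr)))
  rownames(entMat) <- rownames(expr)
  corVec <- vapply(rownames(expr), function(g) {
    h <- entMat[g, ]
    x <- expr[gene, carriers]
    if (any(is.na(h)) || sd(h) == 0 || sd(x) == 0) NA_real_ else cor(x, h)
  }, numeric(1L))
  write.table(data.frame(gene = names(corVec), value = unname(corVec)),
              file.path(outDir, "entropy_correlation_vector.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  conc <- NULL
  if (!is.null(targetGene)) {
    mae <- mutantAllelicExpression(cohort, hit$chrom, hit$pos, hit$ref,
                                   hit$alt, gene)
    conc <- rankConcordance(mae, setNames(expr[targetGene, names(mae)],
                                          names(mae)), expectedSign)
  }
  summary <- list(gene = gene, n_carriers = length(carriers),
                  entropy_expression_r = entCor$r,
                  loo_max_delta = entCor$looMaxDelta,
                  control_permutation_p = ctrl$p,
                  control_null_mean = mean(ctrl$null),
                  target_gene = targetGene,
                  target_rho = if (is.null(conc)) NULL else conc$rho,
                  target_concordant = if (is.null(conc)) NULL else
                    conc$concordant)
  jsonlite::write_json(summary, file.path(outDir, "downstream_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .writeManifest(outDir, "downstream", seed, list(gene = gene))
  invisible(list(sampleEntropy = sampEnt, geneEntropy = geneEnt,
                 entropyCorrelation = entCor, control = ctrl,
                 vVector = vvec, concordance = conc, summary = summary))
}
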