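## Synthetic multi-omic cohort generator with planted ground truth.
##
## Everything is drawn from one seed: gene models and sequences, normalized
## expression with planted fold-changes, isoform abundances (optionally
## entropy-coupled to a driver gene), exome/RNA allelic read counts under a
## clonal-heterozygous purity mixture, regulatory tracks, engineered motif
## sites, background recurrent mutations and contaminating known variants.

#' Built-in synthetic PWM library
#'
#' Three sharply specific 6-bp motifs (consensus probability 0.97 per
#' position) used by the cohort generator to engineer motif gain/loss
#' events. At the default 80\%-of-maximum score threshold only the exact
#' consensus passes, which keeps chance hits rare and planted effects
#' unambiguous.
#'
#' @return Named list of PWM probability matrices with \code{tf_name} and
#'   \code{motif_id} attributes.
#' @export
syntheticPwmLibrary <- function() {
  specs <- list(c(id = "SYN0001.1", tf = "TBX", cons = "TATAAT"),
                c(id = "SYN0002.1", tf = "EBOX", cons = "CACGTG"),
                c(id = "SYN0003.1", tf = "GCF", cons = "GGGCGG"))
  out <- list()
  for (s in specs) {
    cons <- strsplit(s[["cons"]], "")[[1]]
    m <- matrix(0.01, nrow = 4L, ncol = length(cons),
                dimnames = list(.BASES, NULL))
    for (j in seq_along(cons)) m[cons[j], j] <- 0.97
    attr(m, "motif_id") <- s[["id"]]
    attr(m, "tf_name") <- s[["tf"]]
    out[[s[["id"]]]] <- m
  }
  out
}

#' Default planted duon specifications
#'
#' Ten strong-effect duon mutations spanning the effect classes the
#' pipeline detects: expression shifts of +/-1.5 log2 units, allelic skews
#' of 0.8/0.2 paired in direction with the expression shift, all
#' combinations of DNase/ChIP overlap, motif gain/loss/none, and the three
#' protein-altering consequence classes.
#'
#' @param n number of specs (default 10; recycled in order if larger).
#' @return List of \linkS4class{DuonSpec}.
#' @export
defaultDuonSpecs <- function(n = 10L) {
  base <- list(
    DuonSpec(expressionLog2fc = 1.5, allelicSkew = 0.8, inDnase = TRUE,
             inChip = TRUE, motifEffect = "gain"),
    DuonSpec(expressionLog2fc = -1.5, allelicSkew = 0.2, inDnase = FALSE,
             inChip = TRUE, motifEffect = "loss"),
    DuonSpec(expressionLog2fc = 1.5, allelicSkew = 0.8, inDnase = TRUE,
             inChip = FALSE, motifEffect = "none"),
    DuonSpec(expressionLog2fc = 1.5, allelicSkew = 0.8, inDnase = TRUE,
             inChip = TRUE, motifEffect = "loss",
             consequence = "inframe_del"),
    DuonSpec(expressionLog2fc = -1.5, allelicSkew = 0.2, inDnase = TRUE,
             inChip = TRUE, motifEffect = "gain"),
    DuonSpec(expressionLog2fc = 1.5, allelicSkew = 0.8, inDnase = FALSE,
             inChip = FALSE, motifEffect = "gain"),
    DuonSpec(expressionLog2fc = -1.5, allelicSkew = 0.2, inDnase = TRUE,
             inChip = FALSE, motifEffect = "none",
             consequence = "inframe_del"),
    DuonSpec(expressionLog2fc = 1.5, allelicSkew = 0.8, inDnase = TRUE,
             inChip = TRUE, motifEffect = "none"),
    DuonSpec(expressionLog2fc = 1.5, allelicSkew = 0.8, inDnase = TRUE,
             inChip = FALSE, motifEffect = "none",
             consequence = "inframe_ins"),
    DuonSpec(expressionLog2fc = -1.5, allelicSkew = 0.2, inDnase = FALSE,
             inChip = TRUE, motifEffect = "loss"))
  rep(base, length.out = n)
}

#' Expected REDACT string for a planted duon
#'
#' The deterministic oracle tying a \linkS4class{DuonSpec} to the score
#' string the pipeline should produce when the planted effects are strong
#' (|log2fc| >= 1, allelic skew >= 0.75 or <= 0.25, depth >= 50): uppercase
#' where an effect is planted, lowercase where the data layer is simulated
#' without an effect, '*' where the layer is disabled in the configuration.
#' An allelic skew whose direction opposes the planted expression shift is
#' expected lowercase (the pipeline downgrades direction-inconsistent A
#' evidence).
#'
#' @param spec a \linkS4class{DuonSpec}.
#' @param config the \linkS4class{SimulationConfig} the cohort was (or will
#'   be) generated under.
#' @return 6-character REDACT string.
#' @export
expectedRedact <- function(spec, config) {
  en <- config@layersEnabled
  r <- if (spec@nMutantSamples >= 3L &&
           spec@nMutantSamples / config@nSamples > 0.01) "R" else "r"
  e <- if (spec@expressionLog2fc != 0) "E" else "e"
  d <- if (!en[["dnase"]]) "*" else if (spec@inDnase) "D" else "d"
  aDir <- sign(spec@allelicSkew - 0.5)
  eDir <- sign(spec@expressionLog2fc)
  a <- if (!en[["allelic"]]) "*"
    else if (aDir == 0) "a"
    else if (spec@expressionLog2fc != 0 && aDir != eDir) "a"
    else "A"
  cc <- if (!en[["chip"]]) "*" else if (spec@inChip) "C" else "c"
  tt <- if (spec@motifEffect != "none") "T" else "t"
  paste0(r, e, d, a, cc, tt)
}

.randBases <- function(n) sample(.BASES, n, replace = TRUE)

## Place one engineered edit at spliced position s1 (1-based) of a gene's
## sequence; rewrites the window to realize the requested motif effect and
## verifies it with the production scanner, resampling flanks on chance
## hits. Returns the updated sequence and the mutation's ref/alt.
.engineerEdit <- function(seqChars, s1, spec, pwmLib, maxL, geneModel) {
  refLen <- switch(spec@consequence, missense = 1L, inframe_del = 3L,
                   inframe_ins = 0L)
  pwmIdx <- 1L + (s1 %% length(pwmLib))
  pwm <- pwmLib[[pwmIdx]]
  cons <- .BASES[apply(pwm, 2L, which.max)]
  Lc <- length(cons)
  winA <- max(1L, s1 - (maxL + 3L))
  winB <- min(length(seqChars), s1 + refLen + maxL + 3L)
  for (try in seq_len(200L)) {
    seqChars[winA:winB] <- .randBases(winB - winA + 1L)
    if (spec@motifEffect == "gain") {
      ## wild-type carries the consensus with one base broken; the SNV
      ## restores it
      mOff <- 3L
      siteStart <- s1 - mOff + 1L
      seqChars[siteStart:(siteStart + Lc - 1L)] <- cons
      wtBase <- sample(setdiff(.BASES, cons[mOff]), 1L)
      seqChars[s1] <- wtBase
      ref <- wtBase
      alt <- cons[mOff]
    } else if (spec@motifEffect == "loss") {
      ## wild-type carries the full consensus; the edit destroys it
      mOff <- 2L
      siteStart <- s1 - mOff + 1L
      seqChars[siteStart:(siteStart + Lc - 1L)] <- cons
      if (spec@consequence == "inframe_del") {
        ref <- paste(seqChars[s1:(s1 + 2L)], collapse = "")
        alt <- "-"
      } else {
        ref <- seqChars[s1]
        alt <- sample(setdiff(.BASES, ref), 1L)
      }
    } else {
      if (spec@consequence == "inframe_del") {
        ref <- paste(seqChars[s1:(s1 + 2L)], collapse = "")
        alt <- "-"
      } else if (spec@consequence == "inframe_ins") {
        ref <- "-"
        alt <- paste(.randBases(3L), collapse = "")
      } else {
        ref <- seqChars[s1]
        alt <- sample(setdiff(.BASES, ref), 1L)
      }
    }
    pos1 <- genomicFromSpliced(geneModel$exons, s1 - 1L)
    if (spec@consequence == "inframe_ins") pos1 <- pos1 + 1L
    mp <- scanMotifPerturbation(pos1, ref, alt, geneModel,
                                paste(seqChars, collapse = ""), pwmLib)
    if (mp@effect == spec@motifEffect) {
      return(list(seqChars = seqChars, ref = ref, alt = alt, pos = pos1))
    }
  }
  .stopf("could not engineer a '%s' motif effect (gene window too constrained)",
         spec@motifEffect)
}

## Entropy of the lambda-mixture between a uniform k-isoform distribution
## and a point mass on the first isoform.
.mixEntropy <- function(lambda, k) {
  p1 <- lambda / k + (1 - lambda)
  rest <- lambda / k
  h <- -p1 * log2(p1)
  if (rest > 0) h <- h - (k - 1) * rest * log2(rest)
  h
}

## Solve per-sample mixing weights so that the pooled (sample-level)
## entropy H(w) + sum_g w_g * Hmix(lambda, k_g) matches the target.
.solveLambda <- function(target, w, k) {
  hw <- shannonEntropy(w)
  f <- function(l) hw + sum(w * vapply(k, function(kk)
    .mixEntropy(l, kk), numeric(1L))) - target
  lo <- f(0)
  hi <- f(1)
  if (target <= hw) return(0)
  if (hi <= 0) return(1)
  uniroot(f, c(0, 1), tol = 1e-9)$root
}

## Background regulatory track for one gene: exonic chunks of ~25 bp each
## included with probability `coverage`, excluding a guard zone around
## planted positions that must stay uncovered.
.backgroundTrack <- function(geneModel, coverage, exclude1based) {
  rows <- list()
  chunk <- 25L
  for (i in seq_len(nrow(geneModel$exons))) {
    exS <- geneModel$exons[i, 1L] + 1L # 1-based inclusive
    exE <- geneModel$exons[i, 2L]
    starts <- seq.int(exS, exE, by = chunk)
    for (st in starts) {
      en <- min(st + chunk - 1L, exE)
      if (runif(1L) >= coverage) next
      if (length(exclude1based) &&
          any(exclude1based >= st - 2L & exclude1based <= en + 2L)) next
      rows[[length(rows) + 1L]] <- c(st, en)
    }
  }
  rows
}

#' Generate a synthetic cohort with known ground truth
#'
#' Builds a complete \linkS4class{DuonCohort} - gene models, spliced
#' sequences, expression, isoform abundances, allelic read counts, purity,
#' regulatory tracks, PWMs, copy-number flags and a known-variant catalog -
#' together with a truth table describing every planted duon mutation and
#' the REDACT string it is expected to earn. The generation is fully
#' deterministic given the configuration seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return \code{list(cohort = DuonCohort, truth = data.frame)}; the truth
#'   table has one row per planted duon (gene, location, alleles, planted
#'   effect sizes, realized carrier ids and the expected REDACT string).
#' @examples
#' sim <- generateCohort(simulationConfig(seed = 1, nSamples = 20L,
#'   nGenes = 12L, nBackgroundRecurrent = 4L, nBackgroundPrivate = 2L,
#'   nKnownContaminants = 2L, plantedDuons = defaultDuonSpecs(2L)))
#' sim$truth$expected_redact
#' @export
generateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  nS <- config@nSamples
  nG <- config@nGenes
  duons <- config@plantedDuons
  nD <- length(duons)
  samples <- sprintf("S%04d", seq_len(nS))
  genes <- sprintf("G%04d", seq_len(nG))
  pwmLib <- syntheticPwmLibrary()
  maxL <- max(vapply(pwmLib, ncol, integer(1L)))

  ## assign genes: duons first, then any auto targets from the tail
  nTargets <- sum(vapply(duons, function(d) identical(d@targetGene, "auto"),
                         logical(1L)))
  if (nG < nD + nTargets + 1L) {
    .stopf("nGenes too small for %d planted duons and %d auto targets",
           nD, nTargets)
  }
  tailIdx <- nG
  for (i in seq_along(duons)) {
    if (!nzchar(duons[[i]]@gene)) duons[[i]]@gene <- genes[i]
    if (identical(duons[[i]]@targetGene, "auto")) {
      duons[[i]]@targetGene <- genes[tailIdx]
      tailIdx <- tailIdx - 1L
    }
  }
  duonGenes <- vapply(duons, function(d) d@gene, character(1L))
  if (anyDuplicated(duonGenes)) {
    .stopf("planted duons must target distinct genes")
  }

  ## gene models and random sequences on one synthetic chromosome
  models <- list()
  seqList <- character(nG)
  cursor <- 1000L
  for (i in seq_len(nG)) {
    nEx <- sample(2:4, 1L)
    lens <- sample(150:350, nEx, replace = TRUE)
    exons <- matrix(0L, nEx, 2L, dimnames = list(NULL, c("start", "end")))
    pos <- cursor
    for (j in seq_len(nEx)) {
      exons[j, ] <- c(pos, pos + lens[j])
      pos <- pos + lens[j] + sample(200:800, 1L)
    }
    cursor <- pos + 500L
    models[[genes[i]]] <- list(chrom = "chr1",
                               strand = sample(c("+", "-"), 1L),
                               exons = exons)
    seqList[i] <- paste(.randBases(sum(lens)), collapse = "")
  }
  names(seqList) <- genes

  ## planted duon edits
  mutRows <- list()
  truthRows <- list()
  plantedPos <- list() # per gene: 1-based genomic footprint positions
  for (i in seq_along(duons)) {
    d <- duons[[i]]
    g <- d@gene
    gm <- models[[g]]
    seqChars <- strsplit(seqList[[g]], "")[[1]]
    refLen <- switch(d@consequence, missense = 1L, inframe_del = 3L,
                     inframe_ins = 0L)
    ## pick an exon wide enough to hold the motif window with margins
    cum <- cumsum(c(0L, .exonWidths(gm$exons)))
    margin <- maxL + refLen + 6L
    okEx <- which(.exonWidths(gm$exons) > 2L * margin)
    ex <- okEx[sample.int(length(okEx), 1L)]
    s1 <- cum[ex] + sample.int(.exonWidths(gm$exons)[ex] - 2L * margin,
                               1L) + margin
    ed <- .engineerEdit(seqChars, s1, d, pwmLib, maxL, gm)
    seqList[[g]] <- paste(ed$seqChars, collapse = "")
    carriers <- sample(samples, d@nMutantSamples)
    mutRows[[length(mutRows) + 1L]] <- list(
      chrom = gm$chrom, pos = ed$pos, ref = ed$ref, alt = ed$alt, gene = g,
      consequence = d@consequence,
      protein_change = sprintf("p.X%d", i), samples = carriers,
      planted = TRUE)
    fp <- mutationFootprint(ed$pos, ed$ref, ed$alt)
    plantedPos[[g]] <- list(pos = seq.int(fp["start"], fp["end"]),
                            inDnase = d@inDnase, inChip = d@inChip)
    truthRows[[i]] <- data.frame(
      gene = g, chrom = gm$chrom, pos = ed$pos, ref = ed$ref, alt = ed$alt,
      consequence = d@consequence, n_mutant_samples = d@nMutantSamples,
      samples = paste(carriers, collapse = ","),
      expression_log2fc = d@expressionLog2fc,
      allelic_skew = d@allelicSkew, in_dnase = d@inDnase,
      in_chip = d@inChip, motif_effect = d@motifEffect,
      entropy_coupling = d@entropyCoupling,
      entropy_target_r = d@entropyTargetR, target_gene = d@targetGene,
      target_sign = d@targetSign,
      expected_redact = expectedRedact(d, config),
      stringsAsFactors = FALSE)
  }

  ## background mutations (recurrent, private, known contaminants)
  usedGenes <- c(duonGenes,
                 vapply(duons, function(d) d@targetGene, character(1L)))
  pool <- setdiff(genes, usedGenes[nzchar(usedGenes)])
  usedKeys <- vapply(mutRows, function(m)
    .mutKey(m$chrom, m$pos, m$ref, m$alt), character(1L))
  knownKeys <- character()
  drawBackground <- function(nCarriers, known) {
    repeat {
      g <- sample(pool, 1L)
      gm <- models[[g]]
      L <- splicedLength(gm$exons)
      s1 <- sample.int(L, 1L)
      seqChars <- strsplit(seqList[[g]], "")[[1]]
      ref <- seqChars[s1]
      alt <- sample(setdiff(.BASES, ref), 1L)
      pos <- genomicFromSpliced(gm$exons, s1 - 1L)
      key <- .mutKey(gm$chrom, pos, ref, alt)
      if (key %in% usedKeys) next
      usedKeys <<- c(usedKeys, key)
      if (known) knownKeys <<- c(knownKeys, key)
      return(list(chrom = gm$chrom, pos = pos, ref = ref, alt = alt,
                  gene = g, consequence = "missense", protein_change = "",
                  samples = sample(samples, nCarriers), planted = FALSE))
    }
  }
  rr <- config@backgroundRecurrenceRange
  drawCarrierCount <- function() {
    rr[1L] + sample.int(rr[2L] - rr[1L] + 1L, 1L) - 1L
  }
  for (i in seq_len(config@nBackgroundRecurrent)) {
    mutRows[[length(mutRows) + 1L]] <-
      drawBackground(drawCarrierCount(), known = FALSE)
  }
  for (i in seq_len(config@nBackgroundPrivate)) {
    mutRows[[length(mutRows) + 1L]] <- drawBackground(1L, known = FALSE)
  }
  for (i in seq_len(config@nKnownContaminants)) {
    mutRows[[length(mutRows) + 1L]] <-
      drawBackground(drawCarrierCount(), known = TRUE)
  }

  mutations <- data.frame(
    chrom = vapply(mutRows, `[[`, "", "chrom"),
    pos = vapply(mutRows, function(m) as.integer(m$pos), integer(1L)),
    ref = vapply(mutRows, `[[`, "", "ref"),
    alt = vapply(mutRows, `[[`, "", "alt"),
    gene = vapply(mutRows, `[[`, "", "gene"),
    consequence = vapply(mutRows, `[[`, "", "consequence"),
    protein_change = vapply(mutRows, `[[`, "", "protein_change"),
    stringsAsFactors = FALSE)
  mutations$samples <- lapply(mutRows, `[[`, "samples")

  ## expression: per-gene log-normal baseline, planted shifts in carriers
  baseline <- runif(nG, config@exprMeanLog2Range[1L],
                    config@exprMeanLog2Range[2L])
  names(baseline) <- genes
  log2e <- matrix(rnorm(nG * nS, mean = rep(baseline, nS),
                        sd = config@exprSdLog2),
                  nrow = nG, ncol = nS, dimnames = list(genes, samples))
  for (i in seq_along(duons)) {
    d <- duons[[i]]
    carriers <- mutRows[[i]]$samples
    log2e[d@gene, carriers] <- log2e[d@gene, carriers] + d@expressionLog2fc
  }
  expression <- 2^log2e

  ## purity and allelic read counts (clonal heterozygous mixture model)
  pur <- setNames(runif(nS, config@purityRange[1L], config@purityRange[2L]),
                  samples)
  acRows <- list()
  if (config@layersEnabled[["allelic"]]) {
    for (j in seq_along(mutRows)) {
      m <- mutRows[[j]]
      skew <- if (m$planted) duons[[j]]@allelicSkew else NA_real_
      for (s in m$samples) {
        p <- pur[[s]]
        exomeVaf <- p * 0.5 / (p * 0.5 + (1 - p))
        ea <- rbinom(1L, config@exomeDepth, exomeVaf)
        ## null (no A effect): the RNA allelic fraction sits at its
        ## DNA-implied, purity-adjusted expectation
        rnaP <- if (is.na(skew)) {
          .allelicNullP0(ea / config@exomeDepth, p)
        } else skew
        ra <- rbinom(1L, config@rnaDepth, rnaP)
        acRows[[length(acRows) + 1L]] <- data.frame(
          chrom = m$chrom, pos = as.integer(m$pos), ref = m$ref,
          alt = m$alt, sample = s, exome_ref = config@exomeDepth - ea,
          exome_alt = ea, rna_ref = config@rnaDepth - ra, rna_alt = ra,
          stringsAsFactors = FALSE)
      }
    }
  }
  allelic <- if (length(acRows)) do.call(rbind, acRows) else
    .emptyAllelicCounts()

  ## downstream targets: carrier expression follows the mutant-allele dose
  for (i in seq_along(duons)) {
    d <- duons[[i]]
    if (!nzchar(d@targetGene)) next
    carriers <- mutRows[[i]]$samples
    sub <- allelic[allelic$pos == mutRows[[i]]$pos &
                     allelic$sample %in% carriers, , drop = FALSE]
    if (nrow(sub) < 2L) next
    frac <- sub$rna_alt / pmax(sub$rna_ref + sub$rna_alt, 1L)
    dose <- frac * expression[d@gene, sub$sample]
    z <- as.numeric(scale(dose))
    log2t <- baseline[d@targetGene] + d@targetSign * 1.2 * z +
      rnorm(length(z), sd = 0.3)
    expression[d@targetGene, sub$sample] <- 2^log2t
  }

  ## isoform abundances; optionally entropy-coupled to a driver gene
  kIso <- sample(config@isoformRange[1L]:config@isoformRange[2L], nG,
                 replace = TRUE)
  isoIds <- unlist(lapply(seq_len(nG), function(i)
    sprintf("%s.%d", genes[i], seq_len(kIso[i]))))
  isoGene <- setNames(rep(genes, kIso), isoIds)
  isoform <- matrix(0, nrow = length(isoIds), ncol = nS,
                    dimnames = list(isoIds, samples))
  coupledIdx <- which(vapply(duons, function(d)
    d@entropyCoupling != 0 || !is.na(d@entropyTargetR), logical(1L)))
  realizedSlope <- rep(NA_real_, nD)
  if (length(coupledIdx)) {
    d <- duons[[coupledIdx]]
    x <- expression[d@gene, ]
    sigma <- d@entropyNoiseSd
    b <- if (!is.na(d@entropyTargetR)) {
      r <- d@entropyTargetR
      sigma * r / (sd(x) * sqrt(1 - r^2))
    } else {
      d@entropyCoupling
    }
    realizedSlope[coupledIdx] <- b
    w <- sweep(expression, 2L, colSums(expression), "/")
    attMin <- apply(w, 2L, shannonEntropy)
    attMax <- attMin + colSums(w * log2(kIso))
    h0 <- mean((attMin + attMax) / 2)
    target <- h0 + b * (x - mean(x)) + rnorm(nS, sd = sigma)
    target <- pmin(pmax(target, attMin + 0.01), attMax - 0.01)
    for (s in seq_len(nS)) {
      lam <- .solveLambda(target[s], w[, s], kIso)
      row0 <- 0L
      for (i in seq_len(nG)) {
        k <- kIso[i]
        p <- rep(lam / k, k)
        p[1L] <- p[1L] + (1 - lam)
        isoform[row0 + seq_len(k), s] <- expression[i, s] * p
        row0 <- row0 + k
      }
    }
  } else {
    row0 <- 0L
    for (i in seq_len(nG)) {
      k <- kIso[i]
      a <- matrix(rgamma(k * nS, shape = 2), nrow = k)
      p <- sweep(a, 2L, colSums(a), "/")
      isoform[row0 + seq_len(k), ] <-
        sweep(p, 2L, expression[i, ], "*")
      row0 <- row0 + k
    }
  }
  if (nD > 0L) {
    for (i in seq_len(nD)) truthRows[[i]]$entropy_coupling <-
      ifelse(is.na(realizedSlope[i]), truthRows[[i]]$entropy_coupling,
             realizedSlope[i])
  }

  ## regulatory tracks: background chunk coverage plus guaranteed coverage
  ## of planted in-track sites; planted out-of-track sites are guarded
  trs <- list()
  for (kind in c("dnase", "chip")) {
    if (!config@layersEnabled[[kind]]) next
    rows <- list()
    flag <- if (kind == "dnase") "inDnase" else "inChip"
    for (g in genes) {
      excl <- integer()
      pp <- plantedPos[[g]]
      if (!is.null(pp) && !pp[[flag]]) excl <- pp$pos
      rows <- c(rows, .backgroundTrack(models[[g]], config@trackCoverage,
                                       excl))
      if (!is.null(pp) && pp[[flag]]) {
        rows[[length(rows) + 1L]] <- c(min(pp$pos) - 5L, max(pp$pos) + 5L)
      }
    }
    m <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(m[, 1L], m[, 2L]))
    metadata(gr)$kind <- kind
    metadata(gr)$name <- paste0("synthetic_", kind)
    trs[[kind]] <- gr
  }

  ## copy-number flags on background carrier pairs only
  cna <- .emptyCnaFlags()
  if (config@cnaRate > 0) {
    for (j in seq_along(mutRows)) {
      m <- mutRows[[j]]
      if (m$planted) next
      hit <- m$samples[runif(length(m$samples)) < config@cnaRate]
      if (length(hit)) {
        cna <- rbind(cna, data.frame(gene = m$gene, sample = hit,
                                     stringsAsFactors = FALSE))
      }
    }
  }

  cohort <- DuonCohort(
    mutations = mutations, expression = expression,
    isoformExpression = isoform, isoformToGene = isoGene,
    allelicCounts = allelic, purity = pur, cnaFlags = cna, tracks = trs,
    pwms = pwmLib, geneModels = models,
    sequences = Biostrings::DNAStringSet(seqList),
    knownVariants = knownKeys)
  truth <- if (length(truthRows)) do.call(rbind, truthRows) else
    data.frame()
  list(cohort = cohort, truth = truth)
}
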