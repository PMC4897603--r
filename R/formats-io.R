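## Reading and writing every external file the pipeline touches.
## Mutation tables are 1-based; BED tracks and exon tables are 0-based
## half-open and converted to in-memory (GRanges, 1-based) form exactly
## once, here.

#' Read a mutation table
#'
#' Reads a MAF-like tab-separated mutation table with one row per
#' (variant, sample) and aggregates rows into one record per distinct
#' (chrom, pos, ref, alt, gene) with the carrier samples collected into a
#' list-column. The sum of carrier counts equals the number of input rows.
#'
#' @param path path to a TSV with header columns chrom, pos, ref, alt,
#'   gene, sample, consequence and optionally protein_change.
#' @return data.frame with columns chrom, pos, ref, alt, gene, consequence,
#'   protein_change and list-column \code{samples}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tpos\tref\talt\tgene\tsample\tconsequence",
#'              "chr1\t101\tC\tA\tG1\tS1\tmissense",
#'              "chr1\t101\tC\tA\tG1\tS2\tmissense"), tf)
#' readMutationTable(tf)$samples
#' @export
readMutationTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("chrom", "pos", "ref", "alt", "gene", "sample", "consequence")
  missingCols <- setdiff(required, names(df))
  if (length(missingCols)) {
    .stopf("mutation table %s is missing required column(s): %s", path,
           paste(missingCols, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(.emptyMutations())
  }
  posNum <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(posNum) | posNum != as.numeric(df$pos))
  if (length(bad)) {
    .stopf("mutation table %s: non-integer pos '%s' at data line %d", path,
           df$pos[bad[1L]], bad[1L])
  }
  df$pos <- posNum
  badCons <- which(!df$consequence %in% .CONSEQUENCES)
  if (length(badCons)) {
    .stopf("mutation table %s: unknown consequence '%s' at data line %d",
           path, df$consequence[badCons[1L]], badCons[1L])
  }
  if (is.null(df$protein_change)) df$protein_change <- ""
  key <- .mutKey(df$chrom, df$pos, df$ref, df$alt)
  key <- paste(key, df$gene, sep = ":")
  first <- !duplicated(key)
  out <- df[first, c("chrom", "pos", "ref", "alt", "gene", "consequence",
                     "protein_change")]
  out$samples <- unname(split(df$sample, factor(key, levels = key[first])))
  rownames(out) <- NULL
  out
}

#' Write a mutation table
#'
#' Inverse of \code{\link{readMutationTable}}: expands the carrier
#' list-column back to one row per (variant, sample).
#'
#' @param mutations mutation data.frame with list-column \code{samples}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeMutationTable <- function(mutations, path) {
  n <- lengths(mutations$samples)
  flat <- data.frame(
    chrom = rep(mutations$chrom, n), pos = rep(mutations$pos, n),
    ref = rep(mutations$ref, n), alt = rep(mutations$alt, n),
    gene = rep(mutations$gene, n),
    sample = unlist(mutations$samples, use.names = FALSE),
    consequence = rep(mutations$consequence, n),
    protein_change = rep(mutations$protein_change, n),
    stringsAsFactors = FALSE)
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED regulatory track
#'
#' Reads a BED3/BED6 file of DNase-hypersensitivity or ChIP-peak intervals.
#' BED coordinates are 0-based half-open; the returned \code{GRanges} is
#' 1-based inclusive (the conversion happens only here). Intervals are kept
#' exactly as given - overlapping lines are not merged - and zero-length
#' intervals are rejected.
#'
#' @param path BED file path.
#' @param kind "dnase" or "chip"; stored in \code{metadata()$kind}.
#' @param name track label; defaults to the file name.
#' @return \code{GRanges} with \code{metadata()} entries \code{kind} and
#'   \code{name}; BED name fields (column 4) are kept in
#'   \code{mcols()$factor}.
#' @export
readBedTrack <- function(path, kind = c("dnase", "chip"),
                         name = basename(path)) {
  kind <- match.arg(kind)
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) {
                   .stopf("failed to parse BED file %s: %s", path,
                          conditionMessage(e))
                 })
  if (any(GenomicRanges::width(gr) < 1L)) {
    .stopf("BED file %s contains zero-length interval(s) (start >= end)",
           path)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    ranges = IRanges::IRanges(GenomicRanges::start(gr),
                              GenomicRanges::end(gr)))
  bed <- tryCatch(rtracklayer::import(path, format = "bed"),
                  error = function(e) NULL)
  if (!is.null(bed) && !is.null(bed$name)) mcols(gr)$factor <- bed$name
  metadata(gr)$kind <- kind
  metadata(gr)$name <- name
  gr
}

#' Write a BED regulatory track
#'
#' @param gr GRanges track (1-based inclusive in memory; written as 0-based
#'   half-open BED).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBedTrack <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  if (!is.null(mcols(gr)$factor)) df$name <- mcols(gr)$factor
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read JASPAR-format position weight matrices
#'
#' Parses JASPAR 2016 text: a '>' header with motif id and TF name followed
#' by four rows (A, C, G, T) of counts or probabilities, with or without
#' the bracketed row style. Count matrices are converted to probabilities
#' with a per-cell pseudocount (Laplace smoothing); matrices whose columns
#' already sum to 1 are passed through unchanged.
#'
#' @param path JASPAR text file.
#' @param pseudocount per-cell pseudocount used for count-to-probability
#'   conversion (default 0.25).
#' @return Named list of 4 x L probability matrices (rownames A,C,G,T) with
#'   attributes \code{motif_id} and \code{tf_name}.
#' @examples
#' tf <- tempfile(fileext = ".jaspar")
#' writeLines(c(">MA0001.1 TFX",
#'              "A [ 0 0 ]", "C [ 0 0 ]", "G [ 10 10 ]", "T [ 0 0 ]"), tf)
#' readJasparPwm(tf)[[1]]["G", 1]  # (10 + 0.25) / 11
#' @export
readJasparPwm <- function(path, pseudocount = 0.25) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (!length(headers)) .stopf("no '>' motif headers found in %s", path)
  out <- list()
  bounds <- c(headers, length(lines) + 1L)
  for (i in seq_along(headers)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4L) {
      .stopf("motif block %d in %s must have 4 matrix rows, found %d", i,
             path, length(block))
    }
    hdr <- sub("^>\\s*", "", lines[headers[i]])
    parts <- strsplit(trimws(hdr), "\\s+")[[1]]
    motifId <- parts[1L]
    tfName <- if (length(parts) > 1L) parts[2L] else parts[1L]
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("\\[|\\]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) {
      .stopf("motif %s in %s has rows of unequal length (%s)", motifId,
             path, paste(lens, collapse = ","))
    }
    m <- do.call(rbind, rows)
    rownames(m) <- .BASES
    if (any(m < 0)) .stopf("motif %s in %s has negative entries", motifId, path)
    if (all(abs(colSums(m) - 1) <= 1e-6)) {
      pwm <- m
    } else {
      pwm <- sweep(m + pseudocount, 2L, colSums(m) + 4 * pseudocount, "/")
    }
    attr(pwm, "motif_id") <- motifId
    attr(pwm, "tf_name") <- tfName
    out[[motifId]] <- pwm
  }
  out
}

#' Write PWMs in JASPAR text format
#'
#' @param pwms named list of probability matrices as returned by
#'   \code{\link{readJasparPwm}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeJasparPwm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(pwms)) {
    m <- pwms[[id]]
    tf <- attr(m, "tf_name")
    if (is.null(tf)) tf <- id
    writeLines(sprintf(">%s %s", id, tf), con)
    for (b in .BASES) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(m[b, ], digits = 15), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Exclude known (common) variants from a mutation set
#'
#' Removes mutations whose full (chrom, pos, ref, alt) key appears in the
#' known-variant catalog. Matching is exact-key, not position-only, so a
#' somatic event at a polymorphic site with a different alternate allele is
#' retained.
#'
#' @param mutations mutation data.frame (list-column \code{samples}).
#' @param knownVariants character vector of "chrom:pos:ref:alt" keys, or a
#'   data.frame with columns chrom, pos, ref, alt.
#' @return \code{list(kept = ..., removed = ...)}; the two data.frames
#'   partition the input.
#' @export
filterKnownVariants <- function(mutations, knownVariants) {
  if (is.data.frame(knownVariants)) {
    knownVariants <- .mutKey(knownVariants$chrom, knownVariants$pos,
                             knownVariants$ref, knownVariants$alt)
  }
  key <- .mutKey(mutations$chrom, mutations$pos, mutations$ref,
                 mutations$alt)
  hit <- key %in% knownVariants
  list(kept = mutations[!hit, , drop = FALSE],
       removed = mutations[hit, , drop = FALSE])
}

#' Read an expression (or isoform-expression) matrix
#'
#' @param path TSV whose first column holds feature ids and remaining
#'   columns one sample each. Values are assumed already normalized.
#' @return Numeric matrix, features x samples.
#' @export
readExpressionMatrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix
#'
#' @param m features x samples matrix.
#' @param path output TSV path.
#' @param idColumn name for the feature-id column.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(m, path, idColumn = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-model table
#'
#' One exon per row; exon coordinates are 0-based half-open. Exons are
#' sorted per gene and must not overlap.
#'
#' @param path TSV with columns gene, chrom, strand, exon_start, exon_end.
#' @return Named list of gene models (\code{list(chrom, strand, exons)}).
#' @export
readGeneModels <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "strand", "exon_start", "exon_end")
  missingCols <- setdiff(need, names(df))
  if (length(missingCols)) {
    .stopf("gene-model table %s missing column(s): %s", path,
           paste(missingCols, collapse = ", "))
  }
  models <- list()
  for (g in unique(df$gene)) {
    sub <- df[df$gene == g, , drop = FALSE]
    ex <- cbind(start = as.integer(sub$exon_start),
                end = as.integer(sub$exon_end))
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    if (any(ex[, 1L] >= ex[, 2L]) ||
        (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))) {
      .stopf("gene %s in %s: exons must be non-empty and non-overlapping",
             g, path)
    }
    models[[g]] <- list(chrom = sub$chrom[1L], strand = sub$strand[1L],
                        exons = ex)
  }
  models
}

#' Write a gene-model table
#'
#' @param models named list of gene models.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  rows <- lapply(names(models), function(g) {
    gm <- models[[g]]
    data.frame(gene = g, chrom = gm$chrom, strand = gm$strand,
               exon_start = gm$exons[, 1L], exon_end = gm$exons[, 2L],
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## Fixed file names of an on-disk cohort directory.
.cohortFiles <- function(dir) {
  list(mutations = file.path(dir, "mutations.tsv"),
       expression = file.path(dir, "expression.tsv"),
       isoforms = file.path(dir, "isoform_expression.tsv"),
       isoformMap = file.path(dir, "isoform_map.tsv"),
       allelic = file.path(dir, "allelic_counts.tsv"),
       purity = file.path(dir, "purity.tsv"),
       cna = file.path(dir, "cna_flags.tsv"),
       dnase = file.path(dir, "track_dnase.bed"),
       chip = file.path(dir, "track_chip.bed"),
       pwms = file.path(dir, "pwms.jaspar"),
       models = file.path(dir, "gene_models.tsv"),
       fasta = file.path(dir, "gene_sequences.fa"),
       known = file.path(dir, "known_variants.tsv"),
       truth = file.path(dir, "truth_table.tsv"))
}

#' Write a cohort to a directory of plain-text files
#'
#' Serializes every component of a \linkS4class{DuonCohort} into the
#' package's on-disk layout (TSV tables, BED tracks, JASPAR PWMs, FASTA
#' sequences). \code{\link{readCohort}} reproduces the in-memory object.
#'
#' @param cohort a \linkS4class{DuonCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- .cohortFiles(dir)
  writeMutationTable(mutations(cohort), f$mutations)
  writeExpressionMatrix(expressionMatrix(cohort), f$expression, "gene")
  writeExpressionMatrix(isoformExpression(cohort), f$isoforms, "isoform")
  write.table(data.frame(isoform = names(isoformToGene(cohort)),
                         gene = unname(isoformToGene(cohort)),
                         stringsAsFactors = FALSE),
              f$isoformMap, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(allelicCounts(cohort), f$allelic, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = names(purity(cohort)),
                         purity = unname(purity(cohort)),
                         stringsAsFactors = FALSE),
              f$purity, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cnaFlags(cohort), f$cna, sep = "\t", quote = FALSE,
              row.names = FALSE)
  dn <- tracksOfKind(cohort, "dnase")
  if (!is.null(dn)) writeBedTrack(dn, f$dnase)
  ch <- tracksOfKind(cohort, "chip")
  if (!is.null(ch)) writeBedTrack(ch, f$chip)
  if (length(pwms(cohort))) writeJasparPwm(pwms(cohort), f$pwms)
  writeGeneModels(geneModels(cohort), f$models)
  if (length(geneSequences(cohort)))
    Biostrings::writeXStringSet(geneSequences(cohort), f$fasta)
  kv <- knownVariants(cohort)
  kvParts <- strsplit(kv, ":", fixed = TRUE)
  write.table(data.frame(
    chrom = vapply(kvParts, `[`, "", 1L),
    pos = vapply(kvParts, `[`, "", 2L),
    ref = vapply(kvParts, `[`, "", 3L),
    alt = vapply(kvParts, `[`, "", 4L), stringsAsFactors = FALSE),
    f$known, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory
#'
#' @param dir directory written by \code{\link{writeCohort}} (or assembled
#'   by hand in the same layout; the tracks, PWMs, allelic counts, purity
#'   and known-variant files are optional).
#' @return A validated \linkS4class{DuonCohort}.
#' @export
readCohort <- function(dir) {
  f <- .cohortFiles(dir)
  for (req in c("mutations", "expression", "models")) {
    if (!file.exists(f[[req]])) {
      .stopf("cohort directory %s is missing %s", dir, basename(f[[req]]))
    }
  }
  muts <- readMutationTable(f$mutations)
  expr <- readExpressionMatrix(f$expression)
  iso <- if (file.exists(f$isoforms)) readExpressionMatrix(f$isoforms) else
    matrix(0, 0, ncol(expr), dimnames = list(NULL, colnames(expr)))
  isoMap <- character()
  if (file.exists(f$isoformMap)) {
    md <- read.delim(f$isoformMap, stringsAsFactors = FALSE)
    isoMap <- setNames(md$gene, md$isoform)
  }
  ac <- if (file.exists(f$allelic)) {
    read.delim(f$allelic, stringsAsFactors = FALSE,
               colClasses = c(chrom = "character", ref = "character",
                              alt = "character", sample = "character"))
  } else .emptyAllelicCounts()
  pur <- numeric()
  if (file.exists(f$purity)) {
    pd <- read.delim(f$purity, stringsAsFactors = FALSE)
    pur <- setNames(pd$purity, pd$sample)
  }
  cna <- if (file.exists(f$cna)) {
    read.delim(f$cna, stringsAsFactors = FALSE, colClasses = "character")
  } else .emptyCnaFlags()
  trs <- list()
  if (file.exists(f$dnase)) trs$dnase <- readBedTrack(f$dnase, "dnase")
  if (file.exists(f$chip)) trs$chip <- readBedTrack(f$chip, "chip")
  pw <- if (file.exists(f$pwms)) readJasparPwm(f$pwms) else list()
  models <- readGeneModels(f$models)
  seqs <- if (file.exists(f$fasta)) Biostrings::readDNAStringSet(f$fasta)
          else Biostrings::DNAStringSet()
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  kv <- character()
  if (file.exists(f$known)) {
    kd <- read.delim(f$known, stringsAsFactors = FALSE,
                     colClasses = "character")
    if (nrow(kd)) kv <- .mutKey(kd$chrom, kd$pos, kd$ref, kd$alt)
  }
  DuonCohort(mutations = muts, expression = expr, isoformExpression = iso,
             isoformToGene = isoMap, allelicCounts = ac, purity = pur,
             cnaFlags = cna, tracks = trs, pwms = pw, geneModels = models,
             sequences = seqs, knownVariants = kv)
}
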