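## Internal helpers: coordinate arithmetic and allele normalization.
## Conventions (fixed package-wide): mutation positions are 1-based
## (MAF/VCF style); exon and track intervals are 0-based half-open (BED
## style); conversion happens exactly once, at read time for tracks and in
## these helpers for mutations.

.LAYERS <- c("R", "E", "D", "A", "C", "T")
.CONSEQUENCES <- c("missense", "inframe_del", "inframe_ins", "other")
.BASES <- c("A", "C", "G", "T")

.mutKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

.cleanAllele <- function(x) {
  x <- toupper(as.character(x))
  x[x %in% c("-", ".", "")] <- ""
  x
}

## Trim the common prefix, then the common suffix, of ref/alt so that `ref`
## spans exactly the changed reference bases and `pos` points at the first
## changed base (or the first inserted position for pure insertions).
normalizeMutation <- function(pos, ref, alt) {
  ref <- .cleanAllele(ref)
  alt <- .cleanAllele(alt)
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 0L && length(a) > 0L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos <- pos + 1L
  }
  while (length(r) > 0L && length(a) > 0L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  list(pos = as.integer(pos),
       ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

## 1-based genomic footprint of the changed bases: deletions/substitutions
## cover every changed reference base; a pure insertion is anchored to the
## base immediately left of the insertion point.
mutationFootprint <- function(pos, ref, alt) {
  nm <- normalizeMutation(pos, ref, alt)
  if (nchar(nm$ref) > 0L) {
    c(start = nm$pos, end = nm$pos + nchar(nm$ref) - 1L)
  } else {
    anchor <- max(nm$pos - 1L, 1L)
    c(start = anchor, end = anchor)
  }
}

## exons: integer matrix with columns start, end; 0-based half-open,
## sorted, non-overlapping. Offsets into the spliced (concatenated exon)
## sequence are 0-based.
.exonWidths <- function(exons) exons[, 2L] - exons[, 1L]

splicedLength <- function(exons) sum(.exonWidths(exons))

## 0-based spliced offset of a 1-based genomic position; NA if intronic.
splicedOffset <- function(exons, genomicPos) {
  g0 <- genomicPos - 1L
  cum <- cumsum(c(0L, .exonWidths(exons)))
  for (i in seq_len(nrow(exons))) {
    if (g0 >= exons[i, 1L] && g0 < exons[i, 2L]) {
      return(cum[i] + (g0 - exons[i, 1L]))
    }
  }
  NA_integer_
}

## Inverse mapping: 0-based spliced offset -> 1-based genomic position.
genomicFromSpliced <- function(exons, offset0) {
  cum <- cumsum(c(0L, .exonWidths(exons)))
  i <- findInterval(offset0, cum, rightmost.closed = FALSE)
  i[offset0 >= cum[length(cum)]] <- NA_integer_
  as.integer(exons[i, 1L] + (offset0 - cum[i]) + 1L)
}

## Logical vector over the spliced sequence: which exonic bases fall inside
## any interval of `gr` (a GRanges on the same chromosome)?
splicedCoverage <- function(exons, chrom, gr) {
  L <- splicedLength(exons)
  cov <- logical(L)
  if (length(gr) == 0L) {
    return(cov)
  }
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  if (length(gr) == 0L) {
    return(cov)
  }
  cum <- cumsum(c(0L, .exonWidths(exons)))
  s1 <- GenomicRanges::start(gr) # 1-based inclusive
  e1 <- GenomicRanges::end(gr)
  for (i in seq_len(nrow(exons))) {
    exS <- exons[i, 1L] + 1L
    exE <- exons[i, 2L]
    for (j in seq_along(s1)) {
      lo <- max(exS, s1[j])
      hi <- min(exE, e1[j])
      if (lo <= hi) {
        cov[(cum[i] + (lo - exS) + 1L):(cum[i] + (hi - exS) + 1L)] <- TRUE
      }
    }
  }
  cov
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assertSeed <- function(seed) {
  if (is.null(seed) || length(seed) != 1L || is.na(seed)) {
    .stopf("a single non-missing integer 'seed' is required")
  }
  as.integer(seed)
}

## Derive a stream of child seeds (< 2^31) from one master seed.
.childSeeds <- function(seed, n) {
  set.seed(.assertSeed(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
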