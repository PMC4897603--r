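## T layer: transcription-factor binding-motif gain/loss.
##
## Scores are log-odds against a uniform base background (0.25); a site
## "passes" when its score reaches a configurable fraction of the PWM's
## maximum attainable score. Both strands are scanned by also scoring the
## reverse-complemented PWM on the + strand sequence.

.PROB_FLOOR <- 1e-9

.seqToInt <- function(chars) {
  v <- match(chars, .BASES)
  v[is.na(v)] <- 5L # unknown base sentinel; scores as the probability floor
  v
}

.pwmLogOdds <- function(pwm, background = 0.25) {
  lo <- log2(pmax(pwm, .PROB_FLOOR) / background)
  rbind(lo, rep(log2(.PROB_FLOOR / background), ncol(lo)))
}

.pwmMaxScore <- function(lo) sum(apply(lo[1:4, , drop = FALSE], 2L, max))

.revcompLogOdds <- function(lo) {
  rc <- lo[c(4L, 3L, 2L, 1L, 5L), rev(seq_len(ncol(lo))), drop = FALSE]
  rownames(rc) <- rownames(lo)
  rc
}

## Sliding-window scores of one log-odds matrix over an integer-coded
## sequence; returns numeric(0) when the sequence is shorter than the motif.
.windowScores <- function(v, lo) {
  Lp <- ncol(lo)
  n <- length(v)
  if (n < Lp) {
    return(numeric(0L))
  }
  starts <- seq_len(n - Lp + 1L)
  acc <- numeric(length(starts))
  for (k in seq_len(Lp)) {
    acc <- acc + lo[(k - 1L) * 5L + v[starts + k - 1L]]
  }
  acc
}

## Per-PWM, per-strand precomputation against a full spliced sequence.
.pwmPrecompute <- function(pwms, scoreFraction, seqChars = NULL) {
  out <- list()
  for (id in names(pwms)) {
    pwm <- pwms[[id]]
    tf <- attr(pwm, "tf_name")
    if (is.null(tf)) tf <- id
    lo <- .pwmLogOdds(pwm)
    thr <- scoreFraction * .pwmMaxScore(lo)
    for (strand in c("+", "-")) {
      m <- if (strand == "+") lo else .revcompLogOdds(lo)
      entry <- list(id = id, tf = tf, lo = m, thr = thr, Lp = ncol(m))
      if (!is.null(seqChars)) {
        v <- .seqToInt(seqChars)
        entry$W <- .windowScores(v, m)
        entry$pass <- entry$W >= thr
      }
      out[[paste(id, strand)]] <- entry
    }
  }
  out
}

## Best score and pass flag of each PWM (max over both strands) in a short
## window; returns per-motif-id logical pass and the overall best score.
.scanWindow <- function(winChars, precomp) {
  v <- .seqToInt(winChars)
  ids <- unique(vapply(precomp, `[[`, "", "id"))
  pass <- setNames(logical(length(ids)), ids)
  best <- setNames(rep(-Inf, length(ids)), ids)
  for (e in precomp) {
    sc <- .windowScores(v, e$lo)
    if (length(sc)) {
      b <- max(sc)
      if (b > best[[e$id]]) best[[e$id]] <- b
      if (b >= e$thr) pass[[e$id]] <- TRUE
    }
  }
  list(pass = pass, best = best)
}

## Build the wild-type and mutant windows around a (normalized) mutation in
## spliced coordinates. s1/e1: 1-based first/last changed base (for pure
## insertions s1 = anchor, e1 = anchor and the alt is inserted after it).
.mutationWindows <- function(seqChars, s1, e1, alt, insertion, maxL) {
  L <- length(seqChars)
  a <- max(1L, s1 - (maxL - 1L))
  b <- min(L, e1 + (maxL - 1L))
  wt <- seqChars[a:b]
  rs <- s1 - a + 1L
  re <- e1 - a + 1L
  altChars <- if (nchar(alt)) strsplit(alt, "")[[1]] else character()
  if (insertion) {
    mut <- c(wt[seq_len(rs)], altChars,
             if (re < length(wt)) wt[(re + 1L):length(wt)] else character())
  } else {
    mut <- c(if (rs > 1L) wt[seq_len(rs - 1L)] else character(), altChars,
             if (re < length(wt)) wt[(re + 1L):length(wt)] else character())
  }
  list(wt = wt, mut = mut)
}

#' Scan a mutation for transcription-factor motif gain or loss
#'
#' Extracts the exonic window spanning the mutation plus (max motif length
#' - 1) bases of flank, applies the mutation, and scans every PWM over
#' every offset of both windows and both strands. A PWM "passes" in a
#' window when some placement reaches \code{scoreFraction} of that PWM's
#' maximum attainable log-odds score (uniform background). The effect is
#' "gain" when some PWM passes only in the mutant window, "loss" when some
#' PWM passes only in the wild-type window ("gain" takes precedence in the
#' effect label when both occur for different PWMs; both TF lists are
#' returned).
#'
#' @param pos,ref,alt the mutation (1-based genomic position; "-" or ""
#'   denotes an empty allele).
#' @param geneModel gene model (\code{list(chrom, strand, exons)}).
#' @param sequence spliced + strand coding sequence (character or
#'   \code{DNAString}).
#' @param pwms named list of PWM probability matrices.
#' @param scoreFraction pass threshold as a fraction of the maximum score
#'   (default 0.8).
#' @return A \linkS4class{MotifPerturbation}.
#' @export
scanMotifPerturbation <- function(pos, ref, alt, geneModel, sequence, pwms,
                                  scoreFraction = 0.8) {
  if (!length(pwms)) {
    return(new("MotifPerturbation"))
  }
  seqChars <- strsplit(as.character(sequence), "")[[1]]
  nm <- normalizeMutation(pos, ref, alt)
  insertion <- nchar(nm$ref) == 0L
  anchorPos <- if (insertion) max(nm$pos - 1L, 1L) else nm$pos
  off <- splicedOffset(geneModel$exons, anchorPos)
  if (is.na(off)) {
    .stopf("mutation position %d lies outside the gene's exons", pos)
  }
  s1 <- off + 1L
  e1 <- if (insertion) s1 else s1 + nchar(nm$ref) - 1L
  if (e1 > length(seqChars)) {
    .stopf("mutation reference allele extends past the coding sequence")
  }
  maxL <- max(vapply(pwms, ncol, integer(1L)))
  win <- .mutationWindows(seqChars, s1, e1, nm$alt, insertion, maxL)
  precomp <- .pwmPrecompute(pwms, scoreFraction)
  wt <- .scanWindow(win$wt, precomp)
  mu <- .scanWindow(win$mut, precomp)
  tfOf <- vapply(pwms, function(m) {
    tf <- attr(m, "tf_name")
    if (is.null(tf)) "" else tf
  }, character(1L))
  gainIds <- names(which(mu$pass & !wt$pass))
  lossIds <- names(which(wt$pass & !mu$pass))
  effect <- if (length(gainIds)) "gain" else if (length(lossIds)) "loss" else
    "none"
  new("MotifPerturbation", effect = effect,
      gainTfs = unname(tfOf[gainIds]), lossTfs = unname(tfOf[lossIds]),
      wtBestScore = max(wt$best), mutBestScore = max(mu$best))
}

## Effect (any motif gain or loss) of placing the analogous edit at spliced
## position s1 (1-based). Used by the permutation null; shares the window
## semantics of scanMotifPerturbation.
.motifEffectAt <- function(seqChars, s1, refLen, alt, insertion, precomp,
                           maxL) {
  e1 <- if (insertion) s1 else s1 + refLen - 1L
  win <- .mutationWindows(seqChars, s1, e1, alt, insertion, maxL)
  wt <- .scanWindow(win$wt, precomp)
  mu <- .scanWindow(win$mut, precomp)
  any(mu$pass != wt$pass)
}

#' Permutation p-value for motif perturbation
#'
#' Null model for the T layer, analogous to
#' \code{\link{permutationOverlapP}}: the same edit (substitution of the
#' alternate bases, deletion of the same number of bases, or insertion of
#' the same bases) is placed uniformly at random over the gene's exonic
#' sequence \code{nPerm} times, and the p-value is the fraction of
#' placements that produce any motif gain or loss. Single-base
#' substitutions use an exact incremental rescoring fast path.
#'
#' @inheritParams scanMotifPerturbation
#' @param nPerm number of shuffles (default 1000).
#' @param seed RNG seed.
#' @param estimator "n/N" or "add-one".
#' @return Permutation p-value in [0,1].
#' @export
permutationMotifP <- function(pos, ref, alt, geneModel, sequence, pwms,
                              scoreFraction = 0.8, nPerm = 1000L,
                              seed = NULL, estimator = c("n/N", "add-one")) {
  estimator <- match.arg(estimator)
  if (!length(pwms)) {
    return(if (estimator == "n/N") 0 else 1 / (nPerm + 1))
  }
  seqChars <- strsplit(as.character(sequence), "")[[1]]
  L <- length(seqChars)
  nm <- normalizeMutation(pos, ref, alt)
  insertion <- nchar(nm$ref) == 0L
  refLen <- nchar(nm$ref)
  maxL <- max(vapply(pwms, ncol, integer(1L)))
  if (!is.null(seed)) set.seed(.assertSeed(seed))
  if (refLen == 1L && nchar(nm$alt) == 1L) {
    n <- .snvMotifPermCount(seqChars, nm$alt, pwms, scoreFraction, nPerm,
                            maxL)
  } else {
    nPlace <- if (insertion) L else L - refLen + 1L
    if (nPlace < 1L) .stopf("edit longer than the coding sequence")
    precomp <- .pwmPrecompute(pwms, scoreFraction)
    draws <- sample.int(nPlace, nPerm, replace = TRUE)
    n <- 0L
    for (o in draws) {
      n <- n + .motifEffectAt(seqChars, o, refLen, nm$alt, insertion,
                              precomp, maxL)
    }
  }
  if (estimator == "n/N") n / nPerm else (n + 1) / (nPerm + 1)
}

## Vectorized SNV permutation: mutant window scores differ from wild-type
## scores only in the single column covering the edited base, so each
## draw's mutant scores are W[s] + lo[alt, col] - lo[ref, col].
.snvMotifPermCount <- function(seqChars, altBase, pwms, scoreFraction,
                               nPerm, maxL) {
  v <- .seqToInt(seqChars)
  L <- length(v)
  precomp <- .pwmPrecompute(pwms, scoreFraction, seqChars = seqChars)
  draws <- sample.int(L, nPerm, replace = TRUE)
  a <- .seqToInt(altBase)
  changed <- v[draws] != a
  effect <- logical(nPerm)
  ids <- unique(vapply(precomp, `[[`, "", "id"))
  for (id in ids) {
    ## pass flags are per PWM, aggregated over both strands
    passWt <- logical(nPerm)
    passMut <- logical(nPerm)
    for (e in Filter(function(x) x$id == id, precomp)) {
      Lp <- e$Lp
      nStarts <- L - Lp + 1L
      if (nStarts < 1L) next
      ## window starts span o-(maxL-1) .. o+(maxL-1)-Lp+1; those covering
      ## the edit (offsets -(Lp-1)..0) are rescored, the rest reuse the
      ## wild-type pass flags.
      for (d in seq.int(-(maxL - 1L), maxL - Lp)) {
        s <- draws + d
        ok <- s >= 1L & s <= nStarts
        if (!any(ok)) next
        wtHit <- ok & e$pass[pmax(s, 1L)]
        passWt <- passWt | wtHit
        if (d >= -(Lp - 1L) && d <= 0L) {
          col <- 1L - d
          idx <- (col - 1L) * 5L
          mutScore <- e$W[pmax(s, 1L)] + e$lo[idx + a] - e$lo[idx + v[draws]]
          passMut <- passMut | (ok & mutScore >= e$thr)
        } else {
          passMut <- passMut | wtHit
        }
      }
    }
    effect <- effect | (changed & (passWt != passMut))
  }
  sum(effect)
}
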