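## Independent oracles (enumeration / hand rules) and small fixture
## builders used across the suite. These deliberately avoid the code paths
## they are checking.

## Exact two-sided Mann-Whitney p by enumerating every assignment of the
## pooled values to the two groups (valid without ties: the U distribution
## is symmetric, so the |U - mu| rule equals the doubled tail).
enumWilcoxP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idxs <- utils::combn(seq_along(pooled), n1)
  uOf <- function(idx) {
    sum(outer(pooled[idx], pooled[-idx], ">")) +
      0.5 * sum(outer(pooled[idx], pooled[-idx], "=="))
  }
  us <- apply(idxs, 2L, uOf)
  obs <- uOf(seq_len(n1))
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

## Exact two-sided binomial p: sum of point masses no larger than the
## observed one (the conventional small-p method).
enumBinomP <- function(x, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[x + 1L] * (1 + 1e-7)])
}

## Benjamini-Hochberg step-up applied by hand.
handBH <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, ps[i] * n / i)
    q[i] <- running
  }
  out <- numeric(n)
  out[ord] <- q
  out
}

## A sharply specific PWM from a consensus string.
makeTestPwm <- function(consensus, p = 0.97, id = "TST0001.1", tf = "TFX") {
  cons <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - p) / 3, nrow = 4L, ncol = length(cons),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(cons)) m[cons[j], j] <- p
  attr(m, "motif_id") <- id
  attr(m, "tf_name") <- tf
  m
}

## Single-exon gene model starting at 0-based `start`.
singleExonModel <- function(len, chrom = "chr1", start = 0L) {
  list(chrom = chrom, strand = "+",
       exons = cbind(start = as.integer(start),
                     end = as.integer(start + len)))
}

## Evidence map builders for score assembly tests.
ev <- function(layer, status, p = NA_real_, dir = "none") {
  EvidenceResult(layer, status, pValue = p, direction = dir)
}

layerMap <- function(R, E, D, A, C, T) {
  stat <- function(ch, layer) {
    if (ch == "*") ev(layer, "absent")
    else if (ch == toupper(ch)) ev(layer, "consistent", 0.01)
    else ev(layer, "inconsistent", 0.5)
  }
  list(R = stat(R, "R"), E = stat(E, "E"), D = stat(D, "D"),
       A = stat(A, "A"), C = stat(C, "C"), T = stat(T, "T"))
}

## Small planted cohort used by several scoring tests.
smallPlantedSim <- function(seed, nDuons = 1L, nBackground = 20L,
                            duons = NULL) {
  if (is.null(duons)) duons <- defaultDuonSpecs(nDuons)
  generateCohort(simulationConfig(
    seed = seed, nSamples = 60L, nGenes = 30L,
    nBackgroundRecurrent = as.integer(nBackground),
    nBackgroundPrivate = 4L, nKnownContaminants = 3L,
    plantedDuons = duons))
}

fastConfig <- function(seed, ...) {
  redactConfig(seed = seed, nPerm = 500L, nPermMotif = 150L, ...)
}
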