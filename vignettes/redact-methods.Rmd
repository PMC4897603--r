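---
title: "Scoring potential duon mutations: models and methods"
author: "duonscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring potential duon mutations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duonscan)
```

# The problem

Some coding sequences are "duons": they encode amino acids and, in the
same bases, regulatory information such as a transcription-factor binding
site or an open-chromatin element. A somatic mutation in a duon can change
the protein and simultaneously change how much of that protein is made —
a dual hit whose downstream impact can be amplified (a damaging allele
that is also over-expressed) or moderated. duonscan screens a tumor
cohort's coding mutations for this signature by combining six orthogonal
evidence layers into the composite REDACT score and flagging potential
duon mutations (pDMs).

# The six evidence layers

For each candidate mutation the pipeline evaluates:

* **R — recurrence.** The mutation must be carried by at least 3 samples
  *and* by strictly more than 1% of the cohort; since both conditions
  apply, the binding constraint is whichever is greater. R is a filter,
  not a test: mutations failing it are not scored.
* **E — cohort-level expression change.** Two-sided Mann–Whitney U test
  of the gene's normalized expression in carriers versus all other
  samples (exact where feasible, tie-corrected normal approximation
  otherwise); consistent when p < 0.05. The direction (up/down) is the
  carrier-versus-rest median comparison.
* **D — DNase hypersensitivity overlap.** Deterministic overlap of the
  mutation's changed-base footprint with the DNase track (any deleted
  base suffices; insertions are anchored to the base left of the
  insertion point), plus a permutation p-value (below).
* **A — allelic expression imbalance.** Per carrier, an exact two-sided
  binomial test of the RNA-seq alt read count against a null proportion
  derived from the exome allelic fraction adjusted for tumor purity
  (below); per-sample p-values are combined with Fisher's method, and
  the layer is consistent when the combined p < 0.05 and all
  individually significant samples agree in direction. A consistent A
  whose direction contradicts E is downgraded to inconsistent: a mutant
  allele "gaining" expression while the gene overall loses it is not
  coherent dual-effect evidence.
* **C — ChIP peak overlap.** As D, against the ChIP track.
* **T — TF motif perturbation.** Every PWM is scanned over both strands
  of the wild-type and mutant exonic windows around the mutation (window
  = mutation ± max motif length − 1). A site "passes" when its log-odds
  score against a uniform background reaches 80% of that PWM's maximum
  attainable score — a widely used PWM convention, configurable via
  `motifScoreFraction`. Gain = some PWM passes only in the mutant; loss
  = only in the wild type.

Letters are encoded uppercase (consistent), lowercase (data present,
evidence inconsistent) or `*` (data layer absent). A pDM requires
uppercase R, E and at least one of D, C, T. Copy-number alterations at
the locus are annotated (`cna_flagged`), not used for exclusion: they are
a confounder check, not a filter.

# Permutation null for the regulatory layers

The D, C and T p-values come from a deliberately simple within-gene null:
the mutation is re-placed uniformly over the gene's exonic bases `nPerm`
times and the p-value is the fraction of placements showing the feature
(track overlap, or any motif gain/loss for the same edit). The estimator
is kept as n/nPerm; note it depends only on the feature's exonic
footprint, not on the observed position, so it measures how surprising
*any* overlap within this gene would be. Defaults: `nPerm = 10000` for
D/C (cheap coverage lookups) and `nPermMotif = 1000` for T, whose
placements require rescoring the windows that cross the edit;
single-base substitutions use an exact incremental rescoring fast path,
indels re-scan their windows directly. A gene fully covered by a track
yields p = 1 for every mutation in it — weak evidence by construction,
which is why the combined p-value is read alongside the letter code
rather than instead of it. An `(n+1)/(nPerm+1)` estimator is available
(`permEstimator = "add-one"`) for users needing strictly positive
p-values.

# The allelic-imbalance null and tumor purity

The exome VAF of a clonal heterozygous mutation in an impure tumor
understates the tumor-cell allele dose. With c = VAF/purity, the null RNA
alt proportion is

p0 = min( max(c/2, min(c, 0.5)), 1 ).

While c ≤ 1 — the range a fully clonal het can produce — the null is the
corrected VAF capped at the heterozygous expectation 0.5; when c exceeds
1 the DNA itself indicates loss of the wild-type allele, and the cap
relaxes continuously (c/2) up to 1. The rule is continuous and monotone
in c: we found that any rule that jumps between the het cap and an
uncapped corrected VAF at a hard VAF threshold lets binomial sequencing
noise near the threshold flip the null (and hence the direction call)
for borderline samples. When purity is unavailable p0 falls back to the
raw exome VAF. The adjustment is configurable (`purityAdjust = FALSE`).
Multi-clone deconvolution is not attempted.

# Combining p-values and FDR

Per mutation, the available layer p-values among {E, A, D, C, T} (R is a
filter) are combined with Fisher's method, X = −2Σ log p ~ χ² with 2k
degrees of freedom. Permutation p-values of exactly 0 or 1 are clamped by
1/(2·nPerm) — below the estimator's resolution — so the log and probit
transforms are defined; E and A p-values are never clamped. When at least
two p-values exist, Hartung's probit-based method for correlated tests is
reported alongside: t_i = Φ⁻¹(p_i), ρ̂ = 1 − var(t) truncated below at
−1/(k−1) and regularized by Hartung's κ·√(2/(k+1))·(1−ρ̂*) term (default
κ = 0.2), T = Σt / √((1−ρ̃)k + ρ̃k²) referred to the lower normal tail.
The regularization matters: at the truncation boundary the bare variance
term is exactly zero (a 0/0 statistic), and under independent inputs the
boundary is hit with probability P(χ²ₖ₋₁ > k) ≈ 25–50%. With κ = 0.2 the
method is approximately calibrated at the scale it is used here (k ≤ 5
layers); at very large k the ρ̂k² term amplifies estimation noise and no
variant of the formula is calibrated, which is one reason Fisher is the
primary statistic. Benjamini–Hochberg q-values are computed across all
scored mutations on the Fisher p (via `stats::p.adjust`); ranked output
is ordered by (q, combined p, descending carrier count, gene) for
reproducibility.

# Pipeline order

`scoreCohort` applies: known-variant exclusion (exact
chrom:pos:ref:alt key match against the common-variant catalog — a
position-only match would discard true somatic events at polymorphic
sites) → restriction to protein-altering classes (missense, in-frame
indels; nonsense/frameshift/splice-site carriers are out of scope) →
recurrence filter → per-layer evaluation → A-direction downgrade → CNA
annotation → Fisher/Hartung combination → BH FDR → pDM flags. A layer
failure for one mutation marks that layer absent rather than aborting the
cohort. Stage counts (input, post-exclusion, protein-altering, recurrent,
pDM) are logged by `runScore`.

# Downstream analyses

* **Splicing entropy.** Shannon entropy of relative isoform abundances,
  H = −Σ p log₂ p, in bits (base 2 is the Shannon convention; any base
  rescales all comparisons identically), per gene within a sample and
  pooled over all isoforms of all genes for the sample level. All
  isoforms with abundance > 0 count ("expressed"); a minimum-abundance
  floor is available but defaults to none.
* **Entropy–expression correlation.** Pearson by default (Spearman
  available) between a gene's expression and per-sample entropy, with a
  leave-one-out diagnostic reporting how far the coefficient moves when
  any single sample is dropped — a single outlying sample can mask a
  strong association.
* **Pathway input.** Per gene, v = s·(1 − p) with p a two-sample t-test
  p-value (Welch by default — the safer choice under unequal variances;
  pooled available) and s the sign of the carrier-minus-rest mean
  difference, giving a bounded score in [−1, 1] suitable as input for
  information-theoretic pathway enrichment. The functional form is a
  reconstruction from the stated bounds and semantics of that input
  (|v| maximal as p→0, sign carrying direction); the enrichment tool
  itself is external and not reimplemented — `runDownstream` writes the
  two-column TSV it consumes.
* **Rank concordance.** Spearman correlation between mutant-allele
  expression (RNA alt fraction × gene expression) and a target gene's
  expression across carriers, compared against an expected sign.
* **Wild-type control permutation.** Draws of wild-type sample subsets
  (without replacement) build the null distribution of any supplied
  statistic; the empirical p is the two-sided fraction of draws at least
  as extreme as the observation. The statistic is a closure, so the same
  machinery serves the target-correlation control and the
  entropy-correlation control.

# The synthetic cohort generator

`generateCohort` builds a complete multi-omic cohort with known ground
truth so every pipeline stage is testable without external data. It
emulates: gene models (2–4 exons of 150–350 bp on one synthetic
chromosome) with random coding sequences; normalized continuous
expression (log-normal per-gene baselines over log2 3–8, noise SD 0.5
log2 units — count-level realism is unnecessary because the pipeline
consumes level-3-style normalized values); isoform abundances (2–5 per
gene, symmetric Dirichlet); clonal-heterozygous allelic counts under the
purity mixture VAF = p·0.5/(p·0.5 + (1−p)) at exome depth 80 and RNA
depth 60; tumor purity uniform on 0.4–0.7 (typical solid-tumor cohorts
average around 0.6, and this range keeps the mixture VAF in the
heterozygous regime); regulatory tracks covering 20% of each gene's
exonic bases in ~25 bp chunks; the three-PWM synthetic motif library; and
background recurrent (3–8 carriers), private, and known-variant
contaminant mutations.

Planted duons realize each effect class: expression shifts of ±1.5 log2
units in carriers; RNA allelic skew (alt fraction 0.8 or 0.2, paired in
direction with the expression shift — an opposing pair is expected to be
downgraded, and `expectedRedact` encodes that rule); guaranteed
regulatory-track coverage (or a guarded exclusion zone when the flag is
off); and engineered motif sites. Motif gains embed a consensus with one
broken base that the mutation restores; losses embed the full consensus
that the edit destroys; every engineered window is verified with the
production scanner and re-randomized on chance hits, so planted T letters
are deterministic. Background mutations' *null* RNA allelic fraction is
drawn at the same purity-adjusted DNA-implied expectation p0 the A test
uses — "no allelic effect" means the RNA mirrors its DNA-implied dose, so
null A p-values are calibrated under the package's own model.

Entropy coupling is realized by entropy-matched mixtures rather than by
modulating a Dirichlet concentration: each sample's target entropy is
H_s = H₀ + b·(x_s − x̄) + ε with ε ~ N(0, σ) (σ = 0.1 bits), and the
per-gene isoform distributions interpolate between uniform and
single-isoform until the pooled sample entropy matches the target
(solved by uniroot). This makes the planted bits-per-expression-unit
slope exact up to noise, which a concentration parameter does not, at the
cost of tying all genes' isoform usage to one mixing weight per sample —
a caricature of global splicing disruption that is adequate for testing
slope and correlation recovery but not per-gene splicing heterogeneity.
`entropyTargetR` plants a target Pearson correlation directly by deriving
b from the realized driver SD. Planted targets follow
baseline + sign·1.2·z(mutant-allele dose) + N(0, 0.3) in log2 units.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: read-level artifacts and mapping bias in
allelic counts, subclonal architecture (the skew parameter can mimic it
but no clone tree exists), correlated gene-gene expression structure,
realistic mutational signatures or chromatin-context-dependent mutation
rates, real PWM redundancy/degeneracy, and copy-number segments beyond a
boolean flag.

# Numerical choices and degenerate inputs

* Exact binomial two-sided p sums point probabilities ≤ the observed one
  (the conventional small-p method, as in `binom.test`); the doubling
  alternative is not used.
* Mann–Whitney is exact for small untied samples and tie-corrected
  normal otherwise (`wilcox.test` semantics).
* PWM probabilities are floored at 1e-9 before log-odds; unknown bases
  score at the floor. JASPAR count matrices get a 0.25-per-cell Laplace
  pseudocount (configurable); probability-form matrices pass through.
* Permutation p-values are clamped away from {0,1} by 1/(2·nPerm) only
  where a log/probit transform needs them.
* Zero-variance vectors make correlations undefined (NA with a warning),
  not zero; genes with zero variance in both groups get v = 0.
* All randomness flows from explicit seeds; `scoreCohort` seeds once and
  evaluates mutations in a fixed order, so identical cohort + config
  reproduce byte-identical reports.

# Problem sizes used in validation

The shipped test suite validates encoding and the statistical engines
against enumeration oracles, then runs cohort-scale checks at sizes
chosen to give stable statistics at interactive runtimes: null
calibration on 20 cohorts of 100 samples × 300 genes (~100 recurrent
background mutations each, nPerm = 1000, nPermMotif = 150),
planted-signal recovery over 10 seeds of the same cohort size with 10
planted duons, entropy-coupling recovery at n = 50 samples, and 100
seeded replicates of the target-concordance analysis.
`scripts/acceptance.R` re-runs the same battery from scratch at 5 seeds
per block.

# Known limitations

The permutation estimator's independence from the observed position makes
D/C/T p-values a gene-level, not site-level, measure; combined p-values
are therefore interpreted jointly with the letter code. The A layer
assumes one clonal population per sample. The T layer treats motif
presence as binary at the 80%-of-max threshold; affinity changes below
threshold are invisible. Strand is handled by scanning both orientations
of + strand sequences; genes are stored spliced, so motifs spanning exon
junctions in the mRNA are scanned while motifs spanning intronic DNA are
not.
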