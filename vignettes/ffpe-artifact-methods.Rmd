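---
title: "Methods: FFPE artifact QC, concentration-informed cutoffs, phasing and bootstrap CNV"
author: "ffpeQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FFPE artifact QC and post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffpeQC)
```

# The model

## Artifact structure of FFPE amplicon sequencing

Formalin fixation deaminates cytosine to uracil, which templates as
thymine during amplification. In variant-call terms this produces
artifact calls that are (i) dominated by the strand-symmetric C:G>T:A
class, (ii) concentrated at low allele frequency (AF), essentially
(0, 0.10], and (iii) far more numerous in degraded specimens. Degraded
input also yields low pre-normalization library concentrations, so
concentration is a usable proxy for damage. Severely degraded samples
additionally produce an artifact regime at roughly 9--20% AF, which is
the clinically dangerous one: no fixed AF threshold separates it from
genuine subclonal mutations.

The package models the per-sample artifact count as negative binomial
with mean

$$\lambda(c) = \exp(a - b \log c) = e^a c^{-b},$$

where $c$ is the pre-normalization concentration (ng/µl). The
log-linear form is the simplest strictly monotone positive-valued
choice consistent with the strong negative rank correlation seen in
such cohorts; the data only constrain monotonicity, so $a$ and $b$ are
free parameters fitted by `MASS::glm.nb` (Poisson fallback) on
non-degraded samples. Artifact AFs follow a Beta(1.2, 30) truncated to
(0, 0.10]; the high-AF regime uses Beta(2, 2) rescaled onto
[0.09, 0.20] and is active only below a 1.5 ng/µl concentration
trigger.

## Concentration-informed reporting cutoffs

For a sample at concentration $c$, the reporting cutoff is the
smallest AF $f$ with

$$\lambda(c)\,\Pr(\mathrm{AF} \ge f) \le \alpha,$$

i.e. at most $\alpha$ artifact calls expected above the cutoff
($\alpha = 1$ by default), evaluated under the truncated-Beta artifact
AF model, and never below the clinical floors (5% of covering reads
for response-associated, 2.5% for resistance-associated variants).
Since $\lambda$ decreases with $c$, cutoffs are monotone non-increasing
in concentration. The $\lambda$-survival construction is one defensible
reading of "concentration-specific expected artifact rates"; no closed
formula for the cutoff is established in the literature, which is why
both $\alpha$ and the AF model are explicit arguments.

```{r cutoff}
fit <- fitArtifactRate(
    data.frame(sample_id = sprintf("S%d", 1:6),
               pre_norm_conc = c(1.9, 3, 5, 8, 15, 30),
               degraded = FALSE),
    counts = c(210, 150, 90, 60, 35, 18))
vapply(c(1.9, 5, 30), estimateCutoff, numeric(1), fit = fit)
```

## Degraded-sample rule

A sample is flagged when its count of calls above 10% AF exceeds
`max(median + 3 * MAD, floor)` of the cohort counts, or when its
concentration is below 1.5 ng/µl. The MAD uses the usual 1.4826
consistency constant. The absolute floor (default 5) exists because a
clean cohort has near-zero MAD, which would otherwise flag ordinary
samples over one or two noisy calls; degraded samples in the motivating
regime carry at least ~8 high-AF artifacts, so any floor below that
catches them. Binomial sampling noise around a true AF just under 0.10
occasionally pushes a handful of observed AFs over the threshold in
clean samples, which is why the count rule is robust (median/MAD)
rather than a fixed count.

## Rank correlation and enrichment

Burden--concentration association uses Spearman's rank correlation
computed as Pearson on midranks. For $n < 10$ the two-sided p-value is
exact, by enumeration of all $n!$ permutations; for larger $n$ the
t approximation is used. Substitution-class enrichment between the low
and high AF bins uses Fisher's exact test per raw class (2x2: class vs
all others, low vs high bin) with Benjamini--Hochberg correction across
the 12 classes. The 12-class raw spectrum is primary — strand-specific
classes genuinely differ in artifact propensity — and the 6-class
strand-symmetric view is derived on demand, never stored. Directions of
per-class enrichment are reported, not hard-coded: published accounts
of which non-C:G>T:A classes are enriched are internally inconsistent,
so the implementation stays agnostic.

## Post-processing order

Primer exclusion → blacklist construction → germline discrimination →
phasing/merge → protein annotation → thresholds. Details:

* **Primer exclusion.** Primer footprints are synthesised oligo
  sequence; a call is kept only if some covering amplicon's primer-free
  insert contains it. Positions covered by no amplicon go to an
  off-target log.
* **Blacklist.** A site recurring in ≥ 40% of samples (count compared
  against `round(fraction * n)`, minimum 2) with median AF < 10% is a
  systematic artifact; recurrent high-AF sites are common-germline
  candidates and are routed to germline discrimination instead. The
  recurrence default is a stated guess — no numeric definition of
  "recurrent" is established.
* **Germline discrimination.** Population frequency ≥ 1% → germline;
  COSMIC member with population frequency < 0.1% → somatic; everything
  else ambiguous (borderline cases are surfaced, not auto-resolved).
  Thresholds are conventional; lookups are offline TSV fixtures.
* **Phasing and merge.** Two calls are phased when
  `n_both / (n_both + n_a_only + n_b_only) ≥ 0.9`; the fully phased
  case is the degenerate 1.0. Merging applies both edits to the
  reference over the spanning interval (≤ 100 bp), trims the common
  suffix then prefix, and left-aligns in the VCF convention; the merged
  AF is the parent minimum and both parents are recorded for audit.
* **Annotation.** Codon-aware via user-supplied transcript models
  (GFF3-subset + FASTA; synthetic mini-genes in tests — no reference
  genome is bundled). An indel whose length is not a multiple of 3 is a
  frameshift; a missense co-phased with a 5' frameshift is annotated
  `expressed = FALSE` and reported non-actionable.
* **Strand-bias rescue.** An indel within one read length of an
  amplicon end, positioned so one orientation's reads terminate inside
  it (distance $d <$ read length and $d + L >$ read length − margin,
  margin 20 bp), is exempted from strand-bias filtering and marked for
  realignment review. Realignment itself is out of scope.
* **Thresholds.** Target genes use the per-sample cutoff; all other
  genes use a fixed 10% floor (mutations outside the target set are
  considered actionable only in a major clone), applied per variant.
  Non-recurrent calls surviving only in degraded samples are dropped;
  recurrence for this rule is evaluated on the post-threshold set,
  which makes the filter idempotent.

## Bootstrap copy number

Without matched normals, the background for a gene's coverage is built
by resampling the other samples with replacement (samples are
resampled; amplicons stay fixed). The fold is the mean over the gene's
amplicons of sample depth / background mean; percentile 2.5/97.5
bootstrap intervals; a call is significant when the CI excludes 1
*and* the fold is beyond 1.5x in either direction — the numeric gate is
a package choice (configurable), since clinical significance around
1.6x is genuinely borderline. Percentile (not BCa) intervals were
chosen for simplicity and testability. Two robustness choices matter:

* **Size factors are median-of-ratios, not equal totals.** With 8 of
  212 amplicons amplified ~17x, equal-total scaling absorbs ~40% of the
  signal into the size factor and biases the fold down by a quarter or
  more; the median over amplicons is unaffected by a minority of
  amplified amplicons.
* **Zero-depth amplicons in the tested sample are drop-out, not copy
  zero.** They are excluded from the gene mean; otherwise a single
  dropped amplicon (drop-out probability ~0.5%) mimics a significant
  deletion.

Whole-chromosome effects are separated from focal amplification by
`withinChromosomeFold()`: the target/reference-gene depth ratio in the
sample, divided by the median of the same ratio across other samples.
A uniform doubling of the chromosome cancels exactly.

# The synthetic cohort generator

`simulateCohort()` emulates: 26 samples; four concentrations at
1.0/1.0/1.3/1.3 ng/µl and the rest log-spaced 1.9--30; artifact counts
NB with mean $e^a c^{-0.8}$, $a = \log 400$, dispersion 8 (cohort
totals ~3000--3500, matching the reported "a bit over 3300" at 26
samples); spectrum weights 0.22 + 0.22 on C>T and G>A (0.44 jointly)
and the rest uniform; truncated-Beta low-AF component; the 9--20%
high-AF component (mean count 30, NB size 3 — spanning the reported
8--56 per degraded sample) only below 1.5 ng/µl; per-variant depths NB
around 2000x with binomial alt reads and 50/50 strand split; coverage
with lognormal amplicon bias and cell noise (σ = 0.15), 0.5% drop-out.
Planted true variants, phased pairs (read co-occurrence drawn
binomially from the shared fraction) and gene folds come from the
configuration. All draws flow from one seed: identical config + seed is
bit-identical.

What it does **not** emulate: base-level reads (no FASTQ), PCR
duplicates, sequence-context (trinucleotide) signatures, mapping
error, tumour purity, or recurrent artifact hotspots at fixed
positions (artifact loci are uniform over inserts, so the blacklist
machinery is exercised by constructed fixtures rather than the
generator). Passing tests on synthetic cohorts therefore demonstrate
the statistical machinery, not performance on real reads.

# Numerical choices and degenerate inputs

* AF bins are half-open `(low, high]`; defaults (0, 0.10], (0.10, 1].
* Rank ties take midranks; constant concentration or count vectors
  make rho undefined (returned `NA` with a warning, never an error).
* Fisher tables with an empty margin report `p = 1`, OR undefined.
* Degenerate concentration designs fall back to a constant artifact
  rate with a warning; the cutoff then still respects clinical floors.
* Multi-allelic VCF records are split into biallelic rows at ingestion.
* Merging rejects overlapping edits (naming both variants) and REF
  mismatches against the supplied reference window.
* CDS lengths not divisible by 3 flag the transcript partial and warn;
  translation is best-effort up to the last whole codon.
* Problem sizes used in the test and acceptance suites — 26-sample
  cohorts, 100-seed replicate loops, B = 1000 bootstrap replicates —
  mirror the motivating study scale while keeping a full run in a few
  minutes on one CPU.

# Known limitations

* The cutoff model assumes the fitted artifact AF distribution is
  stationary across samples; only the rate varies with concentration.
* HGVS protein strings cover substitutions, frameshifts and in-frame
  del/ins/delins; exotic consequences (stop-loss, start-loss,
  selenocysteine) are out of scope.
* Variants spanning exon boundaries are annotated non-coding rather
  than split.
* The germline/somatic rule is deliberately conservative: anything not
  clearly germline (≥ 1% population frequency) or clearly somatic
  (COSMIC, < 0.1%) stays ambiguous for human review.
* Bootstrap CI width at very high folds reflects amplicon-to-amplicon
  spread in the tested sample and should not be read as a posterior.
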