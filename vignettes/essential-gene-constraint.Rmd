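---
title: "Constraint and de novo enrichment analysis for essential-gene orthologs"
author: "essvar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint and de novo enrichment analysis for essential-gene orthologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(essvar)
options(essvar.quiet = TRUE)
```

## Overview

`essvar` implements a pipeline for characterizing purifying selection on
human orthologs of mouse-essential genes and for testing whether de novo
mutations from trio studies are enriched in such a gene set. This vignette
explains the underlying models and procedures, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the design
choices made where more than one reasonable construction exists.

## Gene sets

The unit of analysis is a *gene universe*: every protein-coding gene with a
stable id, TSS coordinate, total exonic length in bp, and GC percent,
held in a `GeneCatalog`. Classification from mouse phenotype annotations
follows three rules:

* **Lethal wins.** A gene whose mouse ortholog carries at least one
  homozygous lethal-code annotation is essential (EG), even if non-lethal
  phenotypes are also recorded.
* **Heterozygous-only annotations are disregarded.** Lethality (or its
  absence) observed only in heterozygotes says nothing about the null
  phenotype; such rows never drive classification. Consequently a gene is
  NLG when it has a homozygous non-lethal annotation and no homozygous
  lethal one — a heterozygous lethal row does not disqualify it. (Whether
  NLG should also exclude het-lethal genes is genuinely open; we require
  absence of *homozygous* lethality only, which keeps the two rules
  orthogonal.)
* **One-to-one orthology.** Mouse genes mapping to several human genes, or
  human genes claimed by several mouse genes, are excluded with a warning
  rather than resolved heuristically: orthology-resolution policy belongs
  to the upstream resource, not this package.

The lethal phenotype-code set is a configuration input. The shipped default
(`inst/extdata/synthetic_lethal_codes.tsv`) is a constructed stand-in of 46
MP-shaped placeholder codes spanning prenatal, perinatal and postnatal
lethality — replace it with your curated list when working with real
phenotype dumps.

Annotation flags follow fixed thresholds: `ubiquitous_top10` marks the
lowest decile of expression coefficient-of-variation ranks (`floor(0.10 n)`
genes, at least one), and `brain_overexpressed` uses an inclusive p ≤ 1e-4
cut. Both thresholds are arguments, not constants.

## Variant typing

Effect tokens partition into four classes. The *broad exonic missense*
class comprises `SPLICE_SITE_ACCEPTOR`, `SPLICE_SITE_DONOR`, `STOP_GAINED`,
`NON_SYNONYMOUS_CODING`, `STOP_LOST`, `START_LOST` and `START_GAINED`;
within it, stop-codon and splice-site changes are loss-of-function (LoF).
Start-codon changes are broad missense but *not* LoF: the LoF definition
names stop codons and splice sites only. All "missense" tallies therefore
satisfy `n_lof <= n_missense_broad` by construction. A variant is
*putatively damaging* only on the consensus of PolyPhen2 and SIFT; a
missing call on either side is conservatively non-damaging.

Allele frequencies are computed from the genotypes as alternate-allele
count over `2 ×` called samples — missingness shrinks the denominator, it
is never imputed — and *rare* means strictly below 1%. Cohort VCFs are
read through `VariantAnnotation::readVcf` into a `VariantCohort`, a
`SummarizedExperiment` whose `GT` assay holds 0/1/2 allele counts and whose
`rowData` holds the typed annotations.

## Constraint statistics

Per-gene variant rates are corrected for exon length (`count / L`) and
reported as Z-scores against the whole-universe mean and SD; a log1p
variant Z-normalizes `log(count + 1)` instead, which stabilizes the heavy
right tail of count distributions. Both transforms are provided because
figure-level summaries in the literature are sometimes computed on either
scale; they agree in direction, and tests should state which they use.

Two-group comparisons use Wilcoxon tests (`stats::wilcox.test`): exact for
small samples without ties, normal approximation with continuity correction
otherwise. When two properties of the *same* individuals are compared the
paired signed-rank test is used. Degenerate inputs carry no evidence and
return p = 1 (all paired differences zero; all values tied).

Fisher 2×2 panels report an exact two-sided p computed by full enumeration
of the hypergeometric support (summing outcome probabilities not exceeding
the observed one, with the customary 1e-7 relative tolerance). The odds
ratio defaults to the conditional maximum-likelihood estimate as computed
by `stats::fisher.test` — the estimate practitioners actually report with
this test — with the sample cross-product available via
`or_method = "sample"`. The 95% interval is Woolf's logit interval around
the sample log-OR; tables with a zero cell receive a 0.5 continuity
correction on all cells for the OR/CI (never for the p-value) and are
flagged.

The SFS comparison reports per-bin relative excess (share of the focal
set's variants minus the comparator's share; the bins default to
`(0, 0.001], (0.001, 0.005], (0.005, 0.01], (0.01, 0.05], (0.05, 0.1],
(0.1, 0.5]`) plus a one-sided Wilcoxon on the raw frequencies. Excesses sum
to zero across bins by construction.

Promoter conservation means average per-base scores over `TSS ± 100 bp`.
The window is strand-symmetric, so strand is deliberately ignored;
uncovered bases are omitted from the mean rather than treated as zero.
dN/dS and conservation scores are consumed as precomputed per-gene tables —
computing substitution rates from alignments is out of scope.

## Per-individual mutational load

A variant counts for an individual if they carry at least one alternate
allele; a homozygous genotype counts the site once (site-level counting),
with het/hom tallies kept separately for the het/hom LoF ratio.
Per-individual summaries (missense and synonymous counts, their ratio, the
damaging and LoF counts, the LoF fraction among broad missense, genes hit)
are computed per gene set and per frequency stratum (all vs rare). Ratios
with zero denominators are reported missing and excluded pairwise from
tests. Chromosome-Y genes are excluded when the call set declares no Y
genotypes.

## The matched permutation test

Essential genes are longer than average, and de novo event counts correlate
with GC content, so raw in-set event counts are confounded. The test
exchanges each event's gene for *another* gene with total exon length
within ±100 bp and GC within ±2.5 points, uniformly, with replacement
across events and replicates. Key constructions:

* **Adjusted OR.** With `n` events, observed in-set count `O` and
  permutation-mean expectation `E`:
  `OR = [O/(n−O)] / [E/(n−E)]`. The permutation expectation, not a global
  gene-share, is the denominator — that is what makes the OR length- and
  GC-adjusted.
* **Self-exclusion.** The exchange never draws the event's own gene. This
  matters: including the target re-injects the (possibly enriched) observed
  gene into its own null pool and biases the expectation towards the
  observation, attenuating the OR. With the target excluded, the pool has
  the background set-composition at the event's (length, GC) location, and
  the estimator is unbiased under both null and alternative.
* **Unmatchable genes.** An event on a gene with no exchange partner inside
  the tolerances cannot be permuted. By default such events are dropped
  with a logged count; `unmatched = "self"` keeps them as identity
  self-swaps instead, which is conservative because their expectation
  contribution then equals their observation. At genome scale (~20,000
  genes) unmatchable genes are rare; on small synthetic universes the
  long-gene tail makes them common enough to matter, which is why the
  default drops them.
* **p-value.** Add-one permutation p, `(1 + #{replicate ≥ O}) / (1 + B)`,
  one-sided for enrichment; the reported two-sided value doubles it, capped
  at 1. The add-one form never returns exactly zero.
* **Meta-analysis SE.** The SD of replicate log-odds (0.5 continuity
  correction for replicate counts of 0 or n). Degenerate identity
  permutations have zero spread; such studies cannot enter the
  meta-analysis, which requires finite positive SEs.
* **Granularity.** Each event resamples independently (`per_gene = FALSE`);
  a per-gene mode carrying one draw across a gene's events is available,
  matching the coarser reading of a "gene-based" exchange.
* **Exact expectation.** `Σ_events |pool ∩ set| / |pool|` is always
  computed alongside the Monte-Carlo mean, enabling oracle checks and a
  cheap diagnostic for insufficient `n_perm`.

Studies are combined per arm (cases and controls separately) by
inverse-variance fixed-effects meta-analysis with Cochran's Q on k − 1
degrees of freedom; a single study returns itself with Q = 0 and q-p = 1.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
sequence-level realism:

* **Universe.** Exon lengths are log-normal (`meanlog 7.3`, `sdlog 0.8`,
  median ≈ 1.5 kb), with essential genes longer by a factor 1.5 by default;
  GC is truncated normal (mean 46, SD 9) on [20, 80]. Default EG/NLG
  fractions are 2472/20029 and 3811/20029.
* **Cohort.** Per-gene site counts per variant class are Poisson with mean
  `site_rate × L × multiplier[class, ess_class]`. Baseline rates are
  2e-3 (synonymous), 2.2e-3 (broad missense excluding LoF tokens) and
  1.5e-4 (LoF) per bp; constraint multipliers default to 1/1/1
  (synonymous), 0.5/0.9/1 (missense) and 0.3/0.8/1 (LoF) for EG/NLG/OTHER.
  No quantitative effect sizes exist to anchor these; they are free
  parameters chosen once to produce a clear but not overwhelming constraint
  signature, and are documented rather than fitted.
* **Allele frequencies.** Discretized `f(x) ∝ x^(−α)` on the grid
  `j/(2N)`, α = 1 by default (neutral-like); EG sites get an exponent
  increment (`rare_skew_eg = 0.5`) producing the rare-shifted spectrum.
  Genotypes are Hardy–Weinberg at the drawn frequency.
* **Predictions.** PolyPhen2 and SIFT calls are drawn independently given a
  latent damaging state (concordance 0.9 each), so consensus logic is
  genuinely exercised; LoF and synonymous sites carry no predictions.
* **De novo studies.** Event genes are drawn with weight
  `L × gc_weight × (true_or if EG and case)`, where
  `gc_weight = max(1 + 0.2 (GC − mean)/SD, 0.1)` models the GC correlation
  (the correlation is reported in the literature without a coefficient;
  0.2 is a mild default).

Not emulated: linkage disequilibrium, multi-allelic sites, read-level
error, indel realism, population structure. Passing tests on this generator
demonstrate correctness of the accounting and calibration of the tests
under a clean data-generating process — not robustness to the artifacts of
real call sets.

## Numerical choices and degenerate inputs

* RNG: one master seed per entry point; per-study/per-stage child seeds are
  derived deterministically, and generators restore the caller's RNG state.
* Fisher p uses `dhyper` enumeration with the 1e-7 relative tolerance when
  collecting "as extreme" outcomes, matching standard practice.
* Wilcoxon: p = 1 for all-tied or all-zero-difference inputs.
* `compute_af` errors when every genotype is missing; `permuteStudy` errors
  when no events remain or when both observation and expectation saturate.
* Zero-length genes are rejected at catalog construction.

## Problem sizes used in the shipped checks

The test-suite calibration and recovery studies use: 1,000 null studies of
50 events over a 100-gene homogeneous universe at 200 permutations (type-I
error in [0.03, 0.07]); 100 replicates of 4 studies × 300 case events over
a 20,000-gene universe (class labels independent of length and GC, so the
adjusted OR is consistent for the generating odds) at 2,000 permutations;
and 20 replicates of 500-gene / 100-sample cohorts for the directional
constraint signatures. These sizes were chosen as the smallest at which the
claimed operating characteristics are stable.

## Known limitations

* With class labels *correlated* with length (as in real data, where EG are
  longer), matching controls the confound but the adjusted OR is mildly
  conservative relative to the generating odds; the direction of the test
  is unaffected.
* On small universes, dropping unmatchable events discards real
  observations; the `unmatched = "self"` option keeps them at the price of
  a conservative bias.
* The LoF-fraction signature is noisy on small gene sets: a 200-gene
  essential set segregates only a few dozen LoF sites, so a single
  cohort-level draw of a common LoF variant can reverse the per-sample
  comparison; at genome scale this vanishes.
* The per-study SE is derived from permutation spread. It reflects the
  matched-null variance of the in-set count, which matches the sampling
  variance of the observation well near the null and moderately away from
  it; strongly enriched studies will have slightly conservative CIs.
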