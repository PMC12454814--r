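---
title: "Models and methods behind tailshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tailshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailshift)
```

`tailshift` analyses per-read features from nanopore direct RNA sequencing
(DRS): genomic 3'-end positions, poly(A) tail lengths (PAL) and per-read
modification calls, as produced upstream by signal-level tools. This
vignette is the package's own account of the statistical procedures, the
choices made where the design was genuinely open, and what the synthetic
data generator does and does not emulate.

## Alternative polyadenylation

**Site clustering.** Cleavage is imprecise, so read 3' ends scatter around
each true poly(A) site. We cluster per-gene endpoint positions by
single-linkage over the sorted positions, merging adjacent positions with a
gap of at most `window` nt (inclusive; default 24 nt). This is the standard
construction for PAS clusters: deterministic, order-independent and
O(n log n); the test suite proves it equal to brute-force transitive-closure
clustering. A cluster's representative coordinate is its modal endpoint,
with ties broken towards the stop codon in transcription direction so the
rule is strand-symmetric and deterministic.

**Pair selection.** APA is assessed at gene level on the final exon of the
reference transcript (the transcript whose stop codon is most 3'). Among
final-exon clusters with at least `min_count` reads (default 5) in *each*
condition, the two most abundant are retained; the one nearer the stop
codon is the proximal site (pPAS), the farther the distal site (dPAS).
Genes with fewer than two qualifying sites are excluded from testing — an
absence, not an error. The count filter exists because the log-ratio
statistic below is unstable at very low counts.

**Shift statistic.** For conditions 1 and 2 with counts
(pPAS1, dPAS1, pPAS2, dPAS2),

$$D = \left|\log_2\frac{dPAS_1 + c}{dPAS_2 + c} -
            \log_2\frac{pPAS_1 + c}{pPAS_2 + c}\right|$$

with pseudocount `c = 1` by default (the raw ratio is undefined at zero
counts; `c` is configurable). `D` is invariant to overall expression
changes — scaling one condition's counts cancels — and symmetric under
condition swap. A gene is called shifted when `D` exceeds a threshold
encoding "more than a 30% difference in relative abundance". That phrase
admits three readings, all available via `mode`:

* `"log2"` (default): `D > 0.3` on the log2 statistic itself;
* `"fold"`: `D > log2(1.3)` — a 1.3-fold change in the distal/proximal odds;
* `"usage"`: a proximal-usage change of more than 30 percentage points.

The default is the most literal reading of the printed rule; no intent
beyond that is guessed, and the choice is a config switch.

**RED scores.** Per condition, `RED_k = log2((dPAS_k + c)/(pPAS_k + c))`;
the reported quantity is `ΔRED = RED_2 − RED_1` per gene and its mean over
testable genes. The exact functional form is constrained only by the sign
convention: negative values must mean a global 3' UTR shortening, i.e. a
shift towards proximal usage in condition 2; the log2 distal/proximal
usage contrast is the simplest statistic with that property and reduces to
the same quantity that `D` takes the absolute difference of. A shifted
gene with `ΔRED < 0` is classified `proximal_up`, with `ΔRED > 0`
`distal_up`; a significant `D` with `ΔRED` exactly 0 stays `unchanged`
(a sign is required).

## Poly(A) tail length

Per-transcript comparisons use the two-sided Mann-Whitney U test, the
appropriate choice for PAL's skewed, heavy-tailed distributions. When
`n1 + n2 <= 12` the p-value is exact: the tie-aware null distribution of
the rank sum is built by a shift (generating-function) algorithm over the
observed midranks — equivalent to enumerating all `choose(n1+n2, n1)`
assignments, which the tests verify. Larger samples use the normal
approximation with tie correction and a 0.5 continuity correction,
identical to `stats::wilcox.test(exact = FALSE, correct = TRUE)`. On
continuous data at `n = m = 12` the approximation stays within 0.01 of the
exact p; with heavy ties it can overshoot by about 0.01 near `p = 1`
(a known property of the continuity correction, far from any decision
threshold).

The effect-size gate is `FC = control median / treatment median` with
significance requiring `p < 0.05` **and** `max(FC, 1/FC) > 1.5`. The fold
rule is applied two-sidedly because both lengthened and shortened sets are
of interest; a one-sided FC could only ever produce one of them. Which
condition is "control" is an explicit argument — the package never guesses
an ordering. Missing PAL values (signal-level estimators fail on some
reads) are excluded, never imputed and never coerced to zero, and
transcripts with fewer than `min_n = 10` usable reads per condition are
returned flagged untested: medians of fewer reads are unstable.

## m6A stoichiometry

A site's stoichiometry is `modified / (modified + unmodified)` covering
reads; a condition with zero coverage is untestable (`NA`, never 0).
Differential calls between two conditions combine:

* a two-sided **Fisher exact test** on the pooled 2x2 table, by the
  point-probability rule — the p-value sums hypergeometric probabilities of
  all tables no more probable than the observed one (with the conventional
  1e-7 relative guard against floating-point ties). Alternatives such as
  doubling the one-sided p exist, which is why the definition is stated;
  the implementation is verified against exhaustive enumeration for all
  tables with `N <= 40` and against `stats::fisher.test`;
* a stoichiometry difference `Δ = ratio_2 − ratio_1` where each `ratio_k`
  averages per-replicate ratios (replicates without coverage excluded).

Significance requires `|Δ| > 0.1` and `p < 0.05`. The mean-of-replicates Δ
and the pooled-count Fisher test are deliberately different aggregations:
the exact test needs a single 2x2 table, while the effect size should not
let one deep replicate dominate. P-values are reported raw by default
(`p.adjust` with Benjamini-Hochberg is a one-liner downstream for users who
want FDR control).

Region assignment (5'UTR / CDS / 3'UTR) is strand-aware with CDS bounds
inclusive of both termini; multi-isoform genes use the longest
CDS-containing transcript. Metagene profiles place each site at its
fractional position within its region (bin centres at `(k − 0.5)/len`),
histogram into `bins_per_region` bins per region on the concatenated axis,
and normalize to sum to 1. Per-stage modification rates are summarized as
the distribution of per-gene mean site ratios; per-site and per-read
aggregations would be alternatives, and per-gene means were chosen so that
genes with many sites do not dominate the stage summary.

## Quantification and integration

TPM is the per-kilobase read rate normalized to 1e6 per sample. The
differential-expression test is an explicit **stand-in**, labelled
`welch_t_log2_tpm_standin` in output headers: log2 fold change
`log2((mean TPM_2 + 1)/(mean TPM_1 + 1))` and a Welch t test on
`log2(TPM + 1)` across replicates, gated at `p < 0.05` and `|log2FC| > 1`.
Count-model estimators with dispersion shrinkage are deliberately out of
scope; the thresholds, not the estimator, are the contract here.

Stratified comparisons (a feature by alternative-splicing class, by m6A
status, by APA shift class) use a one-way ANOVA omnibus plus all pairwise
Welch t tests; with two groups the result *is* the unpaired t test.
"Modified" transcripts are those with at least one site of stoichiometry
>= 0.1 covered by >= 10 reads — no standard definition exists, so the
thresholds are configurable. Whether modified transcripts carry longer or
shorter tails is computed and reported with its direction; the package
encodes no expectation either way. Correlations are Spearman's rank
correlation: PAL and TPM are both skewed, and no specific correlation
method is implied by the analyses this package mirrors, so ranks are the
robust default.

## The synthetic data generator

The generator emulates a four-stage developmental DRS experiment (AerPeg,
SubPeg, ExpPod1, ExpPod2; 3 replicates each) and exists to give every
downstream stage planted, recorded ground truth.

* **Gene models**: two-exon genes, one transcript each, on two chromosomes
  and both strands; region proportions ~5% 5'UTR / 75% CDS / 20% 3'UTR,
  the typical mRNA anatomy, so uniform site placement reproduces realistic
  regional site fractions. Each 3' UTR holds exactly two poly(A) sites
  separated by `pas_pair_distance_nt` (200 nt) — the APA analysis only ever
  uses a gene's top two sites, so simulating more would add nothing the
  pipeline can see.
* **Counts**: negative binomial per gene x sample (mean 200, dispersion
  0.1), the standard RNA-seq count model. Planted DE genes multiply the
  mean by 4 in the later stages.
* **3' ends**: a two-point proximal/distal mixture (baseline weight 0.5
  per stage) plus rounded-Gaussian noise (sd 5 nt) to exercise the
  clustering stage. The developmental distal-to-proximal shift is planted:
  6% of genes have their proximal odds multiplied by 6 in the last two
  stages. With those defaults the expected global mean RED between an
  early and a late stage is `0.06 x log2(1/6) ≈ −0.155`, matching the
  magnitude such experiments report.
* **PAL**: gamma-distributed with shape 4 — positive and right-skewed like
  real tail-length distributions — with the scale solved (via the gamma
  quantile function) so the distribution *median* hits the stage target
  (84.38 / 79.91 / 81.6 / 86.59 nt). Medians, not means, are the quantity
  such studies print. Planted transcripts (10%) multiply tail lengths by
  1.8 in the later stages; 2% of values are dropped as missing to exercise
  the missing-data contract.
* **m6A**: Poisson(3) sites per gene placed uniformly along the
  transcript; per-site stoichiometry drawn from Beta(8, 8) (mean 0.5,
  matching ~50% global modification rates); planted sites (10%) shift by
  +0.3 in the later stages. Every read of a gene emits one call per site —
  read-span-dependent coverage is not modelled.
* Alternative-splicing class labels are sampled once per transcript;
  splice-graph simulation is out of scope since only class-stratified
  statistics are needed downstream.

Planted effects act on the last two stages, mirroring early-versus-late
developmental contrasts. Expression is homogeneous across genes by default
(`gene_log2_expr_sd = 0`): depth heterogeneity would make the
count-threshold behaviour of the APA test depth-dependent, and a planned
power analysis at ~600 reads per gene per stage puts the APA
false-positive rate at D > 0.3 near 0.08, which homogeneous depth
preserves. For correlation analyses the generator can draw per-gene
expression offsets and link tail length to them
(`gene_log2_expr_sd`, `pal_expr_link`), producing a rank-linked
PAL~expression fixture.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: sequence content and basecalling error,
alignment artefacts, isoform ambiguity in read assignment, more than two
poly(A) sites per gene, read-length-dependent site coverage, positional
enrichment of m6A near the stop codon, correlated effects between analyses
(planted APA/PAL/m6A/DE sets are drawn independently), and batch effects
between replicates. Recovery results on this generator validate the
statistics and their implementation, not upstream feature extraction.

## Numerical and engineering choices

* Coordinates are 1-based inclusive (the GFF3 convention) everywhere
  internally; BED export converts to 0-based half-open at the boundary.
  One internal convention avoids off-by-one drift.
* The annotated CDS is taken to include the stop codon (the common GFF3
  dialect); the stop-codon position is the CDS 3' terminus.
* Reads whose 3' end falls more than 1 kb (configurable) outside their
  gene span are flagged, not dropped — unannotated distal sites are
  biologically plausible.
* All randomness flows through a single seed; identical configs produce
  byte-identical tables, GFF3 and JSON (date-stamp header lines are
  stripped from GFF3 output for this reason). `run.log` carries ISO
  timestamps and is the one output excluded from byte-identity.
* Degenerate inputs resolve explicitly: zero-coverage sites are untestable
  rather than ratio 0; all-tied Mann-Whitney samples give p = 1; constant
  inputs give an undefined correlation with a reason; empty testable sets
  give empty results, not NaN; an all-zero sample gets zero TPM with a
  warning and the sum rule waived.
* Test problem sizes: unit tests run on 10-60 gene simulations at 20-120
  reads/gene/sample; recovery checks run once on the full-scale fixture
  (200 genes, 4 stages x 3 replicates, mean 200 reads/gene/sample), the
  size at which the planted effects' power analysis applies.

## Known limitations

The DE stand-in has no dispersion shrinkage and will be anticonservative
for low-count transcripts relative to count models. APA testing considers
only the final exon's top two sites; intronic and internal-exon APA are
out of scope. The Fisher test pools replicates and therefore ignores
between-replicate overdispersion of stoichiometry. Multi-isoform genes use
a single reference transcript for stop-codon, final-exon and region
definitions. Metagene profiles weight every site equally regardless of
coverage.
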