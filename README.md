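# tailshift

Post-transcriptional analysis of nanopore **direct RNA sequencing** (DRS)
read features for R. DRS yields, per native mRNA molecule, a genomic 3'-end
position, an estimated poly(A) tail length (PAL) and per-site modification
calls. `tailshift` turns tables of those per-read features into the three
analyses this kind of study revolves around, with a seeded synthetic data
generator so every stage can be validated against planted ground truth:

* **Alternative polyadenylation (APA).** Read 3' ends are clustered into
  poly(A) sites (single-linkage, inclusive gap window). Per gene, the two
  most abundant final-exon sites are the proximal (pPAS) and distal (dPAS)
  site by distance from the stop codon. Between two conditions the usage
  shift is

  `D = | log2(dPAS1 / dPAS2) − log2(pPAS1 / pPAS2) |`

  (counts with a pseudocount; `D > 0.3` flags a shift by default). The
  per-condition **relative expression difference** `RED_k = log2(dPAS_k /
  pPAS_k)` summarizes 3' UTR geometry; a negative change `ΔRED = RED_2 −
  RED_1` means global 3' UTR shortening (a distal-to-proximal shift).

* **Poly(A) tail length.** Per-transcript two-sided Mann-Whitney *U* test
  between conditions — exact (tie-aware enumeration) for small samples,
  tie/continuity-corrected normal approximation otherwise — with
  `FC = control median / treatment median`; a call requires `p < 0.05` and
  `max(FC, 1/FC) > 1.5`.

* **m6A stoichiometry.** Per site, `ratio = modified / (modified +
  unmodified)` covering reads. Differential sites between conditions need a
  mean per-replicate ratio difference `|Δ| > 0.1` and a two-sided **Fisher
  exact** `p < 0.05` on the pooled 2x2 table. Metagene profiles histogram
  sites on a region-scaled 5'UTR | CDS | 3'UTR axis.

Around these sit TPM quantification, a clearly-labelled Welch-t
differential-expression stand-in, stratified group comparisons (ANOVA +
pairwise Welch t) and Spearman correlation utilities, and a deterministic
`run_pipeline()` that writes every result table, a BED of site pairs and a
machine-readable JSON summary.

The synthetic generator emulates a four-stage peanut pod development
experiment (stages AerPeg, SubPeg, ExpPod1, ExpPod2; 3 replicates each):
stage-specific PAL medians of 84.38 / 79.91 / 81.6 / 86.59 nt, a planted
distal-to-proximal APA shift in the later stages, ~50% per-site m6A
stoichiometry, and negative-binomial expression. All planted effects are
recorded and returned as ground truth.

## Worked example

```r
library(tailshift)
library(dplyr)

cfg <- sim_config(n_genes = 50, reads_per_gene_mean = 100, seed = 7)
sim <- simulate_reads(cfg, simulate_annotation(cfg))

summarize_pal(sim$reads)
#>   stage       n median    q1    q3
#> 1 AerPeg  14157   84.4  58.0  117.
#> 2 ExpPod1 19303   84.7  58.2  120.
#> 3 ExpPod2 19497   89.5  61.2  127.
#> 4 SubPeg  14734   79.7  55.4  111.
```

Stage medians land on the configured targets (84.38 / 79.91 nt for the two
unperturbed stages; the later stages sit higher because 10% of transcripts
carry a planted 1.8-fold lengthening).

```r
apa <- apa_test(sim$reads, sim$annotation, "SubPeg", "ExpPod2")
table(apa$shift_class)
#>   distal_up proximal_up   unchanged
#>           5           9          36
global_red(apa)
#>   mean_red n_genes
#> 1   -0.165      50
```

The negative global mean RED (−0.165) reports net 3' UTR shortening between
SubPeg and ExpPod2, driven by the planted proximal shifts.

```r
pal_test(sim$reads, "SubPeg", "ExpPod2") %>% filter(significant)
#>   transcript_id control_median treatment_median fold_change  p_value
#> 1 tx0002                  76.1             157.       0.485 9.58e-33
#> ... (5 rows: exactly the transcripts with a planted 1.8-fold effect)

sc <- m6a_site_counts(sim$modcalls, sim$reads)
md <- m6a_diff_test(sc, "SubPeg", "ExpPod2")
sum(md$significant)
#> [1] 18   # the 18 planted Δ = 0.3 sites, out of 165 tested
```

`run_pipeline(run_config(simulate = cfg), "out/")` runs every stage for all
six pairwise stage comparisons and writes `apa_*.tsv`, `pal_*.tsv`,
`m6a_*.tsv`, `de_*.tsv`, `pas_*.bed`, `metagene_profile.tsv`,
`summary.json` and `run.log`; reruns are byte-identical.

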