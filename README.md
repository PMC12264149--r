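# oetm6a

Downstream analysis of low-input m⁶A MeRIP-seq (IP/Input) experiments
across the oocyte-to-embryo transition (OET), implemented as a tested,
reusable R package.

N⁶-methyladenosine (m⁶A) is the most prevalent internal mRNA
modification. Profiling it in single oocytes and preimplantation embryos
(stages GV, MII, 1C, 2C, 8C, blastocyst) yields paired IP and Input
coverage tracks, called peaks, and stage-structured expression matrices.
This package implements everything downstream of alignment and peak
calling for such a study, for analysts who have those inputs (or want a
fully synthetic stand-in):

- **Binned coverage and m⁶A signal** — per-10-bp-bin RPKM tracks and the
  per-bin statistic `s_b = log2((RPKM_IP + 1) / (RPKM_Input + 1))`;
  sample similarity via Pearson *r* over 1-kb windows, PCA, and average-
  linkage clustering on the dissimilarity `1 − r`.
- **Peak annotation** — each peak gets exactly one label by the priority
  hierarchy stop codon (± 200 bp) > 3'UTR > 5'UTR > CDS > exon > intron >
  intergenic; feature enrichment `E_f = log2(observed_f / expected_f)`
  with expected counts from hierarchy-masked genomic lengths (a true
  partition, so expected counts sum to the peak total); metagene profiles
  of peak summits on the concatenated exons of each gene's
  highest-expressed isoform (5'UTR → [0,1), CDS → [1,2), 3'UTR → [2,3));
  RRACH (R = G/A, H = A/C/U) motif counting.
- **Gene-level m⁶A calls** — a gene is m⁶A+ in a stage when any of its
  transcripts' exons overlap any peak in any IP replicate (union rule).
- **Stage dynamics** — median-of-ratios (DESeq-style) normalization;
  literal evaluation of the published M-decay, Z-decay and ZGA rule sets
  on stage-mean TPM; constant genes via entropy specificity (< 0.5, with
  TPM ≥ 10 everywhere); human–mouse homolog expression categories on
  strictly one-to-one homologs (TPM ≥ 50 / ≤ 10 thresholds).
- **miRNA and translation** — RPM normalization, conserved-family
  target maps, weighted targeting counts (Σ log10 RPM over miRNAs with
  RPM ≥ 10); translation efficiency `TE = (Ribo FPKM + 1)/(mRNA FPKM + 1)`
  for genes with mRNA FPKM ≥ 10, grouped by m⁶A status and peak region.
- **Retrotransposons** — RepeatMasker-style annotations filtered to
  analyzable loci (completeness ≥ 0.9, closed boundary; full-length ERVs
  assembled from 5'LTR + internal + 3'LTR fragment runs; exon-overlapping
  loci removed); per-locus expression and m⁶A as max-over-bins,
  replicate-averaged; subfamily summaries, element-scaled profiles, and
  Ctrl-vs-METTL3-inhibitor comparisons.
- **Statistics** — two-sided Wilcoxon rank-sum (exact where possible) and
  one-sided Fisher's exact test built directly on the exact null
  distributions, plus the five-percentile boxplot summary
  (5/25/50/75/95th + mean) used throughout.
- **Synthetic data** — a seeded generator (`sim_config()`,
  `simulate_annotation()`, `simulate_stage_experiment()`,
  `simulate_condition_experiment()`) that emits every input shape above
  with a ground-truth record, so the whole pipeline is verifiable at desk
  scale with no downloads.

## Worked example

Simulate a six-stage experiment with planted decay/ZGA classes and
stop-codon peaks, then run the core analyses:

```r
library(oetm6a)

cfg <- sim_config(n_genes = 150, chrom_length = 1.5e6, depth = 3e4,
                  class_counts = c(m_decay = 15, z_decay = 15,
                                   zga = 15, constant = 15),
                  seed = 11)
sim <- simulate_annotation(cfg)
exp <- simulate_stage_experiment(cfg, sim)

feature_enrichment(exp$peaks$GV$rep1, sim$bundle)
#>      feature observed expected enrichment
#> 1 stop_codon       43    0.822      5.709
#> 2       3UTR        2    3.395     -0.764
#> 3       5UTR        0    0.412         NA
#> 4        CDS        0    6.645         NA
#> 5       exon        0    0.286         NA
#> 6     intron        0    3.885         NA
#> 7 intergenic        0   29.555         NA
```

Peaks land almost exclusively in the stop-codon class (planted summits
are Normal(stop codon, 50 bp)); `E = 5.7` means 2^5.7 ≈ 52-fold more
stop-codon peaks than the genomic length share predicts, the signature
seen in real m⁶A data.

```r
calls <- call_m6a_genes(exp$peaks$GV, sim$bundle,
                        expr = exp$stage_tpm[, "GV"])
table(calls$status)
#>          m6A-          m6A+ not_expressed
#>            87            48            15

cls <- classify_maternal_zga(normalize_expression(exp$expression))
table(cls$label)
#> constant  M-decay     none  Z-decay      ZGA
#>       15       15       90       15       15
```

All 60 planted class genes are recovered exactly (the 15 `not_expressed`
genes at GV are the planted ZGA genes, silent before zygotic genome
activation). Group comparisons print the five-percentile summary used in
the study's boxplots:

```r
compare_groups(c(4.1, 5.3, 6.0, 7.2, 8.4), c(2.0, 2.9, 3.5, 4.4))
#> wilcoxon_two_sided: statistic = 19, p = 0.03175
#>    group n    p5   p25 median   p75   p95 mean
#> 1 group1 5 4.340 5.300    6.0 7.200 8.160  6.2
#> 2 group2 4 2.135 2.675    3.2 3.725 4.265  3.2
```

The full pipeline (simulate → signal → annotate → genes → classify →
compare → mirna → te → retro → report) runs from one YAML config:

```r
run_pipeline(run_config(seed = 1), "results_dir")
# or from the shell:
#   Rscript -e 'oetm6a::oetm6a_cli()' run --config config.yaml --out results_dir
```

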