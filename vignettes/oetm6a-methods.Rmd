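---
title: "Methods: models, conventions and design choices in oetm6a"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in oetm6a}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the
statistical models it implements, the conventions it fixes where the
field leaves room, and what its synthetic-data tests do and do not
establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The measurement model

MeRIP-seq compares an antibody-enriched (IP) library against an Input
library from the same fragmented RNA. After alignment, both are reduced
to fragment coverage on a fixed grid of 10-bp bins, normalized to RPKM
(`n_b / ((bin_size/1000) * (total/1e6))`, each fragment counted once in
every bin it overlaps by at least 1 bp). The per-bin m⁶A signal is

$$ s_b = \log_2\frac{\mathrm{RPKM}_{IP,b} + 1}{\mathrm{RPKM}_{Input,b} + 1}. $$

The +1 pseudocount keeps every bin finite and shrinks low-coverage bins
toward 0; the signal is exactly antisymmetric under an IP/Input swap,
which the suite tests. Because each track is normalized by its *own*
library size, the signal is sensitive to *composition*: if a large share
of the IP library is absorbed by strongly enriched regions, the effective
enrichment observed at any one region shrinks. This is a property of the
statistic, not a bug; it matters when interpreting condition comparisons
(see *The inhibitor world* below).

Sample similarity re-aggregates bins to 1-kb windows (mean), computes
Pearson *r* across all windows, and defines the dissimilarity between
samples as `1 − r`. The original work specifies neither the clustering
linkage nor the PCA preprocessing; this package uses average linkage and
PCA on the feature-centered (not scaled) window × sample matrix, and
records both choices here. A zero-variance track cannot enter a Pearson
correlation; its entries are set missing and it is excluded from
clustering and PCA with a warning rather than silently dropped.

# Peak annotation

Every peak receives exactly one genomic-feature label by priority:
**stop codon** (the annotated 3-nt stop codon extended 200 bp both ways
in genomic space) > 3'UTR > 5'UTR > CDS > exon > intron > intergenic.
Two open points were decided as follows:

- *Stop-codon window in genomic space.* "200 bp upstream to 200 bp
  downstream" is applied to genomic coordinates around the annotated
  stop codon — the simplest reading. A transcript-space window would
  differ for stop codons near splice junctions.
- *Hierarchy-masked expected lengths.* Enrichment scores are
  `E_f = log2(observed_f / expected_f)` with
  `expected_f = total_peaks × L_f / L_genome`. `L_f` is the genomic
  length of feature *f* **after subtracting all higher-priority
  features**, so the seven lengths partition the genome exactly and
  expected counts sum to the peak total. Whether the original analysis
  double-counted overlapping annotation is not stated; masking makes the
  scores comparable across features and gives the partition property the
  tests rely on. A feature with zero observed peaks reports a missing
  score rather than −∞.

Metagene profiles place each peak summit on the concatenated exons of
its gene's *representative* transcript — the isoform with the highest
expression in the matching Input sample, ties broken by longer
transcript, then lexicographic identifier. The position is scaled within
its region to unit length: 5'UTR → [0,1), CDS → [1,2), stop codon and
3'UTR → [2,3), so the first stop-codon base maps exactly to 2.0. Regions
are equal thirds without median-length rescaling: the upstream tool that
inspired the display offers such a rescaling, but no parameters for it
are printed, so the plain version is used and documented. Summits on
non-coding, UTR-less or intronic positions are skipped and counted.

Gene-level m⁶A calls intersect peaks with **exonic intervals** of each
transcript (≥ 1 bp), not full genomic spans, because m⁶A resides on
transcripts; the upstream intersection convention is not printed, so a
`mode = "span"` flag provides the other behaviour and the default is
documented. A gene is m⁶A+ in a stage if any replicate supports it (the
union rule), and genes under a TPM floor (default 1) are reported
`not_expressed` rather than m⁶A−.

RRACH counting uses the DNA alphabet (`[GA][GA]AC[ACT]`) on the
sense-strand concatenated exons of the representative transcript,
overlaps allowed; the motif is displayed in RNA letters only.

# Stage dynamics

Between-sample normalization is the median-of-ratios method: the
reference is the per-gene geometric mean over samples (genes with any
zero excluded); each sample's size factor is the median ratio to the
reference, and abundances are divided by it.

The decay/ZGA rule sets are evaluated **literally** on stage-mean TPM
(replicates averaged arithmetically first — the original work does not
say; logged here):

- M-decay: TPM > 10 in GV; GV > MII; GV/8C > 2; GV/zygote > 2;
  GV/MII < 2.
- Z-decay: TPM > 10 in GV; zygote/GV < 1.5; GV/8C > 2; GV/zygote < 2;
  zygote/8C > 2.
- ZGA: TPM < 1 in GV and MII; TPM > 10 at 8C; 8C > zygote.

"Fold change of A versus B" is read as `TPM_A / TPM_B`; a zero
denominator with positive numerator gives +∞ (the condition can hold),
and 0/0 makes the condition false. M-decay condition (5) *caps* the
GV-to-MII fold change below 2 rather than requiring decay during
maturation — counterintuitive for a maturation-decay class, but it is
what is printed, so it is implemented literally and flagged here.
M-decay is evaluated before Z-decay; a gene satisfying both is labeled
M-decay and flagged rather than dropped. The 2C and blastocyst stages
participate in no rule.

Constant genes use the entropy specificity score — the base-2 KL
divergence of the normalized cross-sample profile from uniform,
`Σ p_i log2(N p_i)` with `0·log 0 = 0` — which is 0 for perfectly even
expression and `log2 N` for one-sample expression. The cited scoring
package prints no formula; KL-from-uniform is its documented definition
and is scale- and permutation-invariant (tested). The constant call is
score < 0.5 *and* TPM ≥ 10 in every sample.

Group comparisons use a two-sided Wilcoxon rank-sum test (exact via the
null rank-sum distribution when both groups have ≤ 25 observations and
no ties; otherwise normal approximation with tie and continuity
correction) and a one-sided Fisher's exact test (hypergeometric tail,
alternative: greater success proportion in the m⁶A+ row). Both kernels
are written against the exact null distributions rather than delegating
to the omnibus test functions so the suite can verify them against full
enumeration. Summaries are the 5th/25th/50th/75th/95th percentiles
(linear interpolation between order statistics, R type 7 — chosen for
determinism across implementations) plus the mean.

# miRNA targeting and translation

miRNA counts are normalized to RPM within each replicate (so each
replicate's RPMs sum to exactly 10⁶) and averaged across replicates per
stage. Only conserved miRNA families with stage RPM ≥ 10 count
(boundary closed: RPM = 10 contributes log10 = 1); a protein-coding gene
is targeted if at least one such miRNA's family targets it, with the
weighted count Σ log10(RPM) over those miRNAs.

Translation efficiency is `(Ribo FPKM + 1)/(mRNA FPKM + 1)` per stage on
replicate-mean FPKM, restricted to protein-coding genes with stage-mean
mRNA FPKM ≥ 10 (the per-stage filter; whether the original filter was
per-stage or global is not stated). For region-resolved TE, a constant
m⁶A+ gene contributes to *every* region group in which it has a peak
summit — the documented multi-membership convention.

# Retrotransposons

Loci pass three filters, in order, with counts logged per rule:

1. **Completeness** (LINE/SINE/SVA and solo LTR): annotated length /
   consensus full length ≥ 0.9, boundary closed (0.90 exactly is kept).
2. **Architecture** (full-length ERVs): same-strand, same-family
   fragment runs within a 500-bp gap tolerance whose segments read
   LTR … internal … LTR. The source database's architecture procedure is
   unstated, so the gap tolerance is a parameter; LTR fragments outside
   such runs fall back to solo-LTR candidates, orphan internal fragments
   are dropped.
3. **Exon exclusion**: any locus overlapping an annotated gene exon by
   ≥ 1 bp is removed, so gene expression cannot masquerade as repeat
   expression.

Per replicate, a locus' expression is the **maximum Input RPKM** over
its overlapping bins and its m⁶A value the maximum signal over the same
bins; stage values are replicate means. "Expressed" and "modified" are
strict (> 0), as printed. Element-scaled profiles divide each locus into
100 equal relative-position segments oriented 5'→3' (minus strand
reversed; 100 is a display choice, the original binning being unstated)
and report the per-segment mean and SD across loci (SD defined as 0 for
a single locus).

# The synthetic world

The generator's defaults state the emulated world: six stages
(GV…blastocyst) × 2 replicates; planted class counts with every printed
inequality satisfied at a 1.5× multiplicative margin; peak summits
Normal(stop codon, sd = 50 bp) truncated to the transcript; IP
enrichment factor 6 inside peak windows (± 100 bp); 10⁵ fragments per
sample at the single-oocyte scale; fragment length 180 ± 30 bp;
log-normal replicate noise (sdlog 0.1); GGACT planted at summit
positions in otherwise random DNA; coding architecture with 5'UTR
100–300 bp, CDS 0.9–6 kb, 3'UTR 0.8–3 kb (lower bounds keep planted
summits inside the stop-codon metagene window given the 50-bp summit
sd; upper bounds provide the length variation that makes length-biased
m⁶A deposition statistically visible); m⁶A gene membership sampled with
probability proportional to exonic length; a 1.5× TE multiplier on m⁶A+
genes; repeat subfamilies with fragmented copies (30% below 0.9
completeness), full-length ERV triplets and solo LTRs.

Modeling decisions worth knowing:

- **Fragment allocation** is multinomial over exon/locus segments with
  weights TPM × length — a Poisson model conditioned on the configured
  depth, so per-bin noise is Poisson-like while the emitted total equals
  the depth exactly (both stated contracts).
- **The IP field.** IP density equals Input density times an enrichment
  field: γ inside planted peaks and across modified repeat loci, 1
  elsewhere, and **0 across expressed-but-unmodified repeat loci**.
  The zero is a deliberate idealization (a fully selective antibody):
  under any nonzero IP background, the max-over-bins statistic exceeds 0
  somewhere on almost every multi-bin locus, and the strict
  "modified ⇔ max signal > 0" rule would approach 100% regardless of
  truth. With γ = 1 the field is flat and IP coincides with Input in
  distribution (the null world used by the calibration tests).
- **Planted-rule enforcement.** After drawing replicate noise, the
  generator re-draws it for any gene whose emitted stage means violate
  the planted class membership (or, for background genes, satisfy any
  class). This implements the generator's stated contract — emitted
  matrices satisfy the planted rules — rather than tuning: rules are
  checked by an independent in-generator evaluator, not the classifier.
- **Composition bias and the inhibitor world.** In the condition
  experiment the treated IP enrichment is γ × reduction factor
  (default 0.5). Because RPKM renormalizes each library, worlds in which
  repeat RNA dominates the library absorb much of the enrichment
  difference into the normalization; the inhibitor comparisons therefore
  assume (and the acceptance test states) a transcriptome-dominated
  library with repeat mass around 20%, with per-locus repeat levels
  exposed as `repeat_level_meanlog`/`repeat_level_sdlog`.
- **The naive peak caller** (threshold runs with gap bridging) exists
  only for synthetic end-to-end runs; the production peaks are an
  upstream input. Its pipeline default threshold is 2 log2 units
  (≥ 4-fold enrichment): near-threshold signal fragments broad regions
  into many small peaks, which would make raw peak *counts*
  uninterpretable in condition comparisons at looser thresholds. Note
  that peak-count monotonicity in the threshold is **not** a theorem for
  any run-based caller (splitting a merged run can increase the count);
  the monotone quantity is the total peak-covered length, and that is
  what the property test asserts.

What a green suite establishes: the formula-level operations are exactly
correct (brute-force agreement), the rule sets are implemented literally
(hand-checked cases and planted-class recovery with precision = recall
= 1), the annotation geometry is correct (transcript-coordinate
arithmetic, partition property, calibrated null enrichment), the
statistical kernels match exhaustive enumeration, and the qualitative
associations of the source study (stop-codon concentration, longer m⁶A+
genes, higher TE, inhibitor-driven loss on retrotransposons) emerge from
the stated synthetic world. What it does **not** establish: agreement
with the study's headline counts (those depend on restricted deposited
datasets), robustness to multi-mapping reads (uniquely aligned input is
a contract), strandedness handling (a strand-aware flag exists, default
off, because the library protocol's effective strandedness is not
asserted), or realism of the noise model beyond Poisson counting
(no GC/fragment-bias, no PCR duplication structure).

# Degenerate inputs and numerical conventions

- Coordinates are 0-based half-open in every data frame; GTF is
  converted on read/write, and a round-trip preserves intervals exactly.
- Readers reject coordinates outside the declared chromosome sizes — no
  silent clipping; malformed GTF lines are reported with their line
  number; transcripts without exons are rejected by identifier.
- narrowPeak summit offsets of −1 (and plain BED) fall back to the
  floored interval midpoint; records with start ≥ end are dropped with a
  count.
- Partial-bin coverage is resampled by length-weighted mean — exact for
  piecewise-constant tracks; bin-aligned round-trips are exact.
- Naive-caller summit tie-break: the leftmost maximal bin, center of the
  bin — determinism over elegance.
- Empty peak lists are an error for enrichment (a denominator-free
  statistic is meaningless) but an empty *file* reads as an empty set
  with a warning.
- The expected-count partition is validated to 10⁻⁹ relative to the
  genome length; everything else that is exact is tested with
  `expect_identical`/tolerance 10⁻¹².
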