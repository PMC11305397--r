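---
title: "Methods: allele-specific amplicon BS/OxBS quantification and companion analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific amplicon BS/OxBS quantification and companion analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astaseq)
```

## The measurement problem

Bisulfite (BS) treatment converts unmethylated cytosine to uracil (read as
T) while 5-methylcytosine (5mC) and 5-hydroxymethylcytosine (5hmC) both
stay C. Oxidative bisulfite (OxBS) first oxidizes 5hmC to 5fC, which
bisulfite then also converts, so only 5mC remains C. Reading the same CpG
in both arms therefore separates the two marks:

* `%5mC = %CG(OxBS)`
* `%5hmC = %CG(BS) − %CG(OxBS)`

In a hybrid cell line carrying one *Mus musculus* (mus) and one
*M. castaneus* (cas) X chromosome, a species-specific SNP inside each
targeted amplicon splits the reads by haplotype, so the marks can be
quantified separately on the inactive (mus) and active (cas) X. That is
the core estimator here (`asta_quantify()`); around it sit the companion
analyses the same study design needs: allele-resolved expression ratios
and gene classification, a pluripotency score, array-scale BS/OxBS
beta-value processing, and CRISPR-screen hit filters.

## Amplicon read model

A sequenced read is: 2–5 random stagger bases, then the gene-specific PCR
primer (a prefix of the BS-converted amplicon), then the rest of the
amplicon body in BS space, truncated at 300 bp (single-end MiSeq
geometry). Only the converted top strand is modelled and analyzed: primers
are designed against BS-converted sequence, so a single strand carries all
the information, and single-end reads see only it. Non-CpG methylation is
taken as zero (the mammalian somatic default); conversion failure enters
only through `conv_rate`.

Per read and CpG, the probability of reading C is

* BS: `f_5mC + f_5hmC + f_C (1 − conv_rate)`
* OxBS: `f_5mC + f_5hmC (1 − ox_rate) + f_C (1 − conv_rate)`

with `(f_C, f_5mC, f_5hmC)` the per-(gene, allele, CpG) composition
(rows must sum to 1), `conv_rate` the bisulfite conversion efficiency and
`ox_rate` the oxidation efficiency. Defaults 0.99 and 0.95 are plausible
for commercial oxBS kits but are configurable assumptions, not published
values. A uniform substitution error (`seq_err`, default 0.001) is applied
last. These three parameters predict the direction of every systematic
bias: incomplete conversion inflates %CG in both arms, incomplete
oxidation moves signal from 5hmC into 5mC — both are asserted as
monotonicity properties in the test suite.

## Classification chain

1. **Gene** — scan the first `max(stagger) + nchar(primer)` bases for an
   exact primer occurrence, compared C/T-collapsed (an unconverted C must
   still match its T in the primer). Reads matching no primer, or more
   than one, are unassigned.
2. **Allele** — locate a 15–20 nt BS-space anchor ending immediately 5'
   of the SNP; the next base decides mus vs cas. Anchor matching is exact,
   C/T-collapsed only at CpG positions inside the anchor (their state is
   methylation-dependent); a duplicated anchor hit, a truncated read or a
   third base at the SNP gives "ambiguous". SNPs whose two alleles
   collapse to the same base after conversion (e.g. C/T on this strand)
   are rejected at panel load: no read could ever distinguish them.
3. **CpG call** — locate the CpG's own 15–20 nt upstream anchor, which
   must itself contain no CpG, and read the following 2-mer: CG
   (methylated), TG (converted) or "other" (anything else, including
   sequencing errors); "other" never enters a %CG denominator.

Anchor lengths are chosen per site: the shortest length in 15–20 whose
occurrence in the converted amplicon is unique (uniqueness is checked in
fully collapsed space, the worst case over ambiguity assignments). If no
CpG-free window of at most 20 nt exists, or the window would run past the
read start, panel construction fails loudly — a panel that cannot be
anchored should not be quantified.

Only reads in which the SNP *and* at least one CpG are recoverable
contribute. Read accounting is kept at every stage so that conservation
(classified + ambiguous + unassigned = input) is checkable exactly.

**Why a 10 nt demultiplexing primer in the default panel.** With exact
matching, a read is lost whenever a sequencing error falls inside the
primer, roughly `1 − (1 − seq_err)^len`. At `seq_err = 0.001` a 20+ nt
primer loses about 2% of reads; 10 nt keeps the loss under 1% while six
random 10-mers remain trivially unique across the panel. Longer primers
work, at the cost of assigned-read fraction.

## Negative-5hmC handling

`%CG(BS) − %CG(OxBS)` is a difference of two noisy binomial estimates and
can be negative. Per CpG, across all its allele × condition cells
(mus/cas × control/IFNγ in the default design): a raw value below −1% in
*any* cell is not biologically explainable, so the whole CpG is discarded;
raw values in [−1, 0) are within acceptable sampling variability and are
clamped to 0; everything else is kept. With other condition sets, "any
cell" generalizes to all cells present. The rule is idempotent and
order-independent. The −1 cut is strict (`< −1` discards); −1 itself
clamps. A per-cell coverage floor (default 100 CG+TG calls) only flags
cells as low-coverage; it never silently removes them.

## Allelic expression, classification, pluripotency, qPCR

The allelic ratio is `mus / (mus + cas)` on raw allele-resolved counts —
library-size normalization cancels in the ratio. A gene is informative if
its cas share exceeds 25% strictly in every population (a gene expressed
almost only from mus cannot be scored for reactivation); informative genes
with an NPC ratio ≤ 0.135 (inclusive) are "reactivating", above it
"escapee". Both boundary conventions are literal and tested at the
boundary. Whether the 25% rule means per-gene cas share or a
transcriptome-wide share is genuinely ambiguous; the per-gene reading is
implemented, as it is the only one that defines per-gene informativeness.
Protein-coding/X-linked filtering is delegated to the construction of the
input table, keeping the operations annotation-agnostic.

The pluripotency score is the arithmetic mean over seven naive-marker
genes (Nanog, Zfp42, Dppa4, Dppa5a, Esrrb, Prdm14, Sall4) of expression
relative to the ESC mean per gene — arithmetic rather than geometric
because the score is described as an average of those ratios; the choice
matters only for strongly discordant genes. ESCs self-score exactly 1,
and the score is linear in each gene's ratio and symmetric under gene
permutation (both property-tested). qPCR expression is `2^−ΔCT` against
the mean Gapdh CT.

## Array-scale BS/OxBS processing

Probe QC removes probes with intensity < 1000 or detection p > 0.01, by
default in any sample (a probe failing once is untrustworthy everywhere);
a per-sample mode is exposed. Thresholds are literal: intensity 1000 and
p = 0.01 pass. Deconvolution is `beta_5mC = beta_OxBS`,
`beta_5hmC = beta_BS − beta_OxBS`. One methods description of this
subtraction circulates with the arms swapped; chemistry forces BS ≥ OxBS
in expectation (5hmC reads methylated in BS only), so BS − OxBS is used
uniformly here, matching the amplicon formula. Negative array `beta_5hmC`
is retained — the amplicon-style clamp is a targeted-assay rule, not an
array one.

Differential positions: a plain Welch two-sample t test per probe supplies
p-values and the beta-scale mean difference as logFC (the original
workflow uses limma's moderated t after batch correction, which is out of
scope here; any externally computed p/logFC table can be fed to
`dmp_filter()` directly). Selection is raw `p < 0.01` and
`|logFC| ≥ 0.1`; BH-adjusted p-values are reported alongside but do not
drive selection. Stratified summaries (autosome/chrX × global, promoter,
gene body, distal) report per-arm means, Δβ = mean(IFNγ) − mean(control)
and an unpaired Welch test; strata with fewer than two values per arm
report means only.

## Screen filters

MAGeCK's RRA scoring is external; implemented here are only the selection
rules over its gene summaries: top-250 per comparison by positive RRA
score (ties at the cut broken by gene name for determinism — tie handling
at rank 250 is otherwise unspecified), deduplicated union across
comparisons; the essentialome intersection `RRA < 0.05` and
`log2FC < −0.75` in every population; and the pairwise hit rule
`RRA < 0.05`, `|log2FC| > 0.8` strict, `goodsgrna ≥ 3` inclusive. All are
pure row filters, checked against brute-force scans.

## What the simulators emulate — and what they do not

The generators reproduce the statistical structure the analyses assume:
binomial read sampling at the CpG with the chemistry mixture above,
negative-binomial expression totals with a binomial allele split,
Gaussian beta noise truncated to [0,1] around the mixture means, planted
QC failures, and screen tables with a controllable signal fraction (and
optionally a shared depleted core, as a real essentialome intersects).
They do not model PCR amplification bias, chimeras, indels, paired-end
geometry, batch effects, probe cross-hybridization, or real genomic
sequence context — so green tests demonstrate that the estimators recover
the parameters of this generative model at the stated coverages, not that
real libraries are free of those artifacts. Default per-sample coverage is
20,000 reads per amplicon and allele: inside the range targeted assays of
this kind achieve, but desk-scale.

Default truth tables place substantial 5mC/5hmC on the mus allele of the
four reactivating-gene amplicons (Mtm1, Dlg3, Eda, Zfp185; 5mC 0.55–0.75,
5hmC 0.10–0.20) and low marks on cas, while the two escapee amplicons
(Ddx3x, Eif2s3x) sit at 2%/1% on both alleles — the qualitative pattern
such promoters show. Gene names label the amplicons; all sequences are
synthetic.

## Numerical and design choices

* Positions are 1-based throughout the R API and serialized formats.
* "Upstream" means 5' on the sequenced strand; anchors end immediately
  before their target base.
* Anchor and primer matching default to zero mismatches
  (`max_mismatch = 0`); a slower mismatch-tolerant path exists for
  degraded data.
* Reads with duplicated anchor occurrences are excluded as ambiguous
  rather than picking a hit.
* %CG denominators exclude non-CG/TG 2-mers; a zero denominator yields a
  missing estimate, never 0.
* FASTQ qualities are written as constant Q40 and ignored on input.
* All simulators take an explicit integer seed and restore the caller's
  RNG state; identical seeds give byte-identical outputs, which the demo
  (`run_demo()`) verifies end-to-end via file hashes.
* Problem sizes used by the test suite and the acceptance script: the
  six-gene panel at 20,000 reads/allele/chemistry for the round-trip
  check; 200 genes at total count ≈ 5,000 for classification recovery;
  1,000 probes × 3 samples/arm at noise SD 0.05 with a +0.05 planted 5hmC
  shift for the array stage; 1,000-gene screen tables. These are the
  package's chosen study conditions for its own validation.

## Interfaces

Panels serialize to JSON or YAML with the `amplicon_spec` field names;
truth tables, sample sheets, tallies and estimates are TSV; every written
table carries a provenance header (`# astaseq_version=…, seed=…,
thresholds…`). The exported functions are the interface; `run_demo()`
binds all stages into one seeded, reproducible run, and
`scripts/acceptance.R` recomputes the headline quantities from scratch.

## Known limitations

* Exact-match anchoring loses reads roughly linearly in `seq_err` times
  anchor length; at defaults the loss is ~1% and is visible in the read
  accounting rather than silently absorbed.
* The Welch test stand-in is less powerful than a moderated-t on small
  arm sizes; with three samples per arm only large beta differences reach
  p < 0.01.
* The bottom strand, indel-tolerant matching and genome-wide bisulfite
  data are out of scope; the estimator is for targeted amplicons with
  known two-haplotype references.
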