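---
title: "Methods: mitochondrial cohort analysis in mitocohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial cohort analysis in mitocohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocohort)
```

## The analysis problem

Deep whole-genome sequencing of a cohort yields, per sample, thousands-fold
coverage of the 16,569 bp circular mitochondrial genome (rCRS,
NC_012920.1). Because every cell carries many mtDNA copies, a variant can
be present in any fraction of them: the variant allele fraction
VAF = AD/DP estimates that heteroplasmic level. Two artifacts complicate
cohort analysis. First, nuclear copies of mitochondrial sequence (NUMTs)
attract mitochondrial reads and can masquerade as low-VAF heteroplasmies;
second, the same read-pair signal, viewed from the nuclear side, is the
evidence from which non-reference NUMT insertions are discovered.
`mitocohort` implements both sides — a high-confidence mtDNA variant set
with heteroplasmy classification, and NUMT discovery with breakpoint
statistics — plus invariable-interval extraction and an mtDNA–nDNA
association scan.

## Variant QC and heteroplasmy classification

Samples are excluded when nDNA contamination exceeds 2% (fraction in
[0,1]), when a phylogeny-based mtDNA contamination check flags them, or
when the mtDNA copy number, estimated as
$(\bar d_{mt} / \bar d_{auto}) \times 2$ (two autosomal copies per diploid
cell), falls below 50 — low copy number makes NUMT-derived false calls more
likely. Calls are retained when FILTER is exactly `PASS`, depth is
strictly above 100×, the position is outside the known artifact and
low-complexity set (66–71, 301, 302, 310, 316, 3107, 12,418–12,425,
16,182–16,194), and VAF ≥ 0.1. The VAF floor reflects the observed bound of
~0.04 on the nDNA:mtDNA depth ratio: a single nuclear locus cannot push a
spurious allele above ~4% of mitochondrial coverage, so 10% is a
conservative floor; the ratio itself is surfaced per sample by
`depth_ratio_report()` as a diagnostic, not a filter. Calls with
VAF ≥ 0.95 are homoplasmic, [0.10, 0.95) heteroplasmic; distinct variants
are then `homoplasmic_only`, `heteroplasmic_only`, or `both` over their
carriers, and frequency-classed as common (carrier frequency ≥ 1%), rare
(≥ 0.1%), ultra-rare (< 0.1%) or private (one carrier, checked first).

Region annotation uses a bundled rCRS gene map (13 protein-coding, 22
tRNA, 2 rRNA genes, D-loop wrapping the origin) flattened into a disjoint
tiling. Where features overlap (e.g. *MT-ATP8*/*MT-ATP6*,
*MT-TI*/*MT-TQ*), precedence is tRNA > rRNA > protein_coding > D-loop,
ties to the earlier start; untiled spacers become `intergenic`. This
precedence is a package choice — the flattening must be deterministic and
no convention is canonical. Region enrichment of variant positions is an
upper-tail hypergeometric test: draws are the distinct variant positions,
successes the region's bases out of 16,569. MitoTIP pathogenicity scores
for tRNA variants are binned at 16.25/12.66/8.44 with boundary values
assigned to the lower bin, since the published ranges touch at their
endpoints.

## NUMT detection

Evidence enters as alignment records (TSV or minimal SAM text) — the
contract starts at aligned reads, mirroring BAM-derived workflows.
Discordant pairs with exactly one mate on chrM and one on a primary
nuclear contig, with pair MAPQ ≥ 20 (default; the upstream pipeline this
emulates does not state a bound), are chained per sample and chromosome by
single linkage with a maximum gap of 500 bp between successive sorted
nuclear positions. "Within 500 bp" could also mean a cap on total cluster
span; chaining was chosen and is oracle-tested against brute-force
connected components. Clusters with fewer than 5 pairs are discarded.
Cluster span midpoints within 1000 bp across samples form one event
(midpoint rather than breakpoint anchoring, since breakpoints do not exist
before refinement); each sample counts once.

Split reads whose nuclear anchor falls within the event span ± 500 bp are
mapped to candidate junctions: a read-order-adjacent (nuclear, chrM)
segment pair defines a nuclear breakpoint at the junction-facing segment
boundary and a mitochondrial breakpoint at the mate boundary. A junction
is confirmed by ≥ 2 split reads agreeing *exactly* (a tolerance is
configurable but defaults to exact identity); an event is refined only
when both a left and a right junction confirm. Unrefined events are
retained and flagged — discarding them would distort frequency accounting
— while concatenated/complex configurations are out of scope. The
pluggable aligner contract lets users supply a real split-mapper; the
default consumes pre-aligned segment coordinates, and
`align_split_read()` provides a local-alignment (Smith–Waterman via
Biostrings) reference adequate for high-identity reads.

Insertion size is circular-arc arithmetic: walking forward from breakpoint
$a$ to $b$ spans $(b - a) \bmod 16569$ bases, so arcs across the origin
(e.g. 16,500 → 100, size 169) need no special casing; identical
breakpoints denote a full-circle insertion of 16,568 bp (the junction base
is not duplicated). Known-NUMT flagging pads published intervals by 500 bp
on both sides before overlap testing. Per-sample counts use the sample
standard deviation (n − 1).

## Breakpoint enrichment

Mitochondrial breakpoints are summarised by their ECDF along the genome
and by counts per region divided by region length; regions shorter than
200 bp (default) are reported but flagged, as normalised counts in short
intervals are randomness-dominated. Nuclear enrichment uses a permutation
test: the observed statistic counts events whose ±100 bp window overlaps
the track; each permutation draws the same number of positions uniformly
over the genome (chromosome chosen proportional to length; windows past a
chromosome end truncated) and the upper-tail p-value is
$(\#\{null \ge obs\} + 1)/(n_{perm} + 1)$. The +1 pseudocount avoids p = 0
and sets the floor at $1/(n_{perm}+1)$. Genome-wide uniform sampling was
chosen over per-chromosome matching (the procedure emulated is ambiguous);
a per-chromosome option would be a small extension. Enrichment is
upper-tail only, matching the directional question asked of repeat tracks.
Stratification runs common, rare, common-and-rare, ultra-rare-plus-private
and all events.

## Invariable intervals

Only SNVs and deletions alter existing nucleotides: an SNV marks its
position variable, a left-anchored VCF deletion (ref `ACT`, alt `A` at p)
marks p+1..p+2 — the anchor base is unchanged. Insertions instead break
run contiguity at their anchor ("gap after k"): they insert material
between reference bases without changing any, so they split intervals
rather than invalidate bases. Maximal runs of non-variable positions,
split at gaps, are the invariable intervals; length-1 runs are kept in the
output so "> 1 nt" and "> 10 nt" summaries are derivable. The 16,569 → 1
adjacency is deliberately not joined — intervals are reported linearly.
Region composition is tested by upper-tail hypergeometric (invariable
bases as draws) and by a one-tailed rank-sum on interval lengths per
region class versus the rest (exact when samples are small and tie-free,
normal approximation otherwise). Cross-cohort intersection is positionwise
on invariable bases, re-segmented at any cohort's interval boundary (an
insertion gap removes no base but must still split), and filtered to
length > 10; the operation is associative and commutative.

## mtDNA–nDNA association

Genotype dosages (0/1/2, missing allowed) pass a sample call-rate filter
(> 0.9) before variant filters: call rate > 0.9, minor allele frequency
> 5%, and exact Hardy–Weinberg p ≥ 10⁻⁶. The HWE test is the standard
exact conditional test on the heterozygote count given allele counts (no
mid-p), implemented with log-factorials and verified against full
enumeration; a chi-square variant is available. mtDNA phenotypes are the
heteroplasmic levels (VAF) of variants carried by ≥ 5% of the unrelated
samples, with non-carriers assigned 0 — exclusion would leave common
homoplasmic variants without variance, so assignment to 0 is the only
workable reading. Note the source conventions differ on the mtDNA
threshold ("major allele frequency > 5%" vs "MAF ≥ 5%"); minor-allele ≥ 5%
is implemented, as a major-allele bound at 5% excludes nothing.

Each nuclear variant is fit by OLS of phenotype on dosage, intercept, top
12 genotype PCs (column-standardised, mean-imputed for PCA only, sign
fixed by the largest-magnitude loading) and sex (0/1 from metadata).
Implementation uses Frisch–Waugh–Lovell residualisation against the
covariate block with degrees of freedom n − p − 1, which is algebraically
the full-model Wald t-test; samples missing a dosage are excluded from
that variant's fit only, and constant or covariate-collinear dosages
return NA rows rather than vanish. BH q-values are computed per scan. The
published significance rule applies the BH-adjusted value against
α/93 = 5.4×10⁻⁴ — an unusual hybrid of FDR and Bonferroni which
`flag_significant()` reproduces verbatim, with `bonferroni = TRUE`
exposing the conventional alternative (raw p against the same divisor).
The stringent rule is raw p < 5×10⁻⁸/93 = 5.4×10⁻¹⁰. Relatedness
inference, LD pruning and mixed models are out of scope; the unrelated
sample list is an input.

## What the synthetic data does and does not emulate

The generators define the study conditions for all tests. `gen_mt_cohort()`
draws a site pool with a mostly-rare Beta(0.3, 3) frequency spectrum,
carried calls homoplasmic with probability 0.978 (the homoplasmic share of
calls in deep cohorts) and otherwise heteroplasmic with true VAF uniform
on [0.12, 0.90] — held off the 0.10/0.95 boundaries so binomial depth
noise cannot flip a class, which is what makes exact truth-agreement
checks meaningful; depths are Poisson around 3000× (deep mtDNA coverage)
and AD is Binomial(DP, VAF), or round(VAF·DP) in noiseless mode. Spurious
calls at artifact sites, below VAF 0.1, at low depth and with non-PASS
filters exercise every filter arm. `gen_numt_reads()` plants insertions at
nuclear positions separated by construction (so recall/false-call counts
are unambiguous), with ≥ 5 discordant pairs and ≥ 2 exactly agreeing split
reads per junction for detectable insertions and ≤ 4 pairs for decoys.
`gen_assoc_dataset()` produces Binomial(2, p) dosages, optional
two-population frequency shifts for PC structure, and phenotypes truncated
to [0, 1]. Not emulated: sequencing-error models beyond binomial sampling,
haplotype LD structure, mapping ambiguity around real NUMT sequence
homology, strand bias, or contamination mixtures. Passing tests therefore
demonstrate the correctness of the statistical machinery and filter logic
under the stated evidence model, not robustness to alignment artifacts in
real data.

## Numerical choices and problem sizes

Filters follow their quoted inequalities exactly: DP strictly > 100, VAF
≥ 0.1 inclusive, contamination strictly > 2% dropped, copy number < 50
dropped, insert size ≥ 250 kept, cluster gap ≤ 500 joins, midpoint
distance ≤ 1000 groups, MAF boundary per module as above. AD > DP is
rejected at parse time. The exact HWE sum uses a 1 + 10⁻¹² relative
tolerance when comparing configuration probabilities, the standard guard
against floating-point ties. Permutation p-values are seed-deterministic;
the pipeline derives per-stage seeds from one global seed so reruns are
byte-identical.

The shipped test and acceptance workloads use sizes chosen to make the
statistical checks decisive at desk scale: 50 planted NUMT insertions plus
50 decoys for recovery; 500 random instances of up to 200 pairs for the
clustering oracle; 500 replicates at 1000 permutations (100 events on a
1 Mb genome, 25% track coverage) for null calibration — with a fixed
seed, and noting that the +1 pseudocount and tied null counts make the
test slightly conservative, so its rejection rate sits a little below the
nominal 5%; association recovery at n = 2000 with 400 SNPs; 1000 random
toy genomes for the interval oracle; 120- and 60-sample synthetic cohorts
for the heteroplasmy spectrum and truth agreement.

## Known limitations

Real NUMT detection contends with reference NUMTs, segmental duplication,
and multi-mapping reads — none modelled here; the detector's exactness
guarantees hold for the aligned-evidence contract it is given. The region
map fixes one overlap-precedence convention; analyses sensitive to the
few overlapping bases should consult the raw table
(`mt_region_table(flatten = FALSE)`). The association scan fits one
variant at a time (no conditional analysis), and the BH-versus-Bonferroni
hybrid threshold is reproduced as published rather than endorsed.
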