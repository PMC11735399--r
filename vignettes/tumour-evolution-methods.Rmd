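---
title: "Models and design choices in tumourEvo"
author: "tumourEvo maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in tumourEvo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumourEvo)
```

tumourEvo analyses multi-region tumour sequencing data for signals of
genome evolution: whole-genome doubling (WGD), the timing of mutations
relative to it, selection before versus after it, parallel copy-number
evolution across regions, and copy-number scars of homologous
recombination deficiency (HRD). This vignette explains each model, the
parameters that matter, what the bundled simulator does and does not
emulate, and the design decisions taken where the methodology was
genuinely open.

## Whole-genome doubling from allele-specific copy number

The input is, per tumour region, an allele-specific copy-number (ASCN)
segmentation: disjoint segments with integer major and minor allele copy
numbers, stored as a `GRanges` inside a `RegionProfile` together with the
sample purity. A region is called doubled when the genome-length-weighted
fraction of segments with major CN $\ge 2$ reaches at least $0.5$; a
fraction with major CN $\ge 3$ of at least $0.5$ is read as two doublings.
Both thresholds are inclusive: a profile sitting exactly at one half is
called doubled.

Choices worth knowing:

* Fractions are weighted by segment length over the covered genome, not by
  segment counts — "half the genome" is a statement about base pairs.
* Sex chromosomes are excluded from numerator and denominator by default
  (`excludeSex = TRUE`) to avoid haploid-X artefacts.
* Calls whose decisive fraction lies within $\pm 0.02$ of the threshold
  are flagged `borderline`. The threshold rule is the whole story here;
  refinement of borderline calls from mutation copy numbers is a separate
  analysis that this package deliberately does not attempt, so the flag is
  the honest output.
* Samples with purity below 0.10 are excluded at load time; ASCN and VAFs
  below that purity are too unstable to interpret.

`harmonizeSegmentation()` re-cuts all regions of a tumour at the union of
their breakpoints. Copy numbers are constant on every sub-interval of an
original segment, so every length-weighted summary (WGD fractions,
ploidy, scar scores) is exactly preserved, and the operation is
idempotent — properties the test suite asserts directly.

## Clonality and mutation timing

Mutation clusters arrive with per-region phyloCCF summaries (mean and 95%
CI). The package does not re-implement phylogenetic CCF clustering; when
only read counts are available, `estimateClusterCCF()` builds a simple
substitute: per mutation and region, the mutation copy number
$m = \mathrm{VAF} \cdot (\rho T + 2(1-\rho)) / \rho$ is divided by its
rounded multiplicity to give a CCF, and cluster means receive percentile
bootstrap intervals (default 200 replicates) over the cluster's mutations.
This is a deliberate simplification: it ignores the phylogeny and treats
mutations within a cluster as exchangeable.

Clonality per region follows a CI-overlap rule: a cluster is clonal when
its 95% CI overlaps the trunk cluster's CI, with the trunk's left bound
raised to at least 0.9 so that a sloppy trunk interval cannot absorb
genuinely subclonal clusters; a non-clonal cluster with positive mean CCF
is subclonal; the rest are absent. The partition is exhaustive, exclusive
and independent of region order. At tumour level a mutation is clonal only
if its cluster is clonal in *every* region.

Timing uses multiplicity: in a doubled tumour a clonal mutation with
rounded multiplicity $\ge 2$ at a locus with major CN $\ge 2$ existed
before the doubling (it was duplicated with the genome) and is *early*;
multiplicity 1 is *late*. Open corners were resolved as follows:

* Multiplicity rounding is nearest-integer with ties-to-even, clamped to
  $[1, T]$ — a clonal mutation is present, so the floor is one copy.
* Loci with major CN $< 2$ in a WGD tumour are *not applicable*: after a
  post-WGD loss the copy number no longer witnesses the doubling, and
  guessing would systematically mislabel such mutations.
* Per-region multiplicity estimates are combined by a depth-weighted mean
  before rounding; the early/late label is the majority over informative
  regions with ties resolved to *late* (the conservative call: *early*
  requires positive evidence of extra copies).

## Timing-stratified dN/dS

Selection is summarised as
$\mathrm{dN/dS} = (n_{obs}/n_{exp}) / (s_{obs}/s_{exp})$, computed per
stratum (e.g. clonal-early versus clonal-late). The expectations come from
`expectedNSCounts()`: every one of the $3L$ single-nucleotide changes of a
coding sequence is classified synonymous or non-synonymous by codon
translation and weighted by the rate of its trinucleotide class under a
96-class spectrum (`SpectrumModel`, rates normalized to sum to one; the
$n_{exp}/s_{exp}$ ratio is invariant to rescaling). The flanking context
of the first and last base wraps around the sequence ends — a fixed,
documented convention that affects exactly two of $L$ positions and keeps
the enumeration total at $3L$.

The 95% CI treats $n_{obs}$ and $s_{obs}$ as independent Poisson counts:
exact Garwood intervals on each are combined on the log-ratio scale. This
is intentionally simpler than regression-based intervals from covariate
models; it is slightly conservative (joint coverage of two 95% intervals),
which the neutral-calibration test quantifies: across 200 neutral
simulations on a 500-codon gene the CI covers 1 in well over 90% of runs
and the median point estimate stays within $[0.9, 1.1]$. Nonsense and
splice mutations count as non-synonymous by default; a truncating-only
stratum (against the nonsense-site expectation) is available via
`truncatingSeparately = TRUE`, since truncating variants are often the
relevant class for tumour suppressors. Cohort category enrichment uses
Pearson's chi-squared without continuity correction on 2×2 tables, with
Fisher's exact test as a flag.

## Mirrored subclonal allelic imbalance

MSAI is the signature of parallel evolution: two regions of one tumour
carry the same class of copy-number event, but on opposite parental
haplotypes. Detection proceeds per harmonized segment:

1. **Phasing.** Among regions with mean $|BAF - 0.5| \ge$ `aiThreshold`
   (default 0.08), the most imbalanced region defines haplotype H1 by its
   per-SNP major alleles. Every other imbalanced region is labelled H1 or
   H2 by majority vote of its per-SNP major alleles against the reference;
   balanced regions stay unassigned. Majority voting (not per-SNP
   assignment) tolerates genotyping noise; at least `minSnps` (default 5)
   SNPs are required. The labels form a consistent two-colouring: flipping
   the reference region flips every label but preserves which pairs are
   mirrored.
2. **Event class.** Relative to the region's rounded weighted ploidy:
   loss/LOH when total CN is below ploidy or the minor allele is zero,
   gain/amplification when above. Measuring against ploidy rather than 2
   keeps WGD tumours sensible.
3. **Mirroring.** A segment where at least two regions share a class but
   carry opposite haplotype labels is an event; adjacent segments with the
   same signature are merged and annotated with overlapping cytobands.

Cohort-level, the per-cytoband proportion of tumours with at least one
event is tested against a permutation null that relocates each tumour's
events to uniformly random genome positions, preserving per-tumour event
counts and lengths. This is the least-assuming null available: it keeps
each tumour's event burden fixed and only randomizes position. The
empirical P uses the add-one estimator $(1 + k)/(n_{perm} + 1)$, so it is
bounded below by $1/(n_{perm}+1)$ and equals 1 when nothing is observed.
Benjamini–Hochberg adjustment across bands is reported alongside raw P
values. The defaults (0.08 imbalance threshold, 5 SNPs) are packaging
choices, exposed as parameters, chosen so that noise-free simulations
yield zero false positives while events with $\ge 10$ SNPs and
$|BAF-0.5| \ge 0.15$ are essentially always recovered.

## HRD scar scores and permutation bands

All scores first merge adjacent segments with identical ASCN, making them
invariant to how a profile happens to be split.

* **LST**: after iteratively absorbing segments shorter than 3 Mb into
  their larger neighbour, count chromosome-internal breakpoints whose
  flanks are both $\ge 10$ Mb and differ in ASCN.
* **TAI**: count allelic-imbalance segments that touch a telomere, do not
  span the full centromere interval, and are not whole-chromosome. No
  minimum segment size is imposed by default (variants of the score
  differ here; the threshold is a parameter).
* **HRD-LOH**: count LOH segments (minor CN 0) longer than 15 Mb that are
  not whole-chromosome.
* **wGII**: per chromosome, the fraction of length whose total CN differs
  from the sample's rounded weighted ploidy, averaged over chromosomes.
  Measuring against ploidy makes a uniformly doubled genome score zero.

Numerical conventions: "whole chromosome" means covering $\ge 95\%$ of
the annotated length, tolerating telomeric gaps; "crossing the
centromere" means spanning the entire centromere interval into the other
arm; smoothing ties (equal-width neighbours) resolve to the left
neighbour. Each scorer is checked exactly against an independent
brute-force oracle on a thousand random profiles.

Group comparisons (scar score or wGII against a binary label) use a
permutation test: the observed group-mean difference (or Spearman
correlation, as a flag) against a label-permutation null, reporting the
null's 90th/95th percentiles — the "confidence band" lines of the
corresponding figures — and an add-one empirical P on the absolute
statistic, so constant data give P = 1 and perfect separation reaches the
floor.

## The simulator: what it emulates, and what it does not

`simulateCase()` builds a tumour at 1 Mb resolution on haplotype-specific
copy-number matrices over a toy genome of five 100 Mb chromosomes
(centromeres at 45–55 Mb). Real genome builds can be supplied through
annotation files, but tests run on the toy genome for speed. The
generative model:

* Purities are uniform on `purityRange` (default 0.4–0.9, a realistic
  multi-region WES range); mean depth defaults to 100×.
* Clonal background SCNAs (two gains, two single-copy losses taken from
  the minor haplotype) precede/follow an exact duplication of the genome
  for each simulated WGD, so the WGD footprint — major CN ≥ 2 over at
  least half the genome — holds by construction, and gains are capped well
  below half the genome in non-WGD cases.
* Truncal mutations are split early/late by `wgdTimingFractionEarly`
  (default 0.5); early mutations carry multiplicity $2^{\#WGD}$, late and
  subclonal ones multiplicity 1. Mutations are placed in bins untouched by
  any event so their local copy number is unambiguous — a simplification
  that trades realism (mutations in CNA regions) for exact truth labels.
* Read counts are binomial with success probability CCF ×
  expected VAF at Poisson(depth); SNP BAFs reflect haplotype-specific CN
  with truncated-Gaussian jitter (s.d. `noise`, default 0.02). Setting
  `noise = 0` replaces *all* stochastic sampling by expectations, giving a
  fully deterministic, noise-free case — the regime in which truth
  recovery is asserted exactly.
* MSAI events are 8 Mb losses of opposite parental haplotypes in two
  region groups, placed in reserved slots that background SCNAs cannot
  touch or abut (an adjacent same-CN loss would merge with the event and
  dilute the phasing vote).
* Scar targets are engineered with shapes that each contribute exactly
  their own count and nothing else: LOH over 92% of a dedicated
  chromosome (spans the centromere, so it is no TAI; its only breakpoint
  has an 8 Mb flank, so it is no LST), telomeric 8 Mb imbalance for TAI,
  and balanced doubled-CN blocks with ≥ 10 Mb flanks for LST. Requesting
  more than the five chromosomes can host raises a capacity error rather
  than silently approximating.

What the simulator does **not** emulate: sequencing error and mapping
artefacts, subclonal copy-number change, mutations inside CNA segments,
kataegis/clustered mutational processes, indels and structural variants,
and real chromosome-arm geometry. Passing tests therefore demonstrate
that the *statistical machinery* is correct under its stated model, not
that the defaults are tuned to any particular real cohort.

Determinism is taken seriously: the same configuration and seed yield a
byte-identical serialized case, every helper that uses randomness takes a
seed and restores the caller's RNG state, and the cohort pipeline embeds
its seed and a configuration hash in the report, which reproduces byte
for byte on rerun.

## Problem sizes used in the checks

The test suite runs the WGD-recovery check on 200 simulated cases, timing
recovery on 50 doubled tumours at 100× and purity 0.5 (aggregate accuracy
well above the 95% requirement), dN/dS calibration on 200 neutral
simulations of 150 mutations each, the site-enumeration oracle on 100
random CDSs up to 60 codons, MSAI false-positive/sensitivity sweeps on
100 + 100 cases, scar-score oracle equivalence on 1,000 random profiles,
and a 20-tumour pipeline determinism check — sizes chosen to make the
suite statistically meaningful while completing in a few minutes on one
CPU.

## Known limitations

* The CCF construction is a bootstrap over per-mutation CCFs, not a
  phylogenetic clustering; with very few mutations per cluster its CIs
  are degenerate and clonality calls lean on the point estimate.
* dN/dS intervals are conservative by construction; with zero synonymous
  observations the upper bound is infinite and the row is flagged rather
  than dropped.
* The MSAI permutation null randomizes event *position* only; it does not
  model cytoband-specific susceptibility (e.g. fragile sites), so its P
  values answer "is this band hit more often than a random location of
  the same events", nothing stronger.
* Scar-score thresholds (3/10/15 Mb, 95% whole-chromosome rule) follow
  the established score definitions and are exposed as parameters; scores
  on exotic genomes (chromosomes much shorter than the thresholds) are
  not meaningful.
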