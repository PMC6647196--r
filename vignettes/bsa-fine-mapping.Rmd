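---
title: "Fine-mapping a dominant locus with pooled sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping a dominant locus with pooled sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamapr)
```

## The mapping problem

`bsamapr` implements the computational spine of a classical map-based
cloning campaign for a single dominant locus, of the kind used to localise
the dominant fuzzless gene of *Gossypium arboreum*: a biparental cross
between a mutant and its near-isogenic wild type, Mendelian segregation
checks on the F2 and BC1 progeny, a bulked-segregant sequencing (BSA-Seq)
genome scan on phenotype-selected pools, recombinant-marker narrowing of
the scan region, and candidate-gene prioritisation from differential
expression plus coding/promoter variant consequences. Because no raw data
accompany the motivating study, the package ships a synthetic-data
generator that reproduces the statistical structure each downstream stage
assumes, and the whole pipeline runs end to end on simulated data.

## Segregation testing

Phenotype counts are tested against the Mendelian expectation (3:1
fuzzless:fuzzy in a dominant F2, 1:1 in a BC1) with a chi-square
goodness-of-fit test, `chi2 = sum((O - E)^2 / E)` on one degree of
freedom, without continuity correction. The convention matters at the
second decimal: the uncorrected statistic gives 0.02 and 0.87 for the two
reference populations (3004/1006 and 315/292), while a Yates-corrected
version would give 0.01 and 0.80. A regression test pins the uncorrected
convention.

## Scan statistics

For each biallelic site the alt allele is anchored to the mutant parent,
which both parents' pool depths verify (the informativeness filter demands
an alt fraction of at least 0.9 in the mutant parent and at most 0.1 in
the wild parent, with minimum depths in parents and pools; failing sites
are dropped, never imputed). Two per-site statistics are computed between
the phenotype pools:

* **SNP-index** per pool, `alt / (ref + alt)`, and the **delta SNP-index**
  `index(fuzzless) - index(fuzzy)`, oriented so the causal peak is
  positive;
* **Euclidean distance (ED)** between the pools' allele-frequency
  vectors, which for a biallelic site reduces to `sqrt(2) * |delta f|`
  and is therefore bounded by `sqrt(2)`. An optional exponent
  (`ed_power`) sharpens peaks; the default of 1 matches a region-calling
  threshold on the 0.35 scale used in the reference analysis.

### The 2/3 ceiling of a dominant F2 scan

For a dominant trait, phenotype-selected F2 pools cannot drive the delta
SNP-index to 1. Enumerating the 1:2:1 genotype classes: the fuzzy pool is
fixed wild (mutant-allele frequency 0), while fuzzless individuals are
Aa:AA in ratio 2:1, giving a mutant-allele frequency of
`(2*(1/2) + 1*1)/3 = 2/3`. The expected causal-site delta SNP-index is
therefore 2/3 (and the ED peak `sqrt(2)*2/3 ≈ 0.94`). The simulator
encodes this truth and the tests verify convergence to 2/3, not to 1 —
the scan must and does detect peaks at that height.

### Smoothing, thresholding and region calling

Raw tracks are smoothed per chromosome with a tricube-distance-weighted
local mean (degree-0 local regression) over a 1 Mb window; the smoother
is a small C++ routine with truncation at chromosome ends, so every
fitted value is a convex combination of in-window raw values. The
reference text says only that "fitted values" were used; a tricube window
mean was chosen for robustness and simplicity, with the window exposed as
a parameter. SNPs and InDels are scanned as separate tracks (as the
reference figures do) and the class-wise regions are unioned per
statistic.

The calling threshold is **median + 3 sample standard deviations of all
fitted values, computed genome-wide** — the rule the reference analysis
used to arrive at its 0.35 cutoff. Candidate regions are maximal runs of
sites with fitted values at or above the threshold; runs separated by
less than `merge_gap` (default 100 kb) are merged, bridging isolated
low-coverage sites without joining distinct peaks. The final candidate
region is the intersection of the ED and delta SNP-index regions.
Coordinates are 1-based inclusive (VCF convention) internally; BED export
is 0-based half-open, and interval length is reported as `end - start`,
the convention under which the published endpoints 76,294 and 2,305,623
bp span 2.23 Mb.

## What the simulator emulates — and the design choice behind it

`sim_config()` defaults encode the reference study conditions: an F2 of
4,010 individuals (607 for BC1 work), a single dominant causal locus,
phenotype pools of 30 + 30, ~50x pooled depth with a small (0.001)
per-read error, 5,000 informative sites per 10 Mb chromosome, and a
Haldane crossover model (Poisson crossover counts, uniform placement, no
interference — interference is irrelevant at this scale). Parent pools
are fixed opposite homozygotes; only informative sites are emitted. Read
depth is Poisson per site and pool and alt counts are binomial in the
pooled allele frequency after error perturbation. Pool selection for a
binary trait is random within phenotype class ("extremely fuzzy" has no
further meaning for a two-state phenotype). An expression module
generates negative-binomial counts for a 2-genotype x 3-stage x
2-replicate design with truth labels, and stage assignment of true DEGs
defaults to the 370:13:22 split observed across stages in the reference
experiment.

**The genome is simulated as 13 chromosomes, not one.** At a realistic
map density (1 cM/Mb) a single 10 Mb chromosome spans only 0.1 Morgan, so
every site on it is tightly linked to the causal locus: the expected
delta SNP-index never falls below ~0.60 anywhere on the chromosome. A
median + 3 SD threshold computed on such a track exceeds its own maximum
and calls nothing — the rule presupposes a mostly-null genome, which is
exactly what it had in the genome-wide reference analysis. The generator
therefore simulates the focal chromosome plus `n_bg_chrom = 12` unlinked
background chromosomes of the same length and marker density (13 in
total, the chromosome number of diploid cotton), and the threshold is
taken genome-wide over all fitted points. Background chromosomes are
drawn only for pooled individuals, which is exact: loci unlinked to the
causal locus segregate independently of phenotype.

A consequence worth stating plainly: on a 10 cM chromosome the scan's
resolution is recombination-limited, not depth-limited. The whole focal
chromosome typically exceeds the genome-wide threshold, so increasing
depth from 20x to 100x does not shrink the called region (widths are
monotone non-increasing but essentially saturated). Narrowing below the
chromosome scale is the job of the recombinant-marker stage, as it was in
the original campaign. Simulations at these settings keep the intersected
candidate region over the true locus in ~99% of 200 replicate scans, and
the causal-site delta SNP-index averages 2/3 as derived above.

## Recombinant narrowing

`narrow_by_recombinants()` reconstructs standard map-based cloning logic,
which the reference describes only implicitly: place the causal locus in
each inter-marker slot in turn; infer each individual's genotype at that
placement from its nearest non-missing flanking markers under a
<= 1-crossover-per-interval assumption (individuals recombinant across
the slot impose no constraint there; missing calls are imputed only when
both flanks agree); accept the slot if every inferred genotype explains
the phenotype under single-locus dominance. The tightest marker pair
bounding the consistent slots is returned, and inconsistency (no slot, or
non-contiguous slots) raises an error rather than being silently
resolved, since it signals genotyping or phenotyping error, or a
multi-locus trait. Gene content of the final interval uses full
containment — the rule under which the published SSR82–InDel9 interval
(70,110 bp) contains exactly its seven annotated ORFs.

## Differential expression: the decision rule and its power floor

The reference analysis called transcripts differential at FDR < 0.01 and
|log2 ratio| >= 1 on FPKM values. The package implements that stated
decision rule directly — FPKM (`fragments * 1e9 / (library_total *
gene_length)`), a pooled-variance two-sample t-test on
`log2(FPKM + pseudo)` (pseudo-count 1 for stability with two
replicates), Benjamini–Hochberg adjustment within each stage, and the
printed cutoffs with the log2-ratio boundary included. The original
Cuffdiff machinery is deliberately not re-implemented, and the real-data
DEG counts (383/370/13/22) are not reproduction targets.

Two replicates leave the t-test 2 degrees of freedom, which imposes a
hard floor on attainable p-values: even a t-statistic of 50 gives
p ≈ 4e-4, and the BH threshold for a gene among k true positives out of
n tested is about `0.01 * k / n`. FDR < 0.01 is therefore reachable only
for strongly expressed, low-dispersion, large-effect genes. The pipeline
demonstration parameterises its true DEGs in that regime (around 16-fold
induction of well-measured genes, consistent with the strong qPCR-scale
effects reported for the reference candidates), and the embedded
candidate genes are up-regulated in the mutant as the reference
candidates were. Under the global null the realised discovery proportion
stays at or below the nominal 0.01; a composition caveat applies to
total-count FPKM normalisation when a large fraction of the library is
perturbed, which is why the demonstration keeps true DEGs a small
fraction of the transcriptome. Dispersion-sharing methods (DESeq2, edgeR,
Cuffdiff) would have far better power at two replicates; emulating them
is out of scope because the target is the printed filter.

qPCR quantification uses the standard `2^-ddCt` normalisation against a
reference gene and calibrator sample.

## Variant consequences

Coding insertions are frameshifts unless their length is a multiple of 3;
in-frame insertions at a codon boundary are named by translating the
insert with the standard nuclear code (the reference case: a TTG
insertion adding a leucine), codon-internal 3k insertions are reported as
composite codon replacements, and the mutated CDS is translated to flag
in-frame insertions that introduce a premature stop. Promoter variants
are substitutions within a configurable window upstream of the annotated
gene start (default 2,000 bp — the reference never defines "promoter
region"), mirrored on the minus strand. Sequence comparison uses a global
alignment (match 1, mismatch -1, gap opening 2, gap extension 1, as
implemented by `Biostrings::pairwiseAlignment`) converted to
substitution/insertion/deletion records; re-applying the records
reconstructs the second sequence exactly, which the tests exercise on
random edits.

## Numerical and interface conventions

* Intervals: 1-based inclusive; length `end - start`; full containment
  for gene queries; intersection is commutative and idempotent.
* All randomness flows from explicit integer seeds; identical seeds give
  bit-identical outputs, including pipeline manifests.
* Zero-variance expression groups are handled deterministically (equal
  means: p = 1; unequal: p = 0); zero-depth pools make a site's index
  undefined and the site is dropped upstream.
* Degenerate calls error loudly: empty tracks, unfillable pools
  (expected minority class minus three binomial SDs below the pool
  size), markers on different chromosomes, inconsistent recombinant
  data.

## Problem sizes used in the shipped checks

The package's own verification uses 200 replicate F2 scans at the full
reference design (4,010 individuals, 13 x 5,000 sites, 50x) for the
containment and convergence checks, brute-force oracles on tracks of up
to 50 sites and p-vectors up to length 1,000, a 2,000-gene null
expression simulation, and an 800-individual end-to-end pipeline run.
These sizes were chosen to give stable Monte-Carlo estimates (standard
errors well inside the tested tolerances) while remaining quick to run.

## Known limitations

* No read-level simulation (FASTQ, mapping bias, indel realignment) and
  no multi-allelic sites.
* The scan offers no depth-dependent confidence envelopes or G'
  statistic; the threshold rule is the reference's median + 3 SD only.
* Linkage-map construction (cM estimation, marker ordering) is out of
  scope; marker positions are taken as given physical coordinates.
* The expression stage models neither transcript assembly nor
  dispersion sharing, and inherits the two-replicate power floor
  discussed above.
* Passing tests on synthetic data show the statistics behave as derived
  under the generator's assumptions (clean biallelic sites, exact
  informative-site parents, Poisson/binomial sampling); they do not
  certify performance on real data with mapping artefacts, segregation
  distortion or polyploid cross-mapping.
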