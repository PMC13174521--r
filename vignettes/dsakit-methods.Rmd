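---
title: "Methods: somatic variant and repeat analysis on donor-specific assemblies"
author: "dsakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic variant and repeat analysis on donor-specific assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsakit)
```

## Scope and model

`dsakit` implements the bespoke computational procedures used when a matched
tumor/normal pair is analysed against the donor's own haplotype-resolved
assembly (a *donor-specific assembly*, DSA) rather than a population
reference. Somatic variation is then the literal difference between the
tumor and normal assemblies, which changes what is statistically possible
in repetitive regions: reads map to the correct haplotype, germline
variation no longer masquerades as somatic signal, and tandem-repeat
features (centromeric satellite, rDNA, distal junctions) become analysable
by k-mer methods.

The package deliberately does not reimplement assemblers, aligners, or
variant callers; it consumes their outputs (FASTA/VCF/BED/PAF/TSV) and
implements the decision layers on top: evidence rule engines, k-mer copy
number estimators, satellite array calling, lift-over with
representation-change classification, cluster detection, repeat-context
statistics, and rDNA profiling. A synthetic diploid genome generator
provides inputs with the statistical structure every stage assumes, so the
full pipeline is exercisable at desk scale with no external data.

## The synthetic diploid genome

`build_normal_genome()` emits miniature chromosome mimics (default 80 kbp,
3 autosome mimics and 5 acrocentric mimics) with a feature ledger in
0-based half-open coordinates. The defaults mirror the biology the
downstream estimators target:

* **Distal-junction (DJ) mimic** — one unique 3 kbp unit placed exactly
  once per acrocentric arm, the same sequence on every arm and haplotype.
  A normal diploid genome therefore carries 10 copies, and each DJ k-mer
  occurs 10 times — exactly the structure the diploid-peak estimator
  assumes (DJ-specific k-mers present once per distal junction and shared
  across arms).
* **rDNA mimic** — a tandem array of 8 identical 2 kbp units per
  acrocentric arm. The real 45S unit is ~45 kbp; the 2 kbp scale-down
  keeps runtimes interactive while preserving the analysis structure,
  with promoter/18S/5.8S/28S/IGS-like subregions placed proportionally
  (`rdna_regions()`).
* **Satellite arrays** — built from a fixed synthetic 171 bp monomer
  (`alpha_monomer_synthetic`, matching the canonical alpha-satellite
  monomer length but not a biological sequence), organised into
  higher-order repeat (HOR) units of 6 monomer slots with ~3% inter-slot
  divergence, tandemly repeated to ~15 kbp per chromosome.
* **Homopolymer and TR tracts** — per-chromosome sets spanning A/T runs of
  6-32 bp, C/G runs of 6-20 bp, and dinucleotide to pentanucleotide units,
  the contexts that drive indel error and slippage mutation models.
* **Germline variation** — heterozygous SNVs at 1e-3 per bp, each assigned
  to one haplotype. Germline variants are SNVs in the generator so that a
  single ledger indexes the reference-mimic and both haplotype FASTAs
  (SNVs do not shift coordinates). The germline *indel* interactions
  needed to exercise representation-change classification are constructed
  directly with `apply_variants()`/`lift_map_from_variants()`, which apply
  any variant set and return the exact block alignment between the two
  coordinate systems — the same primitive used to derive tumors and to
  verify round trips.

`derive_tumor_genome()` layers somatic events on the normal haplotypes:
point SNVs (5e-5 per bp per haplotype), slippage indels in homopolymer/TR
tracts (5% of tracts), monomer-multiple satellite SVs from an
unequal-crossover model (events are whole-monomer deletions or tandem
duplications, so sizes are exact multiples of 171 bp by construction), and
rDNA unit loss (default 30% of units per haplotype, reflecting the
near-halving of rRNA gene copies observed in tumors; contiguous lost units
merge into single deletions). A fraction of variants (20%) is subclonal
with cell fraction uniform on [0.1, 0.6]; truncal variants have cell
fraction 1. Overlapping events on a haplotype are rejected, structural
events taking precedence over small variants so configured loss fractions
are realised exactly. Applying the truth set to the normal sequences
reproduces the tumor sequences byte for byte (tested).

### Noise models

The simulators use the simplest models consistent with the statistics the
pipeline computes: Poisson k-mer counts (`simulate_kmer_coverage()`;
`depth` is per-occurrence coverage, so a diploid single-copy locus peaks
at 2×depth), Binomial read support (`simulate_support_tables()`), and
Beta-Binomial methylation (`simulate_methylation()`, dispersion as
intra-class correlation). Read support follows DSA mapping geometry: at a
somatic site, reads covering the carrier haplotype contig show VAF equal
to the cell fraction (not half of it), which is what makes the >50% tumor
VAF rule sensible; inside somatic duplications the VAF is halved because
reads from both copies pile together, which is what motivates the relaxed
30% rule. These simulations do not model mapping ambiguity, strand bias,
quality-score miscalibration, or coverage waviness, so passing tests
demonstrate correctness of the decision logic and estimators under their
stated statistical assumptions, not robustness to real-world artefacts.

## K-mer copy number

`estimate_copy_number()` implements the GC-matched-bin logic: background
bins of 2 kbp on a chosen chromosome are selected within ±0.02 absolute GC
of the feature (`select_matched_bins()`); feature and bin k-mer counts are
filtered (`filter_kmer_counts()`) by removing unobserved k-mers, counts
more than 3 sample standard deviations above the set mean (a single pass,
strict inequality — all-equal counts remove nothing), and k-mers absent
from the reference set, and by dividing multi-copy k-mer counts by their
multiplicity; the estimate is the ratio of medians divided by
`ploidy_divisor` (2 when the background chromosome is haploid in the
sample). The 3-SD filter is applied separately per k-mer set (feature,
bins); the alternative joint-set reading is possible but the separate
filter is the one implemented and tested. K-mers are strand-canonical
(lexicographic minimum of the k-mer and its reverse complement) because
reads are unstranded.

`estimate_dj_copy_number()` normalises the DJ k-mer count median to the
diploid coverage peak, detected as the mode of the genome-wide k-mer count
spectrum after excluding counts below `min_peak_count` (default one
quarter of the spectrum median, which removes the error/low-count tail).
Copy number is `2 × median / peak`. Estimates are reported as reals;
integer calls are a final rounding step, applied only where an integer is
the quantity of interest.

Calibration (tested): for true copy number 1-20 at 30× coverage the
GC-matched estimator's mean relative error is below 5% over 10 seeds, and
estimates are invariant to depth scaling.

## Satellite regions and SV periodicity

`motif_passes_length_filter()` keeps a candidate motif when its length is
within 2% of n×170 bp for some n up to 5 (alpha-satellite) or 42 (HSat1A);
the denominator of the 2% test is the target multiple n×170, since the
rule measures closeness to that multiple. `call_satellite_regions()` drops
monomer hits above 30% divergence, merges hits transitively while gaps are
at most 100 kbp (inclusive, on interval ends), discards merged cores below
30 kbp, and extends survivors by 1 Mbp of slop clipped to sequence bounds.
`assign_region_chromosome()` names a region by the argmax aligned
fraction, requiring at least 5%; ties yield `unassigned` — a chromosome
name is never fabricated.

`estimate_sv_periodicity()` scores each candidate period p by the mean of
`min(s mod p, p − s mod p)/p` over SV sizes below 5 kbp and returns the
*largest* period within a small tolerance (1e-6) of the optimum: every
divisor of the true period scores 0, so the largest near-optimal period is
the non-degenerate answer. On synthetic monomer-multiple SVs the estimator
returns 171 bp (tested across seeds).

## Evidence rule engines

`evaluate_polish_candidate()` encodes the polishing gates: only homozygous
calls with GQ above 4 and local coverage below twice the mean are
correction candidates; ONT calls are additionally rejected in homopolymers
longer than 6 bp or dinucleotide TRs longer than 11 bp, for 1-2 bp indels,
and below GQ 10; HiFi calls in those repeats yield when any short-accurate
callset has a 1-4 bp indel at the site. `merge_polish_edits()` dedups
identical calls across technologies, removes edits within 5 bp of a
somatic SV breakpoint, and resolves conflicting overlaps by priority
short-accurate > HiFi > ONT. All inequalities are implemented exactly as
printed (strict where strict).

`classify_truncal()` applies technology applicability before voting:
long-read evidence is ignored at homopolymers longer than 6 bp that short
reads cover (coverage above the gate — the 6 bp bound mirrors the
polishing homopolymer rule; "covered by short reads" is not further
specified upstream, so this is a recorded package choice), and short-read
evidence is ignored for indels over 10 bp or low mapping quality (a
caller-supplied flag; MQ < 20 is the suggested convention at I/O). Every
applicable combined-mapping technology with coverage above 5 in both
samples must then show tumor VAF > 0.50 (0.30 inside somatic duplications)
and normal VAF < 0.10; per-haplotype short-read rows must satisfy
(>0.30 and <0.10) or (>0.90 and <0.70). The combined vote is a
conservative AND across technologies — the source phrasing is ambiguous
between AND and OR, so the strict reading is used and per-technology
verdicts are returned for audit. When both the duplication and
per-haplotype contexts apply, both rules are enforced (again the
conservative combination). Technologies at or below the coverage gate
abstain; with no applicable evidence the verdict is
`insufficient_evidence`, not an error. Both engines are verified against
independently coded brute-force oracles over exhaustive grids (tested),
and classification is monotone in tumor and normal support.

## Contig assignment

`score_contig()` computes, per (haplotype, chromosome), query coverage
(merged query intervals over contig length) times the
alignment-length-weighted mean gap-compressed identity; absent cells score
0. Gap-compressed identity is `matches / (matches + mismatches +
gap_openings)` from an extended CIGAR — the de facto definition, recorded
here because the name alone does not pin it down; plain `M` operations are
rejected as ambiguous. `assign_contig()` ranks chromosomes by mean score
across *all* panel haplotypes, requires at least 95% of haplotypes to rank
the winner first and a mean score of at least 0.60. Haplotypes with no
alignments stay in the unanimity denominator (they cannot agree), and a
tied per-haplotype argmax counts as disagreement — both conservative
choices. Panel size is a parameter; tests use up to 20 synthetic
haplotypes while the thresholds reproduce the printed minimum agreeing
count at a 466-haplotype panel.

## Lift-over and representation change

`lift_map()` is an explicit list of colinear alignment blocks between DSA
and reference coordinates — synthetic genomes ship with their true
alignment, so no external chain file or liftOver binary is involved.
`lift_variant()` projects the variant interval plus 50 bp of slop through
the blocks; a projection must cover at least `min_match = 0.1` of the
interval within one colinear run; zero qualifying runs is `unliftable`,
two or more disjoint targets is `multi_lift`. Consecutive blocks separated
by more than `max_colinear_gap` (default 10 kbp) on either side are
treated as separate runs — small gaps are germline indels within one
alignment chain, large gaps indicate distinct placements.

`classify_representation()` reconstructs the local tumor haplotype (DSA
window plus the somatic variant) and the lifted reference window, derives
the variant set a reference-based caller would see (tumor-vs-reference
differences minus normal-vs-reference differences, via global pairwise
alignment and left-alignment normalization — representation comparisons
are meaningless without normalization), and compares the re-derived call
to the DSA truth. Precedence: `unliftable` > `multi_lift` >
`in_germline_cnv` > `reverts_germline` > `type_changed` > `size_changed` >
`difficult_region` > `position_shift_only` > `unchanged`. Type compares
SNV against indel: a deletion that re-represents as a net insertion
through an overlapping germline insertion is a *size* change (the
canonical 2 bp deletion inside a 10 bp germline insertion becomes an 8 bp
net indel), while an SNV that becomes representable only as part of an
indel is a *type* change. `difficult_region` is an input BED tag, not
computed — difficult-region stratifications come from external sources —
and it only demotes calls whose type and size survived. On constructions
where germline indels overlap somatic indels at rate 0.3, the fraction
classified {type_changed, size_changed, reverts_germline} recovers 0.3
within binomial error (tested).

`build_benchmark_regions()` produces the three benchmark tiers: `all`
(slopped lifted somatic regions minus exclusions — subclonal variants, SV
breakpoints ±50 bp, assembly errors, complex repeats),
`nogermlineinterference` (additionally excluding regions whose
representation class is type_changed/size_changed/reverts_germline), and
`nogermlinewithin50bp` (every region at least 50 bp from any germline
variant).

## Clustered mutations

`detect_clusters()` is greedy segmentation of same-haplotype SNVs with
inter-mutation gap at most `max_gap`; runs of at least 6 are kataegis,
runs of 2-5 are omikli. The source reports event counts without printing
its distance and size thresholds, so the defaults here (1 kbp gap, 6, 2-5)
are the standard literature definitions, declared as package defaults and
parameterised — the printed event counts are therefore not reproduction
targets. `compare_cluster_sets()` matches reference-projected clusters to
DSA truth clusters by at least 50% member overlap (parameterised);
unmatched reference clusters are *false*, attributed to opposite-haplotype
collapse when their members span both haplotypes, otherwise to
germline-representation interaction when any member's class is in the
germline-interaction set; unmatched DSA clusters (e.g. wholly inside
unliftable satellite) are *reference-missed*.

## Repeat-context statistics

`annotate_repeat_context()` reads homopolymers (minimum reportable length
4 — the decision rules reference lengths above 6, but the census extends
lower so rate curves have context) and dinucleotide TRs (minimum span 6,
two distinct bases) directly from the sequence as maximal runs containing
or abutting the variant; satellite/segdup/VNTR/STR classes come from
annotation BEDs, with fixed precedence satellite > segdup > VNTR > STR >
diTR > homopolymer > none. `enrichment_table()` computes fold =
(n_class/bp_class)/(n_total/bp_total) — per-bp densities, not per-element;
zero-footprint classes are flagged undefined rather than given a fold.

`sbs96_profile_and_test()` maps SNVs to the 96 pyrimidine-strand
trinucleotide classes and tests each region's profile against the
whole-genome proportions with a chi-square goodness-of-fit, pooling
categories whose expected count falls below 1, with Benjamini-Hochberg
correction across regions. The chi-square+BH combination is a package
choice (the source states only the thresholds p < 1e-4 and FDR < 0.01);
its type-I error at 1e-4 is verified by simulation against the
genome-wide multinomial null (tested at 1e5 simulated regions of 1000
SNVs). Profiles are strand-symmetric by construction.

`homopolymer_indel_rate()` uses per-site semantics: the denominator is the
number of genomic homopolymer tracts of each length (from
`homopolymer_census()`), not bp — a rate-versus-length curve reads
naturally per site — with Wilson 95% intervals. `polya_tail_length()`
measures the maximal terminal A run, optionally tolerating interruptions
flanked by at least 5 A's on both sides.

## rDNA profiling

Reads cannot be assigned to individual rDNA arrays, so all analyses
operate on one collapsed repeat unit. `bin_methylation()` excludes sites
under 100 reads and aggregates into 200 bp bins; the bin mean is the
pooled modified/total ratio over retained sites (coverage-weighted — the
stated "ratio of modified to total reads" is a pooled ratio, not a mean of
site ratios; the distinction is asserted on an unequal-coverage case), and
empty bins are missing, never zero. `per_read_region_methylation()` keeps
alignments covering more than 70% of the reference at more than 90%
identity, removes the globally least-confident 10% of calls (one quantile
across the sample, matching upstream tool behaviour; a per-read variant
would be a one-line change), and returns per-read means — bimodal when a
low-methylation read population is present. `variant_density()` removes
variants below Q30 or 5% allele frequency and reports variants per kb per
region.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open everywhere internally; only VCF I/O
shifts to 1-based. Variant normalization is left-alignment with parsimony
trimming and is idempotent. Interval merging treats book-ended intervals
as mergeable only under an explicit flag. Degenerate inputs error early
with actionable messages: empty k-mer tables, no GC-matched bin (advises
widening the tolerance), zero bin median, no detectable diploid peak,
fewer than 3 SV sizes, zero-length contigs or regions. Ties break
conservatively throughout (largest near-optimal period; unassigned on
chromosome ties; non-agreement on per-haplotype score ties).

## Problem sizes

The default synthetic genome is 8 chromosomes × 80 kbp × 2 haplotypes
(1.28 Mbp diploid) — large enough that k-mer spectra show clean diploid
peaks and satellite arrays hold dozens of monomer-multiple SVs, small
enough that the full test suite, including the 200-run copy-number
calibration and the 1e5-region test calibration, completes in minutes on
one core. All absolute-bp thresholds (100 kbp merge distance, 1 Mbp slop,
30 kbp minimum array) remain at their real-data defaults and are
config-scalable.

## Known limitations

* No read-level simulation: support tables and methylation pileups are
  drawn from their sampling distributions directly, so mapping artefacts
  are out of scope.
* Lift maps support colinear "+"-strand blocks; inversions and
  strand-flipping rearrangements are not projected.
* The representation classifier re-derives one somatic call per window;
  clustered somatic variants inside a single 50 bp window are classified
  by their nearest derived difference.
* Kataegis/omikli thresholds are declared defaults, not inferred source
  values; absolute event counts from any particular dataset are not
  reproduction targets.
* The SRF/TRF motif discovery stages themselves are consumed, not
  reimplemented; only the published filter/merge logic operates here.
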