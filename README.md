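# dsakit

Somatic variant and repeat analysis on donor-specific tumor/normal
assemblies.

## The problem

When a tumor and its matched normal are both assembled telomere-to-telomere,
somatic variation can be read off as the literal difference between the two
assemblies instead of being inferred against a population reference. That
changes the analysis layer: reads map to the donor's own haplotypes, germline
variation stops contaminating somatic calls, and tandem-repeat regions
(centromeric α-satellite, rDNA arrays, acrocentric distal junctions) become
tractable with k-mer methods. `dsakit` implements the decision and
estimation procedures this workflow needs, for methods developers and
benchmark builders working with assembly-based somatic callsets:

* **K-mer copy number** — feature copy number as the ratio of k-mer count
  medians against GC-matched background bins,
  `CN = median(k_feature) / median(k_bins) / ploidy_divisor`
  (bin size 2 kb, k = 31, single-pass 3-SD outlier removal, counts divided
  by genomic multiplicity), and distal-junction style copy number by
  diploid-peak normalisation, `CN = 2 · median(k_DJ) / peak_diploid`.
* **Satellite arrays** — the monomer-multiple motif length filter
  (|L − n·170| / (n·170) ≤ 0.02, n ≤ 5 for α-satellite, n ≤ 42 for HSat1A),
  divergence filtering, 100 kbp transitive merging, 30 kbp minimum array,
  1 Mbp slop, the 5% chromosome-naming rule, and SV-size periodicity with a
  largest-near-optimal-period tie-break.
* **Evidence rule engines** — the multi-technology assembly-polishing
  candidate filter (GQ, coverage, homopolymer/diTR and small-indel gates
  per technology) and the truncal somatic classifier (tumor VAF > 50% and
  normal VAF < 10% at coverage > 5, 30% in somatic duplications,
  two-regime per-haplotype short-read rules, technology applicability
  masks).
* **Contig assignment** — coverage × gap-compressed-identity scoring
  against a haplotype panel with a 95% unanimity rule and 0.60 score floor.
* **Representation shift** — block-list lift-over with ±50 bp slop and
  minMatch 0.1, classification of how germline variation changes a somatic
  variant's reference representation (unliftable, multi-lift, germline CNV,
  reverts-germline, type/size change, position shift), tiered benchmark
  BEDs, and kataegis/omikli cluster detection with haplotype-aware
  false-cluster attribution.
* **Repeat-context statistics** — enrichment folds per repeat class, SBS96
  trinucleotide profiles with per-region chi-square tests and BH
  correction, homopolymer 1 bp indel-rate curves with Wilson intervals,
  and LINE poly-A tail lengths.
* **rDNA profiling** — 200 bp methylation bins over coverage-filtered CpG
  pileups, per-read regional methylation with alignment and confidence
  filters, and per-region variant density under Q30 / 5% AF filters.
* **Synthetic data** — a deterministic diploid tumor/normal genome
  generator (satellite HOR arrays from a 171 bp monomer, rDNA-like tandem
  units, one DJ-like unit per acrocentric arm, homopolymer/TR tracts,
  germline hets, truncal and subclonal somatic SNVs/indels/SVs with
  repeat-biased placement) plus Poisson k-mer, Binomial read-support, and
  Beta-Binomial methylation simulators, so every stage is testable with no
  download.

## Worked example

```r
library(dsakit)

# a synthetic normal diploid genome with the default acrocentric layout
genome <- build_normal_genome(genome_config(seed = 1))
#> diploid genome: 8 chromosomes x 2 haplotypes (1.28 Mbp diploid)
#>   ledger: 861 features (homopolymer, tr, rdna_18S, rdna_28S)
#>   germline het SNVs: 639

# 30x k-mer coverage and distal-junction copy number
counts <- simulate_kmer_coverage(genome, k = 31, depth = 30, seed = 2)
dj <- kmer_table(genome$dj_seq, counts, k = 31)
estimate_dj_copy_number(dj, counts)
#> copy number estimate: 9.900 (diploid-peak)
#>   feature k-mer median: 297.0
#>   diploid peak median: 60.0
#>   k-mers used: 2970 (filtered: 0)

# a tumor derivative and the periodicity of its satellite SVs
tumor <- derive_tumor_genome(genome, somatic_config(seed = 3))
sizes <- tumor$truth$size[tumor$truth$mechanism == "unequal_crossover"]
estimate_sv_periodicity(sizes)$period
#> [1] 171

# truncal classification of the somatic truth set from read support
support <- simulate_support_tables(tumor$truth, default_tech_profiles(),
                                   genome = genome, seed = 4)
labels <- classify_truncal_table(support)
table(labels$label, truncal = tumor$truth$cell_fraction == 1)
#>              truncal
#>               FALSE TRUE
#>   not_somatic    36    0
#>   truncal         6  135
```

What the numbers mean: the genome carries one DJ-like unit per acrocentric
arm per haplotype (5 arms × 2 haplotypes), and the diploid-peak estimator
reads 9.9 ≈ 10 copies back from the k-mer counts — the DJ k-mer median
(297×) sits at five times the diploid coverage peak (60×). The satellite
SVs were generated by a monomer-multiple unequal-crossover model, and the
periodicity estimator recovers the 171 bp monomer exactly. The truncal
classifier recovers all 135 truncal variants; the six subclonal variants it
also labels truncal are those whose simulated cell fraction exceeds 0.5,
which the >50% VAF rule cannot distinguish from truncal by construction.

A full account of the models, parameter defaults, and design choices is in
`vignettes/dsakit-methods.Rmd`.

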