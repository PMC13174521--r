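Package: dsakit
Title: Somatic Variant and Repeat Analysis on Donor-Specific Tumor/Normal Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing somatic variation between matched tumor and
    normal genome assemblies of the same donor. Implements k-mer based copy
    number estimation for tandem-repeat features (GC-matched background bins
    and diploid-peak normalisation), satellite array calling and structural
    variant size periodicity, multi-technology assembly polishing and truncal
    somatic variant classification rule engines, contig chromosome assignment
    by coverage-identity scoring, somatic variant lift-over with
    representation-change classification and kataegis/omikli cluster
    detection, repeat-context statistics (enrichment, SBS96 profiles,
    homopolymer indel rate curves, LINE poly-A tails), and ribosomal DNA
    methylation and variant density profiling. A synthetic diploid
    tumor/normal genome generator provides the statistical structure every
    stage assumes so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
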