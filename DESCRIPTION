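Package: didymascan
Title: Detection of Clustered APOBEC and Carcinogen Mutations in Somatic Catalogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing co-mutagenesis between APOBEC cytidine
    deaminases and bulky-adduct carcinogens in somatic single-nucleotide
    variant catalogs. Classifies mutations into APOBEC (TCW) and
    carcinogen-associated (guanine adduct) context classes, detects
    clustered mutation events and labels them as didyma (strand-coordinated
    APOBEC pairs within 32 nt), omikli, or kataegis, computes per-distance
    pair enrichment against context-, strand- and region-preserving
    simulated backgrounds, refits known SBS96 mutational signatures by
    two-pass non-negative least squares, and attributes events to genic
    space, transcribed strands and expression bins. Includes a synthetic
    data generator that plants didyma inside nucleotide-excision-repair
    sized single-strand tracts so the whole pipeline can be exercised and
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
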