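Package: syntevo
Title: Synteny, Ks Distributions, and Ancestral Karyotype Reconstruction for Polyploidy Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for inferring whole-genome duplication and karyotype history
    from gene order and coding sequence. Reads gene position tables (BED/GFF3),
    CDS FASTA and homologous gene-pair tables; chains homologous anchors into
    collinear blocks in gene-rank space by dynamic programming; estimates
    syntenic depth ratios; computes synonymous and nonsynonymous divergence by
    Nei-Gojobori (1986) counting with Jukes-Cantor correction over
    protein-guided codon alignments; fits Gaussian mixtures to log-Ks
    distributions with BIC model selection; corrects lineage-specific
    evolutionary rates against a shared polyploidy event and dates it;
    profiles collinear gene retention along a reference genome; and
    reconstructs contiguous ancestral regions by adjacency consensus with
    per-branch rearrangement classification. Includes a genome-evolution
    simulator with known truth (whole-genome triplication, fractionation,
    inversions, translocations, fusions and fissions, and codon-sequence
    divergence to a target Ks) used for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    mclust,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
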