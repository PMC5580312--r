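Package: synorth
Title: Synteny-Aware Orthologue Prediction Across Annotated Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts orthologues, inparalogues and de novo gene births across
    multiple annotated genomes (FASTA + GFF3). Genes are compared with full
    Smith-Waterman local alignment and ranked by a fragment-bias-corrected
    similarity score (per-column alignment score weighted by percent identity),
    making the calls robust to truncated gene models from draft assemblies.
    Within-species duplicates are separated from ancestral copies with Markov
    clustering and neighbour-joining trees on codon alignments; pairwise 1:1
    orthologues are assigned by maximum-weight matching and re-calibrated with
    micro-synteny windows; multi-species orthogroups, a consensus species tree
    and named super-orthogroups are then assembled. A genome-evolution
    simulator with planted orthology truth and an evaluation module support
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    Biostrings,
    rtracklayer,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    ape,
    phangorn,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
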