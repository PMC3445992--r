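Package: phyloLGT
Title: Phylogenomic Screening of Inter-Domain Lateral Gene Transfer
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: A phylogenomic pipeline for detecting inter-domain lateral
        gene transfer (LGT) in archaeal genomes from per-gene phylogenies.
        Gene trees annotated with leaf taxonomy are classified by
        sister-group composition into LGT and non-LGT verdicts with
        inferred transfer direction and donor phylum; verdicts from two
        tree-inference methods (neighbor-joining and maximum likelihood)
        are reconciled under congruence rules; codon amelioration is
        scored with the codon adaptation index (CAI) and the effective
        number of codons (ENC) against a genomic background; and
        ancestral gene-family content is reconstructed on a species tree
        by Fitch, Dollo or gain-weighted parsimony. Synthetic-data
        generators with planted transfer histories make every stage
        testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, ape, phangorn, Biostrings,
        jsonlite
Suggests: testthat (>= 3.0.0), seqinr
Config/testthat/edition: 3
biocViews: Phylogenetics, Genetics, SequenceAnalysis, Software
RoxygenNote: 7.3.3
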