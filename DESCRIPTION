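Package: panseed
Title: Alignment-Free Pangenome Genotyping with Spaced Seeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An alignment-free, k-mer-based diploid genotyper built around
    spaced seeds. Provides seed algebra (palindromic seed combinatorics,
    mirror extension), canonical spaced k-mer counting from FASTA/FASTQ,
    exact single-seed sensitivity by dynamic programming with an overlap
    complexity based hill-climbing seed designer, a pangenome bubble-graph
    genotyper driven by a Li-Stephens haplotype-pair hidden Markov model
    over unique-k-mer Poisson emissions, strict genotype-concordance
    evaluation metrics with exact Wilcoxon signed-rank tests, and a diploid
    read/panel simulator so the whole pipeline runs on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
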