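Package: pepscape
Title: Mutational Landscapes of Peptide-Hormone Precursor Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Charts the population-genetic mutational landscape of a
    peptide-hormone precursor gene such as proglucagon (GCG). Aggregates
    missense variants across sequencing cohorts under a maximum-allele-
    frequency rule with singleton tracking, enumerates all theoretically
    possible SNV-derived amino-acid substitutions from the coding sequence,
    maps variants onto the precursor's peptide architecture with dual
    (precursor and peptide-local) numbering, scores per-site evolutionary
    conservation from orthologue alignments with Gaussian-smoothed traces,
    summarizes per-peptide deleteriousness (CADD, PrimateAI) with
    Mann-Whitney contrasts and bootstrap mean-difference estimation, and
    classifies receptor-ligand stability changes from replicate free-energy
    scans. A synthetic-data generator reproduces the statistical structure
    of every input so the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
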