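Package: mesoimmunity
Title: Genotype-Phenotype Analysis of Temperate Phage Superinfection Immunity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing how the immunity-system genotype of temperate
    Cluster A mycobacteriophages (immunity repressor sequences, genome-wide
    repressor binding sites known as stoperators, and gene content) relates to
    superinfection-immunity phenotype. Provides a constrained EM motif finder
    for 13-14 bp stoperator sites, position weight matrix construction and
    normalized motif distances, whole-genome nucleotide and gene-content
    distance estimators, per-gene protein distances with helix-turn-helix
    Hamming distances, an ordinal 0-6 infection scoring rubric with replicate
    aggregation, reciprocal asymmetry and profile-correlation statistics,
    phenotype-versus-distance regressions, a mutation-notation parser for
    escape-mutant catalogs with repressor-impact classification, one-site
    equilibrium binding fits, and a synthetic-clade generator that emulates a
    diverging phage clade with planted stoperators and mesoimmune ordinal
    immunity matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
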