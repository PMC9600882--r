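Package: caproscope
Title: Bioenergetics and Regulon Analysis of Lactate-Based Caproate Fermentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing anaerobic chain-elongation fermentations of
    the kind carried out by Caproicibacterium lactatifermentans. Balances
    fermentation equations exactly over elements and charge using rational
    arithmetic, computes transformed standard reaction Gibbs energies from a
    packaged formation-energy table, and implements a cofactor-ledger model of
    chain-elongation bioenergetics (substrate-level and chemiosmotic ATP via
    the Rnf complex and a V-type ATPase, NADH and reduced-ferredoxin balances,
    hydrogen venting). Also provides IUPAC-consensus position-weight-matrix
    scanning of intergenic regions for transcription-factor binding sites
    (Rex, LldR), transcriptome summary statistics (TPM, differential-gene
    filtering, hypergeometric COG enrichment, transcript fractions, 2^-ddCT),
    and deterministic synthetic-data generators with machine-readable ground
    truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
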