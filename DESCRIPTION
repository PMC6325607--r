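Package: coalscan
Title: Identification and Redox Biochemistry of Protein CoAlation from Tandem-MS and Kinetic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify S-thiolation of protein cysteines by coenzyme A
    (protein CoAlation) from tandem mass-spectrometry data, and to analyse the
    redox biochemistry that accompanies it. Provides in-silico Lys-C digestion
    and monoisotopic peptide mass calculus, combinatorial enumeration of
    cysteine-modified peptidoforms and precursor matching, theoretical b/y
    fragment ladders with CoA remnant chemistry, diagnostic neutral-loss
    scanning of CID spectra, modification-site localization, intact-protein
    mass-shift and occupancy analysis, pseudo-first-order inactivation and
    apparent second-order rate-constant fitting, Michaelis-Menten fitting with
    kcat conventions, cysteine pKa titration fitting, free-thiol
    quantification, and seeded synthetic-data generators for every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
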