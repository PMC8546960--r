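Package: sectorAlloc
Title: Four-Sector Proteome Allocation Analysis of Bacterial Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying proteome allocation in exponentially
    growing bacteria from multi-omics measurements. Converts transcriptome
    sector fractions (TPM x gene length), total-RNA/total-protein ratios and
    growth phenotypes into a four-partition proteome model (ribosomal R,
    metabolic M, unused/hedging U and core Q sectors) with translational and
    metabolic efficiencies, performs regulon/sigma-factor/pathway enrichment
    of differentially expressed genes, quantifies absolute metabolite
    concentrations by 13C isotope dilution with QC rules, and correlates
    metabolite pools with growth phenotypes. Includes a synthetic multi-omics
    study generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
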