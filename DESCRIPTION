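Package: runscan
Title: Runs of Homozygosity, Heterozygosity-Rich Regions and Genomic Inbreeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of runs of homozygosity (sliding-window method) and
    heterozygosity-rich regions (consecutive method) from SNP genotypes in
    PLINK PED/MAP text format, with quality control, per-SNP diversity
    statistics (observed/expected heterozygosity, MAF, FIS), ROH-based
    inbreeding coefficients (FROH, overall and by length class), run islands,
    pedigree (A), SNP-based (VanRaden G) and ROH-overlap relationship
    matrices, and a parameter-sensitivity sweep engine. Includes a gene-drop
    pedigree simulator with recombination so every stage can be exercised and
    validated against known identity-by-descent structure.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
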