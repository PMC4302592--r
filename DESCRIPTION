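Package: xcitrio
Title: Trio-Based Inference of Imprinted X Chromosome Inactivation from
    Allele-Specific Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers imprinted X chromosome inactivation (XCI) from
    mother-father-daughter allele counts at expressed SNPs, as used in
    marsupial parent-of-origin studies. Reads per-sample allele depths
    (VCF or TSV), applies coverage and heterozygote-curation filters,
    exploits paternal X hemizygosity to Mendelian-phase the daughter's
    alleles, classifies SNPs and loci as paternally inactivated or as
    escapers of XCI (>10 percent minor-allele rule), assigns loci to X
    evolutionary strata by a flanking-gene rule, and tests escape-by-
    stratum association with an exact hypergeometric test. Includes a
    seeded synthetic trio generator with known ground truth so the full
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
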