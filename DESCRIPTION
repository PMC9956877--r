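Package: cnfootprint
Title: Copy-Number Footprints of Chemotherapy Exposure in Whole-Genome Doubled Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify copy-number (CN) footprints of anticancer
    therapies from allele-specific somatic CN segment tables. Computes
    length-weighted genome ploidy, loss-of-heterozygosity (LoH) fractions and
    whole-genome doubling (WGD) status; classifies segments into the 48-category
    CN feature space (copy-number level x zygosity x segment length); screens
    tumor-type/treatment combinations for exposure-associated CN category
    differences with rank-based tests, treatment-overlap deduplication and
    Benjamini-Hochberg correction; quantifies the platinum CN footprint
    (per-sample intensity of short CN 1-4 fragments, cumulative profile
    differences, 1-Mb regional distribution) and its association with
    platinum SBS mutational-signature activity; and simulates cohorts with
    known ground truth for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
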