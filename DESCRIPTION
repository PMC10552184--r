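Package: vxmkit
Title: Virtual Crossmatch Assessment and Proficiency-Survey Analysis for HLA Laboratories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for histocompatibility laboratories and proficiency-testing
    programs working with the virtual crossmatch (VXM). Parses HLA allele and
    antigen nomenclature at the mixed resolutions used in donor typing reports,
    matches single-antigen-bead (SAB) antibody panels against donor typings to
    call donor-specific antibodies (DSA) -- including surrogate-bead calls for
    off-panel donor alleles and shared-eplet reactivity flags -- and predicts
    flow-cytometry and complement-dependent-cytotoxicity crossmatch outcomes
    with organ-specific risk stratification. Also implements consensus grading
    of multi-laboratory survey submissions (supermajority rules for crossmatch
    and antibody-specificity analytes), inter-laboratory MFI dispersion
    statistics (mean, SD, percent CV), VXM-versus-physical-crossmatch
    concordance tables, and a synthetic multi-laboratory survey generator with
    scenario presets (low-level DSA, off-panel alleles, C-locus-only DSA,
    shared eplets, high-MFI CDC-negative sera) for validating the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
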