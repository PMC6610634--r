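Package: xifold
Title: Allele-Resolved Analysis of Inactive-X Chromosome Folding and Allelic Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the architecture of the inactive X chromosome
    (Xi) from allele-resolved Hi-C contact matrices, coverage tracks, and
    allele-specific RNA-seq count tables. Implements iterative correction
    (ICE) of binned contact matrices, observed/expected normalization,
    Pearson correlation maps, eigenvector-based A/B and S1/S2 compartment
    calling, Crane-style insulation scores with boundary detection, an
    inter-megadomain interaction statistic for the Dxz4 boundary,
    coverage-track arithmetic (scaling, delta tracks, region densities,
    summit-centered metaprofiles), and the allelic-expression classification
    cascade (%mus, escapee / subject-to-XCI calls, reactivation tests).
    A synthetic-data generator plants compartments, megadomains, and allelic
    silencing with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
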