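Package: larvalpcp
Title: Planar Cell Polarity Analysis for the Drosophila Larval Epidermis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studying planar cell polarity (PCP) in
    the ventral epidermis of the Drosophila larva. Implements a
    neighbour-comparison model of Dachsous (Ds) activity across the
    seventeen cell rows of an abdominal segment, including atypical
    multipolar cells and Dachs-side predictions; membrane-fluorescence
    quantification of Ds levels from line profiles with Tukey multiple
    comparisons and per-row asymmetries; circular statistics for growing
    microtubule (EB1 comet) directions, including Sison-Glaz simultaneous
    multinomial confidence intervals, per-cell bootstrap comparisons,
    22.5-degree sector scans and maximum-likelihood selection among von
    Mises mixture models; exact Fisher tests on predenticle-orientation
    contingency tables; and seeded synthetic-data generators that emulate
    the microscopy inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
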