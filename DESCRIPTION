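Package: nodusym
Title: Multi-Scale Quantification of Legume Nodule Symbiotic Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative comparison of nitrogen-fixing bacteroids across
    physiological scales in determinate (bean) and indeterminate (pea) legume
    root nodules. Implements geometric nodule-volume models from 2-D sections
    (sphere for bean; spherical cap plus cylinder for pea), a bacteroid
    packing census from 3-D segmentation data, acetylene-reduction and
    15N2-fixation rate normalization across eight physiological scales,
    Hi3/top3 absolute proteome quantification with five copy-number
    denominators, and a synthetic-data generator that emulates every raw
    measurement table from a ground-truth parameter set so the full pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
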