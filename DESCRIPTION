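Package: ampliomics
Title: Very-Large-Scale Amplification of Multi-Omics Feature Tables by
    Random-Mask Uniform Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Amplifies a small subject-by-analyte multi-omics matrix
    hundreds-to-thousands-fold by class-aware row replication followed by
    random masking of a configurable fraction of entries, which are refilled
    with uniform draws from each feature's observed range. Includes the
    surrounding machinery needed to exercise the method end-to-end without
    external data: per-feature distribution profiling (range and a normalized
    histogram-entropy randomness score), median fill for missing entries and
    sentinel-zero exception handling, block-wise CSV/HDF5 storage with a
    checksummed manifest, a synthetic quadra-omics generator with planted
    group differences, and an evaluation harness that measures how the
    imputation level changes the detectability of those planted differences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    rhdf5,
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
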