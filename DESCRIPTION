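Package: gsiprofile
Title: Design and Simulation of Dual-Energy CT Automatic Exposure Control Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing dual-energy CT scan profiles on scanners whose
    automatic exposure control selects a fixed tube current from a discrete
    preset grid. Models preset families (rotation time, helical pitch,
    collimation, focal spot, achievable CTDIvol range), builds
    small/medium/large/extra-large profiles by a greedy dose-range covering
    procedure, quantifies how precisely any target CTDIvol can be matched by
    the resulting discrete dose grid, and simulates the scan-time workflow
    (projected noise index, flags, and the technologist's 2 HU switching
    rule) on synthetic patient thickness profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
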