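Package: loxtraj
Title: Gas-Ligand Migration, Competition and Pose Analysis for MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory-analysis toolkit for studying how small gas ligands
    (molecular oxygen and nitric oxide) enter, migrate through, and compete
    inside a protein such as human 15-lipoxygenase-2. Computes ligand-residue
    contact timelines and residence times, named-site occupancy intervals and
    binding-site qualification, entrance assignment along migration paths,
    two-species displacement events near a target atom, catalytically
    competent pose statistics, and substrate coordination profiles. Includes
    a seeded synthetic-trajectory generator with machine-readable ground
    truth for end-to-end validation, and a small monoisotopic mass calculator
    for phosphatidylethanolamine species and their oxidized or nitrosylated
    derivatives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
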