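Package: aortaflow
Title: Haemodynamic Quantification and Prediction Validation for Aortic 4D Flow Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies aortic haemodynamics from voxel-based velocity fields
    (4D velocity-encoded MRI or computational fluid dynamics output): peak
    velocity, secondary flow degree, surface-averaged and Hagen-Poiseuille
    wall shear stress, and categorical helicity/vorticity/eccentricity flow
    grades on lumen cross-sections. Provides Murray's-law outflow splitting
    and node-wise inlet velocity-profile mapping for boundary-condition
    construction, triangulated vessel-wall comparison (mean surface distance,
    Hausdorff distance, iterative-closest-point alignment), and the paired
    predicted-versus-observed validation protocol (Kolmogorov-Smirnov
    normality screen, paired t-test, regression through the origin,
    Bland-Altman limits of agreement, Friedman test on ordinal grades,
    Bonferroni correction). Ships analytic synthetic generators (Poiseuille,
    solid-body swirl, eccentric jet, paired cohorts) with closed-form ground
    truth so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
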