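Package: fetopep
Title: Amniotic Fluid and Fetal Urine Peptidome Comparison and Biomarker
    Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing the endogenous peptide content (peptidome)
    of two fetal body fluids measured by capillary electrophoresis coupled
    to mass spectrometry (CE-MS): amniotic fluid (AF) and fetal urine (FU).
    Implements detection-frequency filtering per gestational-age bin,
    two-fluid overlap (Venn) partitions with count and abundance-share
    summaries, paired-sample Spearman screening that attributes a fetal-urine
    origin to amniotic-fluid peptides, a downstream biomarker-panel workflow
    (Wilcoxon candidate selection, random-forest scoring, cutoff
    optimisation, validation with exact Clopper-Pearson confidence intervals
    and DeLong AUC inference), rule-based in-silico protease digestion, and
    a seeded synthetic CE-MS-like cohort generator with known ground truth
    so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
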