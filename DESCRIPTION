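Package: meltrisk
Title: Mixture Toxic-Risk Screening of Snow-Melt and Road-Runoff Contaminants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening polar contaminants mobilised by urban snow
    melt and road runoff. Implements toxic units under concentration addition
    with an EC50 selection hierarchy (experimental 5th percentile, else a
    baseline-toxicity QSAR with a solubility cap), chronic and acute
    mixture-risk classification per biological quality element, source
    attribution of wastewater-treatment-plant influent compounds by Spearman
    correlation with inlet flow, removal-rate estimation from cumulative
    loads, and synthetic-data generators with known ground truth for
    end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
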