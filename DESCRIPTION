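Package: socchrono
Title: Soil Organic Carbon Stock Change Analysis for Paired Land-Use
    Chronosequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for space-for-time analyses of soil organic carbon (SOC)
    stock change after land-use conversion, built around clustered paired-plot
    designs (one reference forest plot plus one to three converted plots per
    cluster). Computes depth-interval and profile SOC stocks with an
    equal-bulk-density correction that evaluates converted-plot stocks at the
    reference plot's bulk density, litter-layer carbon stocks, and tree and
    bamboo basal areas; derives cluster-paired absolute and relative stock
    differences; fits linear mixed-effects land-use by depth models with
    per-depth contrasts and Holm adjustment; screens covariates with Spearman
    rank correlations; and fits one- and two-pool exponential decay models of
    the proportion of forest carbon remaining, with steady-state times. A
    synthetic-study generator emulating the clustered chronosequence design
    supports end-to-end testing and parameter-recovery simulation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    minpack.lm,
    multcomp,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
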