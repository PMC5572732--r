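Package: audtrait
Title: Screening for Addiction-Like Behavior in Rat Alcohol
    Self-Administration Cohorts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for phenotyping vulnerability to alcohol use disorder in
    operant self-administration cohorts: a synthetic cohort generator with a
    latent single-factor addiction liability, three-criterion percentile
    screening (persistence of seeking during signaled non-availability,
    progressive-ratio breakpoint, resistance to footshock punishment), the
    composite z-score addiction severity index, single-factor validation via
    the eigenvalue-1 rule, and a group-statistics layer including
    summary-statistic ANOVA reconstruction, Tukey-Kramer post hoc tests and
    mixed repeated-measures designs for choice and blood-alcohol data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    withr,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
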