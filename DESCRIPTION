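Package: crtmort
Title: Cluster-Randomised Mortality Trial Analysis with Dual Death Enumeration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for cluster-randomised trials of biannual
    mass drug administration with infant mortality endpoints. Simulates
    complete synthetic trials (gamma-distributed cluster rates, census and
    birth-history observation streams from one underlying truth), accrues
    deaths and person-years at risk under both enumeration procedures,
    estimates incidence rate ratios via cluster-level Poisson regression with
    robust (sandwich) variance, rate differences with a stratified cluster
    bootstrap, and Monte Carlo permutation p values, corrects rate differences
    for death under-ascertainment with a probabilistic bias analysis under a
    beta sensitivity prior, estimates cumulative infant mortality with a
    Demographic and Health Surveys style synthetic cohort life table, and
    provides Hayes-Moulton power and detectable-effect calculations for
    comparisons of incidence rates with between-cluster variation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    sandwich,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
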