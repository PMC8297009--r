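Package: bifactorsim
Title: Simulation and Subgroup Confirmatory Factor Analysis of Structural
    Models of Psychopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Generates large skewed synthetic populations of disorder
    symptom scores from published bifactor generating parameters
    (Fleishman polynomial transforms with Vale-Maurelli intermediate
    correlations), fits four structural models of psychopathology
    (correlated factors, full bifactor, revised bifactor, single factor)
    by maximum likelihood with Satorra-Bentler scaled test statistics and
    sandwich standard errors, computes chi-square based fit indices
    (CFI, TLI, RMSEA with noncentral confidence intervals, SRMR), screens
    solutions for admissibility (Heywood cases, non-positive-definite
    latent covariances, non-significant or negative loadings), derives
    regression factor scores, and sweeps the 63 overlapping
    symptom/factor-score tertile subgroups to assess whether the p-factor
    and its specific factors retain their structure and neurocognitive
    correlates within heterogeneous subgroups of a population.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
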