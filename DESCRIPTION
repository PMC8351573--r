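Package: erlangfit
Title: Grid-Search Fitting of Classical Probability Densities to Age-Binned Cancer Incidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits five classical two-parameter probability density functions
    (gamma/Erlang, Weibull, extreme value (Gumbel), logistic and normal) to
    age-binned crude cancer incidence rates by exhaustive grid search over the
    shape/location and scale parameters, with a nested golden-section search
    for the curve amplitude at every grid node and selection of the global
    R-squared optimum. Reads CDC WONDER-style tab-separated incidence exports,
    generates synthetic incidence cohorts with known ground truth, ranks model
    families while flagging fits that place probability mass at negative ages,
    and interprets the gamma/Erlang optimum as carcinogenesis quantities: the
    average number of driver events (shape k), the mean inter-event interval
    in years (scale b), and the maximal populational susceptibility
    (amplitude/1000, in percent).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
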