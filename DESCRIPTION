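Package: chapmanbias
Title: Dispersal-Related Bias of Two-Sample Mark-Recapture Abundance
    Estimates in Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact and asymptotic moments of Chapman's two-sample
    mark-recapture abundance estimator for closed stream reaches and for
    reaches open to fish dispersal, together with the modified
    expanded-reach sampling design that reduces dispersal-related bias.
    Provides effort-standardized capture probabilities, five-zone design
    comparison tables, critical-abundance calculations for the asymptotic
    bias approximation, a spatially explicit individual-based simulator of
    the two-sample experiment with beta-kernel fish movement, and a small
    command-line interface for estimates, design tables, and simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
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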