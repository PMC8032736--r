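Package: borealburn
Title: Wildfire Burn Severity and Boreal Forest Carbon Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the effect of wildfire on the carbon balance
    of boreal forest landscapes. Implements the satellite burn-severity chain
    (Normalized Burn Ratio, dNBR with summer compositing and background
    correction, gap-filling, and the dNBR to Composite Burn Index to combustion
    fraction mapping with its inverse), a reduced-form monthly carbon-nitrogen
    ecosystem simulator with fire disturbance and post-fire foliage and moss
    recovery, cohort-based regional bookkeeping that contrasts fire and no-fire
    scenarios, diagnostic reports (fire-regime summaries, severity-class
    chronosequences, emission partitions), and a synthetic-data generator so
    the whole pipeline runs and is testable without satellite or climate
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    withr,
    yaml
Suggests:
    optparse,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
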