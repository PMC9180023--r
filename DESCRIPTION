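Package: equipanel
Title: Equity of Tiered Health-Resource Allocation Across Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the equity of health-resource allocation (institutions,
    beds, personnel) across regions in a tiered healthcare system from a
    balanced region-by-year panel. Implements the trapezoid Gini coefficient
    on grouped data under population and geographic-area calibres with
    fairness banding, the health resource density index (resources per
    geometric mean of population and area), the Theil index with its
    between-zone/within-zone decomposition and contribution rates, and the
    Mann-Kendall trend test with tie-corrected variance and continuity
    correction. Includes a synthetic province-panel generator for end-to-end
    testing and a reporting pipeline that emits the full set of index series
    and trend tables as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
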