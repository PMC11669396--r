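Package: bioscore
Title: Biosecurity Scoring and Benchmarking for Pasture-Based Dairy Herds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A farm biosecurity audit pipeline for pasture-based dairy herds:
    elicitation of expert weights for biosecurity management practices by
    best-worst scaling (MaxDiff) with count-based and sequential best-worst
    logit estimators and bootstrap confidence intervals; plausibility-driven
    correction of weight orderings with an auditable log; questionnaire
    scoring per section and subcategory as a percentage of the maximum
    attainable weighted score; cattle-introduction network indicators
    (in degree, inward strength, secondary inward degree) over a rolling
    three-year window with same-category percentile benchmarking; and
    traffic-light farm reports against a comparator score distribution.
    Includes a synthetic-data suite (questionnaire fixtures, expert choice
    panels with known utilities, farm populations with latent quality, and
    cattle movement networks) so the whole pipeline is testable end to end
    without access to national databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
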