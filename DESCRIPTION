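Package: tenderMCDA
Title: Multi-Criteria Decision Analysis for Off-Patent Pharmaceutical Tenders
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds, elicits and applies multi-criteria decision analysis
    (MCDA) frameworks for national tenders of off-patent pharmaceuticals.
    Criteria carry ordinal performance categories with score fractions and
    optional exclusion rules; weights are elicited from workshop votes via
    median voting, modified SMART ranking and swing weighting with two-stage
    normalization; bids are scored with a linear price function anchored to
    the lowest eligible bid and a configurable cut-off; products are ranked
    by weighted composite score, with winner selection and sensitivity
    sweeps over the price weight and cut-off. Ships an Indonesian 6+1
    pilot framework, its workshop vote records and four hypothetical test
    cases as fixtures, plus generators for synthetic tenders and vote
    sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
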