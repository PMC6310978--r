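# tenderMCDA

Multi-criteria decision analysis (MCDA) for national tenders of off-patent
pharmaceuticals.

Lowest-price procurement treats competing off-patent products as
interchangeable, but they differ in equivalence with the reference product,
manufacturing quality (GMP tier), stability, supply reliability and
pharmacovigilance. tenderMCDA scores each candidate product on a weighted
criteria set and ranks by the composite

> *S<sub>j</sub> = Σ<sub>i</sub> w<sub>i</sub> s<sub>ij</sub>*,  Σ w<sub>i</sub> = 1,  s<sub>ij</sub> ∈ [0, 1]

where non-price criteria are scored by ordinal performance categories (with
optional disqualifying *exclusion* categories) and price by a linear value
function anchored at the lowest eligible bid *p*<sub>min</sub>:

> *s(p) = clamp(1 − ((p − p<sub>min</sub>)/p<sub>min</sub>) / c, 0, 1)*

with cut-off excess *c* (bids at or beyond *p*<sub>min</sub>(1 + *c*) score
zero; with *c* = 2, a bid at twice the lowest price scores exactly 0.5).

Criterion weights are elicited from workshop votes: median voting on fixed
option grids for the price weight and cut-off, majority-vote criterion
exclusion, modified SMART ranking by sequential plurality votes, swing
weighting (base 10 points, multiplicative increments up the importance
ladder) and two-stage normalization. The Indonesian 6+1 pilot framework, its
vote records and four hypothetical tender test cases ship as fixtures.

Intended users: procurement agencies and health-technology-assessment
analysts who need a transparent, reproducible alternative to lowest-price
tender scoring, and methodologists studying weight-elicitation processes.

## Worked example

Elicit the weighted framework from the packaged workshop votes, then score
the four pilot test cases (bids 2200 / 2900 / 3000 / 3800 IDR):

```r
library(tenderMCDA)

fw <- elicit_framework(opp_framework("draft"), opp_votes())
weight_report(fw)
#>               criterion rank swing_points nonprice_weight_pct final_weight_pct
#> 1                 price   NA           NA                  NA             40.0
#> 2     quality-assurance    1        51.75                31.3             18.8
#> 3           equivalence    2        34.50                20.9             12.5
#> 4 stability-formulation    2        34.50                20.9             12.5
#> 5    supply-reliability    3        23.00                13.9              8.4
#> 6   real-world-outcomes    4        11.50                 7.0              4.2
#> 7     pharmacovigilance    5        10.00                 6.1              3.6

res <- evaluate_tender(opp_test_cases(), fw)
res
#> MCDA tender evaluation — 4 products, 4 eligible; lowest eligible bid: 2200
#>   #1   test-case-2    price     2900  composite  61.2%
#>   #2   test-case-3    price     3000  composite  59.4%
#>   #3   test-case-1    price     2200  composite  54.1%
#>   #4   test-case-4    price     3800  composite  49.8%
```

The weight report is the elicitation trail: swing points accumulate up the
importance ladder (10 → 11.5 → 23 → 34.5 → 34.5 → 51.75; the 0% increment
between equivalence and stability encodes equal importance), are normalized
to relative non-price weights, and folded against the 40% price weight voted
in the adjustment round (initial medians were 50% for both the price weight
and the cut-off). In the evaluation, the cheapest bid takes the full 40%
price component, yet test case 2 wins: its stronger equivalence, quality and
supply profile outweighs its 32% price premium under the +100% cut-off —
exactly the trade-off the framework exists to make explicit.

What-if analysis over the two parameters the process treats as adjustable:

```r
sensitivity_sweep(opp_test_cases(), fw, "price_weight", c(0.40, 0.50, 0.70))
#>      parameter value      winner                                               ranking changed
#> 1 price_weight   0.4 test-case-2 test-case-2 > test-case-3 > test-case-1 > test-case-4   FALSE
#> 2 price_weight   0.5 test-case-2 test-case-2 > test-case-1 > test-case-3 > test-case-4    TRUE
#> 3 price_weight   0.7 test-case-1 test-case-1 > test-case-2 > test-case-3 > test-case-4    TRUE
```

At the 70% price weight of the pre-MCDA rules the cheapest product wins; at
40% quality carries the tender.

## Command line

A thin Rscript front end ships at `inst/cli/mcda-tender`:

```sh
mcda-tender elicit  --framework indonesia_draft.yaml --votes indonesia_votes.csv --out fw.yaml
mcda-tender score   --framework fw.yaml --matrix tender.csv --format json --out report.json
mcda-tender winners --framework fw.yaml --matrix tender.csv --n 2
mcda-tender sweep   --framework fw.yaml --matrix tender.csv --param price_cutoff --grid 0.5,1.0
mcda-tender fixtures --emit ./fixtures
mcda-tender simulate --out ./sim --n-products 8 --seed 42 --with-votes
```

Reports embed the framework hash, tool version and seed so any run can be
reproduced bit-identically.

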