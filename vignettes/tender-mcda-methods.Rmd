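---
title: "Weighted-sum MCDA for off-patent drug tenders: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-sum MCDA for off-patent drug tenders: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tenderMCDA)
```

## The decision problem

National tenders for off-patent pharmaceuticals are usually decided on price
alone, which implicitly assumes that competing products are interchangeable.
In practice they differ in equivalence with the reference product,
manufacturing quality standards, supply-chain reliability and
pharmacovigilance capability — differences a lowest-price rule cannot see.
tenderMCDA implements a weighted-sum multi-criteria decision analysis (MCDA)
model for such tenders: each product is scored on every criterion, and its
composite score

$$S_j \;=\; \sum_i w_i \, s_{ij}, \qquad \sum_i w_i = 1,\; s_{ij} \in [0,1]$$

is the ranking statistic. One criterion is always the acquisition price; the
others are qualitative criteria with ordinal performance categories.

## Non-price criteria: categories, score fractions, exclusions

A non-price criterion is an ordered scale of performance categories. Each
category maps to a *score fraction* — the share of the criterion's full score
awarded at that level — with the best level at 1 and fractions non-decreasing
up the scale. A category can instead be flagged as an **exclusion category**:
performance so poor that the product is disqualified from the tender rather
than scored (for example, no pharmaceutical-equivalence data at all). An
excluded product receives no composite and no rank, and by default does not
anchor the price function either (see below).

The packaged Indonesian fixtures assign *equally spaced* fractions across
each criterion's non-exclusion categories (worst = 0, best = 1, linear in
between). The pilot workshop validated per-criterion scoring functions but
their exact fractions were never tabulated, so the package uses this neutral
default and lets the YAML config override every single fraction; nothing
downstream depends on the spacing being linear. Which categories are
exclusion categories was likewise a workshop decision rather than a published
table, so the fixtures flag none by default and the mechanism is exercised
through configuration.

## The price criterion

The price score is a linear value function anchored at the lowest eligible
bid $p_{\min}$:

$$s(p) \;=\; \operatorname{clamp}\!\left(1 - \frac{(p - p_{\min})/p_{\min}}{c},\; 0,\; 1\right)$$

where $c > 0$ is the **cut-off excess**: bids at or beyond
$p_{\min}(1 + c)$ score zero (a bid *exactly at* the cut-off scores 0, not an
infinitesimal positive value). With $c = 2$ (a +200% cut-off) a bid at twice
the lowest price scores exactly 0.5. Anchoring the zero point at a fixed
excess over the lowest bid — rather than at the most expensive competitor —
makes the score independent of the price distribution of the field, so the
steepness can be tuned to the expected spread instead of being dictated by
it. The function is scale-free: multiplying all bids by a constant changes
nothing.

Two deliberate edge rules:

* $p_{\min}$ is computed over **eligible** products only; a disqualified bid
  should not distort its competitors' price scores. The alternative
  (`price_reference = "all"`) is available as a flag.
* A price below the context's $p_{\min}$ is an error, not a score above 1 —
  it means the context was built from the wrong bid set.

## Weight elicitation

Weights come from a structured group process, implemented stage by stage in
`elicit_framework()`:

1. **Price weight** ($w_p$): anonymous votes on a 5%–100% grid in 5% steps;
   the group value is the **median**, which damps outliers. For an even
   number of votes the mean of the two middle votes is snapped to the nearest
   grid value, midpoints snapping *down* — a deterministic, grid-closed rule
   (the published medians are all on-grid, so the snap direction only matters
   for hypothetical sessions).
2. **Price cut-off**: the same median rule on a +25%…+500% grid.
3. **Exclusion votes**: a criterion named by a *strict majority* of a round's
   cast votes is dropped before ranking. "Majority voting" without stated
   quorum rules is read as simple majority of votes cast.
4. **Modified SMART ranking**: starting from a hypothetical worst-case
   product, each round's plurality winner is the next most important
   criterion; the last unvoted criterion takes the final rank without a
   round. Tied tallies break lexicographically by criterion id and the tie is
   recorded — determinism over silent arbitrariness.
5. **Swing weighting**: the least important criterion gets 10 points; each
   step up the ladder multiplies the previous points by $1 + \delta_k$, with
   $\delta_k$ the median of that step's votes on a 0–50% (5% steps) / 50–100%
   (10% steps) grid. $\delta_k = 0$ encodes equal importance: identical
   points, shared display rank. Points are kept at full precision.
6. **Two-stage normalization**: ladder points are normalized to relative
   non-price weights ($w_i = P_i / \sum_j P_j$), then folded against the
   price weight ($w_i \leftarrow w_i (1 - w_p)$). Optional adjustment rounds
   re-vote $w_p$ and $c$ after the test-case walk-through and override the
   initial medians.

Weights are stored at full double precision; *display* rounding is half-up
to one decimal percent (`percent_display()`), which reproduces conventional
report tables without accumulating rounding error internally. For the
packaged Indonesian session this pipeline yields the ladder
(10, 11.5, 23, 34.5, 34.5, 51.75), relative weights $P_i/165.25$, and final
weights that display as 40.0 / 18.8 / 12.5 / 12.5 / 8.4 / 4.2 / 3.6 percent.

## Evaluation, ties, winners, sensitivity

`evaluate_tender()` scores every product, disqualifies any that fall in an
exclusion category, anchors the price function on the remaining bids, and
ranks by descending composite. Composite ties break by **lower price first,
then product id**, and are flagged in the output — a procurement context
prefers the cheaper of two equally scored bids, and the residual id
tie-break keeps results reproducible. If every bid is disqualified the
result is an explicit "no eligible bids" object, not an error.
`select_winners()` clamps to the eligible set; multiple winners per tender
are supported because single-winner tenders discourage participation.

`sensitivity_sweep()` re-evaluates the tender over a grid of price weights
or cut-offs. When the price weight is swept, the elicited *relative*
non-price weights are held fixed and re-folded against each grid value —
mirroring the workshop's own adjustment step, where only the price weight
and cut-off were re-voted, never the swing ladder.

## Synthetic data: what it emulates and what it does not

`generate_tender()` draws bids multiplicatively around a reference price,
log-uniform over a factor range defaulting to $[1, 2.5]$ — chosen so that a
+100% cut-off produces both positive and zero price scores in a typical
draw, the regime the test cases probe — with uniform category selections by
default and an optional per-criterion exclusion probability.
`generate_votes()` emulates a voting session around a stated group
preference: numeric rounds displace each voter's preferred grid position by
a rounded $N(0, \text{dispersion})$ number of grid steps (clamped to the
grid); SMART rounds vote the true next criterion with probability
$1/(1+\text{dispersion})$, otherwise uniformly among the remaining
candidates. Dispersion 0 therefore recovers the generating framework
exactly, which is the pipeline's key identifiability check.

These generators emulate the *structure* of a real session — grids, tallies,
round sequence, one category per criterion per product — not its behavioural
features: real voters are correlated, anchor on earlier rounds, and real
tenders have far-from-uniform category profiles. Passing tests demonstrate
arithmetical and procedural correctness, not that any particular weight set
is the right policy.

## Numerical choices and degenerate inputs

* All weight identities are enforced to $10^{-12}$ internally; config
  round-trips are tested to $10^{-9}$ (YAML serialization at 15 significant
  digits).
* Grid membership checks use a $10^{-9}$ absolute tolerance so that
  fractions arriving through `seq()` arithmetic or percent strings compare
  cleanly.
* A framework whose weights are all unset (a pre-elicitation draft) is
  structurally valid; the weight-sum invariant activates as soon as any
  weight is set, and evaluation refuses unweighted frameworks outright.
* Degenerate cases with defined behaviour: a single non-price criterion
  (weights $(1 - w_p, w_p)$, no SMART/swing rounds needed), a zero-spread
  tender (all price scores 1), all-zero increments (all criteria equal),
  all products excluded (explicit empty result).

## Problem sizes

The test suite and examples run at the scale the method is used at — tenders
of 4–12 products, 6–9 criteria, 15–21 voters — plus a 1000-product draw for
the sampling-frequency check and a 60-session Monte-Carlo check of the
median estimator. The whole suite completes in a few seconds on one CPU.

## Known limitations

* The Table-style flattened vote tallies of the original workshop are not
  reconstructible column-by-column; the packaged vote fixture reproduces
  every round's size and median, which is all the pipeline consumes.
* The four packaged test cases' category assignments resolve a genuinely
  ambiguous printed layout (two cases share identical non-price profiles);
  their composites are regression anchors computed by an independent
  brute-force oracle in the tests, not externally published values.
* Weights elicited by a ~20-person workshop carry structural uncertainty the
  package does not model; `sensitivity_sweep()` is the supported way to
  probe how conclusions depend on the two parameters the process itself
  treats as adjustable.
* No game-theoretic bidding behaviour, budget-impact roll-ups or price
  optimization: the package evaluates submitted bids as given.
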