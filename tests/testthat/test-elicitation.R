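grid5 <- option_grid("price_weight")

test_that("median voting reduces a round to its grid median", {
  # even n: mean of the 8th and 9th order statistics, already on grid
  expect_equal(median_vote(rep(c(0.40, 0.45, 0.50, 0.55, 0.60),
                               c(1, 5, 8, 1, 1)), grid5), 0.50)
  # odd n: the 8th order statistic
  expect_equal(median_vote(rep(c(0.35, 0.40, 0.45), c(1, 7, 7)), grid5), 0.40)
  # single vote
  expect_equal(median_vote(0.50, grid5), 0.50)
  # even n with an off-grid mean: midpoint snaps to the lower grid value
  expect_equal(median_vote(c(0.50, 0.55), grid5), 0.50)
  expect_error(median_vote(numeric(0), grid5), "no votes")
  expect_error(median_vote(c(0.40, 0.42), grid5), "off the option grid.*0.42")
})

test_that("modified SMART ranking follows sequential plurality winners", {
  cand <- c("quality", "equivalence", "stability", "reliability",
            "real-world", "pharmacovigilance")
  rounds <- list(
    rep(c("quality", "equivalence"), c(9, 7)),
    rep(c("equivalence", "stability"), c(8, 6)),
    rep(c("stability", "reliability"), c(10, 4)),
    rep(c("reliability", "real-world"), c(9, 5)),
    rep(c("real-world", "pharmacovigilance"), c(11, 5)))
  r <- smart_rank(rounds, cand)
  # the single unvoted criterion takes the last rank without a round
  expect_equal(r$ranking, c("quality", "equivalence", "stability",
                            "reliability", "real-world", "pharmacovigilance"))
  expect_length(r$ties, 0)

  # single criterion, no rounds
  expect_equal(smart_rank(list(), "only")$ranking, "only")

  # tied tallies break lexicographically and are flagged
  r2 <- smart_rank(list(c("b", "a"), c("b", "c", "c", "b")), c("a", "b", "c"))
  expect_equal(r2$ranking, c("a", "b", "c"))
  expect_equal(r2$ties, c("a", "b"))

  # voting for an already-ranked criterion is an error
  expect_error(smart_rank(list(c("a", "a"), c("a", "b")), c("a", "b", "c")),
               "already ranked")
})

test_that("swing points accumulate multiplicatively up the ladder", {
  # the worked single step: 10 + 10 * 50% = 15
  expect_equal(swing_points(c("low", "high"), 0.5)$points,
               c(low = 10, high = 15))
  # the full pilot ladder
  lad <- swing_points(letters[1:6], indonesia_increments)
  expect_equal(unname(lad$points), c(10, 11.5, 23, 34.5, 34.5, 51.75))
  # all-zero increments encode equal importance everywhere
  expect_equal(unname(swing_points(letters[1:4], rep(0, 3))$points), rep(10, 4))
  expect_error(swing_points(letters[1:3], c(-0.1, 0.2)), ">= 0")
  expect_error(swing_points(letters[1:3], 0.5), "2 increments")
})

test_that("ladder points match a closed-form cumulative product oracle", {
  set.seed(41)
  sg <- option_grid("swing")
  for (rep_i in 1:25) {
    m <- sample(2:8, 1)
    inc <- sample(sg, m - 1, replace = TRUE)
    lad <- swing_points(paste0("c", 1:m), inc, base_points = 10)
    oracle <- 10 * cumprod(c(1, 1 + inc))
    expect_equal(unname(lad$points), oracle, tolerance = 1e-15)
  }
})

test_that("two-stage normalization reproduces the pilot weight table", {
  lad <- swing_points(rev(indonesia_final_ranking), indonesia_increments)
  np <- normalize_nonprice(lad)
  expect_equal(sum(np), 1, tolerance = 1e-12)
  expect_equal(unname(np["quality-assurance"]), 51.75 / 165.25,
               tolerance = 1e-12)

  final <- combine_with_price(np, 0.40)
  expect_equal(sum(final), 1, tolerance = 1e-12)
  expect_equal(unname(final["quality-assurance"]), 51.75 / 165.25 * 0.6,
               tolerance = 1e-12)
  expect_equal(percent_display(final[["quality-assurance"]]), 18.8)
  # draft stage at 50% price weight
  draft <- combine_with_price(np, 0.50)
  expect_equal(percent_display(draft[["quality-assurance"]]), 15.7)

  # trivia: symmetric split
  expect_equal(unname(combine_with_price(c(a = 0.5, b = 0.5), 0.5)),
               c(0.5, 0.25, 0.25))
  expect_error(combine_with_price(np, 1.2), "between 0 and 1")
  expect_error(normalize_nonprice(c(a = 0, b = 0)), "positive")
})

test_that("weight maps always conserve total weight", {
  set.seed(42)
  sg <- option_grid("swing")
  for (rep_i in 1:30) {
    m <- sample(2:9, 1)
    inc <- sample(sg, m - 1, replace = TRUE)
    np <- normalize_nonprice(swing_points(paste0("c", 1:m), inc))
    wp <- stats::runif(1, 0.05, 0.95)
    expect_equal(sum(combine_with_price(np, wp)), 1, tolerance = 1e-12)
  }
})

test_that("raising one swing increment shifts weight monotonically", {
  set.seed(43)
  for (rep_i in 1:20) {
    m <- sample(3:7, 1)
    inc <- stats::runif(m - 1, 0, 1)
    j <- sample(m - 1, 1)
    inc2 <- inc
    inc2[j] <- inc[j] + stats::runif(1, 0.05, 0.5)
    w1 <- normalize_nonprice(swing_points(paste0("c", 1:m), inc))
    w2 <- normalize_nonprice(swing_points(paste0("c", 1:m), inc2))
    above <- (j + 1):m
    below <- 1:j
    expect_true(all(w2[above] >= w1[above] - 1e-12))
    expect_true(all(w2[below] <= w1[below] + 1e-12))
  }
})

test_that("final weights are non-increasing along the importance ranking", {
  set.seed(44)
  for (rep_i in 1:20) {
    m <- sample(2:8, 1)
    inc <- stats::runif(m - 1, 0, 1) * rbinom(m - 1, 1, 0.8)
    np <- normalize_nonprice(swing_points(paste0("c", 1:m), inc))
    final <- combine_with_price(np, 0.4)
    ladder_up <- final[paste0("c", 1:m)]  # least -> most important
    expect_true(all(diff(unname(ladder_up)) >= -1e-12))
  }
})

test_that("the full pipeline elicits the published framework from the votes", {
  fw <- elicit_framework(opp_framework("draft"), opp_votes())
  el <- attr(fw, "elicitation")

  # initial medians before the adjustment re-vote
  expect_equal(el$price_weight_initial, 0.50)
  expect_equal(el$price_cutoff_initial, 0.50)
  # the adjustment round overrides them
  expect_equal(fw$price_weight, 0.40)
  expect_equal(fw$price_cutoff_excess, 1.00)

  expect_equal(sort(el$excluded),
               c("added-value-services", "macroeconomic-benefit"))
  expect_equal(el$ranking, indonesia_final_ranking)
  expect_equal(unname(el$ladder$points), c(10, 11.5, 23, 34.5, 34.5, 51.75))

  w <- framework_weights(fw)
  expect_equal(unname(percent_display(w[c("price", "quality-assurance",
                                          "equivalence", "stability-formulation",
                                          "supply-reliability",
                                          "real-world-outcomes",
                                          "pharmacovigilance")])),
               c(40.0, 18.8, 12.5, 12.5, 8.4, 4.2, 3.6))
  expect_equal(sum(w), 1, tolerance = 1e-12)

  rep <- weight_report(fw)
  expect_equal(rep$rank[-1], c(1, 2, 2, 3, 4, 5))  # equal points share a rank
})

test_that("elicitation handles degenerate and faulty vote files", {
  # one non-price criterion: price + criterion split the weight
  fw1 <- mcda_framework(list(criterion("only", categories = toy_scale()),
                             criterion("price", is_price = TRUE)),
                        name = "single")
  votes <- data.frame(
    round_purpose = c("price_weight", "price_cutoff"),
    option_value = c("40%", "100%"), vote_count = c(5L, 5L),
    stringsAsFactors = FALSE)
  out <- elicit_framework(fw1, votes)
  expect_equal(unname(framework_weights(out)[c("only", "price")]),
               c(0.6, 0.4))

  # a missing required round is reported by name
  expect_error(
    elicit_framework(fw1, votes[votes$round_purpose != "price_cutoff", ]),
    "price_cutoff")

  # wrong number of swing rounds
  expect_error(elicit_framework(opp_framework("draft"),
                                opp_votes()[!grepl("swing_step_5",
                                                   opp_votes()$round_purpose), ]),
               "swing_step")
})
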