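test_that("the pilot test cases evaluate and rank deterministically", {
  fw <- opp_framework("final")
  res <- evaluate_tender(opp_test_cases(), fw)

  expect_equal(res$p_min, 2200)
  expect_equal(res$n_eligible, 4)
  # the lowest bid's price component is the full price weight
  p1 <- res$scores[res$scores$product_id == "test-case-1" &
                     res$scores$criterion == "price", ]
  expect_equal(p1$raw_fraction, 1)
  expect_equal(p1$weighted, 0.40, tolerance = 1e-12)
  # ranks are a permutation of 1..eligible
  expect_setequal(res$summary$rank, 1:4)
  # per-product weighted scores sum to the composite
  for (pid in res$summary$product_id) {
    expect_equal(sum(res$scores$weighted[res$scores$product_id == pid]),
                 res$summary$composite[res$summary$product_id == pid],
                 tolerance = 1e-12)
  }
})

test_that("composites equal an independent brute-force oracle", {
  fw <- opp_framework("final")
  tc <- opp_test_cases()
  oracle <- brute_force_composite(tc, fw)
  res <- evaluate_tender(tc, fw)
  expect_equal(res$summary$composite, oracle$composite, tolerance = 1e-12)
  expect_equal(res$summary$excluded, oracle$excluded)

  # and on synthetic tenders with exclusions in play
  set.seed(11)
  for (rep_i in 1:5) {
    fw2 <- toy_framework(exclude_worst_a = TRUE)
    tender <- generate_tender(fw2, 12, reference_price = 500,
                              exclusion_prob = 0.3)
    o <- brute_force_composite(tender, fw2)
    r <- evaluate_tender(tender, fw2)
    expect_equal(r$summary$composite, o$composite, tolerance = 1e-12)
    expect_equal(r$summary$excluded, o$excluded)
  }
})

test_that("a product with perfect performance at the lowest bid scores 1", {
  fw <- toy_framework()
  one <- data.frame(product_id = "solo", price = 100,
                    `crit-a` = "good", `crit-b` = "good",
                    stringsAsFactors = FALSE, check.names = FALSE)
  res <- evaluate_tender(one, fw)
  expect_equal(res$summary$composite, 1, tolerance = 1e-12)
  expect_equal(res$summary$rank, 1L)
})

test_that("excluded products carry no rank and do not anchor the price", {
  fw <- toy_framework(exclude_worst_a = TRUE)
  prods <- toy_products()
  prods$`crit-a` <- c("poor", "fair", "good")  # p1 (cheapest) disqualified
  res <- evaluate_tender(prods, fw)
  expect_true(res$summary$excluded[1])
  expect_true(is.na(res$summary$rank[1]))
  expect_equal(res$p_min, 150)  # anchored on eligible bids only
  expect_setequal(res$summary$rank[!res$summary$excluded], 1:2)
  # the all-bids anchor remains available
  res_all <- evaluate_tender(prods, fw, price_reference = "all")
  expect_equal(res_all$p_min, 100)

  # every product disqualified: explicit empty result, not an error
  prods$`crit-a` <- "poor"
  res0 <- evaluate_tender(prods, fw)
  expect_equal(res0$n_eligible, 0L)
  expect_true(all(res0$summary$excluded))
  expect_true(all(is.na(res0$summary$rank)))
})

test_that("identical products tie, broken by price then id, and are flagged", {
  fw <- toy_framework()
  prods <- data.frame(product_id = c("b-prod", "a-prod", "cheap"),
                      price = c(100, 100, 100),
                      `crit-a` = "fair", `crit-b` = "fair",
                      stringsAsFactors = FALSE, check.names = FALSE)
  res <- evaluate_tender(prods, fw)
  expect_true(all(res$summary$tied))
  expect_equal(res$summary$product_id[order(res$summary$rank)],
               c("a-prod", "b-prod", "cheap"))
  # lower price wins the tie before the id does
  prods$price <- c(100, 100, 90)
  res2 <- evaluate_tender(prods, fw)
  expect_equal(res2$summary$product_id[res2$summary$rank == 1], "cheap")
})

test_that("missing selections are reported by product and criterion", {
  fw <- toy_framework()
  prods <- toy_products()
  prods$`crit-b`[2] <- NA
  expect_error(evaluate_tender(prods, fw), "p2.*crit-b")
  expect_error(evaluate_tender(toy_products()[, 1:3], fw), "crit-b")
})

test_that("dominance is preserved in the ranking", {
  set.seed(21)
  fw <- toy_framework()
  labels <- c("poor", "fair", "good")
  lv <- function(x) match(x, labels)
  for (rep_i in 1:20) {
    tender <- generate_tender(fw, 10, reference_price = 100,
                              spread_range = c(1, 1.9))
    res <- evaluate_tender(tender, fw)
    s <- res$summary
    for (i in 1:9) for (j in (i + 1):10) {
      geq <- lv(tender$`crit-a`[i]) >= lv(tender$`crit-a`[j]) &&
             lv(tender$`crit-b`[i]) >= lv(tender$`crit-b`[j]) &&
             tender$price[i] <= tender$price[j]
      if (geq) expect_lte(s$rank[i], s$rank[j])
    }
  }
})

test_that("rescaling all bid prices changes nothing", {
  set.seed(22)
  fw <- opp_framework("final")
  tender <- generate_tender(fw, 8, reference_price = 3000)
  base <- evaluate_tender(tender, fw)
  for (k in c(0.001, 7, 1e6)) {
    scaled <- tender
    scaled$price <- tender$price * k
    res <- evaluate_tender(scaled, fw)
    expect_equal(res$summary$composite, base$summary$composite,
                 tolerance = 1e-9)
    expect_equal(res$summary$rank, base$summary$rank)
  }
})

test_that("raising the price weight never helps the pricier of twins", {
  fw <- toy_framework()
  twins <- data.frame(product_id = c("cheap", "dear"), price = c(100, 160),
                      `crit-a` = "fair", `crit-b` = "fair",
                      stringsAsFactors = FALSE, check.names = FALSE)
  gap <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(wp) {
    sw <- sensitivity_sweep(twins, fw, "price_weight", wp)
    e <- attr(sw, "evaluations")[[1]]$summary
    e$composite[e$product_id == "cheap"] - e$composite[e$product_id == "dear"]
  }, numeric(1))
  expect_true(all(diff(gap) >= -1e-12))
})

test_that("winner selection clamps to the eligible set", {
  res <- evaluate_tender(opp_test_cases(), opp_framework("final"))
  expect_equal(select_winners(res, 1)$product_id, "test-case-2")
  expect_equal(nrow(select_winners(res, 2)), 2)
  expect_equal(nrow(select_winners(res, 10)), 4)  # more asked than eligible
  expect_equal(select_winners(res, 10)$rank, 1:4)
})

test_that("sensitivity sweeps re-normalize and re-evaluate per grid value", {
  fw <- opp_framework("final")
  tc <- opp_test_cases()
  sw <- sensitivity_sweep(tc, fw, "price_weight", c(0.40, 0.50, 0.70))
  expect_equal(nrow(sw), 3)
  # each run's weights still sum to 1
  for (e in attr(sw, "evaluations")) {
    expect_equal(sum(framework_weights(e$framework)), 1, tolerance = 1e-12)
  }
  # a singleton sweep at the current value is a no-op
  sw1 <- sensitivity_sweep(tc, fw, "price_weight", fw$price_weight)
  base <- evaluate_tender(tc, fw)
  expect_equal(attr(sw1, "evaluations")[[1]]$summary$rank, base$summary$rank)

  # cut-off sweep: the 3800 bid (72.7% excess) scores 0 only under +50%
  swc <- sensitivity_sweep(tc, fw, "price_cutoff", c(0.5, 1.0))
  raw4 <- vapply(attr(swc, "evaluations"), function(e) {
    e$scores$raw_fraction[e$scores$product_id == "test-case-4" &
                            e$scores$criterion == "price"]
  }, numeric(1))
  expect_equal(raw4[1], 0)
  expect_gt(raw4[2], 0)

  expect_error(sensitivity_sweep(tc, fw, "price_weight", numeric(0)), "empty")
  expect_error(sensitivity_sweep(tc, fw, "price_weight", 0), "between 0 and 1")
  expect_error(sensitivity_sweep(tc, fw, "price_cutoff", -1), "positive")
})
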