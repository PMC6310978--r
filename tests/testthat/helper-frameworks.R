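# Small frameworks and tenders built in code for unit and property tests.

# Three-level scale with optional exclusion at the bottom.
toy_scale <- function(exclude_worst = FALSE) {
  category_scale(c("poor", "fair", "good"),
                 is_exclusion = c(exclude_worst, FALSE, FALSE))
}

# price + two non-price criteria, fully weighted
toy_framework <- function(price_weight = 0.5, w_a = 0.3, w_b = 0.2,
                          cutoff = 1.0, exclude_worst_a = FALSE) {
  mcda_framework(
    list(criterion("crit-a", categories = toy_scale(exclude_worst_a),
                   weight = w_a),
         criterion("crit-b", categories = toy_scale(), weight = w_b),
         criterion("price", is_price = TRUE)),
    price_weight = price_weight, price_cutoff_excess = cutoff,
    name = "toy")
}

toy_products <- function() {
  data.frame(product_id = c("p1", "p2", "p3"),
             price = c(100, 150, 210),
             `crit-a` = c("good", "fair", "poor"),
             `crit-b` = c("fair", "good", "good"),
             stringsAsFactors = FALSE, check.names = FALSE)
}

# Independent composite oracle: per-criterion sum straight off the framework
# lists and the price formula, sharing no code with evaluate_tender().
brute_force_composite <- function(products, fw) {
  w <- framework_weights(fw)
  cut <- fw$price_cutoff_excess
  np <- nonprice_criteria(fw)
  lookup <- function(cr, label) {
    for (ct in cr$categories) if (ct$label == label) {
      return(list(frac = ct$score_fraction, excl = ct$is_exclusion))
    }
    stop("label not found")
  }
  excl <- logical(nrow(products))
  nps <- numeric(nrow(products))
  for (i in seq_len(nrow(products))) {
    for (cr in np) {
      hit <- lookup(cr, products[[cr$id]][i])
      if (hit$excl) excl[i] <- TRUE
      nps[i] <- nps[i] + w[[cr$id]] * hit$frac
    }
  }
  pmin_elig <- min(products$price[!excl])
  comp <- rep(NA_real_, nrow(products))
  for (i in which(!excl)) {
    ps <- max(0, min(1, 1 - ((products$price[i] - pmin_elig) / pmin_elig) / cut))
    comp[i] <- nps[i] + w[["price"]] * ps
  }
  list(composite = comp, excluded = excl)
}

# Increments of the Indonesian swing ladder, least to most important.
indonesia_increments <- c(0.15, 1.00, 0.50, 0.00, 0.50)
indonesia_final_ranking <- c("quality-assurance", "equivalence",
                             "stability-formulation", "supply-reliability",
                             "real-world-outcomes", "pharmacovigilance")
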