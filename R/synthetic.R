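# Synthetic tenders and synthetic vote sessions, so every pipeline stage can
# be exercised at arbitrary size without external data.

#' Generate a synthetic tender
#'
#' Draws \code{n_products} candidate products against a framework. Bid prices
#' are multiplicative around a reference price: \code{price = reference_price
#' * f} with \code{f} log-uniform over \code{spread_range} (default
#' \code{c(1, 2.5)}, spanning the lowest bid up to 2.5x — the region where a
#' +100\% cut-off produces both positive and zero price scores). Category
#' selections are drawn independently per criterion: with probability
#' \code{exclusion_prob} a flagged exclusion category (if the criterion has
#' one), otherwise a non-exclusion level from \code{category_probs} (uniform
#' by default).
#'
#' @param fw an \code{mcda_framework} (weights not required).
#' @param n_products number of candidate products (>= 1).
#' @param reference_price anchor price in currency units (default 2200).
#' @param spread_range length-2 multiplicative factor range, \code{1 <= lo <=
#'   hi}.
#' @param category_probs optional named list: criterion id -> probability
#'   vector over its non-exclusion levels (worst to best).
#' @param exclusion_prob probability of drawing an exclusion category on a
#'   criterion that has one (default 0).
#' @param seed optional integer; same seed, same tender.
#' @return performance-matrix data.frame (product_id, price, one column per
#'   non-price criterion).
#' @export
generate_tender <- function(fw, n_products, reference_price = 2200,
                            spread_range = c(1, 2.5), category_probs = NULL,
                            exclusion_prob = 0, seed = NULL) {
  stopifnot(inherits(fw, "mcda_framework"))
  if (n_products < 1L) stop("n_products must be >= 1", call. = FALSE)
  stopifnot(length(spread_range) == 2L, spread_range[1] > 0,
            spread_range[2] >= spread_range[1], reference_price > 0,
            exclusion_prob >= 0, exclusion_prob <= 1)
  if (!is.null(seed)) set.seed(seed)

  f <- exp(stats::runif(n_products, log(spread_range[1]), log(spread_range[2])))
  out <- data.frame(
    product_id = sprintf("P%03d", seq_len(n_products)),
    price = reference_price * f,
    stringsAsFactors = FALSE, check.names = FALSE)

  for (cr in nonprice_criteria(fw)) {
    labels <- vapply(cr$categories, `[[`, character(1), "label")
    ex <- vapply(cr$categories, `[[`, logical(1), "is_exclusion")
    probs <- category_probs[[cr$id]] %||% rep(1 / sum(!ex), sum(!ex))
    if (length(probs) != sum(!ex) || any(probs < 0) || sum(probs) <= 0)
      stop("bad category_probs for criterion '", cr$id, "'", call. = FALSE)
    pick <- character(n_products)
    for (i in seq_len(n_products)) {
      if (any(ex) && exclusion_prob > 0 &&
          stats::runif(1) < exclusion_prob) {
        pick[i] <- sample(labels[ex], 1L)
      } else {
        pick[i] <- sample(labels[!ex], 1L, prob = probs)
      }
    }
    out[[cr$id]] <- pick
  }
  out
}

#' Generate a synthetic workshop vote session
#'
#' Emits a complete vote record (same schema as \code{\link{read_votes}})
#' around a stated group preference, so the elicitation pipeline can be
#' exercised and its parameter recovery tested. Numeric rounds displace each
#' voter's preferred grid position by a rounded \eqn{N(0,
#' \mathrm{dispersion})} number of grid steps, clamped to the grid;
#' categorical (SMART) rounds vote the true next-ranked criterion with
#' probability \eqn{1/(1 + \mathrm{dispersion})} and otherwise uniformly
#' among the other still-unranked candidates. With \code{dispersion = 0}
#' every vote equals the preference, so every median recovers it exactly.
#'
#' @param n_voters voters per round (default 20).
#' @param price_weight,price_cutoff the group's true preference (fractions).
#' @param ranking character vector of non-price criterion ids, most to least
#'   important.
#' @param increments swing increments, least to most important (length
#'   \code{length(ranking) - 1}); each must lie on the swing grid.
#' @param exclusions criterion ids excluded by (unanimous) majority vote.
#' @param dispersion vote noise, in grid steps (>= 0).
#' @param seed optional integer seed.
#' @return vote data.frame (\code{round_purpose}, \code{option_value},
#'   \code{vote_count}).
#' @export
generate_votes <- function(n_voters = 20, price_weight = 0.4,
                           price_cutoff = 1.0, ranking, increments,
                           exclusions = character(0), dispersion = 0,
                           seed = NULL) {
  stopifnot(n_voters >= 1L, dispersion >= 0,
            length(increments) == length(ranking) - 1L)
  if (!is.null(seed)) set.seed(seed)

  vote_numeric <- function(pref, grid) {
    i <- which(abs(grid - pref) <= 1e-9)
    if (!length(i)) stop("preference ", pref, " is off its grid", call. = FALSE)
    shift <- round(stats::rnorm(n_voters, 0, dispersion))
    grid[pmin(length(grid), pmax(1L, i + shift))]
  }
  vote_categorical <- function(truth, candidates) {
    vapply(seq_len(n_voters), function(v) {
      if (length(candidates) == 1L || stats::runif(1) < 1 / (1 + dispersion))
        truth
      else sample(setdiff(candidates, truth), 1L)
    }, character(1))
  }
  tally_rows <- function(purpose, votes) {
    t <- table(votes)
    data.frame(round_purpose = purpose, option_value = names(t),
               vote_count = as.integer(t), stringsAsFactors = FALSE)
  }
  as_pct <- function(x) paste0(round(100 * x, 6), "%")

  rows <- list(
    tally_rows("price_weight",
               as_pct(vote_numeric(price_weight, option_grid("price_weight")))),
    tally_rows("price_cutoff",
               as_pct(vote_numeric(price_cutoff, option_grid("price_cutoff")))))

  for (k in seq_along(exclusions)) {
    votes <- vapply(seq_len(n_voters), function(v) {
      if (stats::runif(1) < 1 / (1 + dispersion)) exclusions[k] else "none"
    }, character(1))
    rows <- c(rows, list(tally_rows(paste0("exclusion_vote_", k), votes)))
  }

  m <- length(ranking)
  if (m > 1L) {
    for (k in seq_len(m - 1L)) {
      cand <- ranking[k:m]
      rows <- c(rows, list(tally_rows(paste0("smart_round_", k),
                                      vote_categorical(ranking[k], cand))))
    }
    sg <- option_grid("swing")
    for (k in seq_len(m - 1L)) {
      rows <- c(rows, list(tally_rows(paste0("swing_step_", k),
                                      as_pct(vote_numeric(increments[k], sg)))))
    }
  }
  do.call(rbind, rows)
}
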