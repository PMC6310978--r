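#' Price scoring context
#'
#' The price score of a bid is anchored to the lowest eligible bid: the
#' context records that anchor \code{p_min} and the cut-off excess \code{c}
#' that sets the slope of the linear function. Keeping the zero point at a
#' fixed excess over the lowest bid (rather than at the most expensive bid)
#' makes the score independent of the price distribution of the competitors.
#'
#' @param p_min lowest eligible bid price (currency units, > 0).
#' @param cutoff_excess positive fraction c: bids at or beyond
#'   \code{p_min * (1 + c)} score zero.
#' @return an object of class \code{mcda_price_context}.
#' @export
price_context <- function(p_min, cutoff_excess) {
  if (!is.numeric(p_min) || length(p_min) != 1L || is.na(p_min) || p_min <= 0)
    stop("p_min must be a single positive price", call. = FALSE)
  if (!is.numeric(cutoff_excess) || length(cutoff_excess) != 1L ||
      is.na(cutoff_excess) || cutoff_excess <= 0)
    stop("cutoff_excess must be a single positive fraction", call. = FALSE)
  structure(list(p_min = p_min, cutoff_excess = cutoff_excess),
            class = "mcda_price_context")
}

#' Linear price score anchored at the lowest bid
#'
#' The lowest bid receives the full price score (1); the score decreases
#' linearly with the relative excess over the lowest bid and reaches 0 at the
#' cut-off \code{p_min * (1 + c)}; bids at or beyond the cut-off score 0:
#' \deqn{s(p) = \max\!\left(0,\; 1 - \frac{(p - p_{min})/p_{min}}{c}\right).}
#' With a +200\% cut-off (c = 2) a bid at twice the lowest price scores
#' exactly 0.5.
#'
#' @param p bid price(s), each \eqn{\ge} \code{ctx$p_min} (the context must be
#'   built from all eligible bids; a lower price is an error, not a score
#'   above 1).
#' @param ctx an \code{\link{price_context}}.
#' @return numeric score(s) in \code{[0, 1]}.
#' @examples
#' price_score(4400, price_context(2200, 2))   # 0.5
#' price_score(2900, price_context(2200, 1))   # 0.6818...
#' @export
price_score <- function(p, ctx) {
  stopifnot(inherits(ctx, "mcda_price_context"))
  if (!is.numeric(p) || length(p) == 0L || anyNA(p) || any(p <= 0))
    stop("bid prices must be positive numbers", call. = FALSE)
  if (any(p < ctx$p_min - 1e-9 * ctx$p_min)) {
    stop("bid price below the context's p_min (", ctx$p_min,
         "); build the price context from all eligible bids", call. = FALSE)
  }
  excess <- (p - ctx$p_min) / ctx$p_min
  pmin(1, pmax(0, 1 - excess / ctx$cutoff_excess))
}

#' Score a product's selected performance category on a criterion
#'
#' Looks up the selected category label on a non-price criterion and returns
#' its score fraction, or an exclusion-flagged score when the category is an
#' exclusion category (the product is disqualified rather than scored).
#'
#' @param criterion an \code{mcda_criterion} with \code{is_price = FALSE}.
#' @param label category label; matched exactly (case-sensitive).
#' @return list of class \code{mcda_criterion_score} with fields
#'   \code{criterion_id}, \code{raw_fraction}, \code{excluded} and
#'   \code{weighted} (\code{raw_fraction * weight}, \code{NA} while the
#'   criterion is unweighted, 0 when excluded).
#' @export
category_score <- function(criterion, label) {
  stopifnot(inherits(criterion, "mcda_criterion"))
  if (criterion$is_price)
    stop("price criterion '", criterion$id,
         "' is scored by the price function, not by category", call. = FALSE)
  labels <- vapply(criterion$categories, `[[`, character(1), "label")
  i <- match(label, labels)
  if (is.na(i)) {
    stop("unknown category '", label, "' for criterion '", criterion$id,
         "'; valid labels: ", paste(labels, collapse = ", "), call. = FALSE)
  }
  cat <- criterion$categories[[i]]
  if (cat$is_exclusion) {
    structure(list(criterion_id = criterion$id, raw_fraction = 0,
                   excluded = TRUE, weighted = 0),
              class = "mcda_criterion_score")
  } else {
    structure(list(criterion_id = criterion$id,
                   raw_fraction = cat$score_fraction, excluded = FALSE,
                   weighted = cat$score_fraction * criterion$weight),
              class = "mcda_criterion_score")
  }
}
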