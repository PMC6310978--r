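#' Voting option grids
#'
#' Workshop votes are cast on fixed discrete grids: the price weight from 5\%
#' to 100\% in 5\% steps; swing increments from 0\% to +50\% in 5\% steps and
#' from +50\% to +100\% in 10\% steps; the price cut-off excess from +25\% to
#' +500\% (25\% steps). All grids are expressed as fractions.
#'
#' @param purpose one of \code{"price_weight"}, \code{"price_cutoff"},
#'   \code{"swing"}.
#' @return strictly increasing numeric vector of allowed vote values.
#' @export
option_grid <- function(purpose = c("price_weight", "price_cutoff", "swing")) {
  purpose <- match.arg(purpose)
  switch(purpose,
    price_weight = seq(0.05, 1, by = 0.05),
    price_cutoff = seq(0.25, 5, by = 0.25),
    swing = c(seq(0, 0.5, by = 0.05), seq(0.6, 1, by = 0.1)))
}

grid_for_purpose <- function(purpose) {
  if (grepl("^price_weight", purpose)) option_grid("price_weight")
  else if (grepl("^price_cutoff", purpose)) option_grid("price_cutoff")
  else if (grepl("^swing", purpose)) option_grid("swing")
  else NULL  # categorical round
}

#' Median of a voting round
#'
#' The group's choice in each numeric round is the median of the cast votes,
#' which damps the influence of outlier voters. For an odd number of votes the
#' median is itself a cast vote and therefore on the grid; for an even number
#' the mean of the two middle votes is snapped to the nearest grid value, with
#' exact midpoints snapped downward, so the result is always an allowed option.
#'
#' @param votes numeric vector of cast votes (fractions), one entry per voter;
#'   use \code{rep()} to expand tallies.
#' @param grid allowed option values (see \code{\link{option_grid}}).
#' @return the median as a grid value.
#' @examples
#' median_vote(rep(c(0.40, 0.45, 0.50, 0.55, 0.60), c(1, 5, 8, 1, 1)),
#'             option_grid("price_weight"))  # 0.50
#' @export
median_vote <- function(votes, grid) {
  if (length(votes) == 0L) stop("no votes cast", call. = FALSE)
  snapped <- grid_match(votes, grid)
  if (anyNA(snapped)) {
    bad <- unique(votes[is.na(snapped)])
    stop("vote(s) off the option grid: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  s <- sort(snapped)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L]
  else snap_to_grid((s[n %/% 2L] + s[n %/% 2L + 1L]) / 2, grid)
}

#' Rank criteria by sequential plurality votes (modified SMART)
#'
#' The modified SMART procedure ranks criteria by importance through a series
#' of group votes: starting from a hypothetical worst-case product, voters
#' repeatedly pick the not-yet-ranked criterion whose improvement from worst
#' to best level would help the product most. Round k's plurality winner takes
#' rank k; when exactly one criterion is left unvoted it takes the last rank
#' without a round. Tied tallies are broken lexicographically by criterion id
#' and the tie is recorded in the result.
#'
#' @param rounds list of character vectors, one per round, each the cast votes
#'   (criterion ids, one entry per voter).
#' @param candidates character vector of all criterion ids to rank.
#' @return list with \code{ranking} (ids, most to least important) and
#'   \code{ties} (ids that won their round on the tie-break).
#' @export
smart_rank <- function(rounds, candidates) {
  stopifnot(length(candidates) >= 1L, !anyDuplicated(candidates))
  ranking <- character(0)
  ties <- character(0)
  remaining <- candidates
  for (k in seq_along(rounds)) {
    votes <- rounds[[k]]
    if (length(votes) == 0L) stop("SMART round ", k, " has no votes", call. = FALSE)
    bad <- setdiff(unique(votes), remaining)
    if (length(bad)) {
      stop("SMART round ", k, " votes for unavailable criterion id(s): ",
           paste(bad, collapse = ", "),
           " (already ranked or unknown)", call. = FALSE)
    }
    tally <- table(votes)
    top <- names(tally)[tally == max(tally)]
    winner <- sort(top)[1L]
    if (length(top) > 1L) ties <- c(ties, winner)
    ranking <- c(ranking, winner)
    remaining <- setdiff(remaining, winner)
  }
  if (length(remaining) == 1L) {
    ranking <- c(ranking, remaining)
  } else if (length(remaining) > 1L) {
    stop("SMART rounds leave ", length(remaining),
         " criteria unranked: ", paste(remaining, collapse = ", "), call. = FALSE)
  }
  list(ranking = ranking, ties = ties)
}

#' Accumulate swing-weighting points up the criterion ladder
#'
#' Swing weighting assigns a fixed number of points (10 by default) to the
#' least important criterion; each subsequent criterion receives the previous
#' criterion's points increased by the voted increment, so
#' \eqn{P_{k+1} = P_k (1 + \delta_{k+1})}. A 0\% increment encodes equal
#' importance (identical points). Points are kept at full precision.
#'
#' @param ranking character vector of criterion ids, least to most important.
#' @param increments numeric vector of step increments (fractions, length
#'   \code{length(ranking) - 1}), each \eqn{\ge 0}; \code{increments[k]} is
#'   the step onto \code{ranking[k + 1]}.
#' @param base_points points of the least important criterion (default 10).
#' @return an object of class \code{mcda_swing_ladder}: list with
#'   \code{ranking}, \code{base_points}, \code{increments} and named
#'   \code{points}.
#' @examples
#' swing_points(c("pv", "rwe", "supply", "stability", "equiv", "quality"),
#'              c(0.15, 1.00, 0.50, 0.00, 0.50))
#' @export
swing_points <- function(ranking, increments, base_points = 10) {
  m <- length(ranking)
  if (length(increments) != m - 1L) {
    stop("need ", m - 1L, " increments for ", m, " ranked criteria, got ",
         length(increments), call. = FALSE)
  }
  if (any(increments < 0)) stop("swing increments must be >= 0", call. = FALSE)
  stopifnot(base_points > 0)
  points <- numeric(m)
  points[1L] <- base_points
  for (k in seq_len(m - 1L)) points[k + 1L] <- points[k] * (1 + increments[k])
  names(points) <- ranking
  structure(list(ranking = ranking, base_points = base_points,
                 increments = increments, points = points),
            class = "mcda_swing_ladder")
}

#' Normalize ladder points to relative non-price weights
#'
#' @param ladder an \code{mcda_swing_ladder} (or a named numeric vector of
#'   points).
#' @return named numeric vector of weights summing to 1.
#' @export
normalize_nonprice <- function(ladder) {
  points <- if (inherits(ladder, "mcda_swing_ladder")) ladder$points else ladder
  if (any(points <= 0)) stop("all ladder points must be positive", call. = FALSE)
  points / sum(points)
}

#' Fold the price weight into the non-price weights
#'
#' Second normalization stage: the relative non-price weights (summing to 1)
#' are scaled by \eqn{1 - w_p} so that together with the price criterion at
#' \eqn{w_p} the complete weight map sums to 1.
#'
#' @param nonprice_weights named numeric vector summing to 1.
#' @param price_weight fraction in (0, 1).
#' @param price_id id under which the price weight is reported.
#' @return named numeric vector over all criteria, summing to 1.
#' @export
combine_with_price <- function(nonprice_weights, price_weight,
                               price_id = "price") {
  if (is.na(price_weight) || price_weight <= 0 || price_weight >= 1)
    stop("price_weight must lie strictly between 0 and 1", call. = FALSE)
  if (abs(sum(nonprice_weights) - 1) > 1e-9)
    stop("non-price weights must sum to 1", call. = FALSE)
  out <- c(stats::setNames(price_weight, price_id),
           nonprice_weights * (1 - price_weight))
  out
}

# ---- vote files ------------------------------------------------------------

#' Read / write workshop vote records
#'
#' Vote files are CSV with columns \code{round_purpose}, \code{option_value},
#' \code{vote_count}. Numeric rounds (\code{price_weight},
#' \code{price_cutoff}, \code{swing_step_k}, and the optional
#' \code{price_weight_adjustment} / \code{price_cutoff_adjustment} re-votes)
#' carry grid values in \code{option_value} in any percent notation;
#' categorical rounds (\code{smart_round_k}, \code{exclusion_vote_k}) carry
#' criterion ids (\code{"none"} in an exclusion round is a vote to keep all).
#'
#' @param path CSV file path.
#' @return data.frame with the three columns above.
#' @export
read_votes <- function(path) {
  if (!file.exists(path)) stop("vote file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("round_purpose", "option_value", "vote_count")
  if (!all(need %in% names(df))) {
    stop("vote file must have columns ", paste(need, collapse = ", "),
         "; missing: ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  }
  df$vote_count <- as.integer(df$vote_count)
  if (anyNA(df$vote_count) || any(df$vote_count < 0))
    stop("vote_count must be a non-negative integer", call. = FALSE)
  df[need]
}

#' @rdname read_votes
#' @param votes data.frame of vote records.
#' @export
write_votes <- function(votes, path) {
  utils::write.csv(votes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

round_purposes <- function(votes) unique(votes$round_purpose)

# Expand one round's tallies to one entry per voter.
expand_round <- function(votes, purpose, numeric = TRUE) {
  sub <- votes[votes$round_purpose == purpose & votes$vote_count > 0L, ]
  if (nrow(sub) == 0L) return(if (numeric) numeric(0) else character(0))
  vals <- if (numeric) parse_fraction(sub$option_value) else sub$option_value
  rep(vals, sub$vote_count)
}

# Numbered purposes like swing_step_1..k, in numeric order.
numbered_purposes <- function(votes, prefix) {
  p <- grep(paste0("^", prefix, "_[0-9]+$"), round_purposes(votes), value = TRUE)
  p[order(as.integer(sub(paste0("^", prefix, "_"), "", p)))]
}

round_median <- function(votes, purpose) {
  median_vote(expand_round(votes, purpose), grid_for_purpose(purpose))
}

# ---- full elicitation pipeline --------------------------------------------

#' Elicit a complete weighted framework from workshop votes
#'
#' Runs the full weight-elicitation pipeline on a draft (unweighted)
#' framework and a vote record:
#' \enumerate{
#'   \item price weight: median of the \code{price_weight} round (overridden
#'     by \code{price_weight_adjustment} when present);
#'   \item price cut-off: median of the \code{price_cutoff} round (overridden
#'     by \code{price_cutoff_adjustment});
#'   \item exclusion votes: a criterion named by a strict majority of an
#'     \code{exclusion_vote_k} round's cast votes is dropped before ranking;
#'   \item modified SMART: \code{smart_round_k} rounds rank the remaining
#'     non-price criteria by importance;
#'   \item swing weighting: \code{swing_step_k} medians are the ladder
#'     increments, applied from the least important criterion upward;
#'   \item two-stage normalization: ladder points are normalized to relative
#'     non-price weights, then folded against the price weight.
#' }
#'
#' @param draft an \code{mcda_framework} (weights may be unset).
#' @param votes a vote data.frame (see \code{\link{read_votes}}) or a path to
#'   a vote CSV.
#' @param base_points swing base points (default 10).
#' @return a validated, fully weighted \code{mcda_framework}; the elicitation
#'   trail (medians, ranking, ties, ladder, relative weights, exclusions) is
#'   attached as \code{attr(, "elicitation")}.
#' @export
elicit_framework <- function(draft, votes, base_points = 10) {
  if (is.character(votes)) votes <- read_votes(votes)
  purposes <- round_purposes(votes)

  np_ids <- vapply(nonprice_criteria(draft), `[[`, character(1), "id")
  needs_ranking <- length(np_ids) > 1L
  required <- c("price_weight", "price_cutoff")
  missing <- setdiff(required, purposes)
  if (length(missing)) {
    stop("vote file is missing required round(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  pw_initial <- round_median(votes, "price_weight")
  pc_initial <- round_median(votes, "price_cutoff")
  pw <- if ("price_weight_adjustment" %in% purposes)
    round_median(votes, "price_weight_adjustment") else pw_initial
  pc <- if ("price_cutoff_adjustment" %in% purposes)
    round_median(votes, "price_cutoff_adjustment") else pc_initial

  # majority-vote exclusions, decided before ranking
  excluded <- character(0)
  for (p in numbered_purposes(votes, "exclusion_vote")) {
    cast <- expand_round(votes, p, numeric = FALSE)
    tally <- table(cast[cast != "none"])
    out <- names(tally)[tally > length(cast) / 2]
    bad <- setdiff(out, np_ids)
    if (length(bad)) {
      stop("exclusion round '", p, "' names unknown criterion id(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    excluded <- union(excluded, out)
  }
  kept_ids <- setdiff(np_ids, excluded)
  if (length(kept_ids) == 0L)
    stop("all non-price criteria were excluded by majority vote", call. = FALSE)

  # modified SMART ranking (most -> least important)
  smart_p <- numbered_purposes(votes, "smart_round")
  if (length(kept_ids) > 1L || length(smart_p) > 0L) {
    rounds <- lapply(smart_p, function(p) expand_round(votes, p, numeric = FALSE))
    smart <- smart_rank(rounds, kept_ids)
  } else {
    smart <- list(ranking = kept_ids, ties = character(0))
  }

  # swing weighting up the reversed ranking
  swing_p <- numbered_purposes(votes, "swing_step")
  m <- length(smart$ranking)
  if (length(swing_p) != m - 1L) {
    stop("need ", m - 1L, " swing_step rounds for ", m,
         " ranked criteria, got ", length(swing_p), call. = FALSE)
  }
  increments <- vapply(swing_p, function(p) round_median(votes, p), numeric(1))
  ladder <- swing_points(rev(smart$ranking), unname(increments), base_points)
  np_weights <- normalize_nonprice(ladder)

  final_w <- combine_with_price(np_weights, pw,
                                price_id = price_criterion(draft)$id)

  fw <- draft
  fw$criteria <- Filter(function(cr) !(cr$id %in% excluded), fw$criteria)
  fw$price_weight <- pw
  fw$price_cutoff_excess <- pc
  for (i in seq_along(fw$criteria)) {
    fw$criteria[[i]]$weight <- unname(final_w[[fw$criteria[[i]]$id]])
  }
  v <- validate_framework(fw)
  if (length(v)) {
    stop("elicited framework fails validation:\n  ",
         paste(v, collapse = "\n  "), call. = FALSE)
  }
  attr(fw, "elicitation") <- list(
    price_weight_initial = pw_initial, price_weight = pw,
    price_cutoff_initial = pc_initial, price_cutoff = pc,
    adjusted = c(price_weight = "price_weight_adjustment" %in% purposes,
                 price_cutoff = "price_cutoff_adjustment" %in% purposes),
    excluded = excluded, ranking = smart$ranking, ties = smart$ties,
    ladder = ladder, nonprice_weights = np_weights)
  fw
}

#' Tabulate elicited weights in workshop-report form
#'
#' One row per criterion with its importance rank (equal ladder points share
#' a rank), swing points, relative non-price weight and final weight, percents
#' rounded half-up to one decimal for display.
#'
#' @param fw a framework returned by \code{\link{elicit_framework}}.
#' @return data.frame with columns \code{criterion}, \code{rank},
#'   \code{swing_points}, \code{nonprice_weight_pct}, \code{final_weight_pct}.
#' @export
weight_report <- function(fw) {
  el <- attr(fw, "elicitation")
  w <- framework_weights(fw)
  pid <- price_criterion(fw)$id
  if (is.null(el)) {
    np <- setdiff(names(w), pid)
    ord <- np[order(-w[np])]
    return(data.frame(criterion = c(pid, ord), rank = c(NA, seq_along(ord)),
                      swing_points = NA_real_, nonprice_weight_pct = NA_real_,
                      final_weight_pct = percent_display(unname(w[c(pid, ord)])),
                      stringsAsFactors = FALSE))
  }
  pts <- el$ladder$points[rev(el$ladder$ranking)]  # most -> least important
  rank <- cumsum(c(1, diff(-unname(pts)) != 0))    # dense rank, ties share
  data.frame(
    criterion = c(pid, names(pts)),
    rank = c(NA_integer_, rank),
    swing_points = c(NA_real_, unname(pts)),
    nonprice_weight_pct = c(NA_real_,
                            percent_display(unname(el$nonprice_weights[names(pts)]))),
    final_weight_pct = percent_display(unname(w[c(pid, names(pts))])),
    stringsAsFactors = FALSE)
}
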