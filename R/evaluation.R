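#' Read a tender performance matrix
#'
#' One row per candidate product: \code{product_id}, \code{price} (currency
#' units), then one column per non-price criterion id holding the selected
#' performance-category label. Columns that match no framework criterion are
#' ignored at evaluation time, so a matrix prepared against a draft framework
#' can be re-used after criteria have been dropped.
#'
#' @param path CSV file path.
#' @return data.frame (criterion-id column names preserved verbatim).
#' @export
read_performance_matrix <- function(path) {
  if (!file.exists(path)) stop("performance matrix not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("product_id", "price")
  if (!all(need %in% names(df))) {
    stop("performance matrix must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df$price <- as.numeric(df$price)
  df
}

#' Evaluate a tender: score, exclude and rank competing products
#'
#' For each product every non-price criterion is scored by category lookup; a
#' product that falls in any exclusion category is disqualified and carries no
#' rank. The lowest bid among the remaining eligible products anchors the
#' linear price function (set \code{price_reference = "all"} to anchor on all
#' bids including disqualified ones). Each eligible product's composite score
#' is \eqn{S = \sum_i w_i s_i} over all criteria including price; products
#' are ranked by descending composite, ties broken by lower price and then by
#' product id (ties are recorded).
#'
#' @param products performance-matrix data.frame
#'   (see \code{\link{read_performance_matrix}}).
#' @param fw a fully weighted, valid \code{mcda_framework}.
#' @param price_reference anchor the price function on \code{"eligible"}
#'   (default) or \code{"all"} bids.
#' @return an object of class \code{mcda_evaluation}: list with
#'   \code{summary} (product_id, price, composite, composite_pct, excluded,
#'   rank, tied), \code{scores} (long per product x criterion: raw and
#'   weighted fractions), \code{p_min}, \code{n_eligible}, \code{framework}.
#' @export
evaluate_tender <- function(products, fw,
                            price_reference = c("eligible", "all")) {
  price_reference <- match.arg(price_reference)
  stopifnot(inherits(fw, "mcda_framework"))
  v <- validate_framework(fw)
  if (length(v)) stop("invalid framework:\n  ", paste(v, collapse = "\n  "),
                      call. = FALSE)
  w <- framework_weights(fw)
  if (anyNA(w)) stop("framework is unweighted; run elicit_framework() first",
                     call. = FALSE)
  if (is.na(fw$price_cutoff_excess))
    stop("framework has no price cut-off; cannot score prices", call. = FALSE)
  if (!is.data.frame(products) || nrow(products) == 0L)
    stop("need at least one product", call. = FALSE)
  if (anyDuplicated(products$product_id))
    stop("duplicate product_id values", call. = FALSE)

  np <- nonprice_criteria(fw)
  np_ids <- vapply(np, `[[`, character(1), "id")
  miss <- setdiff(np_ids, names(products))
  if (length(miss)) {
    stop("performance matrix is missing criterion column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(products)
  pid_col <- as.character(products$product_id)

  # non-price scores, long format
  rows <- vector("list", n * length(np))
  k <- 0L
  excluded <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (cr in np) {
      label <- products[[cr$id]][i]
      if (is.na(label) || !nzchar(label)) {
        stop("product '", pid_col[i], "' has no selection for criterion '",
             cr$id, "'", call. = FALSE)
      }
      sc <- category_score(cr, label)
      if (sc$excluded) excluded[i] <- TRUE
      k <- k + 1L
      rows[[k]] <- data.frame(product_id = pid_col[i], criterion = cr$id,
                              label = label, raw_fraction = sc$raw_fraction,
                              weighted = sc$weighted, excluded = sc$excluded,
                              stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, rows)

  anchor <- if (price_reference == "eligible") products$price[!excluded]
            else products$price
  if (length(anchor) == 0L) {
    # every bid disqualified: explicit empty result, not an error
    summary <- data.frame(product_id = pid_col, price = products$price,
                          composite = NA_real_, composite_pct = NA_real_,
                          excluded = TRUE, rank = NA_integer_, tied = FALSE,
                          stringsAsFactors = FALSE)
    return(structure(list(summary = summary, scores = scores,
                          p_min = NA_real_, n_eligible = 0L,
                          price_reference = price_reference, framework = fw),
                     class = "mcda_evaluation"))
  }
  ctx <- price_context(min(anchor), fw$price_cutoff_excess)
  pid <- price_criterion(fw)$id

  composite <- rep(NA_real_, n)
  price_rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (excluded[i]) {
      price_rows[[i]] <- data.frame(product_id = pid_col[i], criterion = pid,
                                    label = NA_character_, raw_fraction = NA_real_,
                                    weighted = NA_real_, excluded = TRUE,
                                    stringsAsFactors = FALSE)
      next
    }
    ps <- price_score(products$price[i], ctx)
    price_rows[[i]] <- data.frame(product_id = pid_col[i], criterion = pid,
                                  label = NA_character_, raw_fraction = ps,
                                  weighted = ps * w[[pid]], excluded = FALSE,
                                  stringsAsFactors = FALSE)
    nonprice_sum <- sum(scores$weighted[scores$product_id == pid_col[i]])
    composite[i] <- nonprice_sum + ps * w[[pid]]
  }
  scores <- rbind(scores, do.call(rbind, price_rows))

  rank <- rep(NA_integer_, n)
  elig <- which(!excluded)
  ord <- elig[order(-composite[elig], products$price[elig], pid_col[elig])]
  rank[ord] <- seq_along(ord)
  tied <- rep(FALSE, n)
  if (length(ord) > 1L) {
    comp_sorted <- composite[ord]
    eq <- abs(diff(comp_sorted)) <= 1e-12
    tied[ord[c(eq, FALSE) | c(FALSE, eq)]] <- TRUE
  }

  summary <- data.frame(product_id = pid_col, price = products$price,
                        composite = composite,
                        composite_pct = percent_display(composite),
                        excluded = excluded, rank = rank, tied = tied,
                        stringsAsFactors = FALSE)
  structure(list(summary = summary, scores = scores, p_min = ctx$p_min,
                 n_eligible = length(elig),
                 price_reference = price_reference, framework = fw),
            class = "mcda_evaluation")
}

#' @export
print.mcda_evaluation <- function(x, ...) {
  cat("MCDA tender evaluation —", nrow(x$summary), "products,",
      x$n_eligible, "eligible; lowest eligible bid:", x$p_min, "\n")
  s <- x$summary[order(is.na(x$summary$rank), x$summary$rank), ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s %-14s price %8s  composite %s%s\n",
                if (is.na(s$rank[i])) "  --" else sprintf("#%-3d", s$rank[i]),
                s$product_id[i], format(s$price[i]),
                if (s$excluded[i]) "  excluded"
                else sprintf("%5.1f%%", s$composite_pct[i]),
                if (s$tied[i]) "  (tie)" else ""))
  }
  invisible(x)
}

#' Select tender winners
#'
#' Returns the top-ranked eligible products; asking for more winners than
#' there are eligible products returns all of them. Nominating multiple
#' winners per tender keeps manufacturers willing to participate.
#'
#' @param result an \code{mcda_evaluation}.
#' @param n_winners positive integer.
#' @return data.frame: the winning rows of \code{result$summary}, by rank.
#' @export
select_winners <- function(result, n_winners = 1L) {
  stopifnot(inherits(result, "mcda_evaluation"), n_winners >= 1L)
  s <- result$summary
  s <- s[!is.na(s$rank) & s$rank <= min(n_winners, result$n_eligible), ]
  s[order(s$rank), ]
}

#' Sensitivity sweep over the price weight or price cut-off
#'
#' Re-evaluates a tender across a grid of values for one framework parameter.
#' When sweeping the price weight, the elicited relative non-price weights
#' (the proportions before the second normalization stage) are held fixed and
#' re-folded against each grid value, mirroring the workshop's own adjustment
#' step in which only the price weight and cut-off were re-voted. When
#' sweeping the cut-off, weights are untouched and only the price function's
#' slope changes.
#'
#' @param products performance-matrix data.frame.
#' @param fw a fully weighted \code{mcda_framework}.
#' @param parameter \code{"price_weight"} or \code{"price_cutoff"}.
#' @param values numeric grid (fractions; percent notations accepted).
#' @return data.frame of class \code{mcda_sweep}: one row per grid value with
#'   \code{value}, \code{winner}, \code{ranking} (ids best to worst,
#'   \code{" > "}-separated) and \code{changed} (differs from the first
#'   row's ranking); full evaluations in \code{attr(, "evaluations")}.
#' @export
sensitivity_sweep <- function(products, fw,
                              parameter = c("price_weight", "price_cutoff"),
                              values) {
  parameter <- match.arg(parameter)
  if (length(values) == 0L) stop("empty sweep grid", call. = FALSE)
  values <- parse_fraction(values)
  if (parameter == "price_weight" && any(values <= 0 | values >= 1))
    stop("price weight grid values must lie strictly between 0 and 1",
         call. = FALSE)
  if (parameter == "price_cutoff" && any(values <= 0))
    stop("price cut-off grid values must be positive", call. = FALSE)

  pid <- price_criterion(fw)$id
  w <- framework_weights(fw)
  np_prop <- w[setdiff(names(w), pid)] / (1 - w[[pid]])

  evals <- lapply(values, function(v) {
    fwv <- fw
    if (parameter == "price_weight") {
      final <- combine_with_price(np_prop, v, price_id = pid)
      fwv$price_weight <- v
      for (i in seq_along(fwv$criteria))
        fwv$criteria[[i]]$weight <- unname(final[[fwv$criteria[[i]]$id]])
    } else {
      fwv$price_cutoff_excess <- v
    }
    evaluate_tender(products, fwv)
  })

  rank_string <- vapply(evals, function(e) {
    s <- e$summary[!is.na(e$summary$rank), ]
    paste(s$product_id[order(s$rank)], collapse = " > ")
  }, character(1))
  winner <- vapply(evals, function(e) {
    s <- select_winners(e, 1L)
    if (nrow(s)) s$product_id[1L] else NA_character_
  }, character(1))

  out <- data.frame(parameter = parameter, value = values, winner = winner,
                    ranking = rank_string,
                    changed = rank_string != rank_string[1L],
                    stringsAsFactors = FALSE)
  attr(out, "evaluations") <- evals
  class(out) <- c("mcda_sweep", class(out))
  out
}

#' Serialize an evaluation report
#'
#' @param result an \code{mcda_evaluation}.
#' @param format \code{"json"} (machine-readable, includes per-criterion
#'   scores and run metadata), \code{"csv"} (summary table) or \code{"text"}.
#' @param seed optional seed to record in the metadata (synthetic runs).
#' @return character scalar (json/text) or the summary data.frame (csv).
#' @export
format_evaluation <- function(result, format = c("text", "json", "csv"),
                              seed = NULL) {
  format <- match.arg(format)
  if (format == "csv") return(result$summary)
  if (format == "text") {
    fw <- result$framework
    head <- sprintf(
      "Framework: %s (hash %s)\nPrice weight: %.1f%%  cut-off: +%.0f%%  lowest eligible bid: %s\n",
      fw$metadata$name, framework_hash(fw),
      percent_display(fw$price_weight), 100 * fw$price_cutoff_excess,
      format(result$p_min))
    return(paste0(head, paste(utils::capture.output(print(result)),
                              collapse = "\n"), "\n"))
  }
  fw <- result$framework
  obj <- list(
    metadata = list(tool = "tenderMCDA",
                    version = as.character(utils::packageVersion("tenderMCDA")),
                    framework = fw$metadata$name,
                    framework_hash = framework_hash(fw),
                    seed = seed),
    price = list(weight = fw$price_weight,
                 cutoff_excess = fw$price_cutoff_excess,
                 p_min = result$p_min,
                 reference = result$price_reference),
    weights = as.list(framework_weights(fw)),
    summary = result$summary,
    scores = result$scores)
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                   dataframe = "rows", pretty = TRUE)
}
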