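#' Performance category of a criterion
#'
#' A performance category is one rung of a criterion's ordinal scale. Each
#' category maps to a score fraction in \code{[0, 1]} — the share of the
#' criterion's full score a product at that level receives. A category may
#' instead be flagged as an *exclusion* category: performance so poor that the
#' product is disqualified from the tender rather than scored (its stored
#' fraction is forced to 0).
#'
#' @param label short stable identifier, unique within the criterion.
#' @param level ordinal position, 0 = worst.
#' @param score_fraction proportion of the criterion's full score, in
#'   \code{[0, 1]}; ignored (stored as 0) when \code{is_exclusion}.
#' @param description free-text definition of the level.
#' @param is_exclusion logical; disqualify products at this level?
#' @return an object of class \code{mcda_category}.
#' @export
performance_category <- function(label, level, score_fraction = NA_real_,
                                 description = "", is_exclusion = FALSE) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  structure(
    list(label = label,
         level = as.integer(level),
         score_fraction = if (isTRUE(is_exclusion)) 0 else as.numeric(score_fraction),
         description = description,
         is_exclusion = isTRUE(is_exclusion)),
    class = "mcda_category")
}

#' Build an ordered category scale with default equal spacing
#'
#' Convenience constructor for a criterion's full scale. Unless explicit
#' fractions are given, non-exclusion categories receive equally spaced score
#' fractions from 0 (worst non-exclusion level) to 1 (best level); exclusion
#' categories are stored with fraction 0. Every fraction can be overridden.
#'
#' @param labels character vector, worst to best.
#' @param score_fractions optional numeric vector (same length); \code{NA}
#'   entries fall back to the equal-spacing default.
#' @param descriptions optional character vector of level definitions.
#' @param is_exclusion logical vector flagging disqualifying levels.
#' @return list of \code{mcda_category}, ordered by level.
#' @export
category_scale <- function(labels, score_fractions = NULL,
                           descriptions = NULL, is_exclusion = NULL) {
  n <- length(labels)
  stopifnot(n >= 2L, !anyDuplicated(labels))
  is_exclusion <- is_exclusion %||% rep(FALSE, n)
  descriptions <- descriptions %||% rep("", n)
  defaults <- rep(NA_real_, n)
  keep <- !is_exclusion
  m <- sum(keep)
  defaults[keep] <- if (m == 1L) 1 else seq(0, 1, length.out = m)
  fr <- score_fractions %||% defaults
  fr[is.na(fr)] <- defaults[is.na(fr)]
  lapply(seq_len(n), function(i) {
    performance_category(labels[i], level = i - 1L, score_fraction = fr[i],
                         description = descriptions[i],
                         is_exclusion = is_exclusion[i])
  })
}

#' Decision criterion
#'
#' @param id stable slug identifying the criterion in files and matrices.
#' @param name display name.
#' @param definition free-text intended definition.
#' @param categories ordered list of \code{\link{performance_category}}
#'   (empty for the price criterion, whose score comes from the linear price
#'   function instead).
#' @param is_price logical; is this the acquisition-cost criterion?
#' @param weight relative weight in \code{[0, 1]}; \code{NA} until elicited.
#' @return an object of class \code{mcda_criterion}.
#' @export
criterion <- function(id, name = id, definition = "", categories = list(),
                      is_price = FALSE, weight = NA_real_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(
    list(id = id, name = name, definition = definition,
         is_price = isTRUE(is_price), weight = as.numeric(weight),
         categories = categories),
    class = "mcda_criterion")
}

#' Assemble an MCDA framework
#'
#' A framework bundles the weighted criteria set with the two price-function
#' parameters: the price weight \eqn{w_p} and the cut-off excess \eqn{c} (the
#' fractional excess over the lowest bid at and beyond which the price score
#' is zero; \eqn{c = 1} means "+100\%").
#'
#' @param criteria list of \code{\link{criterion}}, exactly one with
#'   \code{is_price = TRUE}.
#' @param price_weight fraction in \code{[0, 1]}; \code{NA} until elicited.
#' @param price_cutoff_excess positive fraction; \code{NA} until elicited.
#' @param name,version,notes metadata recorded in serialized configs.
#' @return an object of class \code{mcda_framework}.
#' @export
mcda_framework <- function(criteria, price_weight = NA_real_,
                           price_cutoff_excess = NA_real_,
                           name = "unnamed", version = "1", notes = "") {
  fw <- structure(
    list(metadata = list(name = name, version = version, notes = notes,
                         schema_version = 1L),
         price_weight = as.numeric(price_weight),
         price_cutoff_excess = as.numeric(price_cutoff_excess),
         criteria = criteria),
    class = "mcda_framework")
  ip <- vapply(criteria, `[[`, logical(1), "is_price")
  if (sum(ip) == 1L && !is.na(price_weight)) {
    fw$criteria[[which(ip)]]$weight <- as.numeric(price_weight)
  }
  fw
}

criterion_ids <- function(fw) vapply(fw$criteria, `[[`, character(1), "id")

price_criterion <- function(fw) {
  ip <- vapply(fw$criteria, `[[`, logical(1), "is_price")
  if (sum(ip) != 1L) stop("framework must have exactly one price criterion")
  fw$criteria[[which(ip)]]
}

#' Non-price criteria of a framework
#' @param fw an \code{mcda_framework}.
#' @return list of \code{mcda_criterion}.
#' @export
nonprice_criteria <- function(fw) {
  Filter(function(cr) !cr$is_price, fw$criteria)
}

#' Criterion weights as a named vector
#' @param fw an \code{mcda_framework}.
#' @return named numeric vector of weights, in criterion order.
#' @export
framework_weights <- function(fw) {
  w <- vapply(fw$criteria, `[[`, numeric(1), "weight")
  names(w) <- criterion_ids(fw)
  w
}

#' Validate a framework against its structural invariants
#'
#' Checks every invariant of the model: exactly one price criterion; non-price
#' criteria with at least two uniquely labelled categories at strictly
#' increasing levels; score fractions in \code{[0, 1]}, non-decreasing with
#' level, 0 for exclusion categories and 1 at the best level; and — once any
#' weight has been set — weights summing to 1 (within 1e-9) with the price
#' criterion's weight equal to \code{price_weight}. A framework whose weights
#' are all unset (the pre-elicitation draft state) is structurally valid.
#'
#' Validation never raises: it returns a character vector of human-readable
#' violations, empty when the framework is valid.
#'
#' @param fw an \code{mcda_framework}.
#' @return character vector of violations (length 0 if valid).
#' @export
validate_framework <- function(fw) {
  v <- character(0)
  say <- function(...) v <<- c(v, paste0(...))
  if (!inherits(fw, "mcda_framework")) return("not an mcda_framework object")

  ids <- criterion_ids(fw)
  if (anyDuplicated(ids)) say("duplicate criterion ids: ",
                              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ip <- vapply(fw$criteria, `[[`, logical(1), "is_price")
  if (sum(ip) != 1L) {
    say("framework must have exactly one price criterion, found ", sum(ip),
        if (sum(ip) > 1L) paste0(" (", paste(ids[ip], collapse = ", "), ")") else "")
  }

  for (cr in fw$criteria) {
    if (cr$is_price) {
      if (length(cr$categories) > 0L)
        say("price criterion '", cr$id, "' must not have performance categories")
      next
    }
    cats <- cr$categories
    if (length(cats) < 2L) {
      say("criterion '", cr$id, "' needs >= 2 performance categories")
      next
    }
    lev <- vapply(cats, `[[`, integer(1), "level")
    lab <- vapply(cats, `[[`, character(1), "label")
    fr <- vapply(cats, `[[`, numeric(1), "score_fraction")
    ex <- vapply(cats, `[[`, logical(1), "is_exclusion")
    if (any(diff(lev) <= 0L))
      say("criterion '", cr$id, "' category levels must be strictly increasing")
    if (anyDuplicated(lab))
      say("criterion '", cr$id, "' has duplicate category labels: ",
          paste(unique(lab[duplicated(lab)]), collapse = ", "))
    if (any(fr < -1e-12 | fr > 1 + 1e-12))
      say("criterion '", cr$id, "' has score fractions outside [0, 1]")
    if (any(ex & abs(fr) > 1e-12))
      say("criterion '", cr$id, "' exclusion categories must store fraction 0")
    keep <- !ex
    if (any(keep)) {
      fk <- fr[keep]
      if (any(diff(fk) < -1e-12))
        say("criterion '", cr$id,
            "' score fractions must be non-decreasing with level")
      if (abs(fk[length(fk)] - 1) > 1e-12)
        say("criterion '", cr$id,
            "' best non-exclusion category must have score fraction 1")
    } else {
      say("criterion '", cr$id, "' has only exclusion categories")
    }
  }

  w <- vapply(fw$criteria, `[[`, numeric(1), "weight")
  weighted <- !all(is.na(w)) || !is.na(fw$price_weight)
  if (weighted) {
    if (anyNA(w)) {
      say("weights are set for some criteria but missing for: ",
          paste(ids[is.na(w)], collapse = ", "))
    } else {
      if (abs(sum(w) - 1) > 1e-9)
        say(sprintf("criterion weights must sum to 1, got %.12f", sum(w)))
      if (any(w < -1e-12))
        say("negative criterion weight(s)")
      if (sum(ip) == 1L && !is.na(fw$price_weight) &&
          abs(w[which(ip)] - fw$price_weight) > 1e-9)
        say("price criterion weight must equal price_weight")
    }
    if (is.na(fw$price_weight))
      say("weighted framework must set price_weight")
  }
  if (!is.na(fw$price_cutoff_excess) && fw$price_cutoff_excess <= 0)
    say("price_cutoff_excess must be positive")
  v
}

#' @export
print.mcda_framework <- function(x, ...) {
  cat("MCDA framework:", x$metadata$name, "(v", x$metadata$version, ")\n", sep = "")
  cat(sprintf("  price weight: %s   cut-off excess: %s\n",
              if (is.na(x$price_weight)) "unset"
              else sprintf("%.1f%%", percent_display(x$price_weight)),
              if (is.na(x$price_cutoff_excess)) "unset"
              else sprintf("+%.0f%%", 100 * x$price_cutoff_excess)))
  for (cr in x$criteria) {
    cat(sprintf("  %-34s %s%s\n", cr$id,
                if (is.na(cr$weight)) "   -  "
                else sprintf("%5.1f%%", percent_display(cr$weight)),
                if (cr$is_price) "  [price]"
                else sprintf("  (%d categories)", length(cr$categories))))
  }
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

fw_to_list <- function(fw) {
  list(
    schema_version = 1L,
    name = fw$metadata$name,
    version = fw$metadata$version,
    notes = fw$metadata$notes,
    price_weight = fw$price_weight,
    price_cutoff_excess = fw$price_cutoff_excess,
    criteria = lapply(fw$criteria, function(cr) {
      out <- list(id = cr$id, name = cr$name, definition = cr$definition,
                  is_price = cr$is_price)
      if (!is.na(cr$weight)) out$weight <- cr$weight
      if (!cr$is_price) {
        out$categories <- lapply(cr$categories, function(ct) {
          list(label = ct$label, level = ct$level,
               score_fraction = ct$score_fraction,
               description = ct$description,
               is_exclusion = ct$is_exclusion)
        })
      }
      out
    })
  )
}

#' Read / write a framework config file
#'
#' Frameworks are stored as schema-versioned YAML. The packaged Indonesian
#' configs (\code{system.file("extdata", "indonesia_draft.yaml", package =
#' "tenderMCDA")} and \code{indonesia_final.yaml}) are the canonical examples
#' of the format. \code{price_weight}, \code{price_cutoff_excess} and category
#' \code{score_fraction} fields accept the usual percent notations (see
#' \code{\link{parse_fraction}}). Saving and re-loading reproduces an
#' equivalent framework (weights at full double precision).
#'
#' @param path file path.
#' @return \code{read_framework} returns an \code{mcda_framework};
#'   \code{write_framework} returns \code{path} invisibly.
#' @export
read_framework <- function(path) {
  if (!file.exists(path)) stop("framework config not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || length(raw) == 0L)
    stop("empty framework config: ", path, call. = FALSE)
  sv <- raw$schema_version
  if (is.null(sv)) stop("framework config is missing 'schema_version'", call. = FALSE)
  if (!identical(as.integer(sv), 1L))
    stop("unknown framework schema_version: ", sv, call. = FALSE)
  if (is.null(raw$criteria)) stop("framework config is missing 'criteria'", call. = FALSE)

  crits <- lapply(raw$criteria, function(cr) {
    if (is.null(cr$id)) stop("criterion entry is missing 'id'", call. = FALSE)
    cats <- lapply(cr$categories %||% list(), function(ct) {
      if (is.null(ct$label))
        stop("category of criterion '", cr$id, "' is missing 'label'", call. = FALSE)
      if (is.null(ct$level))
        stop("category '", ct$label, "' of criterion '", cr$id,
             "' is missing 'level'", call. = FALSE)
      performance_category(
        label = ct$label, level = ct$level,
        score_fraction = if (is.null(ct$score_fraction)) NA_real_
                         else parse_fraction(ct$score_fraction),
        description = ct$description %||% "",
        is_exclusion = isTRUE(ct$is_exclusion))
    })
    criterion(id = cr$id, name = cr$name %||% cr$id,
              definition = cr$definition %||% "",
              categories = cats, is_price = isTRUE(cr$is_price),
              weight = if (is.null(cr$weight)) NA_real_
                       else parse_fraction(cr$weight))
  })
  mcda_framework(
    criteria = crits,
    price_weight = if (is.null(raw$price_weight)) NA_real_
                   else parse_fraction(raw$price_weight),
    price_cutoff_excess = if (is.null(raw$price_cutoff_excess)) NA_real_
                          else parse_fraction(raw$price_cutoff_excess),
    name = raw$name %||% "unnamed", version = as.character(raw$version %||% "1"),
    notes = raw$notes %||% "")
}

#' @rdname read_framework
#' @param fw an \code{mcda_framework}.
#' @export
write_framework <- function(fw, path) {
  yaml::write_yaml(fw_to_list(fw), path, precision = 15L)
  invisible(path)
}

#' Content hash of a framework
#'
#' MD5 of the canonical YAML serialization; reports embed it so a run can be
#' reproduced bit-identically from its inputs.
#'
#' @param fw an \code{mcda_framework}.
#' @return character MD5 hex digest.
#' @export
framework_hash <- function(fw) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_framework(fw, tmp)
  unname(tools::md5sum(tmp))
}
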