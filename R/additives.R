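#' Detect additives in a tokenized ingredient list
#'
#' Matching is case- and diacritic-insensitive over canonical names,
#' synonyms and INS codes.  A lexicon name matches when it occurs as a
#' substring of a normalized token.  Occurrences within a token are
#' selected greedily, longest name first, and may not overlap: so
#' "partially hydrogenated fat" beats the "hydrogenated" it contains,
#' while a token naming two different additives yields both.  A tie
#' between equal-length names from two entries competing for the same
#' text is broken by lexicon file order, with a warning.  Repeated
#' mentions of the same entry collapse to a single match.
#'
#' @param tokens character vector from [normalize_ingredient_text()].
#' @param lexicon an `additive_lexicon` from [load_lexicon()].
#' @return data frame with one row per matched lexicon entry: `entry`
#'   (index into `lexicon$entries`), `canonical_name`, `matched_text`
#'   (the lexicon name that matched), `position` (first matching token
#'   index).
#' @export
detect_additives <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "additive_lexicon"))
  empty <- data.frame(entry = integer(0), canonical_name = character(0),
                      matched_text = character(0), position = integer(0),
                      stringsAsFactors = FALSE)
  if (length(tokens) == 0L) return(empty)
  idx <- lexicon$index
  # prefilter: one vectorized scan over all tokens per lexicon name
  rows_by_token <- rep(list(integer(0)), length(tokens))
  for (i in seq_len(nrow(idx))) {
    for (t in which(grepl(idx$name[i], tokens, fixed = TRUE))) {
      rows_by_token[[t]] <- c(rows_by_token[[t]], i)
    }
  }
  hits <- list()
  for (pos in seq_along(tokens)) {
    rows <- rows_by_token[[pos]]
    if (length(rows) == 0L) next
    tok <- tokens[[pos]]
    occ <- do.call(rbind, lapply(rows, function(i) {
      starts <- gregexpr(idx$name[i], tok, fixed = TRUE)[[1]]
      data.frame(entry = idx$entry[i], name = idx$name[i],
                 start = as.integer(starts),
                 end = as.integer(starts) + idx$nchar[i] - 1L,
                 nchar = idx$nchar[i], stringsAsFactors = FALSE)
    }))
    # greedy longest-first, non-overlapping; ties by entry order
    occ <- occ[order(-occ$nchar, occ$entry, occ$start), , drop = FALSE]
    taken <- logical(nchar(tok))
    for (j in seq_len(nrow(occ))) {
      span <- occ$start[j]:occ$end[j]
      if (any(taken[span])) {
        rival <- occ[seq_len(j - 1L), , drop = FALSE]
        same <- rival[rival$nchar == occ$nchar[j] &
                        rival$entry != occ$entry[j] &
                        rival$start <= occ$end[j] &
                        rival$end >= occ$start[j], , drop = FALSE]
        if (nrow(same) > 0L) {
          warning("token '", tok, "' matches equal-length names from ",
                  "multiple lexicon entries; keeping the first in ",
                  "file order")
        }
        next
      }
      taken[span] <- TRUE
      hits[[length(hits) + 1L]] <- data.frame(
        entry = occ$entry[j],
        canonical_name =
          lexicon$entries[[occ$entry[j]]]$canonical_name,
        matched_text = occ$name[j],
        position = pos,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$position), , drop = FALSE]
  out <- out[!duplicated(out$entry), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve the functional class of a matched additive
#'
#' Multifunction additives take the function authorized for the
#' product's food category when the lexicon records a category
#' override; otherwise the entry's default function (its most common
#' use).  Deterministic.
#'
#' @param entry a lexicon entry (element of `lexicon$entries`) or its
#'   index.
#' @param subgroup the product's food subgroup label.
#' @param lexicon the lexicon (needed when `entry` is an index).
#' @return a functional-class label.
#' @export
resolve_function <- function(entry, subgroup, lexicon = NULL) {
  if (is.numeric(entry)) entry <- lexicon$entries[[entry]]
  ov <- entry$category_overrides
  if (!is.null(subgroup) && !is.na(subgroup) && subgroup %in% names(ov)) {
    return(ov[[subgroup]])
  }
  entry$default_function
}

#' Additive profile of a product
#'
#' Runs tokenization, matching and per-category function resolution for
#' one product and derives the flags used by the screening rule:
#' `has_cosmetic_additive` (at least one match whose resolved function
#' is cosmetic; sweetener-function matches are excluded under the
#' default policy because sweetener presence is already counted by the
#' nutrient profile model), `has_flavor_or_color` (resolved function is
#' flavor, flavor enhancer or color) and `has_sweetener`.
#'
#' @param record one-row catalog data frame (needs `product_id`,
#'   `subgroup`, `ingredients_text`).
#' @param lexicon an `additive_lexicon`.
#' @param exclude_sweeteners logical; when `TRUE` (default) sweetener
#'   matches do not count as cosmetic.
#' @return object of class `additive_profile`: list with `product_id`,
#'   `matches` (data frame with `resolved_function`, `is_cosmetic`,
#'   `is_sweetener` columns appended) and the three logical flags.
#' @export
additive_profile <- function(record, lexicon, exclude_sweeteners = TRUE) {
  stopifnot(nrow(record) == 1L)
  tokens <- normalize_ingredient_text(
    if (is.na(record$ingredients_text)) "" else record$ingredients_text)
  matches <- detect_additives(tokens, lexicon)
  n <- nrow(matches)
  resolved <- character(n)
  cosmetic <- logical(n)
  for (i in seq_len(n)) {
    e <- lexicon$entries[[matches$entry[i]]]
    resolved[i] <- resolve_function(e, record$subgroup)
    cosmetic[i] <- unname(e$is_cosmetic_by_function[[resolved[i]]])
  }
  matches$resolved_function <- resolved
  matches$is_cosmetic <- cosmetic
  matches$is_sweetener <- resolved == "sweetener"

  countable <- matches$is_cosmetic &
    (!exclude_sweeteners | !matches$is_sweetener)
  structure(list(
    product_id = record$product_id,
    matches = matches,
    has_cosmetic_additive = any(countable),
    has_flavor_or_color = any(resolved %in%
                                c("flavor", "flavor_enhancer", "color")),
    has_sweetener = any(matches$is_sweetener)
  ), class = "additive_profile")
}

#' @export
print.additive_profile <- function(x, ...) {
  cat("Additive profile for", x$product_id, "\n")
  if (nrow(x$matches) == 0L) {
    cat("  no additives detected\n")
  } else {
    cat(sprintf("  %-30s %s%s\n", x$matches$canonical_name,
                x$matches$resolved_function,
                ifelse(x$matches$is_cosmetic, " [cosmetic]", "")),
        sep = "")
  }
  cat("  cosmetic additive:", x$has_cosmetic_additive,
      "| flavor/color:", x$has_flavor_or_color,
      "| sweetener:", x$has_sweetener, "\n")
  invisible(x)
}
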