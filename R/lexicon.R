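#' @title Additive lexicon
#' @description The additive lexicon maps ingredient-list names (and
#'   synonyms and INS codes) to functional classes, and each functional
#'   class to a cosmetic/non-cosmetic status following the NOVA
#'   taxonomy: flavors, flavor enhancers, colors, emulsifiers,
#'   emulsifying salts, sweeteners, thickeners, anti-foaming, bulking,
#'   carbonating, foaming, gelling and glazing agents are cosmetic.
#'   The taxonomy is data, not code, so jurisdictions can differ.
#' @name additive_lexicon
NULL

#' Default cosmetic status by functional class
#'
#' Named logical vector covering the functional classes used by the
#' starter lexicon.  Cosmetic classes follow the NOVA taxonomy;
#' safety-motivated classes (preservatives, antioxidants, acidulants,
#' ...) are non-cosmetic.  Stabilizers are grouped with thickeners as
#' cosmetic, matching common practice for Brazilian label surveys.
#'
#' @return named logical vector.
#' @export
default_cosmetic_map <- function() {
  c(flavor = TRUE, flavor_enhancer = TRUE, color = TRUE,
    emulsifier = TRUE, emulsifying_salt = TRUE, sweetener = TRUE,
    thickener = TRUE, anti_foaming = TRUE, bulking_agent = TRUE,
    carbonating_agent = TRUE, foaming_agent = TRUE,
    gelling_agent = TRUE, glazing_agent = TRUE, stabilizer = TRUE,
    preservative = FALSE, antioxidant = FALSE, acidulant = FALSE,
    acidity_regulator = FALSE, anticaking_agent = FALSE,
    humectant = FALSE, raising_agent = FALSE, sequestrant = FALSE)
}

#' Load an additive lexicon from JSON
#'
#' The JSON file is an array of entries with fields `canonical_name`,
#' `synonyms` (array), `ins_code` (string or null), `functions`
#' (array of functional-class labels), `default_function`,
#' `category_overrides` (object subgroup -> function, may be absent)
#' and optionally `is_cosmetic_by_function` (object function -> bool;
#' classes not listed fall back to [default_cosmetic_map()]).
#'
#' Invariants checked at load time: `default_function` is one of
#' `functions`; every override value is one of `functions`; every
#' function has a cosmetic status; no matchable name (canonical,
#' synonym or INS code, after normalization) is shared by two entries.
#'
#' @param path path to the lexicon JSON; defaults to the starter lexicon
#'   shipped with the package.
#' @return an object of class `additive_lexicon`: list with `entries`
#'   (list of entries) and `index` (normalized name -> entry table used
#'   by the matcher).
#' @export
load_lexicon <- function(path = system.file("extdata", "lexicon_starter.json",
                                            package = "upfscan")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw) || length(raw) == 0L) {
    stop("lexicon JSON must be a non-empty array of entries")
  }
  defaults <- default_cosmetic_map()
  entries <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    e <- raw[[i]]
    if (is.null(e$canonical_name) || !nzchar(e$canonical_name)) {
      stop("lexicon entry ", i, " has no canonical_name")
    }
    fns <- unlist(e$functions)
    if (length(fns) == 0L) {
      stop("lexicon entry '", e$canonical_name, "' lists no functions")
    }
    if (is.null(e$default_function) || !e$default_function %in% fns) {
      stop("lexicon entry '", e$canonical_name,
           "': default_function must be one of its functions")
    }
    overrides <- e$category_overrides
    if (is.null(overrides)) overrides <- list()
    for (sub in names(overrides)) {
      if (!overrides[[sub]] %in% fns) {
        stop("lexicon entry '", e$canonical_name, "': override for '",
             sub, "' names function '", overrides[[sub]],
             "' not in its functions")
      }
    }
    cosmetic <- vapply(fns, function(f) {
      own <- e$is_cosmetic_by_function[[f]]
      if (!is.null(own)) return(isTRUE(own))
      if (!f %in% names(defaults)) {
        stop("lexicon entry '", e$canonical_name, "': no cosmetic status ",
             "for function '", f, "'")
      }
      unname(defaults[[f]])
    }, logical(1))
    names(cosmetic) <- fns
    entries[[i]] <- list(
      canonical_name = e$canonical_name,
      synonyms = as.character(unlist(e$synonyms)),
      ins_code = if (is.null(e$ins_code)) NA_character_ else e$ins_code,
      functions = fns,
      default_function = e$default_function,
      category_overrides = lapply(overrides, identity),
      is_cosmetic_by_function = cosmetic
    )
  }

  # matching index over normalized names; collisions across entries are
  # rejected because they would make matches ambiguous
  idx <- do.call(rbind, lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    nm <- c(e$canonical_name, e$synonyms,
            if (!is.na(e$ins_code)) e$ins_code)
    data.frame(entry = i, name = fold_text(nm), stringsAsFactors = FALSE)
  }))
  idx <- idx[!duplicated(idx[, c("entry", "name")]), , drop = FALSE]
  dup <- idx$name[duplicated(idx$name)]
  if (length(dup) > 0L) {
    d <- unique(dup)[1]
    who <- vapply(idx$entry[idx$name == d],
                  function(i) entries[[i]]$canonical_name, character(1))
    stop("lexicon name '", d, "' is shared by entries: ",
         paste(who, collapse = ", "))
  }
  idx$nchar <- nchar(idx$name)
  idx <- idx[order(-idx$nchar, idx$entry), , drop = FALSE]
  rownames(idx) <- NULL
  structure(list(entries = entries, index = idx),
            class = "additive_lexicon")
}

#' @export
print.additive_lexicon <- function(x, ...) {
  cat("Additive lexicon:", length(x$entries), "entries,",
      nrow(x$index), "matchable names\n")
  fns <- sort(unique(unlist(lapply(x$entries, `[[`, "functions"))))
  cat("Functional classes:", paste(fns, collapse = ", "), "\n")
  invisible(x)
}
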