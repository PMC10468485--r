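# Shared fixtures: built in code, no files beyond tempfiles.

make_record <- function(product_id = "X1", name = "test product",
                        subgroup = "Sweet cookies", nova_group = 4,
                        basis = "per_100g", energy_kcal = 400,
                        total_fat_g = NA, sat_fat_g = NA,
                        trans_fat_g = NA, sodium_mg = NA,
                        total_sugars_g = NA, added_sugars_g = NA,
                        ingredients_text = "") {
  as_upf_catalog(data.frame(
    product_id = product_id, name = name, subgroup = subgroup,
    nova_group = nova_group, basis = basis, energy_kcal = energy_kcal,
    total_fat_g = total_fat_g, sat_fat_g = sat_fat_g,
    trans_fat_g = trans_fat_g, sodium_mg = sodium_mg,
    total_sugars_g = total_sugars_g, added_sugars_g = added_sugars_g,
    ingredients_text = ingredients_text, stringsAsFactors = FALSE))
}

# Write a lexicon JSON to a tempfile and load it.
lexicon_from_entries <- function(entries) {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(entries, path, auto_unbox = TRUE, null = "null")
  load_lexicon(path)
}

lexicon_entry <- function(canonical_name, functions,
                          default_function = functions[[1]],
                          synonyms = list(), ins_code = NULL,
                          category_overrides = NULL,
                          is_cosmetic_by_function = NULL) {
  e <- list(canonical_name = canonical_name, synonyms = synonyms,
            functions = as.list(functions),
            default_function = default_function)
  e$ins_code <- ins_code
  if (!is.null(category_overrides)) {
    e$category_overrides <- category_overrides
  }
  if (!is.null(is_cosmetic_by_function)) {
    e$is_cosmetic_by_function <- is_cosmetic_by_function
  }
  e
}

# A small controlled lexicon used across parser tests.
tiny_lexicon <- function() {
  lexicon_from_entries(list(
    lexicon_entry("tartrazina", "color", synonyms = list("tartrazine"),
                  ins_code = "ins 102"),
    lexicon_entry("aroma natural", "flavor"),
    lexicon_entry("sucralose", "sweetener"),
    lexicon_entry("benzoato de sodio", "preservative",
                  ins_code = "ins 211"),
    lexicon_entry("carragena", c("thickener", "gelling_agent"),
                  default_function = "thickener",
                  category_overrides = list(
                    "Dairy beverages" = "thickener",
                    "Sweets in general" = "gelling_agent"))
  ))
}

# Independent re-implementation of the matcher used as an oracle:
# enumerates every (entry, name) occurrence by explicit substring
# scanning, then applies the same longest-first non-overlap precedence.
brute_force_matches <- function(tokens, lexicon) {
  fold <- upfscan:::fold_text
  occ_all <- list()
  for (pos in seq_along(tokens)) {
    tok <- tokens[[pos]]
    occ <- list()
    for (i in seq_along(lexicon$entries)) {
      e <- lexicon$entries[[i]]
      nms <- unique(fold(c(e$canonical_name, e$synonyms,
                           if (!is.na(e$ins_code)) e$ins_code)))
      for (nm in nms) {
        L <- nchar(nm)
        if (L > nchar(tok)) next
        for (s in seq_len(nchar(tok) - L + 1L)) {
          if (substr(tok, s, s + L - 1L) == nm) {
            occ[[length(occ) + 1L]] <- data.frame(
              entry = i, name = nm, start = s, end = s + L - 1L,
              nchar = L, stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(occ) == 0L) next
    occ <- do.call(rbind, occ)
    occ <- occ[order(-occ$nchar, occ$entry, occ$start), , drop = FALSE]
    taken <- logical(nchar(tok))
    for (j in seq_len(nrow(occ))) {
      span <- occ$start[j]:occ$end[j]
      if (any(taken[span])) next
      taken[span] <- TRUE
      occ_all[[length(occ_all) + 1L]] <- data.frame(
        entry = occ$entry[j], position = pos,
        stringsAsFactors = FALSE)
    }
  }
  if (length(occ_all) == 0L) {
    return(data.frame(entry = integer(0), position = integer(0)))
  }
  out <- do.call(rbind, occ_all)
  out <- out[order(out$position), , drop = FALSE]
  out[!duplicated(out$entry), , drop = FALSE]
}

brute_force_profile_flags <- function(text, subgroup, lexicon,
                                      exclude_sweeteners = TRUE) {
  tokens <- normalize_ingredient_text(text)
  m <- brute_force_matches(tokens, lexicon)
  resolved <- vapply(m$entry, function(i) {
    e <- lexicon$entries[[i]]
    ov <- e$category_overrides
    if (!is.null(subgroup) && subgroup %in% names(ov)) ov[[subgroup]]
    else e$default_function
  }, character(1))
  cosmetic <- vapply(seq_along(resolved), function(k) {
    unname(lexicon$entries[[m$entry[k]]]$
             is_cosmetic_by_function[[resolved[k]]])
  }, logical(1))
  sweet <- resolved == "sweetener"
  list(
    has_cosmetic_additive = any(cosmetic & (!exclude_sweeteners | !sweet)),
    has_flavor_or_color = any(resolved %in%
                                c("flavor", "flavor_enhancer", "color")),
    has_sweetener = any(sweet)
  )
}
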