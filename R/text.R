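#' Normalize a free-text ingredient list into tokens
#'
#' Lowercases, folds Latin diacritics to ASCII, flattens parenthesized
#' sub-lists (compound ingredients) into additional tokens, splits on
#' commas and semicolons, trims whitespace and drops empty tokens.
#' Compound ingredients are flattened because additives declared inside
#' them count towards the product's additive profile.
#'
#' @param text character scalar (may be empty or `NA`).
#' @return character vector of normalized tokens, in label order.
#' @examples
#' normalize_ingredient_text("Acucar, CORANTE caramelo")
#' normalize_ingredient_text("farinha (trigo, ferro), sal")
#' @export
normalize_ingredient_text <- function(text) {
  if (length(text) != 1L) stop("`text` must be a single string")
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- fold_text(text)
  # parentheses and brackets act as additional separators
  x <- gsub("[][()]", ",", x)
  tokens <- strsplit(x, "[,;]")[[1]]
  tokens <- trimws(tokens)
  tokens <- gsub("[[:space:]]+", " ", tokens)
  tokens[nzchar(tokens)]
}

# Lowercase + explicit diacritic folding (Portuguese/Spanish coverage).
# chartr is used rather than iconv transliteration, whose output is
# locale-dependent.
fold_text <- function(x) {
  x <- tolower(x)
  chartr(
    "áàâãäéèêëíìîïóòôõöúùûüçñ",
    "aaaaaeeeeiiiiooooouuuucn",
    x
  )
}
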