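#' PAHO nutrient profile model configuration
#'
#' Thresholds of the PAHO NPM, expressed relative to total energy:
#' a product is excessive in free sugars when they supply >= 10% of
#' energy (at 4 kcal/g), in total fat at >= 30% of energy, in saturated
#' fat at >= 10% and in trans fat at >= 1% (fats at 9 kcal/g); sodium is
#' excessive at >= 1 mg per kcal.  All thresholds use ">=" semantics:
#' a value exactly at the threshold is flagged.  Because the criteria
#' are energy-relative they apply identically to per-100 g and
#' per-100 mL panels.
#'
#' @param kcal_per_g_sugar,kcal_per_g_fat Atwater energy factors
#'   (kcal/g).
#' @param free_sugar_energy_threshold,total_fat_energy_threshold,sat_fat_energy_threshold,trans_fat_energy_threshold
#'   energy fractions.
#' @param sodium_mg_per_kcal_threshold mg sodium per kcal.
#' @param zero_energy_sodium_rule what to do with sodium in zero-energy
#'   products, where the mg/kcal ratio diverges:
#'   `"excess_if_any_sodium"` (default) or `"never_excess"`.
#' @param trans_source_keywords ingredient-list phrases identifying
#'   trans-fat sources; matched as diacritic-folded substrings.
#' @return list of class `npm_config`.
#' @export
npm_config <- function(kcal_per_g_sugar = 4,
                       kcal_per_g_fat = 9,
                       free_sugar_energy_threshold = 0.10,
                       total_fat_energy_threshold = 0.30,
                       sat_fat_energy_threshold = 0.10,
                       trans_fat_energy_threshold = 0.01,
                       sodium_mg_per_kcal_threshold = 1.0,
                       zero_energy_sodium_rule = c("excess_if_any_sodium",
                                                   "never_excess"),
                       trans_source_keywords = default_trans_keywords()) {
  zero_energy_sodium_rule <- match.arg(zero_energy_sodium_rule)
  cfg <- list(
    kcal_per_g_sugar = kcal_per_g_sugar,
    kcal_per_g_fat = kcal_per_g_fat,
    free_sugar_energy_threshold = free_sugar_energy_threshold,
    total_fat_energy_threshold = total_fat_energy_threshold,
    sat_fat_energy_threshold = sat_fat_energy_threshold,
    trans_fat_energy_threshold = trans_fat_energy_threshold,
    sodium_mg_per_kcal_threshold = sodium_mg_per_kcal_threshold,
    zero_energy_sodium_rule = zero_energy_sodium_rule,
    trans_source_keywords = trans_source_keywords
  )
  thr <- unlist(cfg[grepl("threshold|kcal_per_g", names(cfg))])
  if (any(thr <= 0)) stop("all thresholds and energy factors must be > 0")
  if (length(trans_source_keywords) == 0L) {
    stop("trans_source_keywords must be non-empty")
  }
  structure(cfg, class = "npm_config")
}

#' Default trans-fat-source keywords (English + Portuguese)
#' @return character vector.
#' @export
default_trans_keywords <- function() {
  c("hydrogenated vegetable fat", "partially hydrogenated fat",
    "hydrogenated vegetable oil", "hydrogenated",
    "gordura vegetal hidrogenada", "gordura parcialmente hidrogenada",
    "oleo vegetal hidrogenado", "hidrogenada", "hidrogenado")
}

#' Load an NPM configuration from YAML
#'
#' Keys mirror the arguments of [npm_config()]; absent keys keep their
#' defaults.  The shipped `npm_paho_default.yaml` reproduces the
#' defaults.
#'
#' @param path YAML file path.
#' @return an `npm_config`.
#' @export
load_npm_config <- function(path = system.file("extdata",
                                               "npm_paho_default.yaml",
                                               package = "upfscan")) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(npm_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown NPM config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(npm_config, vals)
}

#' Fraction of total energy supplied by a nutrient
#'
#' @param nutrient_g grams of nutrient per 100 g/mL.
#' @param kcal_per_g energy factor.
#' @param energy_kcal total energy per 100 g/mL; must be > 0.
#' @return `nutrient_g * kcal_per_g / energy_kcal`.
#' @export
percent_energy <- function(nutrient_g, kcal_per_g, energy_kcal) {
  if (is.na(energy_kcal) || energy_kcal <= 0) {
    stop("percent_energy requires energy_kcal > 0; ",
         "zero-energy products are handled by the caller's rule")
  }
  if (!is.na(nutrient_g) && nutrient_g < 0) stop("nutrient_g must be >= 0")
  nutrient_g * kcal_per_g / energy_kcal
}

#' Read a subgroup-level added-sugar reference table
#'
#' CSV with columns `subgroup,added_sugars_g_per_100`.  Used to impute
#' added sugars for products that do not declare them, by food
#' subgroup.  The shipped `sugar_reference_synthetic.csv` contains
#' illustrative values for the default subgroup taxonomy; substitute a
#' composition-table-derived file for real analyses.
#'
#' @param path CSV path.
#' @return named numeric vector (subgroup -> grams per 100 g/mL).
#' @export
read_sugar_reference <- function(path = system.file(
  "extdata", "sugar_reference_synthetic.csv", package = "upfscan")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!all(c("subgroup", "added_sugars_g_per_100") %in% names(df))) {
    stop("sugar reference needs columns subgroup, added_sugars_g_per_100")
  }
  if (any(df$added_sugars_g_per_100 < 0, na.rm = TRUE)) {
    stop("sugar reference values must be >= 0")
  }
  stats::setNames(df$added_sugars_g_per_100, df$subgroup)
}

#' Estimate a product's added-sugar content
#'
#' Resolution order: a declared `added_sugars_g` is used as-is; else,
#' under the default policy, a declared `total_sugars_g` serves as an
#' upper proxy for added sugars (sugar declaration was voluntary on
#' Brazilian labels, so most products need one of the fallbacks); else
#' the subgroup reference table imputes a typical value; else the
#' result is missing.  The provenance is always reported.
#'
#' @param record one-row catalog data frame.
#' @param sugar_ref named vector from [read_sugar_reference()], or
#'   `NULL` to skip imputation.
#' @param use_total_as_added logical policy (default `TRUE`).
#' @return list with `grams` (numeric or `NA`) and `source` (one of
#'   `"declared"`, `"imputed"`, `"missing"`).
#' @export
estimate_added_sugars <- function(record, sugar_ref = NULL,
                                  use_total_as_added = TRUE) {
  if (!is.na(record$added_sugars_g)) {
    return(list(grams = record$added_sugars_g, source = "declared"))
  }
  if (use_total_as_added && !is.na(record$total_sugars_g)) {
    return(list(grams = record$total_sugars_g, source = "declared"))
  }
  if (!is.null(sugar_ref) && !is.na(record$subgroup) &&
      record$subgroup %in% names(sugar_ref)) {
    return(list(grams = unname(sugar_ref[[record$subgroup]]),
                source = "imputed"))
  }
  list(grams = NA_real_, source = "missing")
}

#' Free sugars from added sugars
#'
#' The default policy equates free sugars with added sugars.  A custom
#' policy function `(added_g, record) -> grams` can add sugars
#' naturally present in honey, syrups or fruit juice when those can be
#' quantified.
#'
#' @param added_g grams of added sugars, or `NA`.
#' @param record the product record (available to custom policies).
#' @param policy `NULL` for the identity policy, or a function.
#' @return grams of free sugars, or `NA`.
#' @export
free_sugars <- function(added_g, record = NULL, policy = NULL) {
  if (is.null(policy)) return(added_g)
  if (is.na(added_g)) return(NA_real_)
  policy(added_g, record)
}

#' Detect trans-fat-source ingredients
#'
#' @param tokens normalized ingredient tokens.
#' @param config an `npm_config` (its `trans_source_keywords` are used).
#' @return `TRUE` iff any token contains any keyword as a
#'   diacritic-folded substring.
#' @export
detect_trans_fat_sources <- function(tokens, config = npm_config()) {
  if (length(tokens) == 0L) return(FALSE)
  keys <- fold_text(config$trans_source_keywords)
  any(vapply(keys, function(k) any(grepl(k, tokens, fixed = TRUE)),
             logical(1)))
}

#' Evaluate the PAHO nutrient profile model for one product
#'
#' The model applies only to processed foods and ultra-processed
#' products (NOVA groups 3 and 4).  For applicable products each
#' criterion is evaluated independently; a nutrient that is not
#' declared (and not imputable, for sugars) leaves its flag `NA` —
#' missing never creates an excess.  Trans fat fires on either the
#' declared-quantity energy criterion or the ingredient keywords.
#' `any_excess` is the OR of the six flags with `NA` treated as
#' `FALSE`.
#'
#' @param record one-row catalog data frame.
#' @param profile the product's [additive_profile()] (for sweetener
#'   presence), or `NULL` for none.
#' @param free_sugars_g grams of free sugars (possibly `NA`), e.g. from
#'   [estimate_added_sugars()] + [free_sugars()].
#' @param config an `npm_config`.
#' @param sugar_source provenance string carried through to the result.
#' @param applicable_override set to `TRUE`/`FALSE` to force the
#'   applicability gate (screening mode without NOVA labels); `NULL`
#'   uses `nova_group %in% c(3, 4)`.
#' @return list of class `npm_result` with fields `applicable`,
#'   `excess_free_sugars`, `excess_sodium`, `excess_total_fat`,
#'   `excess_sat_fat`, `trans_fat_present`, `sweetener_present`,
#'   `any_excess`, `sugar_source`.
#' @export
evaluate_npm <- function(record, profile = NULL, free_sugars_g = NA_real_,
                         config = npm_config(), sugar_source = "missing",
                         applicable_override = NULL) {
  stopifnot(nrow(record) == 1L)
  applicable <- if (is.null(applicable_override)) {
    !is.na(record$nova_group) && record$nova_group %in% c(3, 4)
  } else {
    isTRUE(applicable_override)
  }
  na_result <- function() {
    structure(list(applicable = applicable,
                   excess_free_sugars = NA, excess_sodium = NA,
                   excess_total_fat = NA, excess_sat_fat = NA,
                   trans_fat_present = NA, sweetener_present = NA,
                   any_excess = FALSE, sugar_source = sugar_source),
              class = "npm_result")
  }
  if (!applicable) return(na_result())

  energy <- record$energy_kcal
  if (is.na(energy)) return(na_result())

  frac_flag <- function(grams, kcal_per_g, threshold) {
    if (is.na(grams)) return(NA)
    if (energy > 0) return(percent_energy(grams, kcal_per_g, energy) >=
                             threshold)
    # zero-energy: any positive quantity makes the fraction diverge
    grams > 0
  }
  excess_sugars <- frac_flag(free_sugars_g, config$kcal_per_g_sugar,
                             config$free_sugar_energy_threshold)
  excess_total_fat <- frac_flag(record$total_fat_g, config$kcal_per_g_fat,
                                config$total_fat_energy_threshold)
  excess_sat_fat <- frac_flag(record$sat_fat_g, config$kcal_per_g_fat,
                              config$sat_fat_energy_threshold)

  excess_sodium <- if (is.na(record$sodium_mg)) {
    NA
  } else if (energy > 0) {
    record$sodium_mg / energy >= config$sodium_mg_per_kcal_threshold
  } else if (config$zero_energy_sodium_rule == "excess_if_any_sodium") {
    record$sodium_mg > 0
  } else {
    FALSE
  }

  trans_declared <- frac_flag(record$trans_fat_g, config$kcal_per_g_fat,
                              config$trans_fat_energy_threshold)
  tokens <- normalize_ingredient_text(
    if (is.na(record$ingredients_text)) "" else record$ingredients_text)
  trans_keyword <- detect_trans_fat_sources(tokens, config)
  trans_present <- if (trans_keyword) TRUE else trans_declared

  sweetener <- if (is.null(profile)) NA else profile$has_sweetener

  flags <- c(excess_sugars, excess_sodium, excess_total_fat,
             excess_sat_fat, trans_present, sweetener)
  structure(list(
    applicable = TRUE,
    excess_free_sugars = excess_sugars,
    excess_sodium = excess_sodium,
    excess_total_fat = excess_total_fat,
    excess_sat_fat = excess_sat_fat,
    trans_fat_present = trans_present,
    sweetener_present = sweetener,
    any_excess = any(flags, na.rm = TRUE),
    sugar_source = sugar_source
  ), class = "npm_result")
}

#' @export
print.npm_result <- function(x, ...) {
  if (!x$applicable) {
    cat("PAHO NPM: not applicable (NOVA group 1-2 or no label)\n")
    return(invisible(x))
  }
  flags <- unlist(x[c("excess_free_sugars", "excess_sodium",
                      "excess_total_fat", "excess_sat_fat",
                      "trans_fat_present", "sweetener_present")])
  cat("PAHO NPM result (sugar source:", x$sugar_source, ")\n")
  for (nm in names(flags)) {
    cat(sprintf("  %-20s %s\n", nm,
                if (is.na(flags[[nm]])) "missing" else flags[[nm]]))
  }
  cat("  any excess:", x$any_excess, "\n")
  invisible(x)
}
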