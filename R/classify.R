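#' Combine the additive and nutrient criteria for one product
#'
#' The screening rule flags a product as presumptive ultra-processed
#' when it has at least one cosmetic additive OR, where the nutrient
#' profile model applies, at least one critical nutrient in excess
#' (including trans-fat sources and sweeteners).
#'
#' @param profile an [additive_profile()].
#' @param npm an `npm_result` from [evaluate_npm()].
#' @return one-row data frame: `product_id`, `has_cosmetic_additive`,
#'   `has_flavor_or_color`, `has_sweetener`, `npm_applicable`,
#'   `npm_any_excess`, `combined_flag`, `criteria_fired` (comma-joined
#'   subset of `cosmetic_additive`, `critical_nutrient_excess`).
#' @export
combined_flag <- function(profile, npm) {
  nutrient <- npm$applicable && npm$any_excess
  fired <- c(if (profile$has_cosmetic_additive) "cosmetic_additive",
             if (nutrient) "critical_nutrient_excess")
  data.frame(
    product_id = profile$product_id,
    has_cosmetic_additive = profile$has_cosmetic_additive,
    has_flavor_or_color = profile$has_flavor_or_color,
    has_sweetener = profile$has_sweetener,
    npm_applicable = npm$applicable,
    npm_any_excess = npm$any_excess,
    combined_flag = profile$has_cosmetic_additive || nutrient,
    criteria_fired = paste(fired, collapse = ","),
    stringsAsFactors = FALSE)
}

#' Classify a catalog of packaged foods
#'
#' Runs the full screening pipeline over every record that passes
#' validation: ingredient tokenization and additive matching, added- and
#' free-sugar resolution, the PAHO nutrient profile model (applied to
#' NOVA groups 3-4, or per `no_label_policy` when the reference label is
#' missing), and the combined flag.  Records with validation errors are
#' excluded and reported; warnings never exclude.  Records with no
#' nutrition panel usable by the NPM and an empty ingredient list are
#' kept, flagged `FALSE`, and annotated as having insufficient data.
#'
#' @param catalog a `upf_catalog` (or coercible data frame).
#' @param lexicon an `additive_lexicon`; default: the starter lexicon.
#' @param config an `npm_config`.
#' @param sugar_ref named vector from [read_sugar_reference()], or
#'   `NULL` (default) for no subgroup imputation.
#' @param exclude_sweeteners cosmetic-counting policy, see
#'   [additive_profile()].
#' @param use_total_as_added declared-total sugar policy, see
#'   [estimate_added_sugars()].
#' @param no_label_policy applicability of the NPM for records without
#'   a `nova_group`: `"apply_all"` (default; screening mode applies the
#'   model to every record with a panel) or `"additive_only"`.
#' @param free_sugar_policy `NULL` or a function, see [free_sugars()].
#' @return object of class `upf_classification`: list with `results`
#'   (one row per classified record, input order), `excluded`
#'   (validation errors), `warnings`, `catalog`, `log` (per-stage
#'   counts) and the effective policies.
#' @seealso [summary.upf_classification()], [agreement()],
#'   [group_frequencies()]
#' @export
classify_catalog <- function(catalog,
                             lexicon = load_lexicon(),
                             config = npm_config(),
                             sugar_ref = NULL,
                             exclude_sweeteners = TRUE,
                             use_total_as_added = TRUE,
                             no_label_policy = c("apply_all",
                                                 "additive_only"),
                             free_sugar_policy = NULL) {
  no_label_policy <- match.arg(no_label_policy)
  if (!inherits(catalog, "upf_catalog")) catalog <- as_upf_catalog(catalog)
  if (nrow(catalog) == 0L) warning("empty catalog: no records to classify")

  report <- validate_catalog(catalog)
  bad_ids <- unique(report$product_id[report$severity == "error"])
  valid <- catalog[!catalog$product_id %in% bad_ids, , drop = FALSE]

  rows <- vector("list", nrow(valid))
  sugar_sources <- character(nrow(valid))
  insufficient <- logical(nrow(valid))
  for (i in seq_len(nrow(valid))) {
    rec <- valid[i, ]
    prof <- additive_profile(rec, lexicon,
                             exclude_sweeteners = exclude_sweeteners)
    sug <- estimate_added_sugars(rec, sugar_ref,
                                 use_total_as_added = use_total_as_added)
    fs <- free_sugars(sug$grams, rec, free_sugar_policy)
    override <- if (is.na(rec$nova_group)) {
      no_label_policy == "apply_all"
    } else NULL
    npm <- evaluate_npm(rec, prof, fs, config,
                        sugar_source = sug$source,
                        applicable_override = override)
    row <- combined_flag(prof, npm)
    row$sugar_source <- npm$sugar_source
    rows[[i]] <- row
    no_panel <- is.na(rec$energy_kcal)
    no_ingredients <- is.na(rec$ingredients_text) ||
      !nzchar(trimws(rec$ingredients_text))
    insufficient[i] <- no_panel && no_ingredients
  }
  if (length(rows) > 0L) {
    results <- do.call(rbind, rows)
  } else {
    results <- data.frame(
      product_id = character(0), nova_group = integer(0),
      subgroup = character(0), has_cosmetic_additive = logical(0),
      has_flavor_or_color = logical(0), has_sweetener = logical(0),
      npm_applicable = logical(0), npm_any_excess = logical(0),
      combined_flag = logical(0), criteria_fired = character(0),
      sugar_source = character(0), insufficient_data = logical(0),
      stringsAsFactors = FALSE)
  }
  if (nrow(valid) > 0L) {
    results <- cbind(
      results[, "product_id", drop = FALSE],
      data.frame(nova_group = valid$nova_group,
                 subgroup = valid$subgroup, stringsAsFactors = FALSE),
      results[, setdiff(names(results), "product_id"), drop = FALSE])
    results$insufficient_data <- insufficient
    rownames(results) <- NULL
  }

  structure(list(
    results = results,
    excluded = report[report$severity == "error", , drop = FALSE],
    warnings = report[report$severity == "warning", , drop = FALSE],
    catalog = catalog,
    policies = list(exclude_sweeteners = exclude_sweeteners,
                    use_total_as_added = use_total_as_added,
                    no_label_policy = no_label_policy),
    log = c(n_input = nrow(catalog),
            n_excluded = length(bad_ids),
            n_classified = nrow(valid),
            n_flagged = sum(results$combined_flag),
            n_insufficient = sum(insufficient))
  ), class = "upf_classification")
}

#' @export
print.upf_classification <- function(x, ...) {
  cat("UPF screening of", x$log[["n_input"]], "products\n")
  cat("  classified:", x$log[["n_classified"]],
      "| excluded (validation errors):", x$log[["n_excluded"]], "\n")
  cat(sprintf("  flagged by combined criterion: %d (%.1f%%)\n",
              x$log[["n_flagged"]],
              100 * x$log[["n_flagged"]] /
                max(1L, x$log[["n_classified"]])))
  r <- x$results
  if (nrow(r) > 0L) {
    cat(sprintf("  cosmetic additive: %.1f%% | flavors/colors: %.1f%%\n",
                100 * mean(r$has_cosmetic_additive),
                100 * mean(r$has_flavor_or_color)))
    app <- r$npm_applicable
    if (any(app)) {
      cat(sprintf("  nutrient excess among NPM-applicable (n=%d): %.1f%%\n",
                  sum(app), 100 * mean(r$npm_any_excess[app])))
    }
  }
  cat("  policies:", paste(names(x$policies),
                           unlist(lapply(x$policies, as.character)),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a classification by NOVA group
#'
#' @param object a `upf_classification`.
#' @param by grouping keys, passed to [group_frequencies()].
#' @param ... unused.
#' @return the [group_frequencies()] table.
#' @export
summary.upf_classification <- function(object, by = "nova_group", ...) {
  group_frequencies(object, by = by)
}

#' @export
as.data.frame.upf_classification <- function(x, ...) x$results
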