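#' @title Catalog input/output and validation
#' @description Readers, writers and validators for packaged-food label
#'   catalogs.  A catalog is a data frame with one row per product and
#'   the columns listed under [read_catalog()].  Missing numeric fields
#'   (empty CSV cells, JSON nulls) are kept as `NA`: an undeclared
#'   nutrient is never the same as a declared zero.
#' @name catalog_io
NULL

.catalog_required <- c("product_id", "subgroup", "basis", "energy_kcal",
                       "ingredients_text")
.catalog_numeric <- c("energy_kcal", "total_fat_g", "sat_fat_g",
                      "trans_fat_g", "sodium_mg", "total_sugars_g",
                      "added_sugars_g")
.catalog_columns <- c("product_id", "name", "subgroup", "nova_group",
                      "basis", "energy_kcal", "total_fat_g", "sat_fat_g",
                      "trans_fat_g", "sodium_mg", "total_sugars_g",
                      "added_sugars_g", "ingredients_text")

#' Read a product catalog from CSV or JSON
#'
#' Expected columns/keys: `product_id`, `name`, `subgroup`, `nova_group`,
#' `basis` (`per_100g` or `per_100ml`), `energy_kcal`, `total_fat_g`,
#' `sat_fat_g`, `trans_fat_g`, `sodium_mg`, `total_sugars_g`,
#' `added_sugars_g`, `ingredients_text`.  Nutrient quantities are per
#' 100 g or 100 mL as given by `basis`.  Optional columns may be absent;
#' they are filled with `NA`.  Empty cells map to `NA`, never to zero.
#'
#' @param path path to the catalog file.
#' @param format `"csv"` or `"json"`; guessed from the file extension
#'   when omitted.
#' @return a data frame of class `upf_catalog`, rows in file order, with
#'   a derived logical column `sugar_declared` (`total_sugars_g` present).
#' @export
read_catalog <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("catalog file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    raw <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
  } else {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (!is.data.frame(raw)) stop("JSON catalog must be an array of objects")
    raw[] <- lapply(raw, function(col) {
      col <- as.character(col)
      col[is.na(col)] <- ""
      col
    })
  }
  as_upf_catalog(raw)
}

#' Coerce a data frame to a validated catalog
#'
#' Checks the schema (required columns, unique ids, parseable numerics)
#' and normalizes column types.  Called by [read_catalog()]; exported so
#' in-memory data frames can enter the pipeline directly.
#'
#' @param raw data frame with catalog columns (character or numeric).
#' @return a `upf_catalog` data frame.
#' @export
as_upf_catalog <- function(raw) {
  missing_cols <- setdiff(.catalog_required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("catalog is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(.catalog_columns, names(raw))) raw[[col]] <- NA
  out <- raw[, .catalog_columns]

  for (col in c("product_id", "name", "subgroup", "basis",
                "ingredients_text")) {
    v <- as.character(out[[col]])
    v[!is.na(v) & !nzchar(trimws(v))] <- NA_character_
    out[[col]] <- v
  }
  for (col in c(.catalog_numeric, "nova_group")) {
    out[[col]] <- parse_numeric_column(out[[col]], col)
  }
  out$nova_group <- as.integer(out$nova_group)

  dup <- unique(out$product_id[duplicated(out$product_id)])
  if (length(dup) > 0L) {
    stop("duplicate product_id value(s): ", paste(dup, collapse = ", "))
  }
  out$sugar_declared <- !is.na(out$total_sugars_g)
  rownames(out) <- NULL
  class(out) <- c("upf_catalog", "data.frame")
  out
}

parse_numeric_column <- function(v, col) {
  if (is.numeric(v)) return(as.numeric(v))
  v <- trimws(as.character(v))
  v[v == ""] <- NA_character_
  num <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(num))
  if (length(bad) > 0L) {
    stop("unparseable numeric in column '", col, "' at row(s): ",
         paste(bad, collapse = ", "))
  }
  num
}

#' Validate catalog records
#'
#' Pure function of the catalog: the same input always yields the same
#' report.  Errors exclude a record from classification; warnings never
#' do.  Checks: non-negative quantities, `energy_kcal` present,
#' `nova_group` in 1..4 when present, `basis` in
#' `per_100g`/`per_100ml`, and the consistency warning
#' `sat_fat_g <= total_fat_g`.
#'
#' @param catalog a `upf_catalog` data frame (or one row of it).
#' @return data frame with columns `product_id`, `field`, `severity`
#'   (`"error"` or `"warning"`), `message`; zero rows when clean.
#' @export
validate_catalog <- function(catalog) {
  entries <- list()
  add <- function(id, field, severity, message) {
    entries[[length(entries) + 1L]] <<- data.frame(
      product_id = id, field = field, severity = severity,
      message = message, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(catalog))) {
    rec <- catalog[i, ]
    id <- rec$product_id
    if (is.na(id)) {
      add(NA_character_, "product_id", "error", "missing product_id")
      next
    }
    if (is.na(rec$energy_kcal)) {
      add(id, "energy_kcal", "error", "energy_kcal not declared")
    }
    if (!is.na(rec$basis) && !rec$basis %in% c("per_100g", "per_100ml")) {
      add(id, "basis", "error",
          paste0("basis must be per_100g or per_100ml, got '",
                 rec$basis, "'"))
    }
    if (!is.na(rec$nova_group) && !rec$nova_group %in% 1:4) {
      add(id, "nova_group", "error",
          paste0("nova_group must be in 1..4, got ", rec$nova_group))
    }
    for (col in .catalog_numeric) {
      v <- rec[[col]]
      if (!is.na(v) && v < 0) {
        add(id, col, "error", paste0("negative quantity: ", v))
      }
    }
    if (!is.na(rec$sat_fat_g) && !is.na(rec$total_fat_g) &&
        rec$sat_fat_g > rec$total_fat_g) {
      add(id, "sat_fat_g", "warning",
          "saturated fat exceeds total fat")
    }
  }
  if (length(entries) == 0L) {
    return(data.frame(product_id = character(0), field = character(0),
                      severity = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, entries)
}

#' Validate a single record
#'
#' Convenience wrapper around [validate_catalog()] for one row.
#' @param record one-row catalog data frame.
#' @return validation report data frame (possibly zero rows).
#' @export
validate_record <- function(record) {
  stopifnot(nrow(record) == 1L)
  validate_catalog(record)
}

#' Write a results table to CSV with stable formatting
#'
#' Columns keep their input order; numeric columns are rendered with a
#' fixed number of decimals so repeated runs produce byte-identical
#' files.  Missing values render as empty cells.
#'
#' @param rows data frame to write.
#' @param path output path.
#' @param digits decimals for numeric columns (default 4).
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path, digits = 4) {
  out <- rows
  for (col in names(out)) {
    v <- out[[col]]
    if (is.double(v)) {
      s <- formatC(v, format = "f", digits = digits)
      s[is.na(v)] <- ""
      out[[col]] <- s
    } else if (is.logical(v) || is.integer(v)) {
      s <- as.character(v)
      s[is.na(v)] <- ""
      out[[col]] <- s
    } else {
      v <- as.character(v)
      v[is.na(v)] <- ""
      out[[col]] <- v
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}
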