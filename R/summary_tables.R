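#' Frequency table of screening flags by NOVA group and subgroup
#'
#' Tabulates, for each group (and optionally subgroup within group),
#' the number of products, their share of the catalog, and the
#' percentage carrying each flag: critical nutrient in excess, at least
#' one cosmetic additive, flavors or colors, and the combined
#' criterion.  Columns that depend on the nutrient profile model are
#' `NA` (rendered blank, not 0) for NOVA groups 1-2, where the model is
#' not applied.  Groups empty after filtering are omitted.
#'
#' @param x a `upf_classification` or its `results` data frame.
#' @param by grouping keys: `"nova_group"` or
#'   `c("nova_group", "subgroup")`.
#' @return data frame of class `upf_freq_table` with columns
#'   `nova_group`, `subgroup` (`NA` on group-level rows), `n`,
#'   `share_pct`, `pct_nutrient_excess`, `pct_cosmetic`,
#'   `pct_flavor_color`, `pct_combined`.  Percentages are unrounded;
#'   the print method renders one decimal.
#' @export
group_frequencies <- function(x, by = c("nova_group", "subgroup")) {
  df <- if (inherits(x, "upf_classification")) x$results else x
  if (nrow(df) == 0L) stop("no classification results to tabulate")
  allowed <- c("nova_group", "subgroup")
  if (!all(by %in% allowed) || !"nova_group" %in% by) {
    stop("unknown or unsupported grouping key(s): ",
         paste(setdiff(by, allowed), collapse = ", "),
         " (use nova_group, optionally with subgroup)")
  }
  total <- nrow(df)
  row_for <- function(sub_df, group, subgroup) {
    npm_on <- !is.na(group) && group %in% c(3, 4)
    data.frame(
      nova_group = group, subgroup = subgroup, n = nrow(sub_df),
      share_pct = 100 * nrow(sub_df) / total,
      pct_nutrient_excess = if (npm_on)
        100 * mean(sub_df$npm_any_excess) else NA_real_,
      pct_cosmetic = 100 * mean(sub_df$has_cosmetic_additive),
      pct_flavor_color = 100 * mean(sub_df$has_flavor_or_color),
      pct_combined = if (npm_on)
        100 * mean(sub_df$combined_flag) else NA_real_,
      stringsAsFactors = FALSE)
  }
  rows <- list()
  for (g in sort(unique(df$nova_group), na.last = TRUE)) {
    in_g <- if (is.na(g)) is.na(df$nova_group) else
      !is.na(df$nova_group) & df$nova_group == g
    sub_df <- df[in_g, , drop = FALSE]
    if (nrow(sub_df) == 0L) next
    rows[[length(rows) + 1L]] <- row_for(sub_df, g, NA_character_)
    if ("subgroup" %in% by) {
      for (s in sort(unique(sub_df$subgroup))) {
        ss <- sub_df[!is.na(sub_df$subgroup) & sub_df$subgroup == s, ,
                     drop = FALSE]
        if (nrow(ss) == 0L) next
        rows[[length(rows) + 1L]] <- row_for(ss, g, s)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("upf_freq_table", "data.frame")
  out
}

#' @export
print.upf_freq_table <- function(x, ...) {
  disp <- as.data.frame(x)
  for (col in c("share_pct", "pct_nutrient_excess", "pct_cosmetic",
                "pct_flavor_color", "pct_combined")) {
    v <- sprintf("%.1f", disp[[col]])
    v[is.na(disp[[col]])] <- "-"
    disp[[col]] <- v
  }
  disp$subgroup[is.na(disp$subgroup)] <- ""
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' Pool per-group rates into a whole-sample rate
#'
#' Share-weighted mean: `sum(share_i * rate_i) / sum(share_i)`.  Used
#' to recover whole-sample percentages from per-NOVA-group rates and
#' group shares.
#'
#' @param group_shares positive weights (fractions or percentages).
#' @param group_rates rates on any common scale.
#' @return pooled rate on the same scale as `group_rates`.
#' @export
pooled_rate <- function(group_shares, group_rates) {
  if (length(group_shares) != length(group_rates)) {
    stop("group_shares and group_rates must have equal length")
  }
  if (any(is.na(group_shares)) || any(group_shares <= 0)) {
    stop("group_shares must be positive")
  }
  sum(group_shares * group_rates) / sum(group_shares)
}
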