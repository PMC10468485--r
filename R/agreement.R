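#' 2x2 agreement table
#'
#' Cells follow the usual layout against a reference classification:
#' `a` reference-positive & flag-positive, `b` reference-positive &
#' flag-negative, `c` reference-negative & flag-positive, `d`
#' reference-negative & flag-negative.  Real-valued cells are allowed
#' so that tables reconstructed from rounded published marginals do not
#' accumulate extra rounding error.
#'
#' @param a,b,c,d non-negative cell values.
#' @return object of class `table2x2`.
#' @export
table2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells))) stop("cells must not be NA")
  if (any(cells < 0)) {
    stop("negative cell value: ",
         paste(names(cells)[cells < 0], collapse = ", "))
  }
  n <- sum(cells)
  if (n <= 0) stop("table total must be > 0")
  structure(list(a = a, b = b, c = c, d = d, n = n), class = "table2x2")
}

#' @export
print.table2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(reference = c("positive", "negative"),
                              flag = c("positive", "negative")))
  print(round(m, 2))
  cat("n =", format(x$n), "\n")
  invisible(x)
}

#' Cohen's kappa and percent agreement for a 2x2 table
#'
#' Observed agreement `Po = (a + d) / n`; expected chance agreement
#' `Pe = [(a+b)(a+c) + (c+d)(b+d)] / n^2`; `kappa = (Po - Pe) / (1 - Pe)`.
#' When `Pe = 1` (a degenerate one-sided table) kappa is defined as 1
#' if `Po = 1` and 0 with a warning otherwise.
#'
#' @param table a [table2x2()].
#' @return object of class `upf_agreement`: list with `table`,
#'   `observed_agreement`, `expected_agreement`, `kappa`,
#'   `interpretation` (Landis-Koch band).
#' @export
cohens_kappa <- function(table) {
  stopifnot(inherits(table, "table2x2"))
  n <- table$n
  po <- (table$a + table$d) / n
  pe <- ((table$a + table$b) * (table$a + table$c) +
           (table$c + table$d) * (table$b + table$d)) / n^2
  if (pe >= 1 - .Machine$double.eps^0.5) {
    if (po >= 1 - .Machine$double.eps^0.5) {
      kappa <- 1
    } else {
      warning("expected agreement is 1 with imperfect observed ",
              "agreement; kappa set to 0")
      kappa <- 0
    }
  } else {
    kappa <- (po - pe) / (1 - pe)
  }
  structure(list(table = table, observed_agreement = po,
                 expected_agreement = pe, kappa = kappa,
                 interpretation = interpret_kappa(kappa)),
            class = "upf_agreement")
}

#' @export
print.upf_agreement <- function(x, ...) {
  print(x$table)
  cat(sprintf("observed agreement Po = %.4f (%.1f%%)\n",
              x$observed_agreement, 100 * x$observed_agreement))
  cat(sprintf("expected agreement Pe = %.4f\n", x$expected_agreement))
  cat(sprintf("Cohen's kappa = %.4f (%s)\n", x$kappa, x$interpretation))
  invisible(x)
}

#' Landis-Koch interpretation of a kappa value
#'
#' Contiguous half-open bands: below 0 poor; `[0, 0.20]` slight;
#' `(0.20, 0.40]` fair; `(0.40, 0.60]` moderate; `(0.60, 0.80]`
#' substantial; `(0.80, 1]` almost perfect.
#'
#' @param kappa value in `[-1, 1]`.
#' @return band label.
#' @export
interpret_kappa <- function(kappa) {
  if (is.na(kappa) || kappa < -1 || kappa > 1) {
    stop("kappa must be in [-1, 1]")
  }
  if (kappa < 0) return("poor")
  if (kappa <= 0.20) return("slight")
  if (kappa <= 0.40) return("fair")
  if (kappa <= 0.60) return("moderate")
  if (kappa <= 0.80) return("substantial")
  "almost perfect"
}

#' Reconstruct a 2x2 table from prevalence, sensitivity and agreement
#'
#' Builds the real-valued table implied by the total `n`, the
#' reference-positive prevalence, the flag's sensitivity within the
#' reference-positive class, and the overall observed agreement:
#' `a = n*prev*sens`, `b = n*prev*(1-sens)`, `d = n*Po - a`,
#' `c = n*(1-prev) - d`.  Lets published agreement statistics be
#' recomputed when the underlying table is not printed.
#'
#' @param n total count.
#' @param prevalence,sensitivity,observed_agreement fractions in
#'   `[0, 1]`.
#' @return a [table2x2()] (real-valued cells).
#' @export
reconstruct_from_marginals <- function(n, prevalence, sensitivity,
                                       observed_agreement) {
  check_fraction(prevalence, "prevalence")
  check_fraction(sensitivity, "sensitivity")
  check_fraction(observed_agreement, "observed_agreement")
  a <- n * prevalence * sensitivity
  b <- n * prevalence * (1 - sensitivity)
  d <- n * observed_agreement - a
  c <- n * (1 - prevalence) - d
  check_cells(a = a, b = b, c = c, d = d)
  table2x2(a, b, c, d)
}

#' Reconstruct a 2x2 table from prevalence, sensitivity and flag rate
#'
#' Variant of [reconstruct_from_marginals()] for when the published
#' summary gives the overall flagged proportion instead of the percent
#' agreement: `a = n*prev*sens`, `c = n*flag_rate - a`,
#' `d = n*(1-prev) - c`, `b = n*prev - a`.
#'
#' @param n total count.
#' @param prevalence,sensitivity,overall_flag_rate fractions in `[0, 1]`.
#' @return a [table2x2()].
#' @export
reconstruct_from_flag_rate <- function(n, prevalence, sensitivity,
                                       overall_flag_rate) {
  check_fraction(prevalence, "prevalence")
  check_fraction(sensitivity, "sensitivity")
  check_fraction(overall_flag_rate, "overall_flag_rate")
  a <- n * prevalence * sensitivity
  c <- n * overall_flag_rate - a
  d <- n * (1 - prevalence) - c
  b <- n * prevalence - a
  check_cells(a = a, b = b, c = c, d = d)
  table2x2(a, b, c, d)
}

check_fraction <- function(x, what) {
  if (is.na(x) || x < 0 || x > 1) stop(what, " must be in [0, 1]")
  invisible(x)
}

check_cells <- function(...) {
  cells <- c(...)
  tol <- 1e-9 * max(1, sum(abs(cells)))
  bad <- names(cells)[cells < -tol]
  if (length(bad) > 0L) {
    stop("infeasible marginals: implied cell(s) ",
         paste(bad, collapse = ", "), " negative (",
         paste(sprintf("%s = %.4f", bad, cells[bad]), collapse = ", "),
         ")")
  }
  invisible(cells)
}

#' Agreement between the screening flag and a reference classification
#'
#' Cross-tabulates `combined_flag` (or another flag column) against the
#' reference NOVA label and computes Cohen's kappa.  Records without a
#' reference label are dropped.
#'
#' @param x a `upf_classification` or its `results` data frame.
#' @param flag_col column holding the screening flag (default
#'   `"combined_flag"`).
#' @param reference_col column holding the reference label (default
#'   `"nova_group"`).
#' @param positive_class reference value treated as positive (default
#'   `4`, ultra-processed).
#' @return a `upf_agreement`.
#' @export
agreement <- function(x, flag_col = "combined_flag",
                      reference_col = "nova_group", positive_class = 4) {
  df <- if (inherits(x, "upf_classification")) x$results else x
  stopifnot(flag_col %in% names(df), reference_col %in% names(df))
  keep <- !is.na(df[[reference_col]]) & !is.na(df[[flag_col]])
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records with both flag and reference")
  ref <- df[[reference_col]] == positive_class
  flag <- as.logical(df[[flag_col]])
  cohens_kappa(table2x2(a = sum(ref & flag), b = sum(ref & !flag),
                        c = sum(!ref & flag), d = sum(!ref & !flag)))
}
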