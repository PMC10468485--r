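#' Joint distribution of two Bernoulli flags with a given odds ratio
#'
#' Solves for the 2x2 cell probabilities (p11, p10, p01, p00) that
#' reproduce the marginals `pA`, `pB` exactly and have cross-product
#' (odds) ratio `p11*p00 / (p10*p01)` equal to `odds_ratio` (Plackett
#' construction).  Needed because the two screening criteria overlap:
#' their union rate is determined by the marginals plus this
#' association parameter.
#'
#' @param pA,pB marginal probabilities in `[0, 1]`.
#' @param odds_ratio positive association; 1 = independence.
#' @return named numeric vector `c(p11, p10, p01, p00)`.
#' @export
joint_bernoulli <- function(pA, pB, odds_ratio) {
  check_fraction(pA, "pA")
  check_fraction(pB, "pB")
  if (is.na(odds_ratio) || odds_ratio <= 0) {
    stop("odds_ratio must be > 0")
  }
  degenerate <- pA %in% c(0, 1) || pB %in% c(0, 1)
  if (degenerate || odds_ratio == 1) {
    p11 <- pA * pB
  } else {
    s <- 1 + (pA + pB) * (odds_ratio - 1)
    disc <- s^2 - 4 * odds_ratio * (odds_ratio - 1) * pA * pB
    if (disc < 0) stop("no feasible joint distribution for these inputs")
    p11 <- (s - sqrt(disc)) / (2 * (odds_ratio - 1))
  }
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12) {
    stop("no feasible joint distribution: p11 = ", p11,
         " outside [", lo, ", ", hi, "]")
  }
  p11 <- min(max(p11, lo), hi)
  out <- c(p11 = p11, p10 = pA - p11, p01 = pB - p11,
           p00 = 1 - pA - pB + p11)
  if (any(out < -1e-12)) stop("no feasible joint distribution")
  pmax(out, 0)
}

#' Define one stratum of a synthetic catalog
#'
#' A stratum fixes a NOVA group and the flag-level probabilities the
#' generator realizes: the rate of critical-nutrient excess (NOVA 3-4
#' only), the rate of cosmetic additives, their association (odds
#' ratio), the share of cosmetic-additive products whose additive is a
#' flavor or color, sweetener and non-cosmetic-additive rates, and the
#' probability that total sugars are voluntarily declared (default
#' 0.108, the declaration rate observed on Brazilian labels).
#'
#' @param name stratum/subgroup label.
#' @param nova_group 1-4.
#' @param weight sampling probability; weights must sum to 1 over a
#'   configuration.
#' @param p_excess probability of at least one critical nutrient in
#'   excess (ignored for groups 1-2).
#' @param p_cosmetic probability of at least one cosmetic additive.
#' @param odds_ratio association between the excess and cosmetic flags.
#' @param p_flavor_color_given_cosmetic conditional probability that a
#'   cosmetic-additive product carries a flavor or color.
#' @param p_sweetener probability of a sweetener in the ingredient
#'   list.
#' @param p_noncosmetic probability of an additional non-cosmetic
#'   additive (realism only; never changes truth flags).
#' @param p_sugar_declared probability that `total_sugars_g` is
#'   declared.
#' @return list of class `synth_subgroup`.
#' @export
synth_subgroup <- function(name, nova_group, weight,
                           p_excess = 0, p_cosmetic = 0, odds_ratio = 1,
                           p_flavor_color_given_cosmetic = 1,
                           p_sweetener = 0, p_noncosmetic = 0.3,
                           p_sugar_declared = 0.108) {
  stopifnot(nova_group %in% 1:4, weight >= 0)
  for (p in c(p_excess, p_cosmetic, p_flavor_color_given_cosmetic,
              p_sweetener, p_noncosmetic, p_sugar_declared)) {
    check_fraction(p, "probability")
  }
  if (odds_ratio <= 0) stop("odds_ratio must be > 0")
  structure(list(name = name, nova_group = as.integer(nova_group),
                 weight = weight, p_excess = p_excess,
                 p_cosmetic = p_cosmetic, odds_ratio = odds_ratio,
                 p_flavor_color_given_cosmetic =
                   p_flavor_color_given_cosmetic,
                 p_sweetener = p_sweetener,
                 p_noncosmetic = p_noncosmetic,
                 p_sugar_declared = p_sugar_declared),
            class = "synth_subgroup")
}

#' Synthetic catalog configuration
#'
#' @param subgroups list of [synth_subgroup()] strata; weights must sum
#'   to 1 (tolerance 1e-6).
#' @param n_items number of products to generate.
#' @param seed integer seed (mandatory: catalogs are reproducible).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(subgroups, n_items, seed) {
  stopifnot(length(subgroups) > 0L, n_items > 0)
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a seed is mandatory")
  }
  w <- vapply(subgroups, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-6) {
    stop("subgroup weights must sum to 1 (got ", sum(w), ")")
  }
  structure(list(subgroups = subgroups, n_items = as.integer(n_items),
                 seed = as.integer(seed)), class = "synth_config")
}

#' Default configuration emulating a Brazilian supermarket catalog
#'
#' Four strata matching the NOVA-group composition and per-group flag
#' rates of a large Brazilian packaged-food survey: group shares
#' 71.9% ultra-processed / 13.7% processed / 2.4% culinary ingredients
#' / 12.0% minimally processed; nutrient-excess rates 97.1% (UPF) and
#' 90.9% (processed); cosmetic-additive rates 82.1 / 3.7 / 0.4 / 5.1%;
#' flavor-or-color rates 71.4 / 1.4 / 0.4 / 4.9%.  The overlap of the
#' two UPF criteria is set by an odds ratio of 3.40, which yields a
#' combined-criterion rate of 98.8% among UPF; processed foods use
#' independence.  Sweetener presence is folded into the excess
#' marginal (the published excess rates already count sweeteners), so
#' `p_sweetener = 0`.
#'
#' @param n_items catalog size.
#' @param seed integer seed.
#' @return a [synth_config()].
#' @export
synth_config_table1 <- function(n_items = 5000, seed = 42) {
  synth_config(list(
    synth_subgroup("Minimally processed foods", 1, weight = 0.120,
                   p_cosmetic = 0.051,
                   p_flavor_color_given_cosmetic = 0.049 / 0.051),
    synth_subgroup("Processed culinary ingredients", 2, weight = 0.024,
                   p_cosmetic = 0.004,
                   p_flavor_color_given_cosmetic = 1),
    synth_subgroup("Processed foods", 3, weight = 0.137,
                   p_excess = 0.909, p_cosmetic = 0.037, odds_ratio = 1,
                   p_flavor_color_given_cosmetic = 0.014 / 0.037),
    synth_subgroup("Ultra-processed food products", 4, weight = 0.719,
                   p_excess = 0.971, p_cosmetic = 0.821,
                   odds_ratio = 3.40,
                   p_flavor_color_given_cosmetic = 0.714 / 0.821)
  ), n_items = n_items, seed = seed)
}

.filler_tokens <- c("agua", "acucar", "sal", "farinha de trigo",
                    "leite em po", "oleo de soja", "cacau em po",
                    "amido de milho", "ovos", "fuba de milho")

#' Generate a synthetic catalog with known ground truth
#'
#' Works flag-first: for each product the target flags (cosmetic
#' additive, flavor/color, sweetener, nutrient excess) are drawn from
#' the stratum's probabilities, then a label is materialized that
#' realizes exactly those flags — additive names are taken from the
#' lexicon and nutrient quantities are placed clearly above or below
#' the profile-model thresholds.  The emitted truth table is therefore
#' exact, and running [classify_catalog()] on the catalog must
#' reproduce it item by item.
#'
#' @param config a [synth_config()].
#' @param lexicon the `additive_lexicon` whose names are used.
#' @return list of class `synth_catalog`: `catalog` (a `upf_catalog`),
#'   `truth` (data frame with per-item flags `cosmetic`,
#'   `flavor_color`, `sweetener`, `excess`, `any_excess`, `combined`)
#'   and `config`.
#' @export
generate_catalog <- function(config, lexicon = load_lexicon()) {
  stopifnot(inherits(config, "synth_config"))
  pools <- additive_name_pools(lexicon)
  assert_fillers_clean(lexicon)
  set.seed(config$seed)

  n <- config$n_items
  w <- vapply(config$subgroups, `[[`, numeric(1), "weight")
  stratum <- sample(seq_along(config$subgroups), n, replace = TRUE,
                    prob = w)

  cat_rows <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    sg <- config$subgroups[[stratum[i]]]
    applicable <- sg$nova_group %in% c(3, 4)
    if (applicable) {
      cell <- sample(c("11", "10", "01", "00"), 1,
                     prob = joint_bernoulli(sg$p_excess, sg$p_cosmetic,
                                            sg$odds_ratio))
      excess <- cell %in% c("11", "10")
      cosmetic <- cell %in% c("11", "01")
    } else {
      excess <- NA
      cosmetic <- stats::runif(1) < sg$p_cosmetic
    }
    flavor_color <- cosmetic &&
      stats::runif(1) < sg$p_flavor_color_given_cosmetic
    sweetener <- stats::runif(1) < sg$p_sweetener
    sugar_declared <- stats::runif(1) < sg$p_sugar_declared
    noncosmetic <- stats::runif(1) < sg$p_noncosmetic

    id <- sprintf("SYN%05d", i)
    rec <- materialize_item(
      sg, id, pools,
      flags = list(excess = excess, cosmetic = cosmetic,
                   flavor_color = flavor_color, sweetener = sweetener,
                   sugar_declared = sugar_declared,
                   noncosmetic = noncosmetic))
    cat_rows[[i]] <- rec
    any_excess <- if (applicable) isTRUE(excess) || sweetener else NA
    truth_rows[[i]] <- data.frame(
      product_id = id, subgroup = sg$name,
      nova_group = sg$nova_group, cosmetic = cosmetic,
      flavor_color = flavor_color, sweetener = sweetener,
      excess = excess, any_excess = any_excess,
      combined = cosmetic || isTRUE(any_excess),
      stringsAsFactors = FALSE)
  }
  catalog <- as_upf_catalog(do.call(rbind, cat_rows))
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  structure(list(catalog = catalog, truth = truth, config = config),
            class = "synth_catalog")
}

#' @export
print.synth_catalog <- function(x, ...) {
  cat("Synthetic catalog:", nrow(x$catalog), "products, seed",
      x$config$seed, "\n")
  tab <- table(x$truth$nova_group)
  cat("  NOVA groups:", paste(names(tab), tab, sep = ":",
                              collapse = ", "), "\n")
  cat(sprintf("  truth rates: cosmetic %.1f%%, combined %.1f%%\n",
              100 * mean(x$truth$cosmetic),
              100 * mean(x$truth$combined)))
  invisible(x)
}

# Candidate additive names by role, using default functions only;
# entries with category overrides are excluded so that resolution does
# not depend on the stratum label.
additive_name_pools <- function(lexicon) {
  entries <- lexicon$entries
  no_override <- vapply(entries, function(e)
    length(e$category_overrides) == 0L, logical(1))
  fn <- vapply(entries, `[[`, character(1), "default_function")
  cosmetic <- vapply(seq_along(entries), function(i)
    unname(entries[[i]]$is_cosmetic_by_function[[fn[i]]]), logical(1))
  nm <- vapply(entries, `[[`, character(1), "canonical_name")
  fc_classes <- c("flavor", "flavor_enhancer", "color")
  pools <- list(
    flavor_color = nm[no_override & fn %in% fc_classes],
    cosmetic_other = nm[no_override & cosmetic & !fn %in% fc_classes &
                          fn != "sweetener"],
    sweetener = nm[no_override & fn == "sweetener"],
    noncosmetic = nm[no_override & !cosmetic]
  )
  empty <- names(pools)[vapply(pools, length, integer(1)) == 0L]
  if (length(empty) > 0L) {
    stop("lexicon provides no candidates for role(s): ",
         paste(empty, collapse = ", "))
  }
  pools
}

assert_fillers_clean <- function(lexicon) {
  hits <- detect_additives(.filler_tokens, lexicon)
  if (nrow(hits) > 0L) {
    stop("internal error: filler ingredient matches lexicon entry '",
         hits$canonical_name[1], "'")
  }
}

#' Materialize one synthetic product record
#'
#' Builds a catalog row whose label realizes the drawn flags: additive
#' names from the requested pools appear in the ingredient text, and
#' nutrient quantities are placed at 1.5x (excess) or at most 0.5x
#' (non-excess) of each profile-model threshold, so the classifier's
#' reading of the label reproduces the draw exactly.  Consumes the
#' current RNG stream.
#'
#' @param sg a `synth_subgroup`.
#' @param id product id.
#' @param pools name pools from the lexicon (internal helper
#'   `additive_name_pools`).
#' @param flags list with logicals `excess`, `cosmetic`,
#'   `flavor_color`, `sweetener`, `sugar_declared`, `noncosmetic`.
#' @return one-row data frame in catalog column layout.
#' @export
materialize_item <- function(sg, id, pools, flags) {
  energy <- round(stats::runif(1, 150, 450))
  criteria <- c("sodium", "sat_fat", "total_fat",
                if (flags$sugar_declared) "sugars")
  criterion <- if (isTRUE(flags$excess)) sample(criteria, 1) else "none"

  sodium <- round(energy * if (criterion == "sodium") 1.5 else 0.4)
  sat_fat <- round(energy / 9 *
                     if (criterion == "sat_fat") 0.15 else 0.05, 1)
  total_fat <- round(energy / 9 *
                       if (criterion == "total_fat") 0.45 else 0.15, 1)
  total_fat <- max(total_fat, sat_fat)
  total_sugars <- if (flags$sugar_declared) {
    round(energy / 4 * if (criterion == "sugars") 0.15 else 0.05, 1)
  } else NA_real_

  ingredients <- sample(.filler_tokens, 3)
  if (flags$cosmetic) {
    ingredients <- c(ingredients,
                     if (flags$flavor_color)
                       sample(pools$flavor_color, 1)
                     else sample(pools$cosmetic_other, 1))
  }
  if (flags$sweetener) {
    ingredients <- c(ingredients, sample(pools$sweetener, 1))
  }
  if (flags$noncosmetic) {
    ingredients <- c(ingredients, sample(pools$noncosmetic, 1))
  }

  data.frame(
    product_id = id,
    name = paste("synthetic product", id),
    subgroup = sg$name,
    nova_group = sg$nova_group,
    basis = "per_100g",
    energy_kcal = energy,
    total_fat_g = total_fat,
    sat_fat_g = sat_fat,
    trans_fat_g = 0,
    sodium_mg = sodium,
    total_sugars_g = total_sugars,
    added_sugars_g = NA_real_,
    ingredients_text = paste(ingredients, collapse = ", "),
    stringsAsFactors = FALSE)
}
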