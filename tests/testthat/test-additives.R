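test_that("ingredient text normalizes case, diacritics and sub-lists", {
  expect_identical(normalize_ingredient_text("Açúcar, CORANTE caramelo"),
                   c("acucar", "corante caramelo"))
  expect_identical(normalize_ingredient_text(""), character(0))
  expect_identical(normalize_ingredient_text(NA_character_), character(0))
  expect_identical(
    normalize_ingredient_text("farinha (trigo, ferro), sal"),
    c("farinha", "trigo", "ferro", "sal"))
  expect_identical(normalize_ingredient_text("a; b ;; c,"),
                   c("a", "b", "c"))
})

test_that("lexicon loader enforces entry invariants", {
  expect_error(lexicon_from_entries(list(
    lexicon_entry("x", "color", default_function = "flavor"))),
    "default_function")
  expect_error(lexicon_from_entries(list(
    lexicon_entry("x", "color",
                  category_overrides = list(Bread = "flavor")))),
    "override")
  # duplicate synonym across entries names both entries
  expect_error(lexicon_from_entries(list(
    lexicon_entry("lecitina de soja", "emulsifier",
                  synonyms = list("lecitina")),
    lexicon_entry("lecitina de girassol", "emulsifier",
                  synonyms = list("lecitina")))),
    "lecitina.*lecitina de soja.*lecitina de girassol")
  # unknown functional class with no cosmetic status
  expect_error(lexicon_from_entries(list(
    lexicon_entry("x", "mystery_class"))),
    "cosmetic status")
  # a color entry is cosmetic by default
  lex <- lexicon_from_entries(list(lexicon_entry("urucum", "color")))
  expect_true(lex$entries[[1]]$is_cosmetic_by_function[["color"]])
})

test_that("matching is substring-based with longest-match precedence", {
  lex <- tiny_lexicon()
  toks <- normalize_ingredient_text(
    "agua, TARTRAZINA, aroma natural de morango")
  m <- detect_additives(toks, lex)
  expect_setequal(m$canonical_name, c("tartrazina", "aroma natural"))

  expect_equal(nrow(detect_additives(c("water", "salt"), lex)), 0L)

  # INS codes match too
  m2 <- detect_additives(normalize_ingredient_text("conservante INS 211"),
                         lex)
  expect_identical(m2$canonical_name, "benzoato de sodio")

  # longest name wins over a shorter substring of itself
  lex2 <- lexicon_from_entries(list(
    lexicon_entry("hidrogenada", "emulsifier"),
    lexicon_entry("gordura parcialmente hidrogenada", "emulsifier")))
  m3 <- detect_additives(c("gordura parcialmente hidrogenada"), lex2)
  expect_identical(m3$canonical_name, "gordura parcialmente hidrogenada")

  # two additives inside one token are both found
  m4 <- detect_additives(
    normalize_ingredient_text("corantes naturais urucum e curcuma"),
    load_lexicon())
  expect_setequal(m4$canonical_name, c("urucum", "curcuma"))

  # equal-length entries competing for overlapping text resolve to
  # lexicon file order, with a warning
  lex3 <- lexicon_from_entries(list(
    lexicon_entry("goma abcd", "thickener"),
    lexicon_entry("oma abcde", "thickener")))
  expect_warning(m5 <- detect_additives("goma abcde", lex3),
                 "equal-length")
  expect_identical(m5$canonical_name, "goma abcd")
})

test_that("function resolution honors category overrides then default", {
  lex <- tiny_lexicon()
  carr <- lex$entries[[5]]
  expect_identical(resolve_function(carr, "Sweets in general"),
                   "gelling_agent")
  expect_identical(resolve_function(carr, "Bread"), "thickener")
  expect_identical(resolve_function(lex$entries[[1]], "Bread"), "color")
})

test_that("profile flags follow the cosmetic taxonomy and sweetener policy", {
  lex <- tiny_lexicon()
  rec_sweet <- make_record(ingredients_text = "agua, sucralose")
  p <- additive_profile(rec_sweet, lex)
  expect_true(p$has_sweetener)
  expect_false(p$has_cosmetic_additive)  # excluded under default policy
  p2 <- additive_profile(rec_sweet, lex, exclude_sweeteners = FALSE)
  expect_true(p2$has_cosmetic_additive)

  p3 <- additive_profile(
    make_record(ingredients_text = "agua, tartrazina"), lex)
  expect_true(p3$has_cosmetic_additive)
  expect_true(p3$has_flavor_or_color)

  p4 <- additive_profile(
    make_record(ingredients_text = "agua, benzoato de sodio"), lex)
  expect_false(p4$has_cosmetic_additive)
  expect_false(p4$has_flavor_or_color)
  expect_false(p4$has_sweetener)
})

test_that("profile flags are invariant to token order and unmatched text", {
  lex <- load_lexicon()
  base <- "farinha de trigo, acucar, carmim, goma guar, sorbato de potassio"
  rec <- make_record(ingredients_text = base)
  p <- additive_profile(rec, lex)
  set.seed(11)
  for (k in 1:5) {
    toks <- sample(strsplit(base, ", ")[[1]])
    perm <- make_record(ingredients_text = paste(toks, collapse = ", "))
    pp <- additive_profile(perm, lex)
    expect_identical(pp$has_cosmetic_additive, p$has_cosmetic_additive)
    expect_identical(pp$has_flavor_or_color, p$has_flavor_or_color)
    expect_identical(pp$has_sweetener, p$has_sweetener)
  }
  noisy <- make_record(ingredients_text =
                         paste(base, "polpa de fruta, especiarias",
                               sep = ", "))
  pn <- additive_profile(noisy, lex)
  expect_identical(pn$has_cosmetic_additive, p$has_cosmetic_additive)
  expect_identical(pn$has_flavor_or_color, p$has_flavor_or_color)
})

test_that("matcher agrees with a brute-force oracle on random ingredient lists", {
  lex <- load_lexicon()
  all_names <- unlist(lapply(lex$entries, function(e)
    c(e$canonical_name, e$synonyms)))
  fillers <- c("agua", "sal", "farinha de trigo", "polpa de tomate",
               "Óleo de girassol", "especiarias", "AÇÚCAR mascavo")
  set.seed(202)
  for (k in 1:50) {
    n_add <- sample(0:4, 1)
    parts <- c(sample(fillers, sample(1:3, 1)),
               if (n_add > 0) sample(all_names, n_add))
    text <- paste(sample(parts), collapse = ", ")
    got <- brute_force_profile_flags(text, "Bread", lex)
    rec <- make_record(ingredients_text = text, subgroup = "Bread")
    want <- additive_profile(rec, lex)
    expect_identical(want$has_cosmetic_additive, got$has_cosmetic_additive,
                     info = text)
    expect_identical(want$has_flavor_or_color, got$has_flavor_or_color,
                     info = text)
    expect_identical(want$has_sweetener, got$has_sweetener, info = text)
  }
})

test_that("disabling sweetener exclusion only ever adds cosmetic positives", {
  lex <- load_lexicon()
  texts <- c("agua, sucralose", "agua, carmim", "agua, sal",
             "aspartame, carmim", "goma guar, sucralose",
             "benzoato de sodio, aspartame")
  for (tx in texts) {
    rec <- make_record(ingredients_text = tx)
    strict <- additive_profile(rec, lex, exclude_sweeteners = TRUE)
    loose <- additive_profile(rec, lex, exclude_sweeteners = FALSE)
    expect_true(!strict$has_cosmetic_additive ||
                  loose$has_cosmetic_additive, info = tx)
    # flavor/color implies cosmetic under both policies
    expect_true(!strict$has_flavor_or_color ||
                  strict$has_cosmetic_additive, info = tx)
  }
})
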