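test_that("percent_energy computes the energy fraction", {
  expect_equal(percent_energy(20, 4, 500), 0.16)
  expect_equal(percent_energy(0, 9, 250), 0)
  expect_equal(percent_energy(10, 4, 400), 0.10)
  expect_error(percent_energy(10, 4, 0), "energy_kcal")
  expect_error(percent_energy(-1, 4, 100), ">= 0")
})

test_that("values exactly at each threshold are flagged (>= semantics)", {
  cfg <- npm_config()
  # construct a product sitting exactly at all five thresholds
  rec <- make_record(nova_group = 4, energy_kcal = 360,
                     total_fat_g = 0.30 * 360 / 9,   # 12 g
                     sat_fat_g = 0.10 * 360 / 9,     # 4 g
                     trans_fat_g = 0.01 * 360 / 9,   # 0.4 g
                     sodium_mg = 360,                # 1 mg/kcal
                     ingredients_text = "agua")
  res <- evaluate_npm(rec, NULL, free_sugars_g = 0.10 * 360 / 4,
                      config = cfg)
  expect_true(res$excess_free_sugars)
  expect_true(res$excess_total_fat)
  expect_true(res$excess_sat_fat)
  expect_true(res$trans_fat_present)
  expect_true(res$excess_sodium)
  expect_true(res$any_excess)

  # a hair under every threshold -> nothing fires
  eps <- 1e-9
  rec2 <- make_record(nova_group = 4, energy_kcal = 360,
                      total_fat_g = 0.30 * 360 / 9 - eps,
                      sat_fat_g = 0.10 * 360 / 9 - eps,
                      trans_fat_g = 0.01 * 360 / 9 - eps,
                      sodium_mg = 360 - eps,
                      ingredients_text = "agua")
  res2 <- evaluate_npm(rec2, NULL, free_sugars_g = 0.10 * 360 / 4 - eps,
                       config = cfg)
  expect_false(res2$any_excess)
})

test_that("NPM applies only to NOVA groups 3-4 unless overridden", {
  rec <- make_record(nova_group = 1, energy_kcal = 100, sodium_mg = 500)
  res <- evaluate_npm(rec, NULL, NA_real_)
  expect_false(res$applicable)
  expect_false(res$any_excess)
  expect_true(is.na(res$excess_sodium))

  res34 <- evaluate_npm(make_record(nova_group = 3, energy_kcal = 250,
                                    sodium_mg = 300), NULL, NA_real_)
  expect_true(res34$applicable)
  expect_true(res34$excess_sodium)  # 1.2 mg/kcal >= 1.0

  rec_na <- make_record(nova_group = NA, energy_kcal = 250,
                        sodium_mg = 300)
  off <- evaluate_npm(rec_na, NULL, NA_real_,
                      applicable_override = FALSE)
  expect_false(off$applicable)
  on <- evaluate_npm(rec_na, NULL, NA_real_, applicable_override = TRUE)
  expect_true(on$excess_sodium)
})

test_that("missing nutrients never create an excess flag", {
  rec <- make_record(nova_group = 4, energy_kcal = 300,
                     ingredients_text = "agua")
  res <- evaluate_npm(rec, NULL, NA_real_)
  expect_true(res$applicable)
  expect_true(is.na(res$excess_free_sugars))
  expect_true(is.na(res$excess_sodium))
  expect_true(is.na(res$excess_total_fat))
  expect_true(is.na(res$excess_sat_fat))
  expect_false(res$any_excess)
})

test_that("excess flags are monotone in the nutrient at fixed energy", {
  cfg <- npm_config()
  sod <- seq(0, 800, by = 50)
  flags <- vapply(sod, function(s) {
    evaluate_npm(make_record(nova_group = 4, energy_kcal = 400,
                             sodium_mg = s), NULL, NA_real_,
                 cfg)$excess_sodium
  }, logical(1))
  expect_false(is.unsorted(flags))  # FALSE..FALSE TRUE..TRUE

  fat <- seq(0, 30, by = 2)
  fflags <- vapply(fat, function(g) {
    evaluate_npm(make_record(nova_group = 4, energy_kcal = 400,
                             total_fat_g = g), NULL, NA_real_,
                 cfg)$excess_total_fat
  }, logical(1))
  expect_false(is.unsorted(fflags))
})

test_that("energy-fraction flags are invariant to uniform rescaling", {
  cfg <- npm_config()
  base <- list(energy = 400, fat = 15, sat = 5, sugars = 12, sodium = 420)
  ref <- evaluate_npm(make_record(nova_group = 4,
                                  energy_kcal = base$energy,
                                  total_fat_g = base$fat,
                                  sat_fat_g = base$sat,
                                  sodium_mg = base$sodium),
                      NULL, base$sugars, cfg)
  for (s in c(0.25, 2, 10)) {
    scaled <- evaluate_npm(make_record(nova_group = 4,
                                       energy_kcal = base$energy * s,
                                       total_fat_g = base$fat * s,
                                       sat_fat_g = base$sat * s,
                                       sodium_mg = base$sodium * s),
                           NULL, base$sugars * s, cfg)
    for (f in c("excess_free_sugars", "excess_sodium",
                "excess_total_fat", "excess_sat_fat")) {
      expect_identical(scaled[[f]], ref[[f]], info = paste(f, s))
    }
  }
})

test_that("zero-energy products follow the configured sodium rule", {
  rec <- make_record(nova_group = 4, energy_kcal = 0, sodium_mg = 12)
  res <- evaluate_npm(rec, NULL, NA_real_)
  expect_true(res$excess_sodium)
  cfg2 <- npm_config(zero_energy_sodium_rule = "never_excess")
  expect_false(evaluate_npm(rec, NULL, NA_real_, cfg2)$excess_sodium)
})

test_that("trans fat fires on declared quantity or source keywords", {
  cfg <- npm_config()
  expect_true(detect_trans_fat_sources(
    c("sugar", "hydrogenated vegetable oil", "cocoa"), cfg))
  expect_false(detect_trans_fat_sources(c("sunflower oil"), cfg))
  expect_true(detect_trans_fat_sources(
    normalize_ingredient_text("Gordura Vegetal Hidrogenada"), cfg))

  by_keyword <- evaluate_npm(
    make_record(nova_group = 4, energy_kcal = 400, trans_fat_g = 0,
                ingredients_text = "gordura vegetal hidrogenada"),
    NULL, NA_real_, cfg)
  expect_true(by_keyword$trans_fat_present)
  by_panel <- evaluate_npm(
    make_record(nova_group = 4, energy_kcal = 400, trans_fat_g = 1,
                ingredients_text = "agua"),
    NULL, NA_real_, cfg)
  expect_true(by_panel$trans_fat_present)  # 9/400 = 2.25% >= 1%
})

test_that("added sugars resolve declared > total-proxy > imputed > missing", {
  ref <- c("Sweet cookies" = 25)
  expect_equal(
    estimate_added_sugars(make_record(added_sugars_g = 12), ref),
    list(grams = 12, source = "declared"))
  expect_equal(
    estimate_added_sugars(make_record(total_sugars_g = 30), ref),
    list(grams = 30, source = "declared"))
  expect_equal(
    estimate_added_sugars(make_record(total_sugars_g = 30), ref,
                          use_total_as_added = FALSE),
    list(grams = 25, source = "imputed"))
  expect_equal(
    estimate_added_sugars(make_record(subgroup = "Sweet cookies"), ref),
    list(grams = 25, source = "imputed"))
  expect_equal(
    estimate_added_sugars(make_record(subgroup = "Unknown"), ref),
    list(grams = NA_real_, source = "missing"))
})

test_that("free-sugar policies default to identity and compose", {
  expect_equal(free_sugars(12), 12)
  expect_true(is.na(free_sugars(NA_real_)))
  juicy <- function(added, record) added + 3
  expect_equal(free_sugars(5, NULL, juicy), 8)
})

test_that("NPM config loads from YAML and rejects bad values", {
  cfg <- load_npm_config()
  expect_s3_class(cfg, "npm_config")
  expect_equal(cfg$free_sugar_energy_threshold, 0.10)
  expect_equal(cfg$sodium_mg_per_kcal_threshold, 1.0)
  expect_true("gordura vegetal hidrogenada" %in%
                cfg$trans_source_keywords)
  expect_error(npm_config(total_fat_energy_threshold = 0), "> 0")
  expect_error(npm_config(trans_source_keywords = character(0)),
               "non-empty")
})
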