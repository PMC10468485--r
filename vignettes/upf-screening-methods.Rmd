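---
title: "Screening packaged foods for ultra-processed products: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening packaged foods for ultra-processed products: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upfscan)
```

## The screening problem

The NOVA system classifies foods by the extent and purpose of their
industrial processing; group 4, the ultra-processed food products
(UPF), is the group most consistently associated with poor diet
quality.  Assigning NOVA groups normally requires a trained researcher.
`upfscan` implements a label-only screening rule that approximates that
judgement from two pieces of information that are mandatory on most
packaged-food labels:

1. **Cosmetic additives** in the list of ingredients — additives whose
   function is sensory appeal rather than safety: flavors, flavor
   enhancers, colors, emulsifiers, emulsifying salts, sweeteners,
   thickeners, anti-foaming, bulking, carbonating, foaming, gelling
   and glazing agents.
2. **Critical nutrients in excess** under the Pan American Health
   Organization nutrient profile model (PAHO NPM), evaluated from the
   nutrition facts panel.

A product is flagged as presumptive UPF when it has at least one
cosmetic additive **or**, where the nutrient model applies, at least
one critical nutrient in excess.  Agreement between this flag and a
reference classification is quantified with Cohen's kappa and percent
agreement.

## The nutrient profile model

The PAHO NPM criteria are energy-relative, which makes them applicable
to both per-100 g and per-100 mL panels without conversion:

| criterion | rule | default threshold |
|---|---|---|
| free sugars | energy from free sugars / total energy | ≥ 10% (4 kcal/g) |
| total fat | energy from total fat / total energy | ≥ 30% (9 kcal/g) |
| saturated fat | energy from saturated fat / total energy | ≥ 10% |
| trans fat | energy from trans fat / total energy, **or** a trans-fat-source ingredient | ≥ 1% |
| sodium | mg sodium per kcal | ≥ 1 |
| sweeteners | presence in the list of ingredients | any |

All thresholds use `>=` semantics — a value exactly at a threshold is
flagged — and live in `npm_config()`, serialized in
`inst/extdata/npm_paho_default.yaml`, so jurisdictions that adapt the
model can change them without touching code.

The model is applied only to NOVA groups 3–4 when reference labels are
available.  In screening mode (no labels) the default policy applies
it to every record with a nutrition panel; `no_label_policy =
"additive_only"` disables it instead.  This is the one place where the
package must go beyond its source protocol, which always had
researcher labels, so the choice is an explicit, logged policy.

### Numerical and degenerate cases

* **Missing is never zero.**  An undeclared nutrient leaves its flag
  `NA` and can never produce an excess.  Declared zeros are values.
* **Zero-energy products** (e.g. diet sodas) make every energy
  fraction diverge.  Any positive nutrient quantity is then treated as
  excess; for sodium this is configurable
  (`zero_energy_sodium_rule = "never_excess"`) because regulatory
  practice differs.
* **Free sugars.**  Sugar declaration was voluntary on Brazilian
  labels (about 10.8% of products declared total sugars).  The
  resolution order is: declared added sugars; declared total sugars as
  an upper proxy (policy `use_total_as_added`, default on); a
  per-subgroup reference table (`read_sugar_reference()`); otherwise
  missing.  The shipped reference table is labelled *synthetic*: it
  contains illustrative values, not a reproduction of any composition
  table, and real analyses should substitute their own.
* **Trans fat** fires on either the declared quantity or the
  ingredient keywords ("hydrogenated vegetable fat", "partially
  hydrogenated fat", "hydrogenated vegetable oil", "hydrogenated" and
  Portuguese equivalents), since panels frequently declare 0 g while
  the ingredient list names a hydrogenated fat.

## Additive detection

Ingredient text is lowercased, diacritic-folded and split on commas,
semicolons and parentheses; parenthesized sub-lists (compound
ingredients) are flattened because additives declared inside them
count.  Matching against the lexicon is substring-based within each
token, with occurrences selected greedily longest-first and without
overlap: "partially hydrogenated fat" beats the "hydrogenated" it
contains, while a token naming two additives yields both.  Ties
between equal-length names from different entries resolve to lexicon
file order with a warning — determinism is worth more than an
arbitrary preference.

Multifunction additives take the function recorded for the product's
food category (`category_overrides` in the lexicon) and otherwise
their most common function (`default_function`).  The cosmetic status
of each functional class is data, not code: the starter lexicon (52
entries, Portuguese and English names, INS codes) uses the NOVA
cosmetic list, and groups stabilizers with thickeners as cosmetic,
which matches how label surveys in this literature treat them.  The
starter lexicon is illustrative, not a reproduction of the Anvisa
additive database; serious use should extend it.

**Sweetener policy.**  Sweeteners are both cosmetic additives and a
PAHO NPM criterion.  Counting them in both places would overestimate
the cosmetic-additive frequencies, so by default they count only for
the NPM (`exclude_sweeteners = TRUE`).  The policy is a flag because
the alternative reading is defensible for pure-additive analyses.

## Agreement validation

`agreement()` cross-tabulates the screening flag against the reference
label (positive class: NOVA 4) and computes `Po = (a+d)/n`,
`Pe = [(a+b)(a+c) + (c+d)(b+d)]/n²` and
`kappa = (Po − Pe)/(1 − Pe)`, with Landis–Koch bands for
interpretation.  The printed band edges in the source literature leave
lexical gaps (0.20–0.21, etc.); the package uses contiguous half-open
intervals — below 0 poor, [0, 0.20] slight, (0.20, 0.40] fair,
(0.40, 0.60] moderate, (0.60, 0.80] substantial, (0.80, 1] almost
perfect — which reproduces the customary labelling of 0.6015 as
substantial.

Published agreement statistics rarely come with their 2×2 table.
`reconstruct_from_marginals()` (from prevalence, sensitivity and
percent agreement) and `reconstruct_from_flag_rate()` (from prevalence,
sensitivity and the overall flagged rate) rebuild the implied table.
Cells are kept real-valued deliberately: rounding them to integers
would add error on top of the rounding already present in the printed
inputs, and kappa is invariant to the overall scale of the table
anyway.  Infeasible combinations (a negative implied cell) raise an
error naming the cell.

## The synthetic catalog generator

The real dataset behind this methodology (9,851 items photographed in
Brazilian supermarkets) is available only on request, so the package
ships a generator that emulates its statistical structure and makes
every stage testable.

The generator works **flag-first**: for each product it draws the
target flags, then materializes a label that realizes exactly those
flags — additive names are drawn from the lexicon pools for the
drawn roles, and nutrient quantities are placed at 1.5× (excess) or at
most 0.5× (non-excess) of each threshold, far enough from the boundary
that rounding to label precision cannot flip a flag.  The emitted truth
table is therefore exact ground truth, and the test suite asserts that
`classify_catalog()` reproduces it *item by item*: any mismatch is a
bug in either the generator or the pipeline, never noise.

Because the two criteria overlap, drawing them independently would get
the union wrong.  `joint_bernoulli(pA, pB, odds_ratio)` solves the
Plackett quadratic for the joint cell probabilities that reproduce
both marginals exactly at a given odds ratio.  For the default UPF
stratum (excess 97.1%, cosmetic 82.1%) an odds ratio of 3.40 yields a
union of 98.8% — the published combined-criterion rate.

`synth_config_table1()` encodes the survey's structure as defaults:
group shares 71.9 / 13.7 / 2.4 / 12.0% (UPF, processed, culinary
ingredients, minimally processed), nutrient-excess rates 97.1 and
90.9%, cosmetic rates 82.1 / 3.7 / 0.4 / 5.1%, flavor-or-color rates
71.4 / 1.4 / 0.4 / 4.9%, and a 10.8% sugar-declaration rate.  Two
published cells cannot be emulated jointly: the processed-foods
combined rate is printed as 89.1%, *below* that group's own
nutrient-excess marginal of 90.9%, which no joint distribution can
produce (a union cannot be smaller than a marginal; the printed cells
presumably reflect slightly different denominators).  The generator
therefore targets the marginals and uses independence for that group's
overlap, giving a combined rate of ≈91% there.  Sweetener presence is
folded into the excess marginal (its published definition already
counts sweeteners), so `p_sweetener` defaults to 0.

### What the generator does not emulate

Synthetic labels use a small filler vocabulary and one clearly-placed
excess nutrient per flagged product.  Real labels have messier text
(typos, unregistered synonyms, undeclared additives inside compound
ingredients), nutrient values near thresholds, and correlated
nutrients.  Green tests therefore certify the *logic* — parsing,
thresholding, combination, agreement — not recall of the lexicon
against real-world ingredient spelling, which is bounded by lexicon
coverage.

## Problem sizes and test design

Module tests run the generator at 150–800 items, where all rates are
recovered within 3 binomial standard errors; the end-to-end acceptance
simulation uses 5,000 UPF items, matching the scale at which the
published combined rate of 98.8% has a standard error of about 0.15
percentage points.  The parser is additionally checked against an
independently written brute-force matcher on randomized ingredient
lists, and kappa against closed-form hand calculations.

## Known limitations

* The starter lexicon covers every cosmetic class but is a fraction of
  the additive vocabulary found on real labels.
* Added-sugar imputation is a pluggable table, not a model; the
  shipped table is synthetic.
* NOVA groups are input, not output: the package screens for UPF, it
  does not perform NOVA classification.
* Kappa is reported without a confidence interval; the source
  methodology reported none, and the reconstruction operations work
  from rounded printed inputs whose propagated uncertainty (~±0.005 on
  kappa) dominates sampling error at n ≈ 10⁴.
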