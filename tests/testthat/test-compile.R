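test_that("nested submedium volumes multiply through with the density rule", {
  rs <- parse_recipe_set(c(
    "medium: a", "ref: b @ 20 ml",
    "medium: b", "ref: c @ 50 ml",
    "medium: c", "X @ 4 ml", "Y @ 2 g"))
  flat <- unpack_references(rs[["a"]], rs)
  # X: 0.02 * 0.05 * 4 g = 0.004 g ; Y: 0.02 * 0.05 * 2 g = 0.002 g
  expect_equal(flat$amount[flat$raw_name == "X"], 0.004)
  expect_equal(flat$amount[flat$raw_name == "Y"], 0.002)
  expect_true(all(flat$unit == "g_per_l"))
})

test_that("duplicate compounds across nesting levels are summed", {
  rs <- parse_recipe_set(c(
    "medium: top", "NaCl @ 1 g", "ref: sub @ 500 ml",
    "medium: sub", "NaCl @ 4 g"))
  flat <- unpack_references(rs[["top"]], rs)
  expect_equal(nrow(flat), 1)
  expect_equal(flat$amount, 1 + 0.5 * 4)
})

test_that("a submedium's own scale multiplier applies before dilution", {
  rs <- parse_recipe_set(c(
    "medium: top", "ref: conc10x @ 100 ml",
    "medium: conc10x", "volume: 0.1 l", "NaCl @ 5.844 g"))
  flat <- unpack_references(rs[["top"]], rs)
  # the 100-ml stock is a 10x concentrate: 5.844 g in 0.1 l = 58.44 g/l
  expect_equal(flat$amount, 0.1 * 58.44)
})

test_that("unpacking is flagged for cycles and missing references", {
  rs <- parse_recipe_set(c(
    "medium: a", "ref: b @ 10 ml",
    "medium: b", "ref: a @ 10 ml"))
  expect_error(unpack_references(rs[["a"]], rs), "a -> b -> a")
  rs2 <- parse_recipe_set(c("medium: solo", "ref: ghost @ 10 ml"))
  expect_error(unpack_references(rs2[["solo"]], rs2), "ghost")
})

test_that("a recipe without references is its own flat list", {
  rs <- parse_recipe_set(c("medium: m", "NaCl @ 2 g", "glucose @ 1 g"))
  flat <- unpack_references(rs[["m"]], rs)
  expect_setequal(flat$raw_name, c("NaCl", "glucose"))
  expect_equal(sort(flat$amount), c(1, 2))
})

test_that("gram amounts convert to constituent moles including hydrate waters", {
  comps <- tiny_compounds()
  out <- to_standard_units(
    tibble::tibble(raw_name = "CaCl2 x 2 H2O", amount = 10, unit = "mg"),
    comps)
  ca <- out[out$compound_id == "Ca2+", ]
  cl <- out[out$compound_id == "Cl-", ]
  # 0.010 g / 147.01 g/mol (dihydrate) = 6.802e-5 mol; chloride doubled
  expect_equal(ca$amount, 6.802e-5, tolerance = 1e-3)
  expect_equal(cl$amount, 1.3604e-4, tolerance = 1e-3)
  expect_true(all(out$unit == "mol_per_l"))
})

test_that("trace and gas-substrate entries pass through without concentration", {
  comps <- tiny_compounds()
  out <- to_standard_units(tibble::tibble(
    raw_name = c("vitamin mix", "H2"), amount = c(1, 1),
    unit = c("trace", "gas")), comps)
  expect_setequal(out$unit, c("trace", "gas_substrate"))
  expect_true(all(is.na(out$amount)))
})

test_that("molar entries pass through and same constituents merge", {
  comps <- tiny_compounds()
  out <- to_standard_units(tibble::tibble(
    raw_name = c("glucose", "NaCl", "CaCl2 x 2 H2O"),
    amount = c(0.25, 58.44, 0.147010),
    unit = c("mol", "g", "g")), comps)
  expect_equal(out$amount[out$compound_id == "glucose"], 0.25)
  # chloride from both salts: 1.0 (NaCl) + 2 * 0.001 (dihydrate)
  expect_equal(out$amount[out$compound_id == "Cl-"], 1.002, tolerance = 1e-6)
})

test_that("conversion failures are loud", {
  comps <- tiny_compounds()
  expect_error(to_standard_units(
    tibble::tibble(raw_name = "NaCl", amount = 1, unit = "flagon"), comps),
    "flagon")
  expect_error(to_standard_units(
    tibble::tibble(raw_name = "vitamin mix", amount = 1, unit = "g"), comps),
    "molecular weight")
  expect_error(to_standard_units(
    tibble::tibble(raw_name = "unobtainium", amount = 1, unit = "g"), comps),
    "unobtainium")
})

test_that("compile_medium produces molar compositions end to end", {
  comps <- tiny_compounds()
  rs <- parse_recipe_set(c(
    "medium: brine", "NaCl @ 58.44 g",
    "medium: dilute", "ref: brine10 @ 100 ml",
    "medium: brine10", "NaCl @ 58.44 g",
    "medium: rich1", "peptone @ 5 g"))

  brine <- compile_medium("brine", rs, comps)
  expect_equal(brine$components$amount[brine$components$compound_id == "Na+"], 1)
  expect_equal(brine$components$amount[brine$components$compound_id == "Cl-"], 1)
  expect_true(brine$is_defined)

  dilute <- compile_medium("dilute", rs, comps)
  expect_equal(dilute$components$amount[dilute$components$compound_id == "Na+"],
               0.1)

  rich <- compile_medium("rich1", rs, comps)
  expect_equal(rich$components$g_per_l[rich$components$class == "complex"], 5)
  expect_false(rich$is_defined)
})

test_that("the scale multiplier rescales compiled concentrations", {
  comps <- tiny_compounds()
  rs <- parse_recipe_set(c("medium: half", "volume: 0.5 l", "NaCl @ 29.22 g"))
  m <- compile_medium("half", rs, comps)
  expect_equal(m$multiplier, 2)
  expect_equal(m$components$amount[m$components$compound_id == "Na+"], 1)
})

test_that("mass is conserved through gram-to-mole conversion", {
  comps <- tiny_compounds()
  withr::local_seed(7)
  for (i in 1:20) {
    grams <- runif(1, 1e-4, 100)
    nm <- sample(c("NaCl", "CaCl2 x 2 H2O", "glucose"), 1)
    out <- to_standard_units(
      tibble::tibble(raw_name = nm, amount = grams, unit = "g"), comps)
    rec <- tiny_compounds()[tiny_compounds()$raw_name == nm, ]
    moles_compound <- out$amount[1] / as.numeric(strsplit(
      rec$constituent_ratios, "|", fixed = TRUE)[[1]][1])
    expect_equal(moles_compound * rec$molecular_weight, grams,
                 tolerance = 1e-9)
  }
})

test_that("compilation is order-independent in the ingredient lines", {
  comps <- tiny_compounds()
  lines <- c("NaCl @ 5 g", "glucose @ 2 g", "peptone @ 3 g", "NaCl @ 1 g")
  a <- compile_medium(parse_recipe(c("medium: m", lines)), list(), comps)
  b <- compile_medium(parse_recipe(c("medium: m", rev(lines))), list(), comps)
  expect_equal(a$components, b$components)
})

test_that("a media library collects metadata, long and wide forms", {
  comps <- tiny_compounds()
  rs <- parse_recipe_set(c(
    "medium: m1", "/ph/ 6.8", "NaCl @ 5.844 g",
    "medium: m2", "peptone @ 10 g", "vitamin mix @ 1 trace"))
  lib <- compile_media(rs, comps)
  expect_equal(nrow(lib$media), 2)
  expect_equal(lib$media$ph, c(6.8, NA))
  expect_equal(lib$media$is_defined, c(TRUE, FALSE))
  wide <- media_component_matrix(lib)
  expect_equal(wide$`Na+`[wide$medium_id == "m1"], 0.1)
  expect_true(wide$`trace-vitamins_flag`[wide$medium_id == "m2"])

  dir <- withr::local_tempdir()
  write_media_library(lib, dir)
  expect_true(all(file.exists(file.path(dir, c("media.tsv", "components.tsv",
                                               "matrix.tsv")))))
})
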