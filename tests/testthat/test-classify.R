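rules <- default_ruleset()

test_that("DT50 classification matches the stated class bounds", {
  cases <- list(
    list(1, "L"),     # sulphonamides, solid cattle manure
    list(564, "H"),   # (fluoro)quinolones, solid cattle manure
    list(29.99, "L"),
    list(30, "M"),    # bounds inclusive in MEDIUM
    list(100, "M"),
    list(100.01, "H")
  )
  for (cs in cases) {
    expect_identical(classify_dt50(cs[[1]]), lv(cs[[2]]),
                     info = paste("dt50 =", cs[[1]]))
  }
  expect_error(classify_dt50(0), "positive")
  expect_error(classify_dt50(-3), "positive")
})

test_that("compartment persistence collapses to the maximum level", {
  expect_identical(combine_compartment_persistence(lv(c("M", "L"))),
                   lv("M"))  # tetracyclines: manure M, soil L
  expect_identical(combine_compartment_persistence(lv(c("H", "H"))),
                   lv("H"))
  expect_identical(combine_compartment_persistence(lv(c("L", "L", "M"))),
                   lv("M"))
  expect_identical(combine_compartment_persistence(list(lv("L"), lv("H"))),
                   lv("H"))
  expect_error(combine_compartment_persistence(hazard_level(character())),
               "at least one")
})

test_that("antibiotic DT50 tables collapse to the published group levels", {
  tab_manure <- list(
    "(fluoro)quinolones" = c(564, 226, 82, 75, 121),
    macrolides           = c(2, 94, 79, 50, 61),
    sulphonamides        = c(1, 3, 12, 2, 3),
    tetracyclines        = c(76, 57, 32, 14, 33)
  )
  tab_soil <- list(
    "(fluoro)quinolones" = c(182, 97),
    macrolides           = c(56, 73),
    sulphonamides        = c(1, 1),
    tetracyclines        = c(9, 1)
  )
  expected <- c("(fluoro)quinolones" = "H", macrolides = "M",
                sulphonamides = "L", tetracyclines = "M")
  for (group in names(expected)) {
    levels <- vapply(c(tab_manure[[group]], tab_soil[[group]]),
                     function(d) as.character(classify_dt50(d)), "")
    expect_identical(combine_compartment_persistence(hazard_level(levels)),
                     lv(expected[[group]]), info = group)
  }
})

test_that("microbial persistence scores the achieved log reduction", {
  expect_identical(classify_microbial_persistence(12.6, 60), lv("L")) # 4.76
  # strict rule: 60 / 15.9 = 3.77 logs is below the 4-log LOW bound
  expect_identical(classify_microbial_persistence(15.9, 60), lv("M"))
  expect_identical(classify_microbial_persistence(10, 0), lv("H"))
  expect_identical(classify_microbial_persistence(15, 60), lv("L"))  # 4.0
  expect_identical(classify_microbial_persistence(30, 60), lv("M"))  # 2.0
  expect_error(classify_microbial_persistence(0, 60), "positive")
})

test_that("log K_OC transfer classification matches the worked values", {
  cases <- list(list(0.5, "H"),    # sulphonamides
                list(2.9, "L"),    # (fluoro)quinolones
                list(3.0, "L"),    # tetracyclines
                list(1.5, "M"),
                list(1.0, "M"),    # boundary: no longer water-soluble
                list(2.0, "L"))    # boundary: immobile from 2.0 up
  for (cs in cases) {
    expect_identical(classify_transfer_log_koc(cs[[1]]), lv(cs[[2]]),
                     info = paste("log_koc =", cs[[1]]))
  }
})

test_that("BAF accumulation classification matches the worked values", {
  cases <- list(list(20, "H"),   # cadmium
                list(2.3, "M"),  # lead
                list(2, "M"),    # dioxins
                list(0, "L"),
                list(1, "L"),    # boundary: BAF 1 = no net accumulation
                list(5, "M"))    # boundary
  for (cs in cases) {
    expect_identical(classify_accumulation_baf(cs[[1]]), lv(cs[[2]]),
                     info = paste("baf =", cs[[1]]))
  }
  expect_error(classify_accumulation_baf(-0.1), "non-negative")
})

test_that("concentration occurrence reproduces the published group levels", {
  tab1_chem <- list(
    "(fluoro)quinolones" = c(7900, 92696, 12099),
    macrolides           = c(40, 3836, 6927),
    sulphonamides        = c(1277, 10591, 6277),
    tetracyclines        = c(40805, 30166, 89639)
  )
  expected <- c("(fluoro)quinolones" = "H", macrolides = "L",
                sulphonamides = "L", tetracyclines = "H")
  for (group in names(expected)) {
    expect_identical(
      classify_occurrence_concentration(tab1_chem[[group]], "chemical"),
      lv(expected[[group]]), info = group)
  }
  expect_identical(
    classify_occurrence_concentration(c(1.3e8, 2.2e7, 4.7e4), "microbial"),
    lv("H"))  # E. coli
  expect_identical(
    classify_occurrence_concentration(c(3.1e5, 1.4e4, 3.7e3), "microbial"),
    lv("L"))  # Salmonella

  # worst-case collapse is available but is not the default: under it
  # the sulphonamide group (max 10591 ng/g dm) moves up a class
  max_rules <- classification_ruleset(occurrence_collapse = "max")
  expect_identical(
    classify_occurrence_concentration(tab1_chem$sulphonamides, "chemical",
                                      max_rules),
    lv("M"))
  expect_error(classify_occurrence_concentration(numeric(), "chemical"),
               "at least one")
  mixed <- list(list(kind = "occurrence_concentration", value = 1,
                     units = "ng/g dm", matrix = "a"),
                list(kind = "occurrence_concentration", value = 1,
                     units = "cfu/g dm", matrix = "b"))
  expect_error(classify_occurrence_concentration(mixed, "chemical"),
               "mixed occurrence units")
})

test_that("exceedance occurrence is binary around the 3% threshold", {
  expect_identical(classify_occurrence_exceedance(0.062), lv("H"))  # DON
  expect_identical(classify_occurrence_exceedance(0), lv("L"))      # T-2
  expect_identical(classify_occurrence_exceedance(0.03), lv("L"))   # strict >
  expect_identical(classify_occurrence_exceedance(0.0301), lv("H"))
  expect_error(classify_occurrence_exceedance(1.2), "\\[0, 1\\]")
  expect_error(classify_occurrence_exceedance(-0.1), "\\[0, 1\\]")
})

test_that("weekly guidance values normalise to the daily scale", {
  expect_equal(normalize_hbgv_to_daily(2.5, "per_week"), 2.5 / 7)
  expect_equal(normalize_hbgv_to_daily(10, "per_day"), 10)
  expect_equal(normalize_hbgv_to_daily(0, "per_week"), 0)
  expect_error(normalize_hbgv_to_daily(1, "per_month"))
  expect_error(normalize_hbgv_to_daily(-1, "per_day"), "non-negative")
})

test_that("chemical severity follows the guidance-value cutoff", {
  expect_identical(classify_severity_chemical(0.4), lv("H"))  # aflatoxin B1
  expect_identical(classify_severity_chemical(15), lv("L"))   # pesticides
  expect_identical(classify_severity_chemical(1), lv("H"))    # DON group TDI
  expect_identical(classify_severity_chemical(10), lv("H"))   # cutoff incl.
  expect_identical(classify_severity_chemical(2.5, "per_week"), lv("H"))
  expect_identical(
    classify_severity_chemical(endpoint_flags = "carcinogenic"), lv("H"))
  expect_identical(
    classify_severity_chemical(1000, endpoint_flags = "mutagenic"),
    lv("H"))  # an endpoint classification dominates a mild HBGV
  expect_error(classify_severity_chemical(), "HBGV")
  expect_error(classify_severity_chemical(endpoint_flags = "spicy"),
               "unknown endpoint")
})

test_that("antibiotic severity combines chronic toxicity and resistance", {
  expect_identical(classify_severity_antibiotic(lv("H"), lv("H")), lv("H"))
  expect_identical(classify_severity_antibiotic(lv("L"), lv("H")), lv("M"))
  expect_identical(classify_severity_antibiotic(lv("H"), lv("L")), lv("M"))
  expect_identical(classify_severity_antibiotic(lv("L"), lv("L")), lv("L"))
  expect_error(classify_severity_antibiotic(lv("M"), lv("L")), "binary")
})

test_that("microbial severity reproduces the full published DALY table", {
  got <- vapply(daly_table$daly,
                function(d) as.character(classify_severity_microbial(d)),
                "")
  expect_identical(got, daly_table$class)
  # boundaries are inclusive in MEDIUM
  expect_identical(classify_severity_microbial(0.01), lv("M"))
  expect_identical(classify_severity_microbial(0.1), lv("M"))
  expect_error(classify_severity_microbial(-1), "non-negative")
})

test_that("classifiers are monotone in their scalar input", {
  grids <- list(
    list(f = classify_dt50, x = c(0.5, 5, 29, 30, 65, 100, 101, 1000),
         sign = +1),
    list(f = classify_accumulation_baf,
         x = c(0, 0.5, 1, 1.01, 3, 5, 5.01, 50), sign = +1),
    list(f = classify_occurrence_exceedance,
         x = c(0, 0.01, 0.03, 0.031, 0.5, 1), sign = +1),
    list(f = classify_transfer_log_koc,
         x = c(-1, 0, 0.99, 1, 1.5, 1.99, 2, 5), sign = -1),
    list(f = classify_severity_microbial,
         x = c(0, 0.005, 0.01, 0.05, 0.1, 0.11, 3), sign = +1),
    list(f = function(x) classify_severity_chemical(x),
         x = c(0.01, 1, 10, 10.1, 100), sign = -1)
  )
  for (g in grids) {
    out <- hazard_level(vapply(g$x, function(v) as.character(g$f(v)), ""))
    steps <- diff(as.integer(out)) * g$sign
    expect_true(all(steps >= 0),
                info = paste("monotonicity for grid",
                             paste(g$x, collapse = ",")))
  }
  # microbial persistence: risk decreases with waiting time, increases
  # with days-per-log
  waits <- c(0, 10, 30, 60, 120)
  out <- hazard_level(vapply(
    waits, function(w) as.character(classify_microbial_persistence(12.6, w)),
    ""))
  expect_true(all(diff(as.integer(out)) <= 0))
})
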