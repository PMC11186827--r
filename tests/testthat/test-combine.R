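# frozen cell-for-cell expectations for the published matrices
env_rules_expected <- c(
  "L,L,L" = "L", "L,L,M" = "L", "L,L,H" = "L",
  "L,M,L" = "L", "L,M,M" = "M", "L,M,H" = "M",
  "L,H,L" = "M", "L,H,M" = "M", "L,H,H" = "M",
  "M,L,L" = "M", "M,L,M" = "M", "M,L,H" = "M",
  "M,M,L" = "M", "M,M,M" = "M", "M,M,H" = "M",
  "M,H,L" = "H", "M,H,M" = "H", "M,H,H" = "H",
  "H,L,L" = "M", "H,L,M" = "M", "H,L,H" = "M",
  "H,M,L" = "M", "H,M,M" = "H", "H,M,H" = "H",
  "H,H,L" = "H", "H,H,M" = "H", "H,H,H" = "H")
acc_rules_expected <- c(
  "L,L" = "L", "L,M" = "M", "L,H" = "M",
  "M,L" = "M", "M,M" = "M", "M,H" = "H",
  "H,L" = "M", "H,M" = "M", "H,H" = "H")
prio_rules_expected <- c(
  "L,L" = "L", "L,M" = "L", "L,H" = "M",
  "M,L" = "L", "M,M" = "M", "M,H" = "H",
  "H,L" = "M", "H,M" = "H", "H,H" = "H")

test_that("the default matrices match the published rules cell-for-cell", {
  m <- default_matrices()
  expect_identical(m$presence_environment$entries[names(env_rules_expected)],
                   env_rules_expected)
  expect_identical(m$presence_accumulation$entries[names(acc_rules_expected)],
                   acc_rules_expected)
  expect_identical(m$priority$entries[names(prio_rules_expected)],
                   prio_rules_expected)
})

test_that("all matrices are total and monotone (independent exhaustive check)", {
  m <- default_matrices()
  lvs <- c("L", "M", "H")
  for (name in names(m)) {
    mat <- m[[name]]
    grid <- expand.grid(rep(list(lvs), mat$arity),
                        stringsAsFactors = FALSE)
    keys <- apply(grid, 1L, paste, collapse = ",")
    expect_setequal(names(mat$entries), keys)
    expect_length(mat$entries, 3^mat$arity)
    # monotonicity, re-derived here without the constructor's check:
    # compare every pair of tuples ordered argument-wise
    rank <- function(x) match(x, lvs)
    out <- rank(mat$entries[keys])
    g <- as.matrix(as.data.frame(lapply(grid, rank)))
    for (i in seq_along(keys)) {
      dominates <- rowSums(g >= matrix(g[i, ], nrow(g), ncol(g),
                                       byrow = TRUE)) == ncol(g)
      expect_true(all(out[dominates] >= out[i]),
                  info = paste(name, keys[i]))
    }
  }
})

test_that("presence and priority lookups reproduce the case examples", {
  expect_identical(presence_environment("H", "H", "L"), lv("H"))  # FQ
  expect_identical(presence_environment("L", "L", "H"), lv("L"))  # sulpha
  expect_identical(presence_environment("H", "L", "M"), lv("M"))  # E. coli
  expect_identical(presence_accumulation("M", "H"), lv("H"))      # cadmium
  expect_identical(presence_accumulation("L", "L"), lv("L"))
  expect_identical(presence_accumulation("H", "M"), lv("M"))      # lead
  expect_identical(prioritize("H", "H"), lv("H"))
  expect_identical(prioritize("M", "M"), lv("M"))
  expect_identical(prioritize("L", "M"), lv("L"))
})

test_that("accumulation and environment routes agree on the spot check", {
  # occurrence H with an ineffective pathway gives presence M either way
  for (transfer in c("L", "M", "H")) {
    expect_identical(presence_environment("H", "L", transfer), lv("M"))
  }
  expect_identical(presence_accumulation("H", "L"), lv("M"))
  expect_identical(presence_accumulation("H", "M"), lv("M"))
})

test_that("matrix construction rejects malformed rule sets", {
  expect_error(combination_matrix(c("L,* -> L", "M,* -> M"), arity = 2),
               "not total")
  expect_error(combination_matrix(c("L,* -> L", "*,* -> M", "H,* -> H"),
                                  arity = 2),
               "more than once")
  expect_error(combination_matrix("L,L -> L", arity = 3), "inputs")
  expect_error(combination_matrix(c("L,* -> X", "M,* -> M", "H,* -> H"),
                                  arity = 2),
               "invalid hazard level")
  # a decreasing output must be refused
  expect_error(combination_matrix(c("L,* -> H", "M,* -> M", "H,* -> L"),
                                  arity = 2),
               "not monotone")
})

test_that("the shipped matrix config equals the built-in defaults", {
  loaded <- load_combination_matrices(fixture("table9_matrices.cfg"))
  m <- default_matrices()
  for (name in names(m)) {
    expect_identical(loaded[[name]]$entries[names(m[[name]]$entries)],
                     m[[name]]$entries, info = name)
  }
  # and they survive a save/load round trip
  path <- tempfile(fileext = ".cfg")
  save_combination_matrices(m, path)
  again <- load_combination_matrices(path)
  expect_identical(again$priority$entries[names(m$priority$entries)],
                   m$priority$entries)
})

test_that("prioritize_hazard runs the full pipeline with provenance", {
  reg <- load_hazard_registry(fixture("case1_registry.csv"))
  rec <- prioritize_hazard(reg[["(fluoro)quinolones"]])
  expect_identical(rec$priority, lv("H"))
  expect_identical(rec$presence, lv("H"))
  expect_match(rec$provenance[["transfer"]], "log K_OC")
  expect_match(rec$provenance[["severity"]], "choice class 3")

  # a degenerate all-low profile bottoms out at LOW priority
  low <- make_env_profile(occ = 1, dt50 = 1, log_koc = 5, hbgv = 100)
  expect_identical(prioritize_hazard(low)$priority, lv("L"))

  # classifier failures carry the hazard id
  broken <- make_env_profile()
  broken$severity$hbgv_value <- NULL
  expect_error(prioritize_hazard(broken), "toy")
})

test_that("substrate scenarios select occurrence evidence by matrix", {
  reg <- load_hazard_registry(fixture("case2_registry.csv"))
  cadmium <- reg[["cadmium"]]
  hw <- prioritize_hazard(cadmium, occurrence_matrix = "household waste")
  manure <- prioritize_hazard(cadmium, occurrence_matrix = "manure")
  expect_identical(hw$levels$occurrence, lv("M"))
  expect_identical(manure$levels$occurrence, lv("L"))
  expect_identical(hw$priority, lv("H"))
  expect_error(prioritize_hazard(cadmium, occurrence_matrix = "compost"),
               "no occurrence evidence")
  # without a scenario filter the assigned levels collapse to the worst
  expect_identical(prioritize_hazard(cadmium)$levels$occurrence, lv("M"))
})

test_that("one-level sensitivity re-derives priorities from the matrices", {
  reg <- load_hazard_registry(fixture("case1_registry.csv"))
  # E. coli sits at presence M / severity M; pushing occurrence up one
  # level keeps presence at M (H,L,M -> M), pushing severity up flips
  # the priority to HIGH
  sens <- sensitivity_one_level(reg[["E. coli"]])
  up_sev <- sens[sens$indicator == "severity" & sens$direction == 1L, ]
  expect_identical(up_sev$priority, "H")
  expect_true(up_sev$changed)

  # every row must agree with a direct matrix lookup
  base <- prioritize_hazard(reg[["E. coli"]])
  for (i in seq_len(nrow(sens))) {
    levels <- base$levels
    levels[[sens$indicator[i]]] <- lv(sens$perturbed_level[i])
    presence <- presence_environment(levels$occurrence, levels$persistence,
                                     levels$transfer_accumulation)
    expect_identical(as.character(presence), sens$presence[i])
    expect_identical(as.character(prioritize(presence, levels$severity)),
                     sens$priority[i])
  }

  # an all-low profile: single upward shifts never raise the priority
  # (presence stays L or M with severity L; (L,*)/(M,L) -> L), except
  # that severity H lifts it to M via (L,H)
  low <- make_env_profile(occ = 1, dt50 = 1, log_koc = 5, hbgv = 100)
  sens_low <- sensitivity_one_level(low)
  ups <- sens_low[sens_low$direction == 1L, ]
  expect_true(all(ups$priority == "L"))

  # a profile pinned at (H, H): any single downward shift keeps at
  # least MEDIUM ((M,H) -> H, (H,M) -> H)
  hi <- make_env_profile(occ = 1e6, dt50 = 1000, log_koc = 0, hbgv = 0.1)
  sens_hi <- sensitivity_one_level(hi)
  downs <- sens_hi[sens_hi$direction == -1L, ]
  expect_true(all(lv(downs$priority) >= lv("M")))
})
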