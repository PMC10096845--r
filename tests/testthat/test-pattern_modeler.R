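patterns <- load_fixture("pattern_baselines")
comps <- load_fixture("table2_composites")

test_that("remove_serving matches published modified cells", {
  m <- remove_serving(patterns$USP, comps$usda_meat)
  expect_equal(m[["energy"]], 2001 - 131)
  expect_equal(m[["protein"]], 92 - 20.8)
  expect_true(is.na(m[["folate"]]))  # printed NA propagates
  m2 <- remove_serving(patterns$USP, comps$min_meat)
  expect_equal(round_display(m2[["protein"]], 1), "67.2")
  # null removal: a zero-nutrient composite with token energy
  null_comp <- composite_profile("null", make_nv(energy = 1e-9))
  expect_equal(as.numeric(remove_serving(patterns$USP, null_comp))[-1],
               as.numeric(patterns$USP$baseline)[-1])
  # infeasible: serving energy above baseline
  expect_error(remove_serving(patterns$USP, comps$usda_meat,
                              serving_spec(servings = 16)),
               "infeasible")
})

test_that("serving scaling is linear in grams and servings", {
  two <- remove_serving(patterns$USP, comps$usda_meat,
                        serving_spec(servings = 2))
  expect_equal(two[["protein"]], 92 - 2 * 20.8)
  half <- remove_serving(patterns$USP, comps$usda_meat,
                         serving_spec(grams = 42.5))
  expect_equal(half[["energy"]], 2001 - 131 / 2)
})

test_that("negative modeled amounts warn but are reported", {
  lowpat <- pattern_profile("tiny", make_nv(energy = 200, vitamin_c = 0.01,
                                            basis = "per_pattern_day"))
  bigc <- composite_profile("c", make_nv(energy = 100, vitamin_c = 5))
  expect_warning(m <- remove_serving(lowpat, bigc), "negative")
  expect_equal(m[["vitamin_c"]], 0.01 - 5)
})

test_that("isocaloric formula reproduces published cells", {
  iso <- isocaloric_adjust(patterns$USP, comps$usda_meat)
  expect_equal(iso[["energy"]], 2001)
  expect_equal(iso[["zinc"]], (13 - 3.45) / (2001 - 131) * 2001)
  expect_equal(round_display(iso[["zinc"]], 1), "10.2")
  iso2 <- isocaloric_adjust(patterns$USP, comps$min_meat)
  expect_equal(round_display(iso2[["protein"]], 1), "72.7")
  expect_true(is.na(iso[["folate"]]))
})

test_that("isocaloric identity and closed form hold exactly", {
  for (pn in names(patterns)) for (cn in names(comps)) {
    p <- patterns[[pn]]; cmp <- comps[[cn]]
    mod <- remove_serving(p, cmp)
    iso <- isocaloric_adjust(p, cmp)
    be <- p$baseline[["energy"]]
    expect_equal(as.numeric(iso)[-1],
                 (as.numeric(mod) * be / mod[["energy"]])[-1],
                 tolerance = 1e-12)
    # closed-form percent change: ((1 - c/b)/(1 - ce/be) - 1) * 100
    b <- as.numeric(p$baseline); cc <- as.numeric(cmp$per_serving)
    closed <- ((1 - cc / b) / (1 - cc[1] / b[1]) - 1) * 100
    pci <- percent_change(b, as.numeric(iso))
    expect_equal(pci[-1], closed[-1], tolerance = 1e-9)
  }
})

test_that("percent_change is exact and guards zero baselines", {
  expect_equal(percent_change(92, 71.2), (71.2 - 92) / 92 * 100)
  expect_equal(round(percent_change(92, 71.2)), -23)
  expect_equal(round(percent_change(13, 9.08)), -30)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "zero")
})

test_that("flag threshold is inclusive on |change| with NA passthrough", {
  pol <- flag_policy(10)
  ch <- c(protein = -10, zinc = 10, iron = -9.47, folate = NA)
  fl <- flag_meaningful(ch, pol)
  expect_identical(unname(fl), c(TRUE, TRUE, FALSE, NA))
  # exact -10% arising from float subtraction still flags
  ch2 <- c(thiamin = percent_change(1.8, 1.8 - 0.18))
  expect_true(flag_meaningful(ch2, pol)[["thiamin"]])
  # energy excluded by default, included on request
  che <- c(energy = -50)
  expect_false(flag_meaningful(che, pol)[["energy"]])
  expect_true(flag_meaningful(che, flag_policy(10, flag_energy = TRUE))[["energy"]])
})

test_that("attenuation: nutrients removed proportionally more than energy", {
  for (pn in names(patterns)) for (cn in names(comps)) {
    res <- run_scenario(patterns[[pn]], comps[[cn]])
    b <- as.numeric(res$baseline); cc <- as.numeric(comps[[cn]]$per_serving)
    nshare <- cc / b; eshare <- cc[1] / b[1]
    sel <- which(!is.na(nshare) & nshare > eshare & nshare < 1)
    expect_true(all(abs(res$pct_change_isocaloric[sel]) <
                      abs(res$pct_change_modified[sel])))
  }
})

test_that("density ratios match the published multiples", {
  expect_equal(density_ratio(comps$min_meat, patterns$USP, "protein"),
               (24.83 / 151.27) / (92 / 2001))
  expect_equal(round(density_ratio(comps$min_meat, patterns$USP, "zinc"), 2),
               3.99)
  # a composite with the pattern's own density ratios to 1
  self <- composite_profile("self",
    nutrient_vector(unclass(nv_scale(patterns$USP$baseline, 85 / 2001)),
                    basis = "per_serving_85g"))
  expect_equal(density_ratio(self, patterns$USP, "protein"), 1)
  zero <- pattern_profile("z", make_nv(energy = 2000,
                                       basis = "per_pattern_day"))
  expect_error(density_ratio(comps$min_meat, zero, "protein"),
               "undefined ratio")
})

test_that("run_scenario composes the pieces deterministically", {
  r1 <- run_scenario(patterns$USP, comps$usda_meat)
  r2 <- run_scenario(patterns$USP, comps$usda_meat)
  expect_identical(results_long(r1), results_long(r2))
  expect_equal(sort(names(which(r1$flags_modified))),
               sort(c("protein", "cholesterol", "iron", "phosphorus",
                      "sodium", "zinc", "copper", "selenium", "thiamin",
                      "niacin", "vitamin_b6", "vitamin_b12", "choline")))
  # MSP x minimally processed poultry cholesterol cell
  r3 <- run_scenario(patterns$MSP, comps$min_poultry)
  expect_equal(round_display(r3$modified[["cholesterol"]], 0), "155")
  # null composite: no flags
  null_comp <- composite_profile("null", make_nv(energy = 1e-9))
  r0 <- run_scenario(patterns$USP, null_comp)
  expect_false(any(r0$flags_modified, na.rm = TRUE))
})
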