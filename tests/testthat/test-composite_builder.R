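test_that("composite_spec validates proportion invariants", {
  ok <- composite_spec("c", list(
    list(category_name = "a", proportion = 0.693,
         foods = list(list(food_id = "x", proportion = 0.8385),
                      list(food_id = "y", proportion = 0.1615))),
    list(category_name = "b", proportion = 0.307,
         foods = list(list(food_id = "z", proportion = 1)))))
  expect_s3_class(ok, "composite_spec")
  expect_error(composite_spec("c", list(
    list(category_name = "a", proportion = 0.6,
         foods = list(list(food_id = "x", proportion = 1))))),
    "sum to")
  expect_error(composite_spec("c", list(
    list(category_name = "a", proportion = 1,
         foods = list(list(food_id = "x", proportion = 1.2),
                      list(food_id = "y", proportion = -0.2))))),
    "\\[0, 1\\]")
  # printed four-decimal proportions: loose tolerance plus renormalization
  off <- list(list(category_name = "a", proportion = 1,
                   foods = list(list(food_id = "x", proportion = 0.3454),
                                list(food_id = "y", proportion = 0.1527),
                                list(food_id = "z", proportion = 0.5018))))
  expect_error(composite_spec("c", off), "sum to")
  fixed <- composite_spec("c", off, tol = 1e-3, renormalize = TRUE)
  expect_equal(sum(flatten_spec(fixed)), 1, tolerance = 1e-12)
})

test_that("blend matches hand-computed convex combinations", {
  profiles <- list(x = make_nv(energy = 100, protein = 26),
                   y = make_nv(energy = 100, protein = 24))
  spec <- composite_spec("two", list(
    list(category_name = "a", proportion = 1,
         foods = list(list(food_id = "x", proportion = 0.8385),
                      list(food_id = "y", proportion = 0.1615)))))
  comp <- blend(spec, profiles)
  expect_s3_class(comp, "composite_profile")
  expect_equal(comp$per_serving[["protein"]], 25.677)  # 0.8385*26 + 0.1615*24
  # identity blend
  one <- composite_spec("one", list(
    list(category_name = "a", proportion = 1,
         foods = list(list(food_id = "x", proportion = 1)))))
  expect_equal(as.numeric(blend(one, profiles)$per_serving),
               as.numeric(profiles$x))
  expect_error(blend(spec, profiles["x"]), "no profile for food")
})

test_that("blend propagates missing unless overridden", {
  profiles <- list(
    x = make_nv(energy = 100, protein = 10),
    y = nutrient_vector(c(energy = 100, protein = 10), complete = FALSE))
  spec <- composite_spec("m", list(
    list(category_name = "a", proportion = 1,
         foods = list(list(food_id = "x", proportion = 0.5),
                      list(food_id = "y", proportion = 0.5)))))
  expect_true(is.na(blend(spec, profiles)$per_serving[["zinc"]]))
  expect_equal(blend(spec, profiles,
                     treat_missing_as_zero = TRUE)$per_serving[["zinc"]],
               0.5 * 0)
})

test_that("nested blend equals flat blend and respects convex bounds", {
  set.seed(42)
  for (i in 1:50) {
    spec <- rand_spec(n_cat = sample(2:4, 1))
    ids <- spec_food_ids(spec)
    profiles <- stats::setNames(lapply(ids, function(.) rand_nv()), ids)
    got <- as.numeric(blend(spec, profiles)$per_serving)
    expect_equal(got, unname(oracle_blend(spec, profiles)),
                 tolerance = 1e-12)
    mat <- sapply(profiles, as.numeric)
    expect_true(all(got >= apply(mat, 1, min) - 1e-12))
    expect_true(all(got <= apply(mat, 1, max) + 1e-12))
  }
})

test_that("estimate_proportions normalizes weighted grams", {
  # two categories with weighted grams 693 / 307
  records <- data.frame(
    participant_id = c("a", "b", "c"),
    survey_weight = c(1, 1, 1),
    age_years = c(30, 40, 50),
    food_code = c("f1", "f2", "g1"),
    grams = c(400, 293, 307))
  map <- data.frame(food_code = c("f1", "f2", "g1"),
                    composite_name = "m",
                    category_name = c("beef", "beef", "pork"))
  spec <- estimate_proportions(records, map)
  p <- vapply(spec$categories, `[[`, numeric(1), "proportion")
  expect_equal(unname(p), c(0.693, 0.307))
  within_beef <- vapply(spec$categories[[1]]$foods, `[[`, numeric(1),
                        "proportion")
  expect_equal(unname(within_beef), c(400, 293) / 693)
  # single category -> proportion 1
  one <- estimate_proportions(records[3, ], map[3, ])
  expect_equal(one$categories[[1]]$proportion, 1)
})

test_that("estimate_proportions errors are categorized", {
  records <- data.frame(participant_id = "a", survey_weight = 0,
                        age_years = 30, food_code = "f1", grams = 100)
  map <- data.frame(food_code = c("f1", "g1"), composite_name = "m",
                    category_name = c("beef", "pork"))
  expect_error(estimate_proportions(records, map), "degenerate")
  records$survey_weight <- 1
  expect_error(estimate_proportions(records, map), "empty category.*pork")
  map2 <- rbind(map, map[1, ])
  expect_error(estimate_proportions(records, map2), "exactly one")
})

test_that("estimate_proportions is invariant to weight rescaling and age filter", {
  sim <- generate_intake_records(synthetic_config(seed = 5,
                                                  n_participants = 500))
  s1 <- estimate_proportions(sim$records, sim$map)
  r2 <- sim$records; r2$survey_weight <- r2$survey_weight * 1e3
  s2 <- estimate_proportions(r2, sim$map)
  expect_equal(vapply(s1$categories, `[[`, numeric(1), "proportion"),
               vapply(s2$categories, `[[`, numeric(1), "proportion"))
  # min_age filter excludes exactly the under-age records
  r3 <- sim$records[sim$records$age_years >= 2, ]
  expect_true(nrow(r3) < nrow(sim$records))  # generator includes under-2s
  s3 <- estimate_proportions(r3, sim$map)
  expect_equal(vapply(s1$categories, `[[`, numeric(1), "proportion"),
               vapply(s3$categories, `[[`, numeric(1), "proportion"))
})

test_that("spec JSON round-trips through write/read", {
  spec <- composite_spec("rt", list(
    list(category_name = "a", proportion = 0.25,
         foods = list(list(food_id = "x", proportion = 1))),
    list(category_name = "b", proportion = 0.75,
         foods = list(list(food_id = "y", proportion = 0.5),
                      list(food_id = "z", proportion = 0.5)))))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_composite_specs_json(spec, tmp)
  back <- read_composite_specs_json(tmp)
  expect_equal(flatten_spec(back$rt), flatten_spec(spec))
})
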