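# shared in-code fixtures; no data files

# a complete per-85 g vector with chosen overrides and zeros elsewhere
make_nv <- function(..., basis = "per_serving_85g") {
  amts <- stats::setNames(rep(0, length(panel_ids())), panel_ids())
  over <- list(...)
  amts[names(over)] <- unlist(over)
  nutrient_vector(amts, basis = basis)
}

# random non-negative complete profile (plain draws, independent of the
# synthetic_data module so it can serve as its own check)
rand_nv <- function(basis = "per_serving_85g") {
  amts <- stats::setNames(stats::runif(length(panel_ids()), 0.01, 100),
                          panel_ids())
  nutrient_vector(amts, basis = basis)
}

# random two-level composite spec over n_cat categories
rand_spec <- function(n_cat = 3, max_foods = 4, prefix = "f") {
  cat_p <- stats::runif(n_cat); cat_p <- cat_p / sum(cat_p)
  fid <- 0L
  cats <- lapply(seq_len(n_cat), function(i) {
    nf <- sample.int(max_foods, 1L)
    fp <- stats::runif(nf); fp <- fp / sum(fp)
    foods <- lapply(seq_len(nf), function(j) {
      fid <<- fid + 1L
      list(food_id = sprintf("%s%02d_%02d", prefix, i, j), proportion = fp[j])
    })
    list(category_name = sprintf("c%02d", i), proportion = cat_p[i],
         foods = foods)
  })
  composite_spec("random", cats)
}

spec_food_ids <- function(spec) {
  unlist(lapply(spec$categories, function(ct)
    vapply(ct$foods, `[[`, character(1), "food_id")))
}

# test-side oracle: nested blend by explicit double loop
oracle_blend <- function(spec, profiles) {
  acc <- stats::setNames(rep(0, length(panel_ids())), panel_ids())
  for (ct in spec$categories) {
    inner <- stats::setNames(rep(0, length(panel_ids())), panel_ids())
    for (f in ct$foods)
      inner <- inner + f$proportion * as.numeric(profiles[[f$food_id]])
    acc <- acc + ct$proportion * inner
  }
  acc
}
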