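# Synthetic stand-ins for the external databases: FNDDS-style per-food
# nutrient profiles and NHANES-style dietary-recall records with survey
# weights. These exist so the proportion-estimation stage is testable
# offline; they emulate schemas and magnitudes, not real survey structure
# (no strata/PSUs, no day-2 recalls, no XPT layouts).

#' Configuration for the synthetic generators
#'
#' Defaults describe a realistic small recall survey: 2000 participants,
#' ages uniform on 0-80 (so roughly 2.5% fall below the age-2 filter),
#' log-normal survey weights centred near 25,000 (national weights sum to
#' the population), log-normal consumed amounts centred near an 85 g
#' serving, and two food categories with a 70/30 consumption split.
#' Per-nutrient means follow the scale of a lean-meat per-85 g profile
#' with a 30% coefficient of variation.
#'
#' @param seed integer seed; every generator is a pure function of the
#'   config including this seed
#' @param n_participants number of participants
#' @param n_food_codes_per_category food codes per category
#' @param weight_meanlog,weight_sdlog log-normal survey-weight parameters
#' @param grams_meanlog,grams_sdlog log-normal consumed-grams parameters
#' @param category_share_truth proportion vector summing to 1; ground
#'   truth for the weighted-grams category shares
#' @param mean_records_per_participant Poisson mean of consumption records
#'   per participant
#' @param nutrient_cv coefficient of variation around per-nutrient means
#' @param missing_rate fraction of non-macronutrient entries set missing
#' @export
synthetic_config <- function(seed = 1L,
                             n_participants = 2000L,
                             n_food_codes_per_category = 3L,
                             weight_meanlog = log(25000), weight_sdlog = 0.6,
                             grams_meanlog = log(85), grams_sdlog = 0.5,
                             category_share_truth = c(0.7, 0.3),
                             mean_records_per_participant = 2,
                             nutrient_cv = 0.3,
                             missing_rate = 0) {
  if (abs(sum(category_share_truth) - 1) > 1e-8)
    stop("category_share_truth must sum to 1", call. = FALSE)
  if (any(category_share_truth < 0))
    stop("category_share_truth must be non-negative", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]", call. = FALSE)
  if (n_participants < 1 || n_food_codes_per_category < 1)
    stop("n_participants and n_food_codes_per_category must be >= 1",
         call. = FALSE)
  if (weight_sdlog <= 0 || grams_sdlog <= 0 || nutrient_cv <= 0)
    stop("scale parameters must be positive", call. = FALSE)
  structure(list(
    seed = as.integer(seed),
    n_participants = as.integer(n_participants),
    n_food_codes_per_category = as.integer(n_food_codes_per_category),
    weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
    grams_meanlog = grams_meanlog, grams_sdlog = grams_sdlog,
    category_share_truth = category_share_truth,
    mean_records_per_participant = mean_records_per_participant,
    nutrient_cv = nutrient_cv,
    missing_rate = missing_rate
  ), class = "synthetic_config")
}

# run fn under the config's seed without disturbing the caller's RNG state
with_config_rng <- function(cfg, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cfg$seed, kind = "Mersenne-Twister")
  fn()
}

synthetic_food_codes <- function(cfg) {
  k <- length(cfg$category_share_truth)
  cats <- sprintf("cat%02d", seq_len(k))
  codes <- unlist(lapply(seq_len(k), function(i)
    sprintf("%s_food%02d", cats[i], seq_len(cfg$n_food_codes_per_category))))
  data.frame(food_code = codes,
             composite_name = "synthetic",
             category_name = rep(cats, each = cfg$n_food_codes_per_category),
             stringsAsFactors = FALSE)
}

# per-85 g nutrient means on the scale of a lean-meat profile
synthetic_nutrient_means <- function() {
  c(energy = NA, protein = 24, total_fat = 5, carbohydrate = 1, fiber = 0.2,
    cholesterol = 70, sfa = 2, mufa = 2.2, pufa = 0.5,
    calcium = 11, iron = 1.5, magnesium = 22, phosphorus = 215,
    potassium = 345, sodium = 365, zinc = 3.9, copper = 0.08,
    selenium = 33, vitamin_a = 5, vitamin_e = 0.25, vitamin_d = 0.2,
    vitamin_c = 0.5, thiamin = 0.2, riboflavin = 0.2, niacin = 7,
    vitamin_b6 = 0.55, vitamin_b12 = 1.3, choline = 75, vitamin_k = 1,
    folate = 5)
}

#' Generate synthetic per-85 g food profiles
#'
#' Protein, fat and carbohydrate are drawn log-normally around lean-meat
#' means with the configured CV; energy is then derived from the 4/4/9
#' kcal rule with a uniform +/-10% wobble, so generated energy is always
#' within 20% of `4 protein + 4 carbohydrate + 9 fat`. Micronutrient
#' entries (never energy or the three macros) are set missing at
#' `missing_rate`. The seed and generator name are attached as attributes.
#'
#' @param cfg a [synthetic_config()]
#' @return named list of per-85 g [nutrient_vector()]s keyed by food code
#' @export
generate_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  map <- synthetic_food_codes(cfg)
  mu <- synthetic_nutrient_means()
  sdlog <- sqrt(log(1 + cfg$nutrient_cv^2))
  maskable <- setdiff(panel_ids(),
                      c("energy", "protein", "total_fat", "carbohydrate"))
  profiles <- with_config_rng(cfg, function() {
    stats::setNames(lapply(map$food_code, function(fc) {
      amts <- vapply(panel_ids(), function(k) {
        if (k == "energy") return(NA_real_)
        m <- mu[[k]]
        if (m <= 0) return(0)
        stats::rlnorm(1, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
      }, numeric(1))
      atwater <- 4 * amts[["protein"]] + 4 * amts[["carbohydrate"]] +
        9 * amts[["total_fat"]]
      amts[["energy"]] <- atwater * stats::runif(1, 0.9, 1.1)
      if (cfg$missing_rate > 0) {
        drop <- maskable[stats::runif(length(maskable)) < cfg$missing_rate]
        amts[drop] <- NA_real_
      }
      nutrient_vector(amts, basis = "per_serving_85g")
    }), map$food_code)
  })
  attr(profiles, "generator") <- "dietmod-lognormal-v1"
  attr(profiles, "seed") <- cfg$seed
  profiles
}

#' Generate synthetic dietary-recall intake records
#'
#' Each participant gets one survey weight, an age uniform on 0-80 years,
#' and a Poisson number of consumption records; each record picks a
#' category with probability equal to the true shares, a food code
#' uniformly within it, and a log-normal consumed amount. Because weights,
#' grams and ages are independent of the category choice, the expected
#' weighted-grams category shares equal `category_share_truth`, which is
#' what [estimate_proportions()] should recover.
#'
#' @param cfg a [synthetic_config()]
#' @return list with `records` (intake data.frame), `map` (food-code map
#'   for [estimate_proportions()]) and `truth` (the share vector)
#' @export
generate_intake_records <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  map <- synthetic_food_codes(cfg)
  k <- length(cfg$category_share_truth)
  records <- with_config_rng(cfg, function() {
    n <- cfg$n_participants
    wt <- stats::rlnorm(n, cfg$weight_meanlog, cfg$weight_sdlog)
    age <- stats::runif(n, 0, 80)
    nrec <- stats::rpois(n, cfg$mean_records_per_participant)
    pid <- rep(seq_len(n), nrec)
    m <- length(pid)
    cat_idx <- sample.int(k, m, replace = TRUE,
                          prob = cfg$category_share_truth)
    food_idx <- sample.int(cfg$n_food_codes_per_category, m, replace = TRUE)
    data.frame(
      participant_id = sprintf("P%05d", pid),
      survey_weight = wt[pid],
      age_years = age[pid],
      food_code = sprintf("cat%02d_food%02d", cat_idx, food_idx),
      grams = stats::rlnorm(m, cfg$grams_meanlog, cfg$grams_sdlog),
      stringsAsFactors = FALSE
    )
  })
  attr(records, "generator") <- "dietmod-lognormal-v1"
  attr(records, "seed") <- cfg$seed
  list(records = records, map = map, truth = cfg$category_share_truth)
}
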