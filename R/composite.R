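#' Composite specifications
#'
#' A composite is a representative nutrient profile for a food group,
#' defined as a two-level convex blend: categories (e.g. beef, pork) carry
#' population-weighted proportions that sum to 1, and foods within each
#' category carry within-category proportions that also sum to 1. Blending
#' a spec against per-85 g food profiles yields the composite's per-85 g
#' profile.
#'
#' @param name composite identifier
#' @param categories list of lists, each with `category_name`, `proportion`,
#'   and `foods` — itself a list of lists with `food_id` and `proportion`
#'   (an optional `label` is carried through).
#' @param tol tolerance on the proportion-sum invariants. The default 1e-6
#'   suits full-precision proportions; specs transcribed from tables printed
#'   at four decimals may need `tol = 1e-3` together with
#'   `renormalize = TRUE`.
#' @param renormalize divide each proportion group by its sum after the
#'   tolerance check, so downstream blending is exactly convex.
#' @export
composite_spec <- function(name, categories, tol = 1e-6, renormalize = FALSE) {
  if (!is.character(name) || length(name) != 1L)
    stop("name must be a single string", call. = FALSE)
  if (!length(categories)) stop("at least one category required", call. = FALSE)
  cat_p <- vapply(categories, function(ct) as.numeric(ct$proportion), numeric(1))
  if (any(!is.finite(cat_p)) || any(cat_p < 0) || any(cat_p > 1))
    stop("category proportions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(cat_p) - 1) > tol)
    stop(sprintf("category proportions sum to %.6f, not 1 (tol %g)",
                 sum(cat_p), tol), call. = FALSE)
  categories <- lapply(categories, function(ct) {
    fp <- vapply(ct$foods, function(f) as.numeric(f$proportion), numeric(1))
    if (any(!is.finite(fp)) || any(fp < 0) || any(fp > 1))
      stop("food proportions must lie in [0, 1] in category ",
           ct$category_name, call. = FALSE)
    if (abs(sum(fp) - 1) > tol)
      stop(sprintf("food proportions in category '%s' sum to %.6f, not 1 (tol %g)",
                   ct$category_name, sum(fp), tol), call. = FALSE)
    if (renormalize) {
      ct$foods <- lapply(ct$foods, function(f) {
        f$proportion <- as.numeric(f$proportion) / sum(fp); f
      })
    }
    ct
  })
  if (renormalize) {
    s <- sum(cat_p)
    categories <- Map(function(ct, p) { ct$proportion <- p / s; ct },
                      categories, cat_p)
  }
  structure(list(name = name, categories = categories), class = "composite_spec")
}

#' @export
print.composite_spec <- function(x, ...) {
  cat("<composite_spec>", x$name, "\n")
  for (ct in x$categories) {
    cat(sprintf("  %-34s %6.2f%%\n", ct$category_name, 100 * ct$proportion))
    for (f in ct$foods)
      cat(sprintf("    %-32s %6.2f%%\n", f$food_id, 100 * f$proportion))
  }
  invisible(x)
}

#' Flatten a two-level spec to effective per-food weights
#'
#' The effective weight of a food is `category_proportion *
#' within_category_proportion`; the result sums to 1 and a one-level blend
#' with these weights equals the nested blend.
#'
#' @param spec a [composite_spec()]
#' @return named numeric vector of weights keyed by food id
#' @export
flatten_spec <- function(spec) {
  stopifnot(inherits(spec, "composite_spec"))
  w <- unlist(lapply(spec$categories, function(ct) {
    stats::setNames(
      vapply(ct$foods, function(f) ct$proportion * f$proportion, numeric(1)),
      vapply(ct$foods, function(f) f$food_id, character(1))
    )
  }))
  # a food id may appear under several categories; accumulate
  tapply_w <- tapply(w, names(w), sum)
  stats::setNames(as.numeric(tapply_w), names(tapply_w))
}

#' Blend food profiles into a composite profile
#'
#' Computes the proportion-weighted sum of per-85 g food profiles: for each
#' nutrient, sum over categories of category proportion times the
#' within-category weighted amount. Any missing amount in a contributing
#' food makes the composite amount missing, unless
#' `treat_missing_as_zero = TRUE`.
#'
#' @param spec a [composite_spec()]
#' @param profiles named list of per-85 g [nutrient_vector()]s covering
#'   every food id in the spec
#' @param treat_missing_as_zero policy override; default off so unreported
#'   nutrients propagate as missing
#' @return a [composite_profile()]
#' @export
blend <- function(spec, profiles, treat_missing_as_zero = FALSE) {
  w <- flatten_spec(spec)
  missing_foods <- setdiff(names(w), names(profiles))
  if (length(missing_foods))
    stop("no profile for food(s): ", paste(missing_foods, collapse = ", "),
         call. = FALSE)
  mat <- vapply(names(w), function(f) {
    assert_nv(profiles[[f]], paste0("profile '", f, "'"))
    as.numeric(profiles[[f]])
  }, numeric(length(panel_ids())))
  if (treat_missing_as_zero) mat[is.na(mat)] <- 0
  amounts <- as.numeric(mat %*% w)
  names(amounts) <- panel_ids()
  composite_profile(spec$name,
                    nutrient_vector(amounts, basis = "per_serving_85g",
                                    check_negative = FALSE))
}

#' Estimate composite proportions from survey-weighted intake records
#'
#' Population-weighted consumption of a food (or category) is the sum over
#' in-scope participants of `survey_weight * grams`. Category proportions
#' are each category's share of its composite's total weighted grams;
#' within-category food proportions are analogous over food codes. The age
#' filter is inclusive (`age_years >= min_age`).
#'
#' @param records data.frame of intake records (see [read_intake_csv()])
#' @param map data.frame mapping `food_code` to `composite_name` and
#'   `category_name`; every code belongs to exactly one pair
#' @param min_age inclusive lower age bound in years
#' @return a named list of [composite_spec()]s, one per composite in `map`
#'   (a single-composite map returns the spec directly)
#' @export
estimate_proportions <- function(records, map, min_age = 2) {
  need <- c("participant_id", "survey_weight", "age_years", "food_code", "grams")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(c("food_code", "composite_name", "category_name") %in% names(map)))
    stop("map must have columns food_code, composite_name, category_name",
         call. = FALSE)
  if (anyDuplicated(map$food_code))
    stop("each food_code must map to exactly one (composite, category)",
         call. = FALSE)
  rec <- records[records$age_years >= min_age &
                   records$food_code %in% map$food_code, , drop = FALSE]
  rec$wg <- rec$survey_weight * rec$grams
  if (!nrow(rec) || sum(rec$wg) <= 0)
    stop("degenerate input: no positive weighted consumption after filtering",
         call. = FALSE)
  idx <- match(rec$food_code, map$food_code)
  rec$composite <- map$composite_name[idx]
  rec$category <- map$category_name[idx]

  specs <- lapply(split(seq_len(nrow(map)), map$composite_name), function(mi) {
    m <- map[mi, , drop = FALSE]
    r <- rec[rec$composite == m$composite_name[1L], , drop = FALSE]
    cat_names <- unique(m$category_name)
    W_cat <- vapply(cat_names, function(cn)
      sum(r$wg[r$category == cn]), numeric(1))
    if (any(W_cat <= 0))
      stop("empty category (zero weighted consumption): ",
           paste(cat_names[W_cat <= 0], collapse = ", "),
           " in composite ", m$composite_name[1L], call. = FALSE)
    cats <- lapply(cat_names, function(cn) {
      codes <- m$food_code[m$category_name == cn]
      W_food <- vapply(codes, function(fc)
        sum(r$wg[r$food_code == fc]), numeric(1))
      list(category_name = cn,
           proportion = W_cat[[cn]] / sum(W_cat),
           foods = Map(function(fc, wf) list(food_id = fc,
                                             proportion = wf / sum(W_food)),
                       codes, W_food))
    })
    composite_spec(m$composite_name[1L], cats)
  })
  if (length(specs) == 1L) specs[[1L]] else specs
}

#' Read / write composite specs as JSON
#'
#' The JSON layout mirrors the two-level structure: an object keyed by
#' composite name, each with a `categories` array of
#' `{category_name, proportion, foods: [{food_id, proportion}, ...]}`.
#'
#' @param path JSON file path
#' @param tol,renormalize passed to [composite_spec()]; printed-table specs
#'   transcribed at four decimals need `tol = 1e-3`.
#' @return named list of [composite_spec()]s
#' @export
read_composite_specs_json <- function(path, tol = 1e-6, renormalize = FALSE) {
  obj <- jsonlite::read_json(path)
  out <- lapply(obj, function(cs)
    composite_spec(cs$name, cs$categories, tol = tol,
                   renormalize = renormalize))
  stats::setNames(out, vapply(obj, `[[`, character(1), "name"))
}

#' @rdname read_composite_specs_json
#' @param specs named list of [composite_spec()]s (proportions are written
#'   rounded to 4 decimals, matching conventional display precision)
#' @export
write_composite_specs_json <- function(specs, path) {
  if (inherits(specs, "composite_spec")) specs <- list(specs)
  obj <- lapply(specs, function(s) {
    s$categories <- lapply(s$categories, function(ct) {
      ct$proportion <- round(ct$proportion, 4)
      ct$foods <- lapply(ct$foods, function(f) {
        f$proportion <- round(f$proportion, 4); f
      })
      ct
    })
    unclass(s)
  })
  names(obj) <- vapply(specs, `[[`, character(1), "name")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
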