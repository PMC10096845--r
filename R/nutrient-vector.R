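#' Nutrient vectors
#'
#' A `nutrient_vector` is the universal currency of the package: a complete
#' set of amounts for the 30-key panel (see [nutrient_panel()]), stored at
#' full floating precision, with `NA` marking a missing (not zero) value.
#' Missingness propagates through all arithmetic; it is never silently
#' treated as zero, because a pattern minus a composite with an unreported
#' nutrient has an unknown, not a zero, result.
#'
#' @param amounts named numeric vector; names must be panel ids. Keys not
#'   supplied are an error unless `complete = FALSE`, in which case they are
#'   filled with `NA` (missing).
#' @param basis `"per_serving_85g"` for a food/composite profile or
#'   `"per_pattern_day"` for a daily dietary-pattern total.
#' @param complete require all 30 keys to be supplied?
#' @param check_negative source profiles must be non-negative; internal
#'   callers representing modeled results may disable the check.
#' @return an object of class `nutrient_vector`: a named numeric vector in
#'   panel order with a `basis` attribute.
#' @examples
#' v <- nutrient_vector(c(energy = 131, protein = 20.8), complete = FALSE)
#' v[["protein"]]
#' @export
nutrient_vector <- function(amounts,
                            basis = c("per_serving_85g", "per_pattern_day"),
                            complete = TRUE,
                            check_negative = TRUE) {
  basis <- match.arg(basis)
  if (is.null(names(amounts)) || anyNA(names(amounts)) || any(names(amounts) == ""))
    stop("amounts must be a fully named numeric vector", call. = FALSE)
  check_panel_ids(names(amounts))
  if (anyDuplicated(names(amounts)))
    stop("duplicated nutrient id(s) in amounts", call. = FALSE)
  ids <- panel_ids()
  if (complete && !all(ids %in% names(amounts)))
    stop("incomplete panel: missing ",
         paste(setdiff(ids, names(amounts)), collapse = ", "), call. = FALSE)
  v <- stats::setNames(rep(NA_real_, length(ids)), ids)
  v[names(amounts)] <- as.numeric(amounts)
  if (check_negative && any(v < 0, na.rm = TRUE))
    stop("negative amount(s) in source profile: ",
         paste(ids[which(v < 0)], collapse = ", "), call. = FALSE)
  structure(v, basis = basis, class = "nutrient_vector")
}

#' @export
print.nutrient_vector <- function(x, ...) {
  pan <- nutrient_panel()
  cat("<nutrient_vector> basis:", attr(x, "basis"), "\n")
  df <- data.frame(nutrient = pan$display_name,
                   amount = as.numeric(x),
                   unit = pan$unit)
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' @export
as.data.frame.nutrient_vector <- function(x, ...) {
  pan <- nutrient_panel()
  data.frame(nutrient_id = pan$id, amount = as.numeric(x), unit = pan$unit,
             stringsAsFactors = FALSE)
}

is_nutrient_vector <- function(x) inherits(x, "nutrient_vector")

assert_nv <- function(x, what = "argument") {
  if (!is_nutrient_vector(x))
    stop(what, " must be a nutrient_vector", call. = FALSE)
  invisible(x)
}

#' Scale a nutrient vector
#'
#' Multiplies every non-missing amount by a non-negative factor; missing
#' stays missing and the basis is unchanged. Used for gram conversions
#' (e.g. per-100 g to per-85 g is `factor = 0.85`) and multi-serving
#' scenarios.
#'
#' @param v a [nutrient_vector()]
#' @param factor finite, non-negative multiplier
#' @export
nv_scale <- function(v, factor) {
  assert_nv(v, "v")
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor))
    stop("factor must be a single finite number", call. = FALSE)
  if (factor < 0) stop("factor must be non-negative", call. = FALSE)
  structure(unclass(v) * factor, basis = attr(v, "basis"),
            class = "nutrient_vector")
}

#' Elementwise difference of two nutrient vectors
#'
#' Returns a plain signed named numeric map (not a `nutrient_vector`,
#' because differences may legitimately be negative). A missing operand on
#' either side yields a missing difference.
#'
#' @param a,b [nutrient_vector()] objects on a basis convention established
#'   by the caller (pattern-day minus per-serving is the intended use).
#' @export
nv_subtract <- function(a, b) {
  assert_nv(a, "a"); assert_nv(b, "b")
  out <- unclass(a) - unclass(b)
  attributes(out) <- list(names = names(out))
  out
}

#' Nutrient density per 100 kcal
#'
#' Rescales a profile to amounts per 100 kcal of its own energy. Density is
#' scale-free: grams vs servings of the same food give the same answer.
#'
#' @param v a [nutrient_vector()] with positive, non-missing energy
#' @return named numeric map of amounts per 100 kcal
#' @export
nv_per_100kcal <- function(v) {
  assert_nv(v, "v")
  e <- v[["energy"]]
  if (is.na(e) || e <= 0)
    stop("undefined density: energy is missing or not positive", call. = FALSE)
  unclass(v) * 100 / e
}

#' Serving specification
#'
#' @param grams serving mass in grams (composites are defined per 85 g,
#'   the 3 oz serving used throughout)
#' @param servings positive number of servings
#' @export
serving_spec <- function(grams = 85, servings = 1) {
  if (!is.numeric(grams) || length(grams) != 1L || !is.finite(grams) || grams <= 0)
    stop("grams must be a single positive number", call. = FALSE)
  if (!is.numeric(servings) || length(servings) != 1L || !is.finite(servings) || servings <= 0)
    stop("servings must be a single positive number", call. = FALSE)
  structure(list(grams = grams, servings = servings), class = "serving_spec")
}

# internal: total scale factor relative to the 85 g reference serving
serving_factor <- function(serving) serving$servings * serving$grams / 85
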