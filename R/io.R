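# File-format adapters: nutrient profiles (long or wide CSV, JSON),
# intake-record CSV, and composite-spec JSON. Unit strings in long-format
# profile files must match the panel registry bit-exactly.

#' Read nutrient profiles from CSV
#'
#' Two layouts are accepted. Long: columns `nutrient_id, amount, unit`
#' (one food per file; `food_id` column optional for several). Wide: a
#' `nutrient_id` column plus one column per food. Empty cells and the
#' literal `NA` read as missing.
#'
#' @param path CSV file path
#' @param basis basis to stamp on the resulting vectors
#' @param allow_extras drop unknown nutrient rows instead of erroring?
#' @return named list of [nutrient_vector()]s keyed by food id (a single
#'   unnamed long file yields the key `"food"`)
#' @export
read_profiles_csv <- function(path, basis = "per_serving_85g",
                              allow_extras = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"nutrient_id" %in% names(df))
    stop("profile CSV must have a nutrient_id column", call. = FALSE)
  if ("amount" %in% names(df)) {
    if ("unit" %in% names(df)) check_units(df$nutrient_id, df$unit, allow_extras)
    key <- if ("food_id" %in% names(df)) df$food_id else "food"
    split_df <- split(df, key)
    out <- lapply(split_df, function(d) {
      keep <- d$nutrient_id %in% panel_ids()
      if (any(!keep) && !allow_extras)
        check_panel_ids(d$nutrient_id)  # raises with the offending ids
      nutrient_vector(stats::setNames(d$amount[keep], d$nutrient_id[keep]),
                      basis = basis, complete = FALSE)
    })
    return(out)
  }
  foods <- setdiff(names(df), c("nutrient_id", "unit"))
  if ("unit" %in% names(df)) check_units(df$nutrient_id, df$unit, allow_extras)
  keep <- df$nutrient_id %in% panel_ids()
  if (any(!keep) && !allow_extras) check_panel_ids(df$nutrient_id)
  out <- lapply(foods, function(f) {
    nutrient_vector(stats::setNames(as.numeric(df[[f]][keep]),
                                    df$nutrient_id[keep]),
                    basis = basis, complete = FALSE)
  })
  stats::setNames(out, foods)
}

check_units <- function(ids, units, allow_extras = FALSE) {
  pan <- nutrient_panel()
  expected <- pan$unit[match(ids, pan$id)]
  bad <- !is.na(expected) & units != expected
  if (any(bad))
    stop("unit mismatch for ", paste(unique(ids[bad]), collapse = ", "),
         ": units must match the panel registry exactly", call. = FALSE)
  invisible(TRUE)
}

#' Read nutrient profiles from JSON
#'
#' JSON object mapping food id to an object of `nutrient_id: amount`
#' pairs (`null` for missing).
#' @inheritParams read_profiles_csv
#' @export
read_profiles_json <- function(path, basis = "per_serving_85g",
                               allow_extras = FALSE) {
  obj <- jsonlite::read_json(path)
  lapply(obj, function(food) {
    amts <- vapply(food, function(x) if (is.null(x)) NA_real_ else as.numeric(x),
                   numeric(1))
    keep <- names(amts) %in% panel_ids()
    if (any(!keep) && !allow_extras) check_panel_ids(names(amts))
    nutrient_vector(amts[keep], basis = basis, complete = FALSE)
  })
}

#' Read dietary-recall intake records
#'
#' CSV with header `participant_id, survey_weight, age_years, food_code,
#' grams` (extra columns pass through).
#' @param path CSV file path
#' @export
read_intake_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(food_code = "character"))
  need <- c("participant_id", "survey_weight", "age_years", "food_code", "grams")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("intake CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$survey_weight < 0, na.rm = TRUE))
    stop("survey_weight must be non-negative", call. = FALSE)
  if (any(df$grams < 0, na.rm = TRUE))
    stop("grams must be non-negative", call. = FALSE)
  df
}

#' Write a long-format results CSV
#'
#' One row per nutrient with baseline, modified, isocaloric values, percent
#' changes, and flags, for one or more scenarios.
#' @param results a `removal_result` or list of them
#' @param path output CSV path
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(results_long(results), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_results_csv
#' @export
results_long <- function(results) {
  if (inherits(results, "removal_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      pattern = r$pattern_id,
      composite = r$composite_name,
      nutrient_id = panel_ids(),
      baseline = as.numeric(r$baseline),
      modified = as.numeric(r$modified),
      isocaloric = as.numeric(r$isocaloric),
      pct_modified = as.numeric(r$pct_change_modified),
      pct_isocaloric = as.numeric(r$pct_change_isocaloric),
      flag_modified = as.logical(r$flags_modified),
      flag_isocaloric = as.logical(r$flags_isocaloric),
      stringsAsFactors = FALSE
    )
  }))
}
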