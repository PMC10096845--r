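#' The 30-nutrient panel
#'
#' The package works on a fixed, closed panel of 30 nutrients: energy, the
#' macronutrients (protein, total fat, carbohydrate, fiber, cholesterol and
#' the three fatty-acid classes), nine minerals, and twelve vitamins plus
#' choline. Units are metadata attached to each key and are never converted
#' implicitly; vitamin A is in retinol activity equivalents (RAE), vitamin E
#' in alpha-tocopherol equivalents (ATE), and folate in dietary folate
#' equivalents (DFE).
#'
#' @return A data.frame with columns `id`, `display_name`, `unit` and
#'   `display_decimals` (the default precision used by [render_table()]).
#' @examples
#' nutrient_panel()
#' @export
nutrient_panel <- function() {
  df <- data.frame(
    id = c(
      "energy", "protein", "total_fat", "carbohydrate", "fiber",
      "cholesterol", "sfa", "mufa", "pufa",
      "calcium", "iron", "magnesium", "phosphorus", "potassium", "sodium",
      "zinc", "copper", "selenium",
      "vitamin_a", "vitamin_e", "vitamin_d", "vitamin_c",
      "thiamin", "riboflavin", "niacin", "vitamin_b6", "vitamin_b12",
      "choline", "vitamin_k", "folate"
    ),
    display_name = c(
      "Energy", "Protein", "Total fat", "Carbohydrate", "Dietary fiber",
      "Cholesterol", "Saturated fatty acids", "Monounsaturated fatty acids",
      "Polyunsaturated fatty acids",
      "Calcium", "Iron", "Magnesium", "Phosphorus", "Potassium", "Sodium",
      "Zinc", "Copper", "Selenium",
      "Vitamin A, RAE", "Vitamin E, ATE", "Vitamin D", "Vitamin C",
      "Thiamin", "Riboflavin", "Niacin", "Vitamin B6", "Vitamin B12",
      "Total choline", "Vitamin K", "Folate, DFE"
    ),
    unit = c(
      "kcal", "g", "g", "g", "g",
      "mg", "g", "g", "g",
      "mg", "mg", "mg", "mg", "mg", "mg",
      "mg", "mg", "µg",
      "µg", "mg", "µg", "mg",
      "mg", "mg", "mg", "mg", "µg",
      "mg", "µg", "µg"
    ),
    display_decimals = c(
      0L, 1L, 1L, 0L, 1L,
      0L, 1L, 1L, 1L,
      0L, 1L, 0L, 0L, 0L, 0L,
      2L, 2L, 1L,
      0L, 2L, 2L, 0L,
      2L, 2L, 1L, 2L, 2L,
      0L, 0L, 0L
    ),
    stringsAsFactors = FALSE
  )
  rownames(df) <- df$id
  df
}

#' @rdname nutrient_panel
#' @export
panel_ids <- function() nutrient_panel()$id

# internal: validate a set of nutrient ids against the closed panel
check_panel_ids <- function(ids, allow_extras = FALSE) {
  unknown <- setdiff(ids, panel_ids())
  if (length(unknown) && !allow_extras) {
    stop("unknown nutrient id(s): ", paste(unknown, collapse = ", "),
         " (the panel is closed; pass allow_extras = TRUE to drop them)",
         call. = FALSE)
  }
  intersect(ids, panel_ids())
}
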