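# Packaged fixtures: the published composite definitions, composite
# per-85 g profiles, 2000 kcal pattern baselines, and the printed result
# tables used by the reproduction oracle. Values are stored exactly at
# printed precision; the tables are the package's ground truth, not a
# re-derivation from the underlying consumption databases.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "dietmod")
  if (p == "") stop("fixture file not found: ", file, call. = FALSE)
  p
}

#' Load a packaged fixture
#'
#' * `"table1_specs"` — named list of [composite_spec()]s for the five
#'   composites (USDA meat, minimally/further processed meat and poultry).
#'   Printed proportions are carried at four decimals; one group sums to
#'   0.9999 in print, so specs are validated at a 1e-3 tolerance and
#'   renormalized to exact convexity.
#' * `"table2_composites"` — named list of [composite_profile()]s per
#'   85 g. Folate for USDA meat is missing (printed NA) and propagates.
#' * `"pattern_baselines"` — named list of [pattern_profile()]s for USP
#'   and MSP at the 2000 kcal level (printed baseline energies 2001 and
#'   2085 kcal).
#' * `"printed_results"` — data.frame of the published modified and
#'   isocaloric columns with their asterisk flags, for the oracle
#'   comparison in [reproduce_paper()].
#'
#' @param name fixture name
#' @export
load_fixture <- function(name = c("table1_specs", "table2_composites",
                                  "pattern_baselines", "printed_results")) {
  name <- match.arg(name)
  switch(name,
    table1_specs = read_composite_specs_json(
      fixture_path("composite_specs.json"), tol = 1e-3, renormalize = TRUE),
    table2_composites = {
      profs <- read_profiles_csv(fixture_path("composite_profiles_per85g.csv"),
                                 basis = "per_serving_85g")
      stats::setNames(
        lapply(names(profs), function(nm) composite_profile(nm, profs[[nm]])),
        names(profs))
    },
    pattern_baselines = {
      profs <- read_profiles_csv(fixture_path("pattern_baselines.csv"),
                                 basis = "per_pattern_day")
      stats::setNames(
        lapply(names(profs), function(nm) pattern_profile(nm, profs[[nm]])),
        names(profs))
    },
    printed_results = utils::read.csv(fixture_path("printed_results.csv"),
                                      stringsAsFactors = FALSE,
                                      colClasses = c(baseline = "character",
                                                     modified = "character",
                                                     isocaloric = "character"))
  )
}

#' Composite display names used in output tables
#' @keywords internal
composite_display_names <- c(
  usda_meat = "USDA meat",
  min_meat = "Minimally processed meat",
  min_poultry = "Minimally processed poultry",
  fp_meat = "Further processed meat",
  fp_poultry = "Further processed poultry"
)
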