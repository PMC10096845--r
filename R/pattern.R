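#' Dietary-pattern baselines and composite profiles
#'
#' A `pattern_profile` holds the daily nutrient totals of a 2000 kcal
#' Healthy Dietary Pattern — the Healthy U.S.-Style Pattern (USP, baseline
#' energy prints as 2001 kcal) or the Healthy Mediterranean-Style Pattern
#' (MSP, 2085 kcal) — or any custom pattern. A `composite_profile` holds a
#' composite's per-85 g nutrient vector.
#'
#' @param pattern_id `"USP"`, `"MSP"`, or a custom identifier
#' @param baseline a `per_pattern_day` [nutrient_vector()] with positive
#'   energy
#' @param kcal_level nominal calorie level of the pattern (default 2000)
#' @export
pattern_profile <- function(pattern_id, baseline, kcal_level = 2000) {
  assert_nv(baseline, "baseline")
  if (attr(baseline, "basis") != "per_pattern_day")
    stop("baseline must be on the per_pattern_day basis", call. = FALSE)
  e <- baseline[["energy"]]
  if (is.na(e) || e <= 0)
    stop("baseline energy must be present and positive", call. = FALSE)
  structure(list(pattern_id = pattern_id, kcal_level = kcal_level,
                 baseline = baseline),
            class = "pattern_profile")
}

#' @rdname pattern_profile
#' @param name composite name
#' @param per_serving a `per_serving_85g` [nutrient_vector()] with positive
#'   energy
#' @export
composite_profile <- function(name, per_serving) {
  assert_nv(per_serving, "per_serving")
  if (attr(per_serving, "basis") != "per_serving_85g")
    stop("per_serving must be on the per_serving_85g basis", call. = FALSE)
  e <- per_serving[["energy"]]
  if (is.na(e) || e <= 0)
    stop("composite energy must be present and positive", call. = FALSE)
  structure(list(name = name, per_serving = per_serving),
            class = "composite_profile")
}

#' Flagging policy for meaningful nutrient changes
#'
#' A change of `threshold_pct` percent or more from baseline (inclusive, on
#' the absolute value) marks a meaningful difference. Changes are evaluated
#' on unrounded values by default; `basis = "rounded"` evaluates them on
#' display-rounded values instead (not the faithful default — kept for
#' sensitivity checks).
#'
#' @param threshold_pct positive percent threshold (default 10)
#' @param basis `"unrounded"` or `"rounded"`
#' @param flag_energy include energy in flagging? Off by default: the
#'   energy change is reported but never starred (it is below 10% for every
#'   scenario here, and the isocaloric column restores it exactly).
#' @export
flag_policy <- function(threshold_pct = 10,
                        basis = c("unrounded", "rounded"),
                        flag_energy = FALSE) {
  basis <- match.arg(basis)
  if (!is.numeric(threshold_pct) || length(threshold_pct) != 1L ||
      !is.finite(threshold_pct) || threshold_pct <= 0)
    stop("threshold_pct must be a single positive number", call. = FALSE)
  structure(list(threshold_pct = threshold_pct, basis = basis,
                 flag_energy = flag_energy), class = "flag_policy")
}

# internal: per-serving vector scaled to the requested serving
scaled_serving <- function(comp, serving) {
  nv_scale(comp$per_serving, serving_factor(serving))
}

#' Remove a composite serving from a pattern baseline
#'
#' Subtracts the nutrients of `servings` x `grams` of the composite from
#' the pattern's daily totals. Missing composite nutrients propagate to
#' missing results. Removing more energy than the baseline holds is an
#' error; a negative modeled amount for any other nutrient is reported
#' with a warning rather than clamped.
#'
#' @param pattern a [pattern_profile()]
#' @param comp a [composite_profile()]
#' @param serving a [serving_spec()]
#' @return the modified `per_pattern_day` [nutrient_vector()]
#' @export
remove_serving <- function(pattern, comp, serving = serving_spec()) {
  stopifnot(inherits(pattern, "pattern_profile"),
            inherits(comp, "composite_profile"))
  s <- scaled_serving(comp, serving)
  if (s[["energy"]] >= pattern$baseline[["energy"]])
    stop("infeasible removal: serving energy (", s[["energy"]],
         " kcal) is not below baseline energy (",
         pattern$baseline[["energy"]], " kcal)", call. = FALSE)
  d <- nv_subtract(pattern$baseline, s)
  neg <- names(d)[!is.na(d) & d < 0]
  if (length(neg))
    warning("negative modeled amount(s) after removal: ",
            paste(neg, collapse = ", "), call. = FALSE)
  structure(d, basis = "per_pattern_day", class = "nutrient_vector")
}

#' Isocaloric removal of a composite serving
#'
#' Removes the serving and then scales the whole remaining diet back up to
#' the baseline calorie level, i.e. for every nutrient
#' `(baseline - composite) / (baseline kcal - composite kcal) * baseline
#' kcal`. All remaining foods are in effect increased proportionally to the
#' calories removed, so the energy row equals the baseline exactly.
#'
#' @inheritParams remove_serving
#' @return the isocaloric `per_pattern_day` [nutrient_vector()]
#' @export
isocaloric_adjust <- function(pattern, comp, serving = serving_spec()) {
  stopifnot(inherits(pattern, "pattern_profile"),
            inherits(comp, "composite_profile"))
  s <- scaled_serving(comp, serving)
  be <- pattern$baseline[["energy"]]
  denom <- be - s[["energy"]]
  if (is.na(denom) || denom <= 0)
    stop("infeasible removal: modified energy must be positive", call. = FALSE)
  d <- nv_subtract(pattern$baseline, s) * be / denom
  d[["energy"]] <- be  # exact by construction, restated to avoid roundoff
  structure(d, basis = "per_pattern_day", class = "nutrient_vector")
}

#' Percent change from a baseline value
#'
#' `(new - baseline) / baseline * 100`, at full precision; display rounding
#' is the caller's job. Vectorized; missing operands give missing changes.
#'
#' @param baseline_value,new_value numeric (scalars or aligned vectors)
#' @export
percent_change <- function(baseline_value, new_value) {
  if (any(!is.na(baseline_value) & baseline_value == 0))
    stop("undefined change: baseline value is zero", call. = FALSE)
  (new_value - baseline_value) / baseline_value * 100
}

#' Flag meaningful changes
#'
#' @param changes named numeric map of signed percent changes
#' @param policy a [flag_policy()]
#' @return named logical map; `TRUE` where `|change| >= threshold`, `NA`
#'   (not evaluable) where the change itself is missing
#' @export
flag_meaningful <- function(changes, policy = flag_policy()) {
  stopifnot(inherits(policy, "flag_policy"))
  # inclusive threshold with a float guard: a change that is exactly -10%
  # in exact arithmetic (e.g. 1.8 - 0.18 against a 1.8 baseline) must not
  # drop below it through binary roundoff
  out <- abs(changes) >= policy$threshold_pct - 1e-9
  if (!policy$flag_energy && "energy" %in% names(out))
    out[["energy"]] <- FALSE
  out
}

#' Nutrient-density ratio of a composite to a pattern
#'
#' Ratio of per-100 kcal densities: how many times more (or less) of a
#' nutrient the composite supplies than the overall pattern per calorie.
#' Minimally processed meat, for instance, carries roughly 3.6x the
#' protein density and 4x the zinc density of the USP.
#'
#' @param comp a [composite_profile()]
#' @param pattern a [pattern_profile()]
#' @param key a panel nutrient id
#' @export
density_ratio <- function(comp, pattern, key) {
  stopifnot(inherits(comp, "composite_profile"),
            inherits(pattern, "pattern_profile"))
  key <- match.arg(key, panel_ids())
  num <- nv_per_100kcal(comp$per_serving)[[key]]
  den <- nv_per_100kcal(pattern$baseline)[[key]]
  if (is.na(den) || den <= 0)
    stop("undefined ratio: pattern density for ", key,
         " is zero or missing", call. = FALSE)
  num / den
}

#' Run a full removal scenario
#'
#' Composes serving removal, isocaloric adjustment, percent changes, and
#' meaningful-change flags for one (pattern, composite) pair.
#'
#' @inheritParams remove_serving
#' @param policy a [flag_policy()]
#' @return a `removal_result`: list with `pattern_id`, `composite_name`,
#'   `baseline`, `modified`, `isocaloric` (nutrient vectors),
#'   `pct_change_modified`, `pct_change_isocaloric` (named numeric), and
#'   `flags_modified`, `flags_isocaloric` (named logical, `NA` = not
#'   evaluable)
#' @export
run_scenario <- function(pattern, comp, serving = serving_spec(),
                         policy = flag_policy()) {
  modified <- remove_serving(pattern, comp, serving)
  isocaloric <- isocaloric_adjust(pattern, comp, serving)
  base <- pattern$baseline
  if (policy$basis == "rounded") {
    dec <- nutrient_panel()$display_decimals
    rd <- function(v) stats::setNames(
      mapply(round_half_away, as.numeric(v), dec), panel_ids())
    pcm <- percent_change(rd(base), rd(modified))
    pci <- percent_change(rd(base), rd(isocaloric))
  } else {
    pcm <- percent_change(unclass(base), unclass(modified))
    pci <- percent_change(unclass(base), unclass(isocaloric))
  }
  structure(list(
    pattern_id = pattern$pattern_id,
    composite_name = comp$name,
    serving = serving,
    policy = policy,
    baseline = base,
    modified = modified,
    isocaloric = isocaloric,
    pct_change_modified = pcm,
    pct_change_isocaloric = pci,
    flags_modified = flag_meaningful(pcm, policy),
    flags_isocaloric = flag_meaningful(pci, policy)
  ), class = "removal_result")
}

#' @export
print.removal_result <- function(x, ...) {
  cat(sprintf("<removal_result> %s - %s (%g x %g g serving, threshold %g%%)\n",
              x$pattern_id, x$composite_name, x$serving$servings,
              x$serving$grams, x$policy$threshold_pct))
  n_mod <- sum(x$flags_modified, na.rm = TRUE)
  n_iso <- sum(x$flags_isocaloric, na.rm = TRUE)
  cat(sprintf("  flagged (>=%g%%): %d after removal, %d after isocaloric removal\n",
              x$policy$threshold_pct, n_mod, n_iso))
  invisible(x)
}
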