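#' Display rounding
#'
#' All internal arithmetic is full precision; rounding happens only at
#' display time, using round-half-away-from-zero (the convention that
#' matches essentially all printed cells of the source tables, as opposed
#' to R's IEC 60559 banker's rounding). Trailing zeros are kept and signed
#' zero is normalized to `"0"`.
#'
#' @param value numeric (vectorized); `NA` renders as `"NA"`
#' @param decimals non-negative integer count of decimals to keep
#' @return character vector of formatted values
#' @examples
#' round_display(76.186, 1)   # "76.2"
#' round_display(1032.97, 0)  # "1033"
#' @export
round_display <- function(value, decimals) {
  if (any(decimals < 0)) stop("decimals must be >= 0", call. = FALSE)
  decimals <- rep_len(as.integer(decimals), length(value))
  r <- round_half_away(value, decimals)
  r[!is.na(r) & r == 0] <- 0  # normalize -0
  out <- character(length(value))
  for (d in unique(decimals)) {
    sel <- decimals == d
    out[sel] <- formatC(r[sel], format = "f", digits = d, big.mark = "")
  }
  out[is.na(value)] <- "NA"
  out
}

# numeric round-half-away-from-zero at d decimals (vectorized over both)
round_half_away <- function(x, d) {
  p <- 10^d
  sign(x) * trunc(abs(x) * p + 0.5) / p
}

#' Per-nutrient rounding specification
#'
#' @param decimals named integer vector keyed by nutrient id; keys omitted
#'   fall back to the panel's `display_decimals` defaults (derived from the
#'   printed precision of the baseline tables: energy 0, protein 1,
#'   cholesterol 0, zinc 2, ...).
#' @return named integer vector over the full panel
#' @export
rounding_spec <- function(decimals = NULL) {
  pan <- nutrient_panel()
  out <- stats::setNames(pan$display_decimals, pan$id)
  if (!is.null(decimals)) {
    check_panel_ids(names(decimals))
    if (any(decimals < 0)) stop("decimals must be >= 0", call. = FALSE)
    out[names(decimals)] <- as.integer(decimals)
  }
  out
}

#' Render removal results as a publication-style table
#'
#' One row per nutrient; per result, columns Baseline / After Removal /
#' After Isocaloric Removal. Cells whose unrounded change meets the flag
#' threshold are suffixed `" *"`; missing values render as `"NA"`.
#'
#' @param results a `removal_result` or list of them (sharing the panel)
#' @param spec a [rounding_spec()]
#' @param format `"csv"`, `"tsv"`, or `"markdown"`
#' @return a single string (lines joined by newline)
#' @export
render_table <- function(results, spec = rounding_spec(),
                         format = c("csv", "tsv", "markdown")) {
  if (inherits(results, "removal_result")) results <- list(results)
  if (!length(results)) stop("no results to render", call. = FALSE)
  if (!is.character(format) || !all(format %in% c("csv", "tsv", "markdown")))
    stop("unknown format: ", paste(setdiff(format, c("csv", "tsv", "markdown")),
                                   collapse = ", "), call. = FALSE)
  format <- match.arg(format)
  pan <- nutrient_panel()
  cols <- list(Nutrient = sprintf("%s (%s)", pan$display_name, pan$unit))
  for (r in results) {
    lab <- sprintf("%s %s", r$pattern_id, r$composite_name)
    star <- function(txt, flags) {
      ifelse(!is.na(flags) & flags, paste(txt, "*"), txt)
    }
    dec <- spec[pan$id]
    cols[[paste(lab, "Baseline")]] <-
      round_display(as.numeric(r$baseline), dec)
    cols[[paste(lab, "After Removal")]] <-
      star(round_display(as.numeric(r$modified), dec), r$flags_modified)
    cols[[paste(lab, "After Isocaloric Removal")]] <-
      star(round_display(as.numeric(r$isocaloric), dec), r$flags_isocaloric)
  }
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  switch(format,
    csv = df_to_delim(df, ","),
    tsv = df_to_delim(df, "\t"),
    markdown = df_to_markdown(df)
  )
}

# RFC-4180-style quoting: quote fields containing the delimiter, quotes,
# or newlines; double embedded quotes.
df_to_delim <- function(df, sep) {
  quote_field <- function(x) {
    need <- grepl(paste0("[\"\n", sep, "]"), x)
    x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
    x
  }
  body <- apply(df, 1L, function(row) paste(quote_field(row), collapse = sep))
  paste(c(paste(quote_field(names(df)), collapse = sep), body),
        collapse = "\n")
}

df_to_markdown <- function(df) {
  widths <- pmax(nchar(names(df)),
                 apply(df, 2L, function(x) max(nchar(x), 3L)))
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  hdr <- paste0("| ", paste(mapply(pad, names(df), widths), collapse = " | "),
                " |")
  rule <- paste0("|", paste(vapply(widths + 2L, function(w)
    strrep("-", w), character(1)), collapse = "|"), "|")
  body <- apply(df, 1L, function(row)
    paste0("| ", paste(mapply(pad, row, widths), collapse = " | "), " |"))
  paste(c(hdr, rule, body), collapse = "\n")
}
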