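# Packaged case studies: three exclusion scenarios (anticoagulants for
# AFib/VTE, CGRP-blocking migraine preventives, antipsoriatics) together
# with the printed reference tables they reproduce and an erratum registry
# for cells the stated rates cannot yield.

FIXTURE_NAMES <- c("anticoagulants", "migraine", "psoriasis")

# internal: path to a packaged data file
fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "formularyimpact")
  if (!nzchar(p)) stop(sprintf("packaged file missing: %s", file), call. = FALSE)
  p
}

#' Load a packaged case-study scenario
#'
#' @param name One of `"anticoagulants"`, `"migraine"`, `"psoriasis"`.
#' @return A validated `exclusion_scenario`.
#' @export
fixture_scenario <- function(name = FIXTURE_NAMES) {
  name <- match.arg(name)
  load_scenario(fixture_path(paste0(name, ".yaml")))
}

#' Load a packaged printed reference table
#'
#' Reference tables store each cell as printed — including the original
#' hyphen/en-dash mix and thousands separators — plus an erratum note for
#' cells that the model's stated rates cannot reproduce (typos and bound
#' conventions in the source tables). Erratum cells are reported but never
#' failed by [compare_to_reference()].
#'
#' @param name One of `"anticoagulants"`, `"migraine"`, `"psoriasis"`.
#' @return A `reference_table`: list with `name` and a `cells` tibble holding
#'   `formulary`, `medication`, `column`, `printed` (verbatim),
#'   `printed_low`/`printed_high` (parsed), and `erratum` (`NA` when clean).
#' @export
reference_table <- function(name = FIXTURE_NAMES) {
  name <- match.arg(name)
  raw <- utils::read.delim(fixture_path(paste0("reference_", name, ".tsv")),
                           sep = "\t", header = TRUE,
                           colClasses = "character", fill = TRUE,
                           quote = "", na.strings = NULL)
  if (!"erratum" %in% names(raw)) raw$erratum <- ""
  raw$erratum[is.na(raw$erratum)] <- ""
  parsed <- t(vapply(raw$printed, parse_printed_range, numeric(2)))
  cells <- tibble::tibble(
    formulary = raw$formulary,
    medication = raw$medication,
    column = raw$column,
    printed = raw$printed,
    printed_low = parsed[, 1],
    printed_high = parsed[, 2],
    erratum = ifelse(nzchar(raw$erratum), raw$erratum, NA_character_)
  )
  structure(list(name = name, cells = cells), class = "reference_table")
}

#' Parse a printed "low-high" cell
#'
#' Accepts both hyphen and en dash separators and ignores thousands
#' separators; the printed sources mix both dash forms.
#'
#' @param text A printed range such as `"734–1784"` or `"1,612-1,971"`.
#' @return Numeric vector `c(low, high)`.
#' @export
parse_printed_range <- function(text) {
  clean <- gsub(",", "", trimws(text))
  parts <- strsplit(clean, "[-–—]")[[1]]
  parts <- parts[nzchar(parts)]
  vals <- suppressWarnings(as.numeric(parts))
  if (length(vals) == 1L && !is.na(vals)) vals <- c(vals, vals)
  if (length(vals) != 2L || anyNA(vals) || any(vals < 0)) {
    stop(sprintf("cannot parse printed range '%s'", text), call. = FALSE)
  }
  unname(vals)
}

#' All packaged case studies
#'
#' @return A named list with one element per case study, each a list with
#'   `scenario` (an `exclusion_scenario`) and `reference` (a
#'   `reference_table`).
#' @examples
#' fx <- case_studies()
#' run_scenario(fx$anticoagulants$scenario)
#' @export
case_studies <- function() {
  out <- lapply(FIXTURE_NAMES, function(n) {
    list(scenario = fixture_scenario(n), reference = reference_table(n))
  })
  names(out) <- FIXTURE_NAMES
  out
}
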