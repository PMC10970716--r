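# Rounding and formatting to the printed-table conventions, table
# rendering, and golden comparison against printed reference tables.

#' Round half-up
#'
#' Commercial ("half-up") rounding, as used by the printed tables; base R's
#' `round()` rounds half to even and would disagree on exact halves.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Format a count in thousands for display
#'
#' Values of at least 10 print as integers (half-up, optional thousands
#' separator); values below 10 print with one decimal place, so small cells
#' like 0.6 thousand keep a significant digit.
#'
#' @param x Nonnegative numeric scalar (thousands of persons).
#' @param big_mark Thousands separator, default none (use `","` for the
#'   `1,612` style).
#' @return Character scalar.
#' @examples
#' format_count(1784.47)  # "1784"
#' format_count(0.64)     # "0.6"
#' @export
format_count <- function(x, big_mark = "") {
  stopifnot(is.numeric(x), length(x) == 1L)
  if (is.na(x) || x < 0) stop("format_count: x must be nonnegative", call. = FALSE)
  if (x >= 10) {
    formatC(round_half_up(x, 0), format = "f", digits = 0, big.mark = big_mark)
  } else {
    formatC(round_half_up(x, 1), format = "f", digits = 1)
  }
}

# internal: "low-high" display of a pair of bounds
format_range_cell <- function(low, high, big_mark = "") {
  paste0(format_count(low, big_mark), "-", format_count(high, big_mark))
}

# fixed column order of rendered tables
RENDER_COLUMNS <- c("Medication", "Market Share %", "Potentially Affected",
                    "Likely to Discontinue", "Adverse Events")

#' Render an impact table
#'
#' Deterministic column order (Medication, Market Share %, Potentially
#' Affected, Likely to Discontinue, Adverse Events), one block per
#' formulary. All numeric content is identical across styles; markdown adds
#' a heading per formulary while csv/tsv carry the formulary as a column.
#'
#' @param t An `impact_table` from [run_scenario()].
#' @param style `"csv"`, `"tsv"`, or `"markdown"`.
#' @return A single character scalar (the rendered table text).
#' @export
render_table <- function(t, style = c("markdown", "csv", "tsv")) {
  stopifnot(inherits(t, "impact_table"))
  style <- match.arg(style)
  rows <- t$rows
  cells <- data.frame(
    Formulary = rows$formulary,
    Medication = rows$medication,
    share = sprintf("%.2f", 100 * rows$share),
    affected = mapply(format_range_cell, rows$affected_low, rows$affected_high),
    discontinue = mapply(format_range_cell, rows$discontinue_low,
                         rows$discontinue_high),
    adverse = mapply(format_range_cell, rows$adverse_events_low,
                     rows$adverse_events_high),
    stringsAsFactors = FALSE
  )
  if (style %in% c("csv", "tsv")) {
    sep <- if (style == "csv") "," else "\t"
    header <- paste(c("Formulary", RENDER_COLUMNS), collapse = sep)
    body <- apply(cells, 1L, paste, collapse = sep)
    return(paste(c(header, body), collapse = "\n"))
  }
  # markdown: one block per formulary, in first-appearance order
  out <- character(0)
  for (f in unique(cells$Formulary)) {
    blk <- cells[cells$Formulary == f, -1L, drop = FALSE]
    out <- c(out,
             sprintf("## %s (%s, 000s)", f, t$scenario_name),
             "",
             paste0("| ", paste(RENDER_COLUMNS, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(RENDER_COLUMNS)),
                               collapse = "|"), "|"),
             apply(blk, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |")),
             "")
  }
  paste(out, collapse = "\n")
}

# internal: printed precision (decimal places) of a printed number string
printed_decimals <- function(text) {
  text <- gsub(",", "", trimws(text))
  if (grepl("\\.", text)) nchar(sub("^[^.]*\\.", "", text)) else 0L
}

#' Compare an impact table to a printed reference table
#'
#' For every reference cell, rounds the computed bounds half-up at the
#' precision of the corresponding printed bound and measures the difference
#' in printed units (one printed unit is one step in the last printed digit:
#' 1 for "734", 0.1 for "2.3", 0.01 for "0.06"). Cells carrying an erratum
#' flag are reported as `skipped_erratum` and never fail, whatever their
#' delta.
#'
#' @param t An `impact_table` from [run_scenario()].
#' @param ref A [reference_table()].
#' @param tol Tolerance in printed units (integer, default 1).
#' @return A `comparison_report`: list with `cells` (a tibble with per-cell
#'   status `match` / `within_tolerance` / `mismatch` / `skipped_erratum`
#'   and deltas in printed units) and `summary` (named status counts).
#' @export
compare_to_reference <- function(t, ref, tol = 1) {
  stopifnot(inherits(t, "impact_table"), inherits(ref, "reference_table"),
            is.numeric(tol), tol >= 0)
  col_map <- c(affected = "affected", discontinue = "discontinue",
               adverse_events = "adverse_events")
  out <- vector("list", nrow(ref$cells))
  for (i in seq_len(nrow(ref$cells))) {
    cell <- ref$cells[i, ]
    if (!cell$column %in% names(col_map)) {
      stop(sprintf("unknown reference column '%s'", cell$column), call. = FALSE)
    }
    row <- t$rows[t$rows$formulary == cell$formulary &
                    t$rows$medication == cell$medication, ]
    if (nrow(row) != 1L) {
      stop(sprintf("reference cell (%s, %s, %s) has no computed counterpart",
                   cell$formulary, cell$medication, cell$column),
           call. = FALSE)
    }
    comp_low <- row[[paste0(cell$column, "_low")]]
    comp_high <- row[[paste0(cell$column, "_high")]]
    bounds_txt <- strsplit(gsub(",", "", cell$printed), "[-–—]")[[1]]
    bounds_txt <- bounds_txt[nzchar(bounds_txt)]
    dec_low <- printed_decimals(bounds_txt[1])
    dec_high <- printed_decimals(bounds_txt[length(bounds_txt)])
    delta_low <- abs(round_half_up(comp_low, dec_low) - cell$printed_low) *
      10^dec_low
    delta_high <- abs(round_half_up(comp_high, dec_high) - cell$printed_high) *
      10^dec_high
    status <- if (!is.na(cell$erratum)) {
      "skipped_erratum"
    } else if (delta_low < 0.5 && delta_high < 0.5) {
      "match"
    } else if (delta_low <= tol + 1e-9 && delta_high <= tol + 1e-9) {
      "within_tolerance"
    } else {
      "mismatch"
    }
    out[[i]] <- tibble::tibble(
      formulary = cell$formulary, medication = cell$medication,
      column = cell$column, printed = cell$printed,
      computed_low = comp_low, computed_high = comp_high,
      delta_low = delta_low, delta_high = delta_high,
      status = status, erratum = cell$erratum)
  }
  cells <- do.call(rbind, out)
  summary <- table(factor(cells$status,
                          levels = c("match", "within_tolerance", "mismatch",
                                     "skipped_erratum")))
  structure(list(reference = ref$name, tolerance = tol,
                 cells = cells, summary = as.list(summary)),
            class = "comparison_report")
}

#' Number of non-erratum mismatches in a comparison report
#' @param report A `comparison_report`.
#' @return Integer count of `mismatch` cells.
#' @export
n_mismatches <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  sum(report$cells$status == "mismatch")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> vs reference '%s' (tolerance %g printed units)\n",
              x$reference, x$tolerance))
  cat(sprintf("  match: %d  within_tolerance: %d  mismatch: %d  skipped_erratum: %d\n",
              x$summary$match, x$summary$within_tolerance,
              x$summary$mismatch, x$summary$skipped_erratum))
  bad <- x$cells[x$cells$status %in% c("mismatch", "skipped_erratum"), ]
  if (nrow(bad)) {
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("  [%s] %s %s %s: printed %s, computed %.3g-%.3g\n",
                  bad$status[i], bad$formulary[i], bad$medication[i],
                  bad$column[i], bad$printed[i],
                  bad$computed_low[i], bad$computed_high[i]))
    }
  }
  invisible(x)
}

#' Serialize a comparison report to JSON
#' @param report A `comparison_report`.
#' @return A JSON string.
#' @export
comparison_to_json <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  jsonlite::toJSON(list(reference = report$reference,
                        tolerance = report$tolerance,
                        summary = report$summary,
                        cells = report$cells),
                   auto_unbox = TRUE, digits = NA, na = "null")
}
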