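# Factor attribution: which model input drives the spread of an output.
# Two statistics formalize the informal "largest source of variance" claim
# for a deterministic product cascade: (1) within-range attribution — for a
# single output cell, the share of log(high/low) contributed by each ranged
# factor; (2) cross-medication spread — how much wider the outputs of a
# share group are made by market-share differences than by any ranged
# factor.

#' Attribute an output cell's range width to its factors
#'
#' For a pure product `out = prod(f_i)` of positive bounded factors,
#' `log(out.high / out.low) = sum(log(f_i.high / f_i.low))`, so each
#' factor's share of the output's log-width is
#' `log(f_i.high / f_i.low) / log(out.high / out.low)`. Shares are
#' nonnegative and sum to one, and are invariant to units (persons vs
#' thousands). The coupled compound adverse-event rule enters as a single
#' composite factor whose ratio is that of its evaluated bounds.
#'
#' @param s A valid `exclusion_scenario`.
#' @param formulary Formulary name.
#' @param medication Medication brand name.
#' @param output `"affected"`, `"discontinue"`, or `"adverse_events"`.
#' @return An `attribution_report`: list with `output`, `output_range`, and
#'   `factors` — a tibble (`factor`, `low`, `high`, `ratio`, `share`) ranked
#'   by share, containing only the ranged (non-degenerate) factors.
#' @export
attribute_range_width <- function(s, formulary, medication,
                                  output = c("affected", "discontinue",
                                             "adverse_events")) {
  output <- match.arg(output)
  assert_valid_scenario(s)
  s$share_groups <- lapply(s$share_groups, normalize_shares)
  f <- find_formulary(s, formulary)
  fm <- find_medication(s, medication)
  om <- resolve_outcome_model(s, fm$med$outcome_model_id)

  factors <- c(
    list(covered_lives = bounded_range(covered_lives(s$population)),
         prevalence = s$indication$prevalence),
    lapply(s$indication$eligibility_factors, bounded_range),
    list(calibration = bounded_range(s$indication$calibration_factor),
         formulary_share = bounded_range(f$market_share),
         medication_share = bounded_range(fm$med$share))
  )
  if (output %in% c("discontinue")) {
    factors$discontinuation <- om$discontinuation
  }
  if (output == "adverse_events") {
    rule <- om$adverse_event_rule
    factors$adverse_event_rate <- if (rule$type == "flat_rate") {
      rule$rate
    } else {
      coupled_compound_rate(om$discontinuation,
                            rule$event_given_discontinuation,
                            rule$event_given_switch)
    }
  }

  lows <- vapply(factors, function(x) x$low, numeric(1))
  highs <- vapply(factors, function(x) x$high, numeric(1))
  if (any(lows <= 0)) {
    stop(sprintf("attribution undefined: factor '%s' has a zero low bound",
                 names(factors)[which(lows <= 0)[1]]), call. = FALSE)
  }
  out_range <- bounded_range(prod(lows) / 1000, prod(highs) / 1000)
  ratios <- highs / lows
  log_width <- sum(log(ratios))
  shares <- if (log_width > 0) log(ratios) / log_width else rep(0, length(ratios))

  tab <- tibble::tibble(factor = names(factors), low = unname(lows),
                        high = unname(highs), ratio = unname(ratios),
                        share = unname(shares))
  tab <- tab[tab$ratio > 1, , drop = FALSE]    # point factors carry no width
  tab <- tab[order(-tab$share), , drop = FALSE]
  structure(list(scenario = s$name, formulary = formulary,
                 medication = medication, output = output,
                 output_range = out_range, factors = tab),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("<attribution_report> %s / %s / %s, output %s\n",
              x$scenario, x$formulary, x$medication, format(x$output_range)))
  if (nrow(x$factors) == 0L) {
    cat("  no ranged factors (point-valued output)\n")
  } else {
    for (i in seq_len(nrow(x$factors))) {
      cat(sprintf("  %-22s ratio %6.3f  share %5.1f%%\n",
                  x$factors$factor[i], x$factors$ratio[i],
                  100 * x$factors$share[i]))
    }
  }
  invisible(x)
}

#' Cross-medication spread within a share group
#'
#' Market shares differ across the medications of a class far more than any
#' ranged rate differs across its bounds, so the share is typically the
#' dominant source of spread in the printed tables. This statistic reports
#' the max/min market-share ratio within a group (zero-share medications
#' excluded with a warning), the within-range ratios of every ranged factor,
#' the per-medication affected ranges, and which source dominates.
#'
#' @param s A valid `exclusion_scenario`.
#' @param formulary Formulary name.
#' @param group Share-group id.
#' @return A `spread_report`: list with `spread_factor` (max share / min
#'   share), `shares`, `within_factors` (factor, ratio), `dominant` (factor
#'   name; `"market_share"` when the spread exceeds every within-range
#'   ratio), and `affected` (per-medication ranges, thousands).
#' @export
cross_medication_spread <- function(s, formulary, group) {
  assert_valid_scenario(s)
  s$share_groups <- lapply(s$share_groups, normalize_shares)
  f <- find_formulary(s, formulary)
  g <- NULL
  for (gg in s$share_groups) if (gg$group_id == group) g <- gg
  if (is.null(g)) stop(sprintf("group '%s' not found", group), call. = FALSE)

  shares <- vapply(g$medications, function(m) m$share, numeric(1))
  names(shares) <- vapply(g$medications, function(m) m$brand_name, character(1))
  if (any(shares == 0)) {
    warning(sprintf("excluding %d zero-share medication(s) from the spread ratio",
                    sum(shares == 0)))
  }
  pos <- shares[shares > 0]
  spread <- if (length(pos) > 1L) max(pos) / min(pos) else 1

  within <- list(prevalence = s$indication$prevalence)
  for (m in g$medications) {
    om <- resolve_outcome_model(s, m$outcome_model_id)
    within[[paste0("discontinuation:", om$id)]] <- om$discontinuation
    rule <- om$adverse_event_rule
    within[[paste0("adverse_event_rate:", om$id)]] <-
      if (rule$type == "flat_rate") rule$rate else
        coupled_compound_rate(om$discontinuation,
                              rule$event_given_discontinuation,
                              rule$event_given_switch)
  }
  within <- within[!duplicated(names(within))]
  wlow <- vapply(within, function(x) x$low, numeric(1))
  whigh <- vapply(within, function(x) x$high, numeric(1))
  wratio <- ifelse(wlow > 0, whigh / wlow, Inf)
  within_tab <- tibble::tibble(factor = names(within), ratio = wratio)
  within_tab <- within_tab[order(-within_tab$ratio), , drop = FALSE]

  dominant <- if (spread > max(within_tab$ratio)) {
    "market_share"
  } else {
    within_tab$factor[1]
  }

  L <- covered_lives(s$population)
  pool <- affected_pool(L, s$indication, f)
  affected <- do.call(rbind, lapply(g$medications, function(m) {
    a <- medication_affected(pool, m$share)
    tibble::tibble(medication = m$brand_name, share = m$share,
                   affected_low = a$low, affected_high = a$high)
  }))

  structure(list(scenario = s$name, formulary = formulary, group = group,
                 spread_factor = spread, shares = shares,
                 within_factors = within_tab, dominant = dominant,
                 affected = affected),
            class = "spread_report")
}

#' @export
print.spread_report <- function(x, ...) {
  cat(sprintf("<spread_report> %s / %s / group '%s'\n",
              x$scenario, x$formulary, x$group))
  cat(sprintf("  market-share spread (max/min): %.3g\n", x$spread_factor))
  for (i in seq_len(nrow(x$within_factors))) {
    cat(sprintf("  within-range ratio %-28s %6.3f\n",
                x$within_factors$factor[i], x$within_factors$ratio[i]))
  }
  cat(sprintf("  dominant spread source: %s\n", x$dominant))
  invisible(x)
}

#' Serialize an attribution or spread report to JSON
#' @param report An `attribution_report` or `spread_report`.
#' @return A JSON string.
#' @export
sensitivity_to_json <- function(report) {
  if (inherits(report, "attribution_report")) {
    jsonlite::toJSON(list(kind = "attribution",
                          scenario = report$scenario,
                          formulary = report$formulary,
                          medication = report$medication,
                          output = report$output,
                          output_low = report$output_range$low,
                          output_high = report$output_range$high,
                          factors = report$factors),
                     auto_unbox = TRUE, digits = NA)
  } else if (inherits(report, "spread_report")) {
    jsonlite::toJSON(list(kind = "spread",
                          scenario = report$scenario,
                          formulary = report$formulary,
                          group = report$group,
                          spread_factor = report$spread_factor,
                          within_factors = report$within_factors,
                          dominant = report$dominant,
                          affected = report$affected),
                     auto_unbox = TRUE, digits = NA)
  } else {
    stop("not a sensitivity report", call. = FALSE)
  }
}

# internal lookups
find_formulary <- function(s, name) {
  for (f in s$formularies) if (f$name == name) return(f)
  stop(sprintf("formulary '%s' not found", name), call. = FALSE)
}

find_medication <- function(s, brand_name) {
  for (g in s$share_groups) {
    for (m in g$medications) {
      if (m$brand_name == brand_name) return(list(group = g, med = m))
    }
  }
  stop(sprintf("medication '%s' not found", brand_name), call. = FALSE)
}
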