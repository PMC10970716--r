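#' Covered lives
#'
#' Number of people whose pharmacy benefits fall under the formularies being
#' modeled: the total population times the sum of the covered segment
#' percentages. With the 2022 US inputs (333.3M total; 48.5% employer
#' private + 6.1% small-group private + 14.7% Medicare Part D = 69.3%) this
#' is about 231 million people.
#'
#' @param p A [population_model()].
#' @return Covered lives, persons.
#' @export
covered_lives <- function(p) {
  stopifnot(inherits(p, "population_model"))
  p$total_population *
    sum(vapply(p$segments, function(s) s$percent, numeric(1)))
}

#' Indication pool under one formulary
#'
#' The number of people (in thousands) with the indication whose benefits sit
#' under a given formulary: covered lives x prevalence x eligibility factors
#' x calibration factor x formulary market share, divided by 1000. All bounds
#' propagate coupled (bound-wise); there is no intermediate rounding.
#'
#' @param L Covered lives, persons (see [covered_lives()]).
#' @param ind An [indication()].
#' @param f A [formulary()].
#' @return A `bounded_range`, thousands of persons.
#' @export
affected_pool <- function(L, ind, f) {
  stopifnot(is.numeric(L), length(L) == 1L, L >= 0,
            inherits(ind, "indication"), inherits(f, "formulary"))
  factors <- c(
    list(covered_lives = L, prevalence = ind$prevalence),
    ind$eligibility_factors,
    list(calibration = ind$calibration_factor,
         formulary_share = f$market_share)
  )
  pool <- scenario_product(factors)
  bounded_range(pool$low / 1000, pool$high / 1000)
}

#' Patients affected for one medication
#'
#' Apportions a formulary's indication pool to a medication by its market
#' share (prescriptions for the medication over all prescriptions in its
#' class or subclass).
#'
#' @param pool A `bounded_range` pool in thousands (see [affected_pool()]).
#' @param share Market-share fraction in `[0, 1]`.
#' @return A `bounded_range`, thousands of persons.
#' @export
medication_affected <- function(pool, share) {
  pool <- as_bounded_range(pool)
  stopifnot(is.numeric(share), length(share) == 1L)
  if (share < 0 || share > 1) {
    stop(sprintf("share must be in [0, 1], got %g", share), call. = FALSE)
  }
  bounded_range(pool$low * share, pool$high * share)
}

#' Patients likely to discontinue therapy
#'
#' @param affected A `bounded_range` of affected patients (thousands).
#' @param om An [outcome_model()].
#' @return A `bounded_range`, thousands: affected times the discontinuation
#'   fraction, bound-wise.
#' @export
discontinuations <- function(affected, om) {
  affected <- as_bounded_range(affected)
  stopifnot(inherits(om, "outcome_model"))
  scenario_product(list(affected = affected,
                        discontinuation = om$discontinuation))
}

#' Patients likely to have adverse events
#'
#' Applies the outcome model's adverse-event rule to the affected range:
#' a flat rate multiplies directly; the coupled compound rule first evaluates
#' `e*d + s*(1 - d)` at aligned bounds ([coupled_compound_rate()]) or, in
#' `"conservative"` mode, takes the true envelope over the rate box
#' ([conservative_envelope()]).
#'
#' @param affected A `bounded_range` of affected patients (thousands).
#' @param om An [outcome_model()].
#' @param mode `"coupled"` (default; reproduces printed low/high tables) or
#'   `"conservative"`.
#' @return A `bounded_range`, thousands.
#' @export
adverse_events <- function(affected, om, mode = c("coupled", "conservative")) {
  affected <- as_bounded_range(affected)
  stopifnot(inherits(om, "outcome_model"))
  mode <- match.arg(mode)
  rule <- om$adverse_event_rule
  rate <- if (rule$type == "flat_rate") {
    rule$rate
  } else if (mode == "coupled") {
    coupled_compound_rate(om$discontinuation,
                          rule$event_given_discontinuation,
                          rule$event_given_switch)
  } else {
    conservative_envelope(om$discontinuation,
                          rule$event_given_discontinuation,
                          rule$event_given_switch)
  }
  scenario_product(list(affected = affected, adverse_event_rate = rate))
}

#' Run the full exclusion-impact cascade
#'
#' Executes the whole model for a scenario: covered lives, the indication
#' pool under each formulary, and per-medication affected / discontinuation /
#' adverse-event ranges. Deterministic; all quantities are carried in
#' thousands of persons with no intermediate rounding.
#'
#' Share groups are *views* of the same indication pool, not partitions of
#' it: when a scenario carries two subclasses of the same class (e.g.
#' monoclonal antibodies and small-molecule antagonists among CGRP-blocking
#' migraine preventives), each group's medications sum to the full pool, so
#' the cross-group total is deliberately a multiple of the pool.
#'
#' @param s A valid `exclusion_scenario` (shares normalized, as
#'   [load_scenario()] and [case_studies()] return them).
#' @param mode Adverse-event evaluation mode, `"coupled"` or
#'   `"conservative"`; see [adverse_events()].
#' @return An `impact_table`: a list with `scenario_name`, `mode`,
#'   `covered_lives` (persons), `rows` (a tibble with one row per formulary x
#'   medication and paired `*_low`/`*_high` columns in thousands), and
#'   `pools` (a tibble of per-formulary, per-group pool bounds).
#' @export
run_scenario <- function(s, mode = c("coupled", "conservative")) {
  mode <- match.arg(mode)
  assert_valid_scenario(s)
  s$share_groups <- lapply(s$share_groups, normalize_shares)
  L <- covered_lives(s$population)

  rows <- list()
  pools <- list()
  for (f in s$formularies) {
    for (g in s$share_groups) {
      pool <- affected_pool(L, s$indication, f)
      pools[[length(pools) + 1L]] <- tibble::tibble(
        formulary = f$name, group_id = g$group_id,
        pool_low = pool$low, pool_high = pool$high)
      for (m in g$medications) {
        om <- resolve_outcome_model(s, m$outcome_model_id)
        aff <- medication_affected(pool, m$share)
        dis <- discontinuations(aff, om)
        ae <- adverse_events(aff, om, mode = mode)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          formulary = f$name,
          medication = m$brand_name,
          generic_name = m$generic_name,
          group_id = g$group_id,
          share = m$share,
          affected_low = aff$low, affected_high = aff$high,
          discontinue_low = dis$low, discontinue_high = dis$high,
          adverse_events_low = ae$low, adverse_events_high = ae$high)
      }
    }
  }

  structure(list(scenario_name = s$name,
                 mode = mode,
                 covered_lives = L,
                 rows = do.call(rbind, rows),
                 pools = do.call(rbind, pools)),
            class = "impact_table")
}

#' @export
print.impact_table <- function(x, ...) {
  cat(sprintf("<impact_table> scenario '%s' (%s mode), %d rows, units: thousands\n",
              x$scenario_name, x$mode, nrow(x$rows)))
  print(x$rows, ...)
  invisible(x)
}
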