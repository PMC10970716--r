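#' Population coverage segment
#'
#' One slice of the national population whose pharmacy benefits are counted
#' as covered by the formularies under study (e.g. employer-sponsored private
#' insurance, small-group private insurance, Medicare Part D).
#'
#' @param name Segment label.
#' @param percent Fraction of the total population in this segment, in
#'   `[0, 1]`.
#' @return A `coverage_segment` object.
#' @export
coverage_segment <- function(name, percent) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(percent), length(percent) == 1L)
  if (percent < 0 || percent > 1) {
    stop(sprintf("coverage_segment '%s': percent must be in [0, 1], got %g",
                 name, percent), call. = FALSE)
  }
  structure(list(name = name, percent = as.numeric(percent)),
            class = "coverage_segment")
}

#' Population model
#'
#' The national population total plus the insurance segments counted as
#' covered lives. The covered-lives base is `total_population` times the sum
#' of the segment percentages (see [covered_lives()]).
#'
#' @param total_population Total population, persons, `> 0`.
#' @param segments List of [coverage_segment()] objects; their percents must
#'   sum to at most 1.
#' @return A `population_model` object.
#' @export
population_model <- function(total_population, segments) {
  stopifnot(is.numeric(total_population), length(total_population) == 1L)
  if (total_population <= 0) {
    stop("population_model: total_population must be positive", call. = FALSE)
  }
  stopifnot(is.list(segments))
  segments <- lapply(segments, function(s) {
    if (inherits(s, "coverage_segment")) s else coverage_segment(s$name, s$percent)
  })
  tot <- sum(vapply(segments, function(s) s$percent, numeric(1)))
  if (tot > 1 + 1e-9) {
    stop(sprintf("population_model: segment percents sum to %g > 1", tot),
         call. = FALSE)
  }
  structure(list(total_population = as.numeric(total_population),
                 segments = segments),
            class = "population_model")
}

#' Formulary
#'
#' A national formulary (typically run by a pharmacy benefit manager) and its
#' share of covered lives.
#'
#' @param name Formulary label, e.g. `"CVS"` or `"ESI"`.
#' @param market_share Fraction of covered lives under this formulary, in
#'   `(0, 1]`.
#' @return A `formulary` object.
#' @export
formulary <- function(name, market_share) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(market_share), length(market_share) == 1L)
  if (market_share <= 0 || market_share > 1) {
    stop(sprintf("formulary '%s': market_share must be in (0, 1], got %g",
                 name, market_share), call. = FALSE)
  }
  structure(list(name = name, market_share = as.numeric(market_share)),
            class = "formulary")
}

#' Indication
#'
#' The disease (or combined diseases) whose treatments are subject to
#' exclusion, with its prevalence interval among covered lives and any
#' multiplicative eligibility restrictions (e.g. "only the 33.3% with more
#' than 3 attacks per month are eligible for preventive treatment").
#'
#' @param name Indication label.
#' @param prevalence A `bounded_range` fraction of covered lives.
#' @param eligibility_factors Named numeric vector (or named list) of
#'   fractions in `(0, 1]`, applied multiplicatively in order.
#' @param calibration_factor A single fraction in `(0, 1]` scaling the
#'   indication pool; defaults to 1. Used when a source model documents an
#'   additional scaling whose components are not separately printed.
#' @param calibration_provenance Free-text note recording where a
#'   non-unit `calibration_factor` came from.
#' @return An `indication` object.
#' @export
indication <- function(name, prevalence, eligibility_factors = list(),
                       calibration_factor = 1.0,
                       calibration_provenance = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  prevalence <- check_fraction(prevalence, sprintf("indication '%s' prevalence", name))
  eligibility_factors <- as.list(eligibility_factors)
  for (i in seq_along(eligibility_factors)) {
    f <- eligibility_factors[[i]]
    lbl <- names(eligibility_factors)[i]
    if (is.null(lbl) || !nzchar(lbl)) lbl <- sprintf("eligibility factor %d", i)
    if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1) {
      stop(sprintf("indication '%s': %s must be a fraction in (0, 1]",
                   name, lbl), call. = FALSE)
    }
  }
  if (!is.numeric(calibration_factor) || length(calibration_factor) != 1L ||
      calibration_factor <= 0 || calibration_factor > 1) {
    stop(sprintf("indication '%s': calibration_factor must be in (0, 1]", name),
         call. = FALSE)
  }
  structure(list(name = name,
                 prevalence = prevalence,
                 eligibility_factors = eligibility_factors,
                 calibration_factor = as.numeric(calibration_factor),
                 calibration_provenance = calibration_provenance),
            class = "indication")
}

#' Medication
#'
#' One medication in a share group. Exactly one of `prescriptions` (a raw
#' count) or `share` (a fraction of the group) is given at construction;
#' after [normalize_shares()] every medication carries a `share` and the
#' shares of a group sum to one.
#'
#' @param brand_name,generic_name Medication names.
#' @param group_id Identifier of the share group (class or subclass) the
#'   medication belongs to.
#' @param outcome_model_id Identifier of the [outcome_model()] that applies.
#' @param prescriptions Optional nonnegative prescription count.
#' @param share Optional fraction in `[0, 1]`.
#' @param note Optional free-text annotation (e.g. an erratum note).
#' @return A `medication` object.
#' @export
medication <- function(brand_name, generic_name, group_id, outcome_model_id,
                       prescriptions = NULL, share = NULL, note = NULL) {
  stopifnot(is.character(brand_name), length(brand_name) == 1L,
            is.character(generic_name), length(generic_name) == 1L,
            is.character(group_id), length(group_id) == 1L,
            is.character(outcome_model_id), length(outcome_model_id) == 1L)
  if (is.null(prescriptions) && is.null(share)) {
    stop(sprintf("medication '%s': one of prescriptions or share is required",
                 brand_name), call. = FALSE)
  }
  if (!is.null(prescriptions) && !is.null(share)) {
    stop(sprintf("medication '%s': give prescriptions or share, not both",
                 brand_name), call. = FALSE)
  }
  if (!is.null(prescriptions) &&
      (!is.numeric(prescriptions) || prescriptions < 0)) {
    stop(sprintf("medication '%s': prescriptions must be a nonnegative count",
                 brand_name), call. = FALSE)
  }
  if (!is.null(share) && (!is.numeric(share) || share < 0 || share > 1)) {
    stop(sprintf("medication '%s': share must be a fraction in [0, 1]",
                 brand_name), call. = FALSE)
  }
  structure(list(brand_name = brand_name, generic_name = generic_name,
                 group_id = group_id, outcome_model_id = outcome_model_id,
                 prescriptions = prescriptions, share = share, note = note),
            class = "medication")
}

#' Share group
#'
#' A medication class or subclass within which market shares are defined:
#' each medication's share is its prescriptions divided by all prescriptions
#' in the group, so shares sum to one within a group.
#'
#' @param group_id Unique group identifier.
#' @param medications List of [medication()] objects, all with this
#'   `group_id`.
#' @return A `share_group` object (normalization status untouched; see
#'   [normalize_shares()]).
#' @export
share_group <- function(group_id, medications) {
  stopifnot(is.character(group_id), length(group_id) == 1L,
            is.list(medications), length(medications) > 0L)
  for (m in medications) {
    if (!inherits(m, "medication")) {
      stop("share_group: medications must be medication objects", call. = FALSE)
    }
    if (m$group_id != group_id) {
      stop(sprintf("share_group '%s': medication '%s' declares group '%s'",
                   group_id, m$brand_name, m$group_id), call. = FALSE)
    }
  }
  structure(list(group_id = group_id, medications = medications,
                 normalization = "within_group"),
            class = "share_group")
}

#' Outcome model
#'
#' The literature-derived outcome rates attached to a medication: a
#' discontinuation fraction range and an adverse-event rule. The rule is
#' either a flat rate applied to everyone affected, or a coupled compound
#' rule combining the event risk among discontinuers with the event risk
#' among the complementary switchers (see [coupled_compound_rate()]).
#'
#' @param id Unique identifier referenced by [medication()] objects.
#' @param discontinuation A `bounded_range` fraction.
#' @param adverse_event_rule A list: either
#'   `list(type = "flat_rate", rate = <bounded_range>)` or
#'   `list(type = "coupled_compound",
#'         event_given_discontinuation = <bounded_range>,
#'         event_given_switch = <bounded_range>)`.
#' @return An `outcome_model` object.
#' @export
outcome_model <- function(id, discontinuation, adverse_event_rule) {
  stopifnot(is.character(id), length(id) == 1L, is.list(adverse_event_rule))
  discontinuation <- check_fraction(discontinuation,
                                    sprintf("outcome_model '%s' discontinuation", id))
  type <- adverse_event_rule$type
  if (identical(type, "flat_rate")) {
    adverse_event_rule$rate <-
      check_fraction(adverse_event_rule$rate,
                     sprintf("outcome_model '%s' flat rate", id))
  } else if (identical(type, "coupled_compound")) {
    adverse_event_rule$event_given_discontinuation <-
      check_fraction(adverse_event_rule$event_given_discontinuation,
                     sprintf("outcome_model '%s' event_given_discontinuation", id))
    adverse_event_rule$event_given_switch <-
      check_fraction(adverse_event_rule$event_given_switch,
                     sprintf("outcome_model '%s' event_given_switch", id))
  } else {
    stop(sprintf("outcome_model '%s': unknown adverse_event_rule type '%s'",
                 id, as.character(type)), call. = FALSE)
  }
  structure(list(id = id, discontinuation = discontinuation,
                 adverse_event_rule = adverse_event_rule),
            class = "outcome_model")
}

#' Flat-rate adverse-event rule
#' @param rate A `bounded_range` fraction applied to everyone affected.
#' @return A rule list for [outcome_model()].
#' @export
flat_rate <- function(rate) {
  list(type = "flat_rate", rate = as_bounded_range(rate))
}

#' Coupled compound adverse-event rule
#' @param event_given_discontinuation,event_given_switch `bounded_range`
#'   fractions (event risk among discontinuers / among switchers).
#' @return A rule list for [outcome_model()].
#' @export
coupled_compound <- function(event_given_discontinuation, event_given_switch) {
  list(type = "coupled_compound",
       event_given_discontinuation = as_bounded_range(event_given_discontinuation),
       event_given_switch = as_bounded_range(event_given_switch))
}

#' Exclusion scenario
#'
#' The complete input of the impact model: population coverage, formularies,
#' indication, medication share groups, and outcome models.
#'
#' @param name Scenario label.
#' @param population A [population_model()].
#' @param formularies List of [formulary()] objects (nonempty).
#' @param indication An [indication()].
#' @param share_groups List of [share_group()] objects with unique ids.
#' @param outcome_models List of [outcome_model()] objects; every
#'   medication's `outcome_model_id` must resolve.
#' @param output_unit Output unit, currently `"thousands"`.
#' @param annotations Optional named list of documented, unused annotations.
#' @return A validated `exclusion_scenario` object.
#' @export
exclusion_scenario <- function(name, population, formularies, indication,
                               share_groups, outcome_models,
                               output_unit = "thousands",
                               annotations = NULL) {
  s <- structure(list(name = name, population = population,
                      formularies = formularies, indication = indication,
                      share_groups = share_groups,
                      outcome_models = outcome_models,
                      output_unit = output_unit,
                      annotations = annotations),
                 class = "exclusion_scenario")
  assert_valid_scenario(s)
  s
}

#' Validate a scenario, aggregating all errors
#'
#' Collects every violated invariant rather than stopping at the first, and
#' names the offending field path in each message.
#'
#' @param s An `exclusion_scenario` (or a structurally similar list).
#' @return Character vector of error messages; empty if valid.
#' @export
validate_scenario <- function(s) {
  errs <- character(0)
  add <- function(path, msg) errs <<- c(errs, sprintf("%s: %s", path, msg))

  if (!is.character(s$name) || length(s$name) != 1L || !nzchar(s$name)) {
    add("name", "must be a nonempty string")
  }

  p <- s$population
  if (is.null(p)) {
    add("population", "missing")
  } else {
    if (!is.numeric(p$total_population) || p$total_population <= 0) {
      add("population.total_population", "must be positive")
    }
    tot <- 0
    for (i in seq_along(p$segments)) {
      seg <- p$segments[[i]]
      path <- sprintf("population.segments[%d]", i)
      if (!is.numeric(seg$percent) || seg$percent < 0 || seg$percent > 1) {
        add(paste0(path, ".percent"), "must be a fraction in [0, 1]")
      } else {
        tot <- tot + seg$percent
      }
    }
    if (tot > 1 + 1e-9) add("population.segments", sprintf("percents sum to %g > 1", tot))
  }

  if (length(s$formularies) == 0L) add("formularies", "must be nonempty")
  for (i in seq_along(s$formularies)) {
    f <- s$formularies[[i]]
    if (!is.numeric(f$market_share) || f$market_share <= 0 || f$market_share > 1) {
      add(sprintf("formularies[%d].market_share", i), "must be in (0, 1]")
    }
  }

  ind <- s$indication
  if (is.null(ind)) {
    add("indication", "missing")
  } else {
    pr <- ind$prevalence
    if (!is_bounded_range(pr) || pr$low < 0 || pr$high > 1) {
      add("indication.prevalence", "must be a bounded_range within [0, 1]")
    }
    for (i in seq_along(ind$eligibility_factors)) {
      f <- ind$eligibility_factors[[i]]
      if (!is.numeric(f) || f <= 0 || f > 1) {
        add(sprintf("indication.eligibility_factors[%d]", i),
            "must be a fraction in (0, 1]")
      }
    }
    if (!is.numeric(ind$calibration_factor) ||
        ind$calibration_factor <= 0 || ind$calibration_factor > 1) {
      add("indication.calibration_factor", "must be in (0, 1]")
    }
  }

  om_ids <- vapply(s$outcome_models, function(m) m$id, character(1))
  if (anyDuplicated(om_ids)) add("outcome_models", "ids must be unique")

  gids <- vapply(s$share_groups, function(g) g$group_id, character(1))
  if (anyDuplicated(gids)) add("share_groups", "group_ids must be unique")
  for (gi in seq_along(s$share_groups)) {
    g <- s$share_groups[[gi]]
    gpath <- sprintf("share_groups[%d]", gi)
    if (length(g$medications) == 0L) add(gpath, "must contain medications")
    for (mi in seq_along(g$medications)) {
      m <- g$medications[[mi]]
      mpath <- sprintf("%s.medications[%d]", gpath, mi)
      if (is.null(m$share) && is.null(m$prescriptions)) {
        add(mpath, "needs share or prescriptions")
      }
      if (!is.null(m$share) && (m$share < 0 || m$share > 1)) {
        add(paste0(mpath, ".share"), "must be a fraction in [0, 1]")
      }
      if (!is.null(m$prescriptions) && m$prescriptions < 0) {
        add(paste0(mpath, ".prescriptions"), "must be nonnegative")
      }
      if (!m$outcome_model_id %in% om_ids) {
        add(paste0(mpath, ".outcome_model_id"),
            sprintf("'%s' does not resolve to an outcome model",
                    m$outcome_model_id))
      }
    }
  }

  if (!identical(s$output_unit, "thousands")) {
    add("output_unit", "must be 'thousands'")
  }

  errs
}

# internal: stop with all validation errors at once
assert_valid_scenario <- function(s) {
  errs <- validate_scenario(s)
  if (length(errs)) {
    stop("invalid scenario:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  }
  invisible(s)
}

#' Normalize market shares within a group
#'
#' Computes each medication's market share as its prescriptions divided by
#' all prescriptions in the group. When printed percentages (already
#' fractions) are supplied instead of counts, they are renormalized by their
#' own sum, so shares sum to exactly one either way (printed table columns
#' typically sum to 99.99--100.01% because of rounding).
#'
#' @param group A [share_group()].
#' @return The group with every medication's `share` populated and summing to
#'   one; `prescriptions` fields are preserved.
#' @export
normalize_shares <- function(group) {
  stopifnot(inherits(group, "share_group"))
  meds <- group$medications
  has_rx <- vapply(meds, function(m) !is.null(m$prescriptions), logical(1))
  has_sh <- vapply(meds, function(m) !is.null(m$share), logical(1))
  if (all(has_rx)) {
    w <- vapply(meds, function(m) m$prescriptions, numeric(1))
  } else if (all(has_sh)) {
    w <- vapply(meds, function(m) m$share, numeric(1))
  } else {
    stop(sprintf("share_group '%s': mix of prescription counts and shares",
                 group$group_id), call. = FALSE)
  }
  tot <- sum(w)
  if (tot <= 0) {
    stop(sprintf("share_group '%s': all weights are zero", group$group_id),
         call. = FALSE)
  }
  for (i in seq_along(meds)) meds[[i]]$share <- w[i] / tot
  group$medications <- meds
  group
}

#' @export
print.exclusion_scenario <- function(x, ...) {
  n_meds <- sum(vapply(x$share_groups, function(g) length(g$medications),
                       integer(1)))
  cat(sprintf("<exclusion_scenario> '%s'\n", x$name))
  cat(sprintf("  population: %.1fM, %d segments (covered lives %.1fM)\n",
              x$population$total_population / 1e6,
              length(x$population$segments),
              covered_lives(x$population) / 1e6))
  cat(sprintf("  formularies: %s\n",
              paste(vapply(x$formularies,
                           function(f) sprintf("%s (%.0f%%)", f$name,
                                               100 * f$market_share),
                           character(1)), collapse = ", ")))
  cat(sprintf("  indication: %s, prevalence %s\n",
              x$indication$name, format(x$indication$prevalence)))
  cat(sprintf("  medications: %d in %d group(s)\n",
              n_meds, length(x$share_groups)))
  invisible(x)
}

# internal: resolve a medication's outcome model
resolve_outcome_model <- function(s, outcome_model_id) {
  for (m in s$outcome_models) if (m$id == outcome_model_id) return(m)
  stop(sprintf("outcome model '%s' not found", outcome_model_id), call. = FALSE)
}
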