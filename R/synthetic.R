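# Seeded generator of random exclusion scenarios with the structural
# assumptions of the model: a covered-lives fraction, an ordered prevalence
# interval, market shares summing to one within each group, and bounded
# outcome rates. Used by the property-style tests to exercise every stage
# without external data.

#' Generator configuration
#'
#' Sampling intervals for every scenario ingredient. Fraction intervals must
#' lie within `[0, 1]`; a fixed seed makes [generate_scenario()] fully
#' deterministic.
#'
#' @param seed Integer seed for the generator's random stream.
#' @param n_groups Number of share groups.
#' @param n_medications Length-2 integer range of medications per group.
#' @param n_segments Length-2 integer range of coverage segments.
#' @param population Length-2 range of the total population (persons).
#' @param coverage Length-2 range of the covered-lives fraction.
#' @param n_formularies Number of formularies.
#' @param formulary_share Length-2 range of formulary market shares.
#' @param prevalence_low Length-2 range for the prevalence low bound.
#' @param prevalence_width Length-2 range for the prevalence interval width.
#' @param discontinuation Length-2 interval the discontinuation bounds are
#'   drawn from (as an ordered pair).
#' @param event_rate Length-2 interval adverse-event-rate bounds are drawn
#'   from.
#' @param rule_mix Probability that a group's outcome model uses the coupled
#'   compound rule rather than a flat rate.
#' @return A `generator_config` object.
#' @export
generator_config <- function(seed = 1L,
                             n_groups = 2L,
                             n_medications = c(2L, 5L),
                             n_segments = c(2L, 4L),
                             population = c(5e7, 5e8),
                             coverage = c(0.4, 0.8),
                             n_formularies = 2L,
                             formulary_share = c(0.05, 0.45),
                             prevalence_low = c(0.005, 0.08),
                             prevalence_width = c(0.001, 0.05),
                             discontinuation = c(0.02, 0.4),
                             event_rate = c(0.02, 0.6),
                             rule_mix = 0.5) {
  check_interval <- function(x, what, lo = -Inf, hi = Inf) {
    if (!is.numeric(x) || length(x) != 2L || x[1] > x[2] ||
        x[1] < lo || x[2] > hi) {
      stop(sprintf("generator_config: %s must be an ordered pair within [%g, %g]",
                   what, lo, hi), call. = FALSE)
    }
  }
  stopifnot(is.numeric(seed), length(seed) == 1L,
            n_groups >= 1L, n_formularies >= 1L,
            is.numeric(rule_mix), rule_mix >= 0, rule_mix <= 1)
  if (n_medications[1] < 1L) {
    stop("generator_config: n_medications must allow at least one medication",
         call. = FALSE)
  }
  check_interval(n_medications, "n_medications", 1)
  check_interval(n_segments, "n_segments", 1)
  check_interval(population, "population", 1)
  check_interval(coverage, "coverage", 0, 1)
  check_interval(formulary_share, "formulary_share", 1e-6, 1)
  check_interval(prevalence_low, "prevalence_low", 0, 1)
  check_interval(prevalence_width, "prevalence_width", 0, 1)
  check_interval(discontinuation, "discontinuation", 0, 1)
  check_interval(event_rate, "event_rate", 0, 1)
  structure(list(seed = as.integer(seed), n_groups = as.integer(n_groups),
                 n_medications = as.integer(n_medications),
                 n_segments = as.integer(n_segments),
                 population = population, coverage = coverage,
                 n_formularies = as.integer(n_formularies),
                 formulary_share = formulary_share,
                 prevalence_low = prevalence_low,
                 prevalence_width = prevalence_width,
                 discontinuation = discontinuation,
                 event_rate = event_rate, rule_mix = rule_mix),
            class = "generator_config")
}

# internal: draw an ordered (low, high) pair uniformly within an interval
draw_ordered_pair <- function(interval) {
  v <- sort(stats::runif(2, interval[1], interval[2]))
  bounded_range(v[1], v[2])
}

#' Generate a random exclusion scenario
#'
#' Draws a complete, valid scenario from a [generator_config()]: segment and
#' medication weights come from a symmetric-Dirichlet-style scheme (positive
#' gamma draws normalized to sum to one), rate bounds are drawn as ordered
#' pairs, and one outcome model is created per share group. The generator
#' runs one seeded random stream per call and records the seed in the
#' scenario name, so a fixed config reproduces the scenario exactly.
#'
#' @param cfg A `generator_config`.
#' @return A validated `exclusion_scenario` with normalized shares.
#' @export
generate_scenario <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)

  total <- stats::runif(1, cfg$population[1], cfg$population[2])
  nseg <- sample(seq(cfg$n_segments[1], cfg$n_segments[2]), 1L)
  wseg <- stats::rgamma(nseg, shape = 1)
  cover <- stats::runif(1, cfg$coverage[1], cfg$coverage[2])
  segs <- lapply(seq_len(nseg), function(i) {
    coverage_segment(sprintf("segment-%d", i), cover * wseg[i] / sum(wseg))
  })

  fmls <- lapply(seq_len(cfg$n_formularies), function(i) {
    formulary(sprintf("formulary-%d", i),
              stats::runif(1, cfg$formulary_share[1], cfg$formulary_share[2]))
  })

  plow <- stats::runif(1, cfg$prevalence_low[1], cfg$prevalence_low[2])
  pwidth <- stats::runif(1, cfg$prevalence_width[1], cfg$prevalence_width[2])
  prev <- bounded_range(plow, min(plow + pwidth, 1))
  n_elig <- sample(0:2, 1L)
  elig <- list()
  if (n_elig > 0) {
    for (i in seq_len(n_elig)) {
      elig[[sprintf("eligibility-%d", i)]] <- stats::runif(1, 0.2, 1)
    }
  }
  ind <- indication("synthetic indication", prev, elig,
                    calibration_factor = stats::runif(1, 0.7, 1))

  oms <- list()
  grps <- list()
  for (gi in seq_len(cfg$n_groups)) {
    om_id <- sprintf("om-%d", gi)
    disc <- draw_ordered_pair(cfg$discontinuation)
    rule <- if (stats::runif(1) < cfg$rule_mix) {
      e <- draw_ordered_pair(cfg$event_rate)
      # the switch risk stays below the discontinuation event risk, the
      # structural assumption under which the coupled pairing is coherent
      sv <- sort(stats::runif(2, 0, e$low))
      coupled_compound(e, bounded_range(sv[1], sv[2]))
    } else {
      flat_rate(draw_ordered_pair(cfg$event_rate))
    }
    oms[[gi]] <- outcome_model(om_id, disc, rule)

    k <- sample(seq(cfg$n_medications[1], cfg$n_medications[2]), 1L)
    w <- stats::rgamma(k, shape = 1)
    gid <- sprintf("group-%d", gi)
    meds <- lapply(seq_len(k), function(mi) {
      medication(sprintf("med-%d-%d", gi, mi),
                 sprintf("generic-%d-%d", gi, mi),
                 gid, om_id, share = w[mi] / sum(w))
    })
    grps[[gi]] <- share_group(gid, meds)
  }

  exclusion_scenario(
    name = sprintf("synthetic-seed-%d", cfg$seed),
    population = population_model(total, segs),
    formularies = fmls,
    indication = ind,
    share_groups = grps,
    outcome_models = oms
  )
}

#' Scale one factor of a scenario
#'
#' Returns a copy of the scenario with a single scalable quantity multiplied
#' by `multiplier`, everything else untouched. Supports the linearity,
#' monotonicity, and normalization-invariance property checks.
#'
#' Recognized factors: `"prevalence"` (both bounds), `"population"`,
#' `"calibration"`, `"market_share:<formulary name>"`,
#' `"eligibility:<label>"`, and `"group_weights:<group_id>"` (scales every
#' share in the group and renormalizes, which leaves the model's outputs
#' unchanged).
#'
#' @param s An `exclusion_scenario`.
#' @param factor Factor name, see above.
#' @param multiplier Positive scale factor; the result must still satisfy
#'   all scenario invariants (e.g. scaled fractions must stay within
#'   bounds).
#' @return A validated, scaled `exclusion_scenario`.
#' @export
perturb_scenario <- function(s, factor, multiplier) {
  stopifnot(inherits(s, "exclusion_scenario"),
            is.character(factor), length(factor) == 1L,
            is.numeric(multiplier), length(multiplier) == 1L, multiplier > 0)
  if (factor == "prevalence") {
    p <- s$indication$prevalence
    s$indication$prevalence <- bounded_range(p$low * multiplier,
                                             p$high * multiplier)
  } else if (factor == "population") {
    s$population$total_population <- s$population$total_population * multiplier
  } else if (factor == "calibration") {
    s$indication$calibration_factor <-
      s$indication$calibration_factor * multiplier
  } else if (startsWith(factor, "market_share:")) {
    name <- sub("^market_share:", "", factor)
    hit <- FALSE
    for (i in seq_along(s$formularies)) {
      if (s$formularies[[i]]$name == name) {
        s$formularies[[i]]$market_share <-
          s$formularies[[i]]$market_share * multiplier
        hit <- TRUE
      }
    }
    if (!hit) stop(sprintf("formulary '%s' not found", name), call. = FALSE)
  } else if (startsWith(factor, "eligibility:")) {
    label <- sub("^eligibility:", "", factor)
    if (!label %in% names(s$indication$eligibility_factors)) {
      stop(sprintf("eligibility factor '%s' not found", label), call. = FALSE)
    }
    s$indication$eligibility_factors[[label]] <-
      s$indication$eligibility_factors[[label]] * multiplier
  } else if (startsWith(factor, "group_weights:")) {
    gid <- sub("^group_weights:", "", factor)
    hit <- FALSE
    for (i in seq_along(s$share_groups)) {
      if (s$share_groups[[i]]$group_id == gid) {
        meds <- s$share_groups[[i]]$medications
        for (j in seq_along(meds)) {
          if (!is.null(meds[[j]]$prescriptions)) {
            meds[[j]]$prescriptions <- meds[[j]]$prescriptions * multiplier
          } else {
            # scale as raw weights: move to prescriptions space so the
            # within-[0,1] share invariant cannot be violated pre-normalization
            meds[[j]]$prescriptions <- meds[[j]]$share * multiplier
            meds[[j]]$share <- NULL
          }
        }
        s$share_groups[[i]]$medications <- meds
        s$share_groups[[i]] <- normalize_shares(s$share_groups[[i]])
        hit <- TRUE
      }
    }
    if (!hit) stop(sprintf("group '%s' not found", gid), call. = FALSE)
  } else {
    stop(sprintf("unknown scalable factor '%s'", factor), call. = FALSE)
  }
  assert_valid_scenario(s)
  s
}
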