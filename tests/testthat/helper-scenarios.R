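# Shared oracles and hand-built scenarios for the suite.

# Brute-force corner oracle for a product of bounded factors: enumerate all
# 2^k low/high combinations and take min/max. Valid for comparing against
# the coupled product because a nonnegative product is monotone in each
# factor.
corner_product_range <- function(factors) {
  combos <- expand.grid(lapply(factors, function(f) c(f[1], f[2])))
  vals <- apply(combos, 1L, prod)
  c(min(vals), max(vals))
}

# Corner oracle for e*d + s*(1-d) over the box d x e x s (multilinear, so
# corners attain the extrema).
corner_compound_range <- function(d, e, s) {
  g <- expand.grid(d = d, e = e, s = s)
  vals <- g$e * g$d + g$s * (1 - g$d)
  c(min(vals), max(vals))
}

# A small fully hand-specified scenario used across module tests.
tiny_scenario <- function() {
  exclusion_scenario(
    name = "tiny",
    population = population_model(1e6, list(
      coverage_segment("covered", 0.5))),
    formularies = list(formulary("A", 0.4), formulary("B", 0.2)),
    indication = indication("toy disease", bounded_range(0.01, 0.02)),
    share_groups = list(share_group("g1", list(
      medication("m1", "gen1", "g1", "om1", share = 0.75),
      medication("m2", "gen2", "g1", "om1", share = 0.25)))),
    outcome_models = list(outcome_model(
      "om1", bounded_range(0.1, 0.2),
      flat_rate(bounded_range(0.3, 0.5))))
  )
}

# Independent per-cell recomputation of the whole cascade with plain
# arithmetic (no package cascade calls): the oracle run_scenario must match.
oracle_impact <- function(s) {
  L <- s$population$total_population *
    sum(vapply(s$population$segments, function(x) x$percent, numeric(1)))
  ind <- s$indication
  elig <- prod(unlist(ind$eligibility_factors), 1)
  out <- list()
  for (f in s$formularies) {
    base_low <- L * ind$prevalence$low * elig * ind$calibration_factor *
      f$market_share / 1000
    base_high <- L * ind$prevalence$high * elig * ind$calibration_factor *
      f$market_share / 1000
    for (g in s$share_groups) {
      meds <- normalize_shares(g)$medications
      for (m in meds) {
        om <- NULL
        for (o in s$outcome_models) if (o$id == m$outcome_model_id) om <- o
        a_lo <- base_low * m$share
        a_hi <- base_high * m$share
        d <- om$discontinuation
        rule <- om$adverse_event_rule
        if (rule$type == "flat_rate") {
          r_lo <- rule$rate$low; r_hi <- rule$rate$high
        } else {
          e <- rule$event_given_discontinuation
          sw <- rule$event_given_switch
          r_lo <- e$low * d$low + sw$low * (1 - d$low)
          r_hi <- e$high * d$high + sw$high * (1 - d$high)
        }
        out[[length(out) + 1L]] <- data.frame(
          formulary = f$name, medication = m$brand_name, group_id = g$group_id,
          affected_low = a_lo, affected_high = a_hi,
          discontinue_low = a_lo * d$low, discontinue_high = a_hi * d$high,
          adverse_events_low = a_lo * r_lo, adverse_events_high = a_hi * r_hi,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# Draw a random fraction range (ordered pair) for property tests.
random_fraction_range <- function() {
  v <- sort(runif(2))
  bounded_range(v[1], v[2])
}

# Draw a random (d, e, s) triple satisfying the coupled rule's structural
# assumption: the event risk among switchers never exceeds the risk among
# discontinuers (s$high <= e$low).
random_compound_inputs <- function() {
  d <- random_fraction_range()
  e <- random_fraction_range()
  sv <- sort(runif(2, 0, e$low))
  list(d = d, e = e, s = bounded_range(sv[1], sv[2]))
}
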