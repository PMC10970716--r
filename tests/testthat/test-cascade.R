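test_that("covered lives is total population times summed segment percents", {
  us <- population_model(333.3e6, list(
    coverage_segment("employer private", 0.485),
    coverage_segment("small group private", 0.061),
    coverage_segment("Medicare Part D", 0.147)))
  L <- covered_lives(us)
  expect_equal(L, 333.3e6 * 0.693, tolerance = 1e-12)
  # within 0.1% of the quoted ~230.9 million
  expect_lt(abs(L - 230.9e6) / 230.9e6, 0.001)
  expect_equal(covered_lives(population_model(5e5, list(
    coverage_segment("all", 1)))), 5e5)
  expect_equal(covered_lives(population_model(5e5, list())), 0)
})

test_that("affected_pool runs the pool chain in thousands", {
  ind <- indication("AFib/VTE", bounded_range(0.014, 0.034))
  cvs <- formulary("CVS", 0.33)
  pool <- affected_pool(230.9e6, ind, cvs)
  expect_equal(pool$low, 230.9e6 * 0.014 * 0.33 / 1000, tolerance = 1e-9)
  expect_equal(round(pool$high, 1), 2590.7)      # the "800k to 2.6M" upper pool
  # zero prevalence gives an empty pool
  empty <- affected_pool(230.9e6, indication("none", bounded_range(0, 0)), cvs)
  expect_equal(c(empty$low, empty$high), c(0, 0))
  # calibration is linear
  half <- indication("AFib/VTE", bounded_range(0.014, 0.034),
                     calibration_factor = 0.5)
  ph <- affected_pool(230.9e6, half, cvs)
  expect_equal(c(ph$low, ph$high), c(pool$low, pool$high) / 2, tolerance = 1e-12)
})

test_that("medication_affected apportions the pool by share and conserves it", {
  pool <- bounded_range(1066.8, 2590.7)
  r <- medication_affected(pool, 0.6888)
  expect_equal(round(r$low, 1), 734.8)
  expect_equal(round(r$high, 1), 1784.5)
  expect_true(medication_affected(pool, 1) == pool)
  shares <- c(0.5, 0.3, 0.2)
  parts <- lapply(shares, function(sh) medication_affected(pool, sh))
  expect_equal(sum(vapply(parts, function(p) p$low, numeric(1))), pool$low,
               tolerance = 1e-9)
  expect_equal(sum(vapply(parts, function(p) p$high, numeric(1))), pool$high,
               tolerance = 1e-9)
  expect_error(medication_affected(pool, 1.2), "\\[0, 1\\]")
})

test_that("discontinuations and adverse events apply the outcome model bound-wise", {
  om_cc <- outcome_model("ac", bounded_range(0.17, 0.30),
                         coupled_compound(bounded_range(0.45, 0.85),
                                          bounded_range(0.02, 0.10)))
  aff <- bounded_range(734.8, 1784.5)
  d <- discontinuations(aff, om_cc)
  expect_equal(round(c(d$low, d$high), 1), c(124.9, 535.4))
  ae <- adverse_events(aff, om_cc)
  expect_equal(round(c(ae$low, ae$high), 1), c(68.4, 580.0))

  om_flat <- outcome_model("ps", bounded_range(0.06, 0.09),
                           flat_rate(bounded_range(0.15, 0.35)))
  af <- adverse_events(bounded_range(444.9, 889.7), om_flat)
  expect_equal(round(c(af$low, af$high), 1), c(66.7, 311.4))

  zero <- outcome_model("z", bounded_range(0, 0),
                        flat_rate(bounded_range(0, 0)))
  expect_equal(discontinuations(aff, zero)$high, 0)
  expect_equal(adverse_events(aff, zero)$high, 0)
})

test_that("run_scenario matches the independent per-cell arithmetic oracle", {
  s <- tiny_scenario()
  t <- run_scenario(s)
  want <- oracle_impact(s)
  expect_equal(nrow(t$rows), nrow(want))
  for (col in c("affected_low", "affected_high", "discontinue_low",
                "discontinue_high", "adverse_events_low",
                "adverse_events_high")) {
    expect_equal(t$rows[[col]], want[[col]], tolerance = 1e-12)
  }
})

test_that("pool conservation holds per formulary and share group", {
  for (s in list(tiny_scenario(), fixture_scenario("anticoagulants"),
                 fixture_scenario("migraine"))) {
    t <- run_scenario(s)
    for (i in seq_len(nrow(t$pools))) {
      p <- t$pools[i, ]
      rows <- t$rows[t$rows$formulary == p$formulary &
                       t$rows$group_id == p$group_id, ]
      expect_equal(sum(rows$affected_low), p$pool_low,
                   tolerance = 1e-6 * p$pool_low)
      expect_equal(sum(rows$affected_high), p$pool_high,
                   tolerance = 1e-6 * p$pool_high)
    }
  }
})

test_that("migraine subclasses are views of one pool, so the cross-group sum doubles it", {
  t <- run_scenario(fixture_scenario("migraine"))
  cvs <- t$pools[t$pools$formulary == "CVS", ]
  expect_equal(nrow(cvs), 2)
  expect_equal(cvs$pool_low[1], cvs$pool_low[2], tolerance = 1e-12)
  rows <- t$rows[t$rows$formulary == "CVS", ]
  expect_equal(sum(rows$affected_low), 2 * cvs$pool_low[1], tolerance = 1e-9)
})

test_that("outputs are ordered ranges dominated by the affected count", {
  for (s in list(fixture_scenario("anticoagulants"),
                 fixture_scenario("psoriasis"))) {
    t <- run_scenario(s)
    r <- t$rows
    expect_true(all(r$affected_low <= r$affected_high))
    expect_true(all(r$discontinue_low <= r$discontinue_high))
    expect_true(all(r$adverse_events_low <= r$adverse_events_high))
    expect_true(all(r$discontinue_low <= r$affected_low + 1e-12))
    expect_true(all(r$discontinue_high <= r$affected_high + 1e-12))
    expect_true(all(r$adverse_events_low <= r$affected_low + 1e-12))
    expect_true(all(r$adverse_events_high <= r$affected_high + 1e-12))
  }
})

test_that("formulary outputs scale exactly by the market-share ratio", {
  t <- run_scenario(fixture_scenario("anticoagulants"))
  cvs <- t$rows[t$rows$formulary == "CVS", ]
  esi <- t$rows[t$rows$formulary == "ESI", ]
  expect_equal(esi$affected_low / cvs$affected_low,
               rep(0.24 / 0.33, nrow(cvs)), tolerance = 1e-12)
  expect_equal(esi$adverse_events_high / cvs$adverse_events_high,
               rep(0.24 / 0.33, nrow(cvs)), tolerance = 1e-12)
})

test_that("conservative mode widens or preserves every adverse-event range", {
  s <- fixture_scenario("anticoagulants")
  cpl <- run_scenario(s, mode = "coupled")
  env <- run_scenario(s, mode = "conservative")
  expect_true(all(env$rows$adverse_events_low <=
                    cpl$rows$adverse_events_low + 1e-12))
  expect_true(all(env$rows$adverse_events_high >=
                    cpl$rows$adverse_events_high - 1e-12))
  # affected and discontinue are monotone products: identical across modes
  expect_equal(env$rows$affected_high, cpl$rows$affected_high)
  expect_equal(env$rows$discontinue_low, cpl$rows$discontinue_low)
})

test_that("eligibility factors multiply order-independently", {
  base <- tiny_scenario()
  a <- base; a$indication$eligibility_factors <- list(x = 0.5, y = 0.8)
  b <- base; b$indication$eligibility_factors <- list(y = 0.8, x = 0.5)
  ta <- run_scenario(a); tb <- run_scenario(b)
  expect_equal(ta$rows$affected_high, tb$rows$affected_high, tolerance = 1e-12)
})
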