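test_that("constructors enforce domain invariants", {
  expect_error(coverage_segment("x", 1.2), "\\[0, 1\\]")
  expect_error(population_model(-5, list()), "positive")
  expect_error(population_model(100, list(coverage_segment("a", 0.7),
                                          coverage_segment("b", 0.6))),
               "sum")
  expect_error(formulary("F", 0), "\\(0, 1\\]")
  expect_error(indication("i", bounded_range(0.5, 2)), "\\[0, 1\\]")
  expect_error(medication("m", "g", "grp", "om"), "prescriptions or share")
  expect_error(medication("m", "g", "grp", "om", prescriptions = 10,
                          share = 0.5), "not both")
  expect_error(outcome_model("om", bounded_range(0.1, 0.2),
                             list(type = "nonsense")), "unknown")
})

test_that("scenario validation aggregates errors with field paths", {
  s <- tiny_scenario()
  s$formularies[[1]]$market_share <- 2        # invalid
  s$share_groups[[1]]$medications[[1]]$share <- -0.1
  s$share_groups[[1]]$medications[[2]]$outcome_model_id <- "missing"
  errs <- validate_scenario(s)
  expect_length(errs, 3)
  expect_match(errs, "formularies\\[1\\].market_share", all = FALSE)
  expect_match(errs, "share_groups\\[1\\].medications\\[1\\].share", all = FALSE)
  expect_match(errs, "does not resolve", all = FALSE)
})

test_that("normalize_shares divides counts by the group total", {
  g <- share_group("ac", list(
    medication("Eliquis", "apixaban", "ac", "om", prescriptions = 6888),
    medication("Xarelto", "rivaroxaban", "ac", "om", prescriptions = 2976),
    medication("Pradaxa", "dabigatran", "ac", "om", prescriptions = 131),
    medication("Savaysa", "edoxaban", "ac", "om", prescriptions = 6)))
  gn <- normalize_shares(g)
  shares <- vapply(gn$medications, function(m) m$share, numeric(1))
  w <- c(6888, 2976, 131, 6)
  expect_equal(shares, w / sum(w), tolerance = 1e-12)  # direct-division oracle
  expect_equal(sum(shares), 1, tolerance = 1e-12)
  # matches the printed percentages within rounding
  expect_equal(shares, c(68.88, 29.76, 1.31, 0.06) / 100, tolerance = 5e-4)
})

test_that("normalize_shares renormalizes printed percentages by their own sum", {
  g <- share_group("g", list(
    medication("a", "a", "g", "om", share = 0.6888),
    medication("b", "b", "g", "om", share = 0.2976),
    medication("c", "c", "g", "om", share = 0.0131),
    medication("d", "d", "g", "om", share = 0.0006)))
  shares <- vapply(normalize_shares(g)$medications, function(m) m$share,
                   numeric(1))
  expect_equal(sum(shares), 1, tolerance = 1e-12)
  # single medication gets the full share; all-zero weights are rejected
  g1 <- share_group("g", list(medication("only", "o", "g", "om", share = 0.4)))
  expect_equal(normalize_shares(g1)$medications[[1]]$share, 1)
  g0 <- share_group("g", list(medication("z", "z", "g", "om", prescriptions = 0)))
  expect_error(normalize_shares(g0), "zero")
})

test_that("scenario files round-trip through YAML and JSON", {
  s <- tiny_scenario()
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    save_scenario(s, path)
    s2 <- load_scenario(path)
    expect_true(scenario_equal(s, s2))
    # byte-stable second save
    path2 <- withr::local_tempfile(fileext = paste0(".", ext))
    save_scenario(s2, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("percent and fraction spellings load to the same scenario", {
  frac <- withr::local_tempfile(fileext = ".yaml")
  pct <- withr::local_tempfile(fileext = ".yaml")
  make_config <- function(seg, fml, shr) c(
    "name: spelled",
    "population:",
    "  total: 1000000",
    "  segments:",
    paste0("    - {name: covered, ", seg, "}"),
    "formularies:",
    paste0("  - {name: A, ", fml, "}"),
    "indication:",
    "  name: d",
    "  prevalence: {low: 0.01, high: 0.02}",
    "share_groups:",
    "  - group_id: g",
    "    medications:",
    paste0("      - {brand_name: m, generic_name: m, ", shr,
           ", outcome_model: om}"),
    "outcome_models:",
    "  - id: om",
    "    discontinuation: {low: 0.1, high: 0.2}",
    "    adverse_event_rule: {type: flat_rate, rate: {low: 0.3, high: 0.5}}")
  writeLines(make_config("fraction: 0.5", "market_share: 0.4", "share: 1.0"),
             frac)
  writeLines(make_config("percent: 50", "market_share_percent: 40",
                         "share_percent: 100"), pct)
  expect_true(scenario_equal(load_scenario(frac), load_scenario(pct)))
})

test_that("invalid configs report every offending field, not just the first", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "name: broken",
    "population:",
    "  total: -5",
    "  segments:",
    "    - {name: covered, fraction: 0.5}",
    "formularies:",
    "  - {name: A, market_share: 1.5}",
    "indication:",
    "  name: d",
    "  prevalence: {low: 0.02, high: 0.01}",
    "share_groups:",
    "  - group_id: g",
    "    medications:",
    "      - {brand_name: m, generic_name: m, share: -0.1, outcome_model: om}",
    "outcome_models:",
    "  - id: om",
    "    discontinuation: {low: 0.1, high: 0.2}",
    "    adverse_event_rule: {type: flat_rate, rate: {low: 0.3, high: 0.5}}"),
    path)
  err <- tryCatch(load_scenario(path), error = function(e) conditionMessage(e))
  expect_match(err, "population.total")
  expect_match(err, "formularies\\[1\\].market_share")
  expect_match(err, "indication.prevalence")
  expect_match(err, "medications\\[1\\].share")
})

test_that("saving an invalid scenario is rejected before writing", {
  s <- tiny_scenario()
  s$formularies <- list()
  path <- withr::local_tempfile(fileext = ".yaml")
  expect_error(save_scenario(s, path), "formularies")
  expect_false(file.exists(path))
})

test_that("packaged fixtures validate, normalize, and carry the study inputs", {
  fx <- case_studies()
  expect_named(fx, c("anticoagulants", "migraine", "psoriasis"))
  for (f in fx) {
    expect_length(validate_scenario(f$scenario), 0)
    for (g in f$scenario$share_groups) {
      shares <- vapply(g$medications, function(m) m$share, numeric(1))
      expect_equal(sum(shares), 1, tolerance = 1e-9)
    }
  }
  ac <- fx$anticoagulants$scenario
  shares <- vapply(ac$share_groups[[1]]$medications, function(m) m$share,
                   numeric(1))
  # printed percentages (sum 100.01) renormalized
  expect_equal(shares, c(68.88, 29.76, 1.31, 0.06) / 100.01, tolerance = 1e-9)
  expect_equal(ac$indication$prevalence$low, 0.014)
  expect_equal(ac$indication$prevalence$high, 0.034)
  # psoriasis prevalence low implies ~3.46M US cases before formulary share
  ps <- fx$psoriasis$scenario
  expect_equal(covered_lives(ps$population) * ps$indication$prevalence$low / 1e6,
               3.46, tolerance = 0.01)
  # migraine calibration is explicit, flagged, and overridable
  mg <- fx$migraine$scenario
  expect_lt(mg$indication$calibration_factor, 1)
  expect_match(mg$indication$calibration_provenance, "calibrated")
  expect_equal(length(mg$share_groups), 2)
})

test_that("fixture round-trips reproduce the loaded scenario", {
  s <- fixture_scenario("anticoagulants")
  path <- withr::local_tempfile(fileext = ".yaml")
  save_scenario(s, path)
  expect_true(scenario_equal(s, load_scenario(path)))
})
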