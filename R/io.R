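# Scenario configuration I/O.
#
# Canonical on-disk form is YAML; JSON is accepted (and written when the file
# extension is .json). Percentages may be written either as fractions
# (`fraction: 0.485` / `share: 0.6888`) or as percents (`percent: 48.5` /
# `share_percent: 68.88`); they are stored internally as fractions. A
# descriptive schema ships at `system.file("schema", "scenario-schema.json",
# package = "formularyimpact")`.

# internal: read a fraction that may be expressed as a percent
read_fraction <- function(node, frac_key, pct_key, path, errs) {
  has_frac <- !is.null(node[[frac_key]])
  has_pct <- !is.null(node[[pct_key]])
  if (has_frac && has_pct) {
    errs$add(path, sprintf("give %s or %s, not both", frac_key, pct_key))
    return(NA_real_)
  }
  if (has_frac) return(as.numeric(node[[frac_key]]))
  if (has_pct) return(as.numeric(node[[pct_key]]) / 100)
  NA_real_
}

# internal: parse a {low, high} mapping (optionally percent-scaled)
read_range <- function(node, path, errs, percent = FALSE) {
  if (is.null(node) || is.null(node$low) || is.null(node$high)) {
    errs$add(path, "must be a mapping with 'low' and 'high'")
    return(NULL)
  }
  scale <- if (percent || identical(node$unit, "%")) 1 / 100 else 1
  lo <- as.numeric(node$low) * scale
  hi <- as.numeric(node$high) * scale
  tryCatch(bounded_range(lo, hi), error = function(e) {
    errs$add(path, conditionMessage(e))
    NULL
  })
}

# internal: tiny error collector with field paths
error_collector <- function() {
  errs <- character(0)
  list(
    add = function(path, msg) errs <<- c(errs, sprintf("%s: %s", path, msg)),
    all = function() errs
  )
}

#' Load a scenario configuration
#'
#' Reads a YAML (canonical) or JSON scenario file, resolves percents to
#' fractions, normalizes market shares (whether given as prescription counts
#' or printed percentages), and validates. Validation errors are aggregated —
#' every offending field path is reported, not just the first.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return A validated `exclusion_scenario` with all shares normalized.
#' @seealso [save_scenario()], [case_studies()]
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop(sprintf("scenario file not found: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  scenario_from_list(raw, source = path)
}

#' Build a scenario from a plain configuration list
#'
#' The list form mirrors the YAML schema. Used by [load_scenario()]; exposed
#' for programmatic construction from other sources.
#'
#' @param raw A nested list as produced by parsing a scenario file.
#' @param source Label used in error messages.
#' @return A validated `exclusion_scenario`.
#' @export
scenario_from_list <- function(raw, source = "<list>") {
  errs <- error_collector()

  name <- raw$name
  if (is.null(name) || !nzchar(name)) errs$add("name", "required")

  pop <- NULL
  if (is.null(raw$population)) {
    errs$add("population", "required")
  } else {
    segs <- list()
    for (i in seq_along(raw$population$segments)) {
      sn <- raw$population$segments[[i]]
      p <- read_fraction(sn, "fraction", "percent",
                         sprintf("population.segments[%d]", i), errs)
      if (is.na(p)) {
        errs$add(sprintf("population.segments[%d]", i),
                 "needs 'fraction' or 'percent'")
      } else if (p < 0 || p > 1) {
        errs$add(sprintf("population.segments[%d]", i),
                 sprintf("fraction %g outside [0, 1]", p))
      } else {
        segs[[length(segs) + 1L]] <-
          coverage_segment(sn$name %||% sprintf("segment %d", i), p)
      }
    }
    tot <- as.numeric(raw$population$total %||% raw$population$total_population %||% NA)
    if (is.na(tot) || tot <= 0) {
      errs$add("population.total", "must be a positive number")
    } else if (length(errs$all()) == 0L) {
      pop <- tryCatch(population_model(tot, segs), error = function(e) {
        errs$add("population", conditionMessage(e)); NULL
      })
    }
  }

  fmls <- list()
  if (length(raw$formularies) == 0L) errs$add("formularies", "must be nonempty")
  for (i in seq_along(raw$formularies)) {
    fn <- raw$formularies[[i]]
    sh <- read_fraction(fn, "market_share", "market_share_percent",
                        sprintf("formularies[%d]", i), errs)
    if (is.na(sh) || sh <= 0 || sh > 1) {
      errs$add(sprintf("formularies[%d].market_share", i),
               "must be a fraction in (0, 1]")
    } else {
      fmls[[length(fmls) + 1L]] <- formulary(fn$name %||% sprintf("F%d", i), sh)
    }
  }

  ind <- NULL
  if (is.null(raw$indication)) {
    errs$add("indication", "required")
  } else {
    rn <- raw$indication
    prev <- read_range(rn$prevalence, "indication.prevalence", errs)
    elig <- list()
    for (i in seq_along(rn$eligibility_factors)) {
      en <- rn$eligibility_factors[[i]]
      v <- read_fraction(en, "fraction", "percent",
                         sprintf("indication.eligibility_factors[%d]", i), errs)
      if (is.na(v) || v <= 0 || v > 1) {
        errs$add(sprintf("indication.eligibility_factors[%d]", i),
                 "must be a fraction in (0, 1]")
      } else {
        elig[[en$label %||% sprintf("eligibility %d", i)]] <- v
      }
    }
    calib <- as.numeric(rn$calibration_factor %||% 1.0)
    if (!is.null(prev) && calib > 0 && calib <= 1) {
      ind <- indication(rn$name %||% "indication", prev, elig, calib,
                        rn$calibration_provenance)
    } else if (calib <= 0 || calib > 1) {
      errs$add("indication.calibration_factor", "must be in (0, 1]")
    }
  }

  oms <- list()
  for (i in seq_along(raw$outcome_models)) {
    on <- raw$outcome_models[[i]]
    opath <- sprintf("outcome_models[%d]", i)
    disc <- read_range(on$discontinuation, paste0(opath, ".discontinuation"), errs)
    rule <- on$adverse_event_rule
    parsed_rule <- NULL
    if (is.null(rule) || is.null(rule$type)) {
      errs$add(paste0(opath, ".adverse_event_rule"), "requires a 'type'")
    } else if (rule$type == "flat_rate") {
      r <- read_range(rule$rate, paste0(opath, ".adverse_event_rule.rate"), errs)
      if (!is.null(r)) parsed_rule <- flat_rate(r)
    } else if (rule$type == "coupled_compound") {
      e <- read_range(rule$event_given_discontinuation,
                      paste0(opath, ".adverse_event_rule.event_given_discontinuation"),
                      errs)
      sw <- read_range(rule$event_given_switch,
                       paste0(opath, ".adverse_event_rule.event_given_switch"),
                       errs)
      if (!is.null(e) && !is.null(sw)) parsed_rule <- coupled_compound(e, sw)
    } else {
      errs$add(paste0(opath, ".adverse_event_rule.type"),
               sprintf("unknown type '%s'", rule$type))
    }
    if (!is.null(disc) && !is.null(parsed_rule)) {
      oms[[length(oms) + 1L]] <- tryCatch(
        outcome_model(on$id %||% sprintf("om%d", i), disc, parsed_rule),
        error = function(e) { errs$add(opath, conditionMessage(e)); NULL })
    }
  }
  oms <- Filter(Negate(is.null), oms)

  grps <- list()
  for (gi in seq_along(raw$share_groups)) {
    gn <- raw$share_groups[[gi]]
    gpath <- sprintf("share_groups[%d]", gi)
    gid <- gn$group_id %||% sprintf("group%d", gi)
    meds <- list()
    for (mi in seq_along(gn$medications)) {
      mn <- gn$medications[[mi]]
      mpath <- sprintf("%s.medications[%d]", gpath, mi)
      sh <- read_fraction(mn, "share", "share_percent", mpath, errs)
      rx <- mn$prescriptions
      if (is.na(sh) && is.null(rx)) {
        errs$add(mpath, "needs 'share', 'share_percent', or 'prescriptions'")
        next
      }
      if (!is.na(sh) && (sh < 0 || sh > 1)) {
        errs$add(paste0(mpath, ".share"),
                 sprintf("fraction %g outside [0, 1]", sh))
        next
      }
      med <- tryCatch(
        medication(mn$brand_name %||% sprintf("med%d", mi),
                   mn$generic_name %||% "",
                   gid,
                   mn$outcome_model %||% mn$outcome_model_id %||% "",
                   prescriptions = if (is.null(rx)) NULL else as.numeric(rx),
                   share = if (is.na(sh)) NULL else sh,
                   note = mn$note),
        error = function(e) { errs$add(mpath, conditionMessage(e)); NULL })
      if (!is.null(med)) meds[[length(meds) + 1L]] <- med
    }
    if (length(meds)) {
      g <- tryCatch(share_group(gid, meds), error = function(e) {
        errs$add(gpath, conditionMessage(e)); NULL
      })
      if (!is.null(g)) {
        g <- tryCatch(normalize_shares(g), error = function(e) {
          errs$add(gpath, conditionMessage(e)); NULL
        })
      }
      if (!is.null(g)) grps[[length(grps) + 1L]] <- g
    } else {
      errs$add(gpath, "contains no loadable medications")
    }
  }

  if (length(errs$all())) {
    stop(sprintf("invalid scenario config '%s':\n  %s", source,
                 paste(errs$all(), collapse = "\n  ")), call. = FALSE)
  }

  s <- structure(list(name = name, population = pop, formularies = fmls,
                      indication = ind, share_groups = grps,
                      outcome_models = oms,
                      output_unit = raw$output_unit %||% "thousands",
                      annotations = raw$annotations),
                 class = "exclusion_scenario")
  assert_valid_scenario(s)
  s
}

#' Serialize a scenario to a plain list
#'
#' Inverse of [scenario_from_list()] up to share normalization: fractions are
#' written as fractions, shares as normalized shares.
#'
#' @param s An `exclusion_scenario`.
#' @return A nested list mirroring the YAML schema.
#' @export
scenario_to_list <- function(s) {
  list(
    name = s$name,
    population = list(
      total = s$population$total_population,
      segments = lapply(s$population$segments, function(seg) {
        list(name = seg$name, fraction = seg$percent)
      })
    ),
    formularies = lapply(s$formularies, function(f) {
      list(name = f$name, market_share = f$market_share)
    }),
    indication = {
      ind <- s$indication
      out <- list(name = ind$name,
                  prevalence = list(low = ind$prevalence$low,
                                    high = ind$prevalence$high))
      if (length(ind$eligibility_factors)) {
        out$eligibility_factors <- lapply(
          seq_along(ind$eligibility_factors), function(i) {
            list(label = names(ind$eligibility_factors)[i],
                 fraction = ind$eligibility_factors[[i]])
          })
      }
      out$calibration_factor <- ind$calibration_factor
      if (!is.null(ind$calibration_provenance)) {
        out$calibration_provenance <- ind$calibration_provenance
      }
      out
    },
    share_groups = lapply(s$share_groups, function(g) {
      list(group_id = g$group_id,
           medications = lapply(g$medications, function(m) {
             out <- list(brand_name = m$brand_name,
                         generic_name = m$generic_name,
                         outcome_model = m$outcome_model_id)
             # exactly one weight field round-trips; shares re-derive from
             # counts at load time
             if (!is.null(m$prescriptions)) {
               out$prescriptions <- m$prescriptions
             } else {
               out$share <- m$share
             }
             if (!is.null(m$note)) out$note <- m$note
             out
           }))
    }),
    outcome_models = lapply(s$outcome_models, function(m) {
      rule <- m$adverse_event_rule
      r <- if (rule$type == "flat_rate") {
        list(type = "flat_rate",
             rate = list(low = rule$rate$low, high = rule$rate$high))
      } else {
        list(type = "coupled_compound",
             event_given_discontinuation =
               list(low = rule$event_given_discontinuation$low,
                    high = rule$event_given_discontinuation$high),
             event_given_switch =
               list(low = rule$event_given_switch$low,
                    high = rule$event_given_switch$high))
      }
      list(id = m$id,
           discontinuation = list(low = m$discontinuation$low,
                                  high = m$discontinuation$high),
           adverse_event_rule = r)
    }),
    output_unit = s$output_unit,
    annotations = s$annotations
  )
}

#' Save a scenario configuration
#'
#' Writes YAML (default) or JSON depending on the file extension. The written
#' form reloads to an equal scenario, and saving twice produces byte-stable
#' output.
#'
#' @param s A valid `exclusion_scenario`.
#' @param path Destination path; `.json` selects JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(s, path) {
  assert_valid_scenario(s)
  lst <- scenario_to_list(s)
  lst$annotations <- lst$annotations %||% NULL
  lst <- Filter(Negate(is.null), lst)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path, precision = 15)
  }
  invisible(path)
}

#' Structural scenario equality
#'
#' Compares two scenarios field by field with a numeric tolerance, ignoring
#' representation details (such as whether shares were loaded from counts or
#' percentages) only insofar as both sides are normalized.
#'
#' @param a,b `exclusion_scenario` objects.
#' @param tol Absolute numeric tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
scenario_equal <- function(a, b, tol = 1e-9) {
  num_eq <- function(x, y) {
    if (is.null(x) && is.null(y)) return(TRUE)
    if (is.null(x) || is.null(y)) return(FALSE)
    abs(x - y) <= tol
  }
  la <- scenario_to_list(a)
  lb <- scenario_to_list(b)
  cmp <- function(x, y) {
    if (is.numeric(x) && is.numeric(y)) return(num_eq(x, y))
    if (is.list(x) && is.list(y)) {
      if (length(x) != length(y)) return(FALSE)
      if (!identical(sort(names(x) %||% character(0)),
                     sort(names(y) %||% character(0)))) return(FALSE)
      nm <- names(x)
      idx <- if (is.null(nm)) seq_along(x) else nm
      all(vapply(idx, function(i) cmp(x[[i]], y[[i]]), logical(1)))
    } else {
      identical(x, y)
    }
  }
  cmp(la, lb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
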