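---
title: "The formulary-exclusion impact model: structure, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The formulary-exclusion impact model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formularyimpact)
```

## The question the model answers

When a pharmacy benefit manager (PBM) excludes a medication from a national
formulary, every patient taking that medication under that formulary must
switch to a different active ingredient (therapeutic substitution) or stop
treatment. The model in this package estimates, for a candidate exclusion,
three population quantities: how many people are *potentially affected*, how
many are *likely to discontinue* therapy altogether, and how many are likely
to have *adverse events* (worsening disease after discontinuation plus side
effects of a forced switch).

## The cascade

The model is a deterministic multiplicative cascade. For a formulary $F$ and
a medication $m$ in class (or subclass) $g$:

$$
A_{F,m} \;=\; \underbrace{P \textstyle\sum_i c_i}_{\text{covered lives } L}
\;\times\; p \;\times\; \prod_j f_j \;\times\; \kappa
\;\times\; m_F \;\times\; m_d ,
$$

where $P$ is the total population, $c_i$ the insurance-segment fractions
counted as covered (employer private, small-group private, Medicare Part D),
$p$ the indication prevalence, $f_j$ optional eligibility restrictions
(e.g. only the 33.3% of migraine patients with more than three attacks per
month qualify for preventive treatment), $\kappa$ a calibration factor
(below), $m_F$ the formulary's market share of covered lives, and $m_d$ the
medication's market share of prescriptions within its class. Downstream,

$$
D_{F,m} = A_{F,m} \cdot d, \qquad
E_{F,m} = A_{F,m} \cdot r,
$$

with $d$ the discontinuation fraction and $r$ the adverse-event rate, either
a flat rate or the coupled compound rate

$$
r \;=\; e\,d + s\,(1 - d),
$$

combining the event risk $e$ among discontinuers with the risk $s$ among the
$1-d$ who switch. All outputs are carried in thousands of persons as reals;
nothing is rounded inside the cascade, only at display time.

## Coupled bounds, not intervals

Every ranged input is a `bounded_range`: a low/high pair in which each bound
belongs to one coherent scenario. The low bound of every output is computed
with *all* inputs at their low value, and the high bound with all inputs at
their high value — including the complement $1-d$ inside the compound rate,
which is evaluated at the same scenario's $d$ (so the low scenario uses the
*largest* switching share). For a product of nonnegative factors this coupled
evaluation coincides with the true interval extremes, because the product is
monotone in each factor. For the compound rate it does not: the true
minimum/maximum of $e\,d + s\,(1-d)$ over the input box (available as
`conservative_envelope()`, computed by corner enumeration — the expression is
multilinear, so corners suffice) can be wider. The package defaults to the
coupled semantics because that is what published low/high tables in this
genre print; `run_scenario(..., mode = "conservative")` switches every
compound adverse-event cell to the envelope.

The coupled pairing is only coherent when the pessimistic evaluation
dominates the optimistic one. That is guaranteed when the event risk among
discontinuers is at least the risk among switchers ($e_{\text{low}} \ge
s_{\text{high}}$; in the anticoagulant case study, 45–85% versus 2–10%).
When inputs violate it, `coupled_compound_rate()` refuses with a pointer to
the envelope rather than silently returning an inverted pair. Relatedly,
`range_complement()` returns a scenario-*aligned* pair that is numerically
decreasing whenever the input has positive width; it is deliberately not a
`bounded_range` and is the single documented exemption from the low ≤ high
invariant.

## Inputs, units, and the packaged case studies

Scenarios are YAML (canonical) or JSON files; percentages may be written as
percents or fractions and are stored as fractions; medication weights may be
prescription counts or printed percentages, and either way shares are
normalized within each class to sum to exactly one (printed percentage
columns sum to 99.99–100.01% because of rounding; renormalizing by their own
sum both fixes that and makes pool conservation exact). A descriptive JSON
schema ships under `inst/schema/`; validation is implemented natively and
reports *every* offending field path at once rather than failing on the
first.

Three case studies ship as data files, with the model inputs that underlie
them:

* **anticoagulants** — combined atrial-fibrillation/venous-thromboembolism
  prevalence 1.4–3.4% (bound-wise sum of 1.0–2.9% and 0.4–0.5%, precomputed
  into one range in the fixture), discontinuation 17–30%, coupled compound
  adverse events with $e$ = 45–85% and $s$ = 2–10%;
* **migraine** — prevalence 9.5–11.6%, eligibility 33.3%, discontinuation
  9–19%, flat adverse-event rate 50%; two share groups (CGRP monoclonal
  antibodies; gepants) that are alternative *views* of the same eligible
  pool, not partitions — each group's shares sum to one over the full pool,
  so the cross-group total is deliberately twice the pool;
* **psoriasis** — prevalence 1.5–3%, one share group of nineteen agents in
  which TNF inhibitors carry discontinuation 6–9% and all other agents
  9–19% (outcome models therefore attach per medication, by id), flat
  adverse-event rate 15–35%.

Both modeled formularies (CVS, 33% of covered lives; ESI, 24%) are present
in every scenario, so each table prints one block per formulary and every
output pair stands in the exact ratio 0.24/0.33.

### The migraine calibration factor

The migraine reference table's affected pools are ≈0.837× what covered
lives × prevalence × eligibility × formulary share yields; the residual
scaling evidently comes from an input documented only in supplementary
material that is not part of the printed record. Back-division of the
reference pools gives 0.8368 at the low bound and 0.8379 at the high bound;
the fixture freezes the midpoint, 0.8374, as an explicit
`calibration_factor` with `calibration_provenance:
"calibrated_to_table_2"`. Making the factor an ordinary, overridable input
keeps the reproduction honest: set it to 1 to see the uncalibrated model.
The fixture also stores, as a documented *unused* annotation, the statement
that only 40% of treated patients continue older (non-CGRP) preventives
after six months: no pipeline step consistent with the printed tables
consumes it, and inventing one would contradict the tables.

### The covered-lives base and the ±1 tolerance

Covered lives are computed exactly: 333.3M × (48.5% + 6.1% + 14.7%) =
230.98M. The printed record itself mixes hand-rounded bases (some cells
back-derive from 230.8M, others from 230.9M), so its cells are reproducible
only to about one printed unit. The golden comparison therefore rounds the
computed value half-up *at the precision of each printed bound* (one unit is
1 for "734", 0.1 for "2.3", 0.01 for "0.06") and accepts a default tolerance
of one printed unit. This is tight enough that any real modeling bug —
a wrong rate, share, or bound pairing — produces mismatches.

### Errata

A small registry of reference cells is flagged as errata and reported but
never failed: a discontinuation high bound printed as 103 where the stated
19% of 662 gives ≈126; one printed as 19 where 19% of ≈196 gives ≈37; an
entire adverse-event column printed with the 35% rate at *both* bounds
instead of 15–35%; a cell printed as ".04" where the stated rates give
≈0.4; and one adverse-event low bound printed as 0.2 where 15% of the
affected count gives ≈0.5. Two label errata are recorded as notes in the
fixtures (a brand attributed to the wrong generic name; the prose swapping
the two formularies' totals relative to the table). The registry keeps the
typos visible while letting the comparison certify the model.

## Sensitivity statistics

"Which input drives the spread?" is formalized as two separate, exactly
computable statistics rather than one conflated number:

* **Within-range attribution** (`attribute_range_width()`): for a product
  output, $\log(\text{high}/\text{low})$ decomposes additively over the
  factors, so each ranged factor's share is its log-ratio over the output's
  log-ratio. Shares are nonnegative, sum to one, and are invariant to units;
  the compound adverse-event rate enters as one composite factor (the ratio
  of its evaluated bounds). Attribution requires strictly positive low
  bounds and is refused otherwise.
* **Cross-medication spread** (`cross_medication_spread()`): the max/min
  market-share ratio within a class, compared against every within-range
  factor ratio. In the anticoagulant case study the share spread
  (0.6888/0.0006 ≈ 1148) dwarfs the widest ranged factor (prevalence,
  0.034/0.014 ≈ 2.43), so market share is ranked the dominant source of
  cross-row spread — the model's way of making precise the observation that
  any medication above a few percent market share moves tens of thousands
  to millions of people.

## The synthetic-scenario generator

`generate_scenario()` draws complete scenarios with the structure the model
assumes — a covered-lives fraction (0.4–0.8 of a 50–500M population split
over 2–4 segments), two formularies with shares 5–45%, an ordered prevalence
interval (low 0.5–8%, width 0.1–5%), 0–2 eligibility factors, per-group
outcome models mixing flat and coupled rules (discontinuation 2–40%, event
rates 2–60%, switch risk drawn below the discontinuation event risk so the
coupled pairing stays coherent), and Dirichlet-style shares (positive gamma
weights, normalized). These defaults were chosen once to bracket the three
case studies' magnitudes generously. One seeded stream per call makes
generation byte-reproducible; the seed is recorded in the scenario name.

The generator emulates the *structure* of real scenario inputs, not their
provenance: real prevalence ranges come from overlapping epidemiological
studies and real shares from prescription databases, with correlations and
reporting biases no uniform draw reproduces. Passing property tests on
generated scenarios therefore certifies the arithmetic and the invariants
(conservation of the pool across shares, linearity in every single factor,
bound ordering, oracle equivalence), not the realism of any particular
estimate.

## Numerical choices

Pure arithmetic throughout; no iterative numerics. Range-comparison
tolerances in the tests are absolute 1e-9 on fractions and 1e-6 (relative)
on counts. Display rounding is half-up (`round_half_up()`), matching
commercial table conventions rather than R's round-half-even; values below
10 thousand print with one decimal. Scalars promote to degenerate ranges so
the algebra has one code path. Degenerate inputs behave continuously:
zero-width ranges collapse the envelope onto the coupled rate, a zero
prevalence yields zero pools, and all-zero share weights are rejected rather
than normalized.

Problem sizes used by the checks: corner-enumeration containment on 1000
random rate triples, oracle equivalence of the full cascade on 500 seeded
synthetic scenarios (plus 100 in the module suite), and 2^k corner products
for k ≤ 5 — all chosen to exercise the algebra densely while keeping the
whole suite fast on a single CPU.

## Limitations

The model is a static, single-year, population-level cascade. It has no age
or severity stratification and no time dynamics, so it cannot say which
patients are affected or when. It treats prevalence, shares, and rates as
exogenous ranges — there is no distributional uncertainty propagation, and
no correlation between inputs beyond the coupled-scenario convention and the
compound rule. Cost consequences of exclusions are out of scope. Aggregate
headline figures that depend on inputs not present in the printed record
(supplementary-only totals) are deliberately not modeled; the package
reproduces exactly the cells its inputs can derive.
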