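---
title: "The hfsms monitoring engine: rules, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hfsms monitoring engine: rules, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfsms)
```

## The problem

After a hospitalization for acute decompensated heart failure, congestion —
fluid overload presenting as nocturnal dyspnea, rapid weight gain and
fatigue — often rebuilds within days. A daily SMS dialogue is a minimal
instrument to catch that early: the patient answers four short questions a
day, and a fixed clinical flowchart turns the answer stream into alarms.
`hfsms` is that flowchart as software, decoupled from any telephony so it
can be tested, replayed and simulated offline.

## The day grid and the alarm rules

Everything is day-granular: a *day* is a local calendar date of the
follow-up window, indexed from 1. Clock times in `schedule_config()` only
order serialized logs. Each patient session is a grid of (day × question)
cells holding a parsed answer or nothing.

The engine's core is consecutive-day **streak detection with debounce**.
For a daily predicate $q_d$ (e.g. "answered yes to the dyspnea question")
and threshold $k$, an alarm fires on day $d$ when $q_{d-k+1}, \dots, q_d$
all hold and no alarm has fired within the same uninterrupted run; the rule
re-arms on the first day the predicate fails. Equivalently: one alarm per
maximal run of length $\ge k$, placed on the day the run first reaches
$k$. The test suite proves this equivalence against an independent
run-enumeration oracle (`rle`-based) on thousands of random sessions; the
acceptance script repeats that check at run time.

Four rules are instances of this scheme (dyspnea = yes, fatigue = yes,
medication = no, each with $k$ = `symptom_streak_days` = 2 days; and
non-response with $k$ = `nonresponse_streak_days` = 2 days, where a day
qualifies only when *zero* of the four questions were answered). The weight
rule slides a `weight_window_days` = 3-day window and fires when every day
in the window has a valid numeric weight and

$$ w_d - \min(w_{d-2}, w_{d-1}, w_d) \;\ge\; \texttt{weight\_gain\_kg} = 2\ \mathrm{kg}, $$

with the same re-arm semantics on the window condition.

### Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `symptom_streak_days` | 2 | days | dyspnea/fatigue/medication streak length |
| `nonresponse_streak_days` | 2 | days | fully-silent days before the alarm |
| `weight_gain_kg` | 2.0 | kg | gain within the window |
| `weight_window_days` | 3 | days | sliding, fully-observed window |
| `weight_loss_kg` | off | kg | optional symmetric loss rule |
| `educational_period_days` | 2 | days | educational message cadence |
| `educational_first_day` | 2 | day index | cadence anchor |

The defaults are the clinical flowchart; they serialize literally into the
YAML configuration (`write_config()`), and the round-trip is tested.

## Design choices where the design was open

**Weight-rule formula.** "Two kilograms in three consecutive days" admits
two readings: last-vs-first (endpoint) or last-vs-minimum over the window.
The engine defaults to last-vs-minimum because it is clinically
conservative — a dip-then-surge trajectory (69 → 71.5 kg) is exactly the
rebound a congestion check exists to catch — and exposes
`weight_endpoint_only = TRUE` for the endpoint reading.

**Debounce.** One alarm per episode, not one per qualifying day pair. A
seven-day symptom run is a single deterioration the care team is already
acting on; re-alarming daily would train operators to ignore the channel.
The re-arm-on-break semantics means a treated, resolved and recurring
symptom alarms again.

**Invalid replies.** A reply the parser cannot interpret still proves the
patient is responsive, so it counts against the non-response rule; but it
asserts no symptom, so it breaks symptom streaks and invalidates weight
windows. This "responded vs valid" split also drives response accounting:
the answered count in reports includes invalid replies.

**Reply disambiguation.** An SMS reply carries no reference to the question
it answers. A bare reply is attached by arrival order within its calendar
day of receipt (local-midnight boundary): numeric-looking text to the
weight question, a yes/no token to the oldest unanswered binary question in
slot order (morning first), anything else to the oldest unanswered question
of any kind. This is the simplest deterministic contract consistent with
two binary questions per slot, but it is ambiguous in principle — if the
morning binary question went unanswered, an evening "yes" would be
mis-attributed. The log format therefore accepts an optional `question_id`
column that targets a reply directly; serialized cohorts always use it, so
round-trips are exact. First-wins on conflicting duplicates; identical
duplicates (same patient, date, time, text, target) are discarded, making
log replay idempotent.

**Adherence question.** The deployed protocol's materials are inconsistent
about whether the evening adherence probe asked about meals or medications;
the alarm flowchart and the response table are defined on the medication
wording, so the default catalog uses it, with
`default_question_catalog(meals = TRUE)` providing the meals variant.

**Slot assignment.** Which two questions go morning versus evening is not
fixed by the protocol text. Dyspnea ("during last night…") and weight
(best measured first thing, per the educational guidance) are morning
questions; medication and fatigue summarize the day and go in the evening.
The catalog is data, so any other split is a one-line change.

**No pre-enrollment history.** Streaks never extend across the window
boundary: day 1 starts every run at length 1.

## The simulator and the shipped cohort

`generate_cohort(sim_config(...))` draws each cell independently: an answer
is present with the per-question response probability; present binary
answers follow the daily symptom probabilities (dyspnea, fatigue) or the
medication-miss probability; weights follow
$w_d = \text{baseline} + \text{drift}\cdot d + \varepsilon_d$,
$\varepsilon_d \sim N(0, \sigma^2)$, rounded to 0.1 kg. An optional
contiguous outage window silences whole days, reason-tagged `POWER_OUTAGE`.
The defaults are the prototype study conditions: 10 patients, 7-day windows
starting September 2017, response probability 0.94 (the observed 247/264
response rate), symptom probabilities 0.10/0.15 (the order of magnitude
implied by 3 dyspnea and 4 fatigue streak patients in 66 patient-days),
medication-miss 0, baseline 70 kg with zero drift and 0.3 kg noise.

What the simulator deliberately does *not* model: day-to-day correlation of
symptoms (real dyspnea clusters; cells here are independent), adherence
decay over the week, clinically coupled weight-symptom trajectories, and
free-text reply noise beyond the invalid-token path. Passing tests on
simulated cohorts therefore validate the *engine's bookkeeping and rule
semantics*, not the epidemiology of real replies.

The shipped prototype cohort (`prototype_cohort()`) is a different object:
a reconstruction of a real 10-patient field test from its published
marginal counts. Only marginals were published — per-question answered
counts per patient, alarm tallies, unanswered reasons — so the exact day
placement in `inst/extdata/prototype_grid_synthetic.csv` is synthetic:
missing answers are placed so that no patient is fully silent two days
running (no non-response alarm was reported), the ten outage-tagged misses
form one contiguous storm window, symptom runs sit on days 4–5 with exactly
length 2, and the two low-adherence patients are disjoint from the seven
alarm carriers. The constructor re-validates every one of these constraints
on load and refuses a grid that violates any, so the fixture cannot drift
silently.

```{r}
cohort <- prototype_cohort()
summarize_cohort(cohort)
```

## Numerical and degenerate-input notes

* Weight values are validated to (0, 500) kg at parse time; out-of-range
  numbers become `INVALID`, not errors.
* The weight comparison uses `>=` on doubles; thresholds and weights are
  0.1 kg-resolution quantities, so no tolerance is applied.
* A window shorter than `weight_window_days` can never fire the weight
  rule; a streak threshold longer than the window can never fire a streak
  rule; a 1-day window supports no educational message when the anchor is
  day 2. All are exercised in tests.
* `validate_session()` returns violations rather than raising, so callers
  can report every defect of an imported log at once.

## Problem sizes

The test suite checks oracle equivalence on 1,000 random sessions of up to
14 days (plus 60 sessions across three threshold configurations in the unit
tests) and conservation on simulated cohorts of 3–5 patients; the
acceptance script re-runs the 1,000-session oracle comparison and 20
conservation cohorts at every invocation. These sizes fully cover the
engine's state space per rule (runs, breaks, re-arms, window boundaries)
while keeping a full run in seconds.

## Known limitations

* The engine is day-granular by design; sub-day timing (a reply at 23:59
  versus 00:01) changes the day a reply belongs to.
* Attachment of bare (untargeted) replies is order-dependent within a day;
  exactness requires the `question_id` column.
* The transport is an in-memory abstraction; carrier behavior (blocking,
  delivery receipts, cost) is explicitly out of scope.
* One language pair (English/Portuguese token sets) ships by default;
  token sets are configurable but per-catalog localization is not.
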