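# hfsms — a rule-based SMS telemonitoring engine for heart-failure follow-up

Patients discharged after acute decompensated heart failure (ADHF) are most
likely to be readmitted in the first weeks at home, usually because fluid
congestion builds up again: nocturnal dyspnea, rapid weight gain, worsening
fatigue. Plain SMS — no smartphone, no data plan — is enough to watch for
those signs daily. `hfsms` implements the complete monitoring logic of such
a system as an offline, fully testable R package: who gets which message on
which day, how free-text replies are interpreted, and when the hospital is
alarmed. The GSM modem, web server and GUI of a deployed system are out of
scope; the transport is an explicit plug-in point.

It is intended for digital-health researchers who want to study, simulate or
extend SMS monitoring protocols without any telephony infrastructure.

## The protocol and the alarm model

Each patient is followed for one week after discharge (day 1 = first
follow-up day; everything is day-granular). Every day four **feedback
questions** go out — two in the morning, two in the evening:

| id | question | answer | slot |
|---|---|---|---|
| DYSPNEA | During last night, did you wake up with shortness of breath once? | yes/no | morning |
| WEIGHT | What's your weight today? | kg | morning |
| MEDICATION | Have you taken all your medications today? | yes/no | evening |
| FATIGUE | Have you felt more tired today than you did yesterday? | yes/no | evening |

plus one unidirectional **educational reinforcement** every second day
(salt avoidance, fluid-accumulation explanation, daily weighing), cycled in
fixed order. Replies are parsed tolerantly (case, whitespace, accents,
`sim/não`, comma decimals, a trailing `kg`); unparseable text is recorded as
`INVALID`, which still counts as *responding* but never as a symptom.

Five rules are evaluated over each patient's day grid. Writing
`x_d` for the day-`d` answer and `w_d` for the weight:

* **NON_RESPONSE** — zero answers to all four questions on ≥ 2 consecutive days;
* **DYSPNEA_STREAK** — `x_d = yes` on ≥ 2 consecutive days;
* **MEDICATION_STREAK** — `x_d = no` on ≥ 2 consecutive days;
* **FATIGUE_STREAK** — `x_d = yes` on ≥ 2 consecutive days;
* **WEIGHT_GAIN** — over a 3-day window with all weights observed,
  `w_d − min(w_{d−2}, w_{d−1}, w_d) ≥ 2 kg`.

Every rule is **debounced**: it fires once, on the day the condition is
first completed, and re-arms only after a day that breaks the condition — an
uninterrupted 7-day symptom run is one clinical episode, one alarm. Missing
or invalid answers break streaks and invalidate weight windows. Each alarm
notifies both the patient and the hospital manager. All thresholds live in
`alarm_config()`; an optional symmetric weight-loss rule is off by default.

## Worked example

The package ships a synthetic reconstruction of a published 10-patient
prototype cohort (nine 7-day windows, one patient withdrawn after three days
for an acute coronary syndrome), rebuilt from its published marginal counts
and re-validated on every load:

```r
library(hfsms)
cohort <- prototype_cohort()
summarize_cohort(cohort)
#> <hf_summary> 10 patients: 264 feedback messages sent, 247 answered, 17 unanswered
#>   DYSPNEA     61/66 answered
#>   WEIGHT      62/66 answered
#>   MEDICATION  61/66 answered
#>   FATIGUE     63/66 answered
#>   alarms: 7 (NON_RESPONSE=0, DYSPNEA_STREAK=3, WEIGHT_GAIN=0, MEDICATION_STREAK=0, FATIGUE_STREAK=4)
```

264 questions were scheduled (9×7×4 + 1×3×4) and 247 answered; the 17
missed answers are reason-tagged (10 power outage, 4 not seen, 3 forgot).
The alarm engine fires exactly seven times: three patients with two
consecutive dyspnea nights, four with two consecutive worse-fatigue days; no
weight-gain, medication or non-response alarm — matching the reported
prototype test. The same numbers fall out of the full pipeline
(`run_pipeline(out_dir, fixture = TRUE)`), which also writes `sessions.csv`,
`alarms.csv`, `notifications.jsonl` and `summary.json`.

Simulated cohorts are available through `generate_cohort(sim_config(...))`
— per-question response probability, daily symptom probabilities, a linear
weight model and an optional outage window, bit-reproducible under a seed.

## Command line

A thin Rscript front end lives in `exec/hfsms`:

```sh
hfsms simulate --seed 1 --n-patients 10 --days 7 --out runs/sim
hfsms replay --fixture --out runs/proto
hfsms report --profiles profiles.csv --inbound inbound.csv --out runs/rep
hfsms validate-config --config engine.yaml
```

Inbound logs are CSV (`patient_id,date,time,raw_text`, optional
`question_id`) or JSON lines; the engine configuration is one YAML document
with `questions`, `educational`, `schedule` and `alarms` sections
(`write_config()` emits the defaults).

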