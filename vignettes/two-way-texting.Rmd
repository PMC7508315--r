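---
title: "Two-way text-message patient reporting: models, protocols and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-way text-message patient reporting: models, protocols and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txtpro)
```

## The problem

Adolescents with chronic conditions such as sickle cell disease are asked to
self-report symptoms frequently — daily pain episodes, school attendance,
weekly pain-interference scales. Paper diaries are filled in retrospectively
or not at all; smartphone apps exclude patients without data plans. Plain SMS
reaches essentially every phone, but free-text messages need a human reader.
`txtpro` implements the alternative: *structured* SMS self-reports under a
small template grammar that a machine can validate, combined with per-patient
schedules, automatic reminders, real-time error-proofing, and threshold
alarms to providers. A synthetic cohort simulator stands in for the SMS
gateway, so the whole pipeline is testable end to end.

## The template grammar

Three template kinds cover the report formats in use:

* **`pair_list`** — the daily pain report. Header `P`, then
  intensity/location pairs joined by `&`: `P2CHEST&3BELLY` is chest pain of
  intensity 2 plus abdominal pain of intensity 3. Intensity is the standard
  1–10 numerical rating scale (10 = worst imaginable pain); the eight
  location codes (`HEAD`, `CHEST`, `BELLY`, `BACK`, `UL`, `UR`, `LL`, `LR`)
  are the common sickle-cell pain sites. `PN` alone means *no pain today*.
* **`code_choice`** — daily school attendance as one of four two-letter
  codes: `WD` (whole day attended), `AM` / `AF` (absent morning/afternoon),
  `AW` (absent whole day).
* **`digit_vector`** — the weekly pediatric 8-item pain-interference short
  form, answered as eight digits 0–4 in a single message, e.g. `01324101`.

Parsing is case-insensitive and whitespace-tolerant, with canonical
uppercase storage. Two properties make the grammar safe for a parser rather
than a human reader:

1. **Prefix-freedom.** No location code is a prefix of another, so every
   valid pain message has exactly one tokenization. The test suite verifies
   this against a brute-force enumeration of all digit/code split points.
2. **Greedy digit consumption.** Intensity digits are consumed before the
   alphabetic location code, which is the only reading under which the
   two-digit intensity `10` is unambiguous (`P10BACK` cannot be "1, 0BACK"
   because locations never start with a digit).

Every violation maps to exactly one error code (the first encountered left
to right). Where the printed format examples leave the taxonomy open we made
the following calls: text after the no-event code (`PN&2HEAD`), a bare
header, or a token without leading digits are all `trailing_garbage`; a
digits-only pain token is `unknown_location`; non-digits in a scale answer
are reported (`bad_code`) before a length mismatch, which is reported before
an out-of-range digit. A repeated location is rejected outright
(`duplicate_location`) rather than resolved last-wins: under the
error-proofing philosophy the patient should restate an ambiguous report.

Invalid messages always earn an *error-proofing instruction* naming the
violated rule and embedding the template's `valid_example`:

```{r}
res <- parse_report("P0HEAD", pain_template())
res$error_code
cat(strwrap(res$instruction, 70), sep = "\n")
```

## Scheduling and windows

Each patient carries a schedule of daily/weekly recurrences expanded into
concrete *report events*: a completion window anchored at a local clock time
in the patient's IANA timezone, stored as UTC instants. Windows stay at the
configured wall-clock time across daylight-saving transitions. Defaults,
all configurable:

* **Inpatient pain:** three chances per day, 2-hour windows opening 08:00,
  12:00 and 17:00 — inside the 7AM–7PM reporting span of the inpatient
  protocol. "Three chances" could also be read as one window with three
  reminders; we chose three independent windows because daily compliance
  (at least one valid report per day) is identical under either reading.
* **Outpatient pain:** three personalized chances (defaults 07:00, 15:30,
  20:00 — before school, after school, before bedtime).
* **Attendance:** one daily query around dinnertime (18:00, 2 h window).
* **Weekly scale:** one long weekend window, Friday 18:00 → Sunday 21:00
  (51 h), matching the "Friday evening to Sunday evening" flexibility.
* **Reminders:** one per window at the midpoint, since no published offsets
  exist; reminders are suppressed as soon as a valid response arrives and
  are never due outside the window.

On-time means inside the closed window interval; late valid reports are
retained (they count toward compliance, not toward the on-time rate).
Response latency is measured from the initial prompt — the window opening —
because that is the only anchor defined for every event regardless of how
many reminders fired. Schedules import/export as an RFC 5545 iCalendar
subset (`RRULE`, `EXDATE`, private `X-TXTPRO-*` properties), written by the
package itself since no R iCalendar package is available; the writer/reader
pair covers exactly the constructs the scheduler emits and round-trips
losslessly.

## The conversation loop and alarms

`handle_inbound()` validates each message against the pending event's
template. Invalid → instruction, unlimited retries within the window (no cap
is published; capping would silently discard willing reporters). Valid →
canonical storage, with `corrected = TRUE` when an earlier attempt at the
same event was invalid. Threshold alarms are **strict**: a pain score above
the provider-set threshold alarms (threshold 5, score 6 alarms; score 5 does
not — "above" reads as strict, and the worked example is consistent).
Multi-site reports alarm on their **maximum** intensity, the clinically
conservative aggregation; thresholds are defined for pain only. Only weekly
scale reports are resubmittable (last write wins within the window); extra
pain or attendance reports within one window are stored as additional
reports, since multiple daily pain reports are encouraged.

One-way health tips come from a message pool — 54 synthetic tips in 11
topical subsets ship with the package — selected by *shuffled-cycle*
sampling: each patient sees a random permutation of the pool, reshuffled on
exhaustion with no repeat across the cycle boundary. "Avoid repetitive
messages" is stated without an algorithm; shuffled cycles give exact
uniformity over whole cycles and a guaranteed gap of at least pool-size
between repeats.

## Outcome statistics

Definitions, with deliberate attention to denominators:

* **Compliance** = query days (patient-local calendar days with ≥ 1
  scheduled query) that have ≥ 1 valid report, over all query days. Weekly
  compliance counts query weeks the same way.
* **Received messages** count *final outcomes*: an invalid attempt later
  corrected collapses into its valid, corrected message; only
  never-corrected invalid attempts add to the received count. This is the
  convention under which the reference deployment's counts are coherent
  (378 valid of 383 received, with 8 of the 378 "initially invalid").
* **Validity** = valid / received; **correction** = corrected / valid.
* **On-time** is exposed with both denominators — over valid and over
  received — because the reference deployment's two settings print rates
  with different denominators (330/378 inpatient over valid, 423/595
  outpatient over received). Both are computed and labelled; the default is
  over valid.
* **Mean latency** averages prompt-to-message minutes over on-time valid
  messages only.
* Empty denominators yield `NA`, never 0.

`reconstruct_trial_log()` builds a deterministic synthetic log whose
marginal counts equal the reference pilot cohort (27 adolescents, 23
inpatient and 18 outpatient enrollments), so every published rate is
recomputed — not restated — by the statistics layer:

```{r}
ref <- reconstruct_trial_log()
round(100 * compliance_rate(ref$log, ref$events, "pain", "inpatient"), 1)
round(100 * overall_accuracy(ref$log, ref$events, "pain"), 1)
```

Only the counts are faithful; message texts, patient-day allocation and
timestamps are synthetic (they are not published), so latency summaries of
the reconstruction are fixture values, not findings.

## The cohort simulator

`simulate_cohort()` drives the real conversation engine with generated
traffic. Per two-way event: respond with probability `respond_probability`
(default 0.95) at a log-normal latency (median 30 min, `sdlog` 0.6 — the
scale motivated by observed mean response times in the mid-30s to mid-40s
of minutes, not a fit); with probability `format_error_probability`
(default 0.05) the first message is mutated invalid and retried with
probability `retry_probability` (default 0.9) five minutes later.
Enrollment defaults are 5 inpatient and 20 outpatient days (observed means
5.1 and 19.9). The pain process — Bernoulli pain day, geometric site count
capped at 8, uniform intensities — is purely a fixture with no clinical
realism claimed: passing tests show the *pipeline* (parsing, windowing,
counting) is correct, not that simulated adolescents behave like real ones.
Ground truth for every intended outcome is emitted alongside the traffic,
so classification tests never re-derive labels from the system under test.

Calibration experiments in the tests and acceptance script use 30 patients
× 100 days with a single daily query (3,000 events — enough for a binomial
standard error around 0.4 percentage points) and set the format-error
probability to zero, so that observed compliance is an exact binomial draw
of `respond_probability`; the error/retry channel is checked separately
against the injected invalid→valid counts and the error × retry product.

## Known limitations

* The transport is an abstraction: no delivery receipts, carrier failures,
  or message loss; the simulator models patients, not networks.
* Instruction text is English-only and not localized.
* Free-text interpretation is deliberately out of scope — unparseable
  messages earn an instruction, never a guess.
* Threshold alarms are defined on pain scores only; weekly-scale totals do
  not alarm.
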