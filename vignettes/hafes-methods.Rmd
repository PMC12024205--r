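---
title: "Methods: rule-based hearing-aid fitting from encoded complaints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based hearing-aid fitting from encoded complaints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hafes)
```

## The problem

Hearing-aid fitting is iterative: after the initial prescription, wearers
return with complaints — whistling, sounds too loud in noise, the sound
cutting out — and a hearing-care professional translates each complaint
into an action: a physical check, counselling, a therapy referral, or an
electroacoustic adjustment of the device within the manufacturer's
constraints. Where audiologists are scarce, that translation step is the
bottleneck. `hafes` encodes it as an explicit, explainable expert system:
a structured questionnaire turns the complaint into six integer codes, a
fitting guide maps code patterns to prioritized solution plans, and a
deterministic inference pass computes constraint-clamped parameter changes
with a full reasoning trace. The package favors transparent rules over
learned models deliberately: every recommendation can be audited, and the
system runs offline with no data infrastructure.

## The complaint model

A complaint is described by six characteristics, collected by one closed
question each, in three sections:

| Section | Dimension | Items |
|---|---|---|
| Nature of the complaint | cause | 18 |
| | specificity (which sounds) | 7 |
| Listening context | environment | 5 |
| | activity | 8 |
| Impact assessment | frequency | 7 |
| | discomfort | 3 |

Item codes are 0-based integers in catalog order and identical across
locales (English and French labels ship with the package), so encoded
responses are language-independent. The frequency scale is stored with
seven ordinal levels (never … always) and discomfort with three
(tolerable, annoying, unbearable); both are ordinal and travel with each
recommendation as urgency metadata rather than selecting the complaint
class.

The four nature/context dimensions span
`18 × 7 × 5 × 8 = 5040` distinct complaint descriptions:

```{r}
enumerate_complaint_space(get_questionnaire())
```

Including the impact dimensions multiplies this by `7 × 3`, giving
105,840. (A figure of 125,840 is sometimes quoted for the full space; it
is not the arithmetic product of the stated catalog sizes, so the package
computes and reports the product.)

### Environment bands

The environment question is anchored to sound-level bands: very quiet
(0–20 dB), quiet (25–60 dB), noisy (65–80 dB), very noisy (90–140 dB).
The printed anchors leave gaps (20–25, 80–90 dB); `classify_environment()`
closes each gap by extending a band's upper edge to the next band's lower
anchor — \[0, 20\], (20, 60\], (60, 80\], (80, ∞) — so classification is a
total, monotone step function, and levels above 140 dB remain "very
noisy". The fifth environment item ("varies/unspecified") exists only as a
questionnaire answer; the classifier never produces it.

### Consistency screening

Some code combinations are logically incoherent (the canonical example: an
own-voice complaint while listening to the radio in a quiet room).
Screening rules name forbidden combinations over at least two dimensions.
`check_consistency()` *flags* matching complaints rather than deleting
them: the audit trail is preserved, and `recommend()` refuses a flagged
complaint unless the caller explicitly overrides screening. Only one
screening example is documented in the source guide; the packaged rule
list ships that rule plus one structural rule (reporting no sound at all
while naming specific problem sounds) and is user-editable in the
knowledge-base file.

## The knowledge base

A knowledge base bundles five things, stored in one schema-versioned JSON
document:

* **Parameter specifications** — canonical name, manufacturer alias,
  group, unit, typical range, default, and `step_unit`, the magnitude of
  one command level.
* **Device profiles** — per-model range overrides. The effective range of
  a parameter on a device is the *intersection* of its typical range and
  the override. In the packaged Balafon fixture, MCL (most comfortable
  loudness, alias `min_dyn`) has typical range 0–120 dB, and the BTE
  profile overrides it to 0–70 dB; the intersection rule honors both the
  generic and the device-specific statements.
* **The fitting guide** — complaint classes as per-dimension code
  patterns with ordered solution plans (see below).
* **Consistency rules** and the **adjustment policy** — the 4–12 dB
  noticeable-gain range and the 6 dB default step unit.

Serialization is canonical: object keys are recursively sorted and numbers
written at full precision, so saving the same knowledge base twice is
byte-identical and `load(save(kb))` is the identity. This makes fixture
files diffable and round-trip properties testable exactly.

An optional Turtle export (`export_ontology()`) renders the same content
as an RDF/OWL class skeleton plus individuals — e.g. the silence-detection
parameter `enerFaibl` appears as an individual of a `Silence` subclass of
`FittingParameter`. The export is a plain serializer; no description-logic
reasoning is performed or needed, because the matching semantics below
replace it.

## The fitting guide and matching semantics

Each guide entry carries a pattern over the four nature/context
dimensions — each dimension either a set of allowed codes or a wildcard —
and a prioritized list of solutions in six categories: Recommendation (R),
physical adjustment (AP), electroacoustic adjustment (EA), Therapy (T),
Consultation (C), Accommodation (AC). (`AE` is accepted as an input alias
for `EA`.) EA solutions carry exactly a parameter reference and a command;
other categories never do.

`match_complaint()` is an explicit most-specific-match evaluator:

1. every entry whose pattern accepts the complaint is a candidate;
2. the candidate pinning down the most dimensions (highest specificity
   score) wins — "whistling in a quiet environment" beats generic
   "whistling";
3. ties break to the lowest entry id (guide order);
4. if no entry matches, a total consultation fallback is returned.

This evaluator is the behavioral replacement for a semantic-web rule
engine: the guide is small and closed, so explicit scoring gives the same
observable complaint-to-recommendation mapping while remaining trivially
auditable. The test suite checks the evaluator against an independent
brute-force scorer over the entire 5040-complaint enumeration.

Entries may optionally carry demographic guard fields (an age range,
comorbidity tags) which act as extra pattern dimensions when demographics
are supplied; no demographic rules ship, because none are clinically
documented for this guide, but the capability is exercised in the tests.

### The packaged guide and its placeholders

The published extract of the Balafon fitting guide prints 22 rows (1–17,
19, 20, 23–25); the full 33-class guide lives in an appendix that is not
transcribed here. The fixture therefore ships the 22 published rows
verbatim plus 11 entries marked `source = "synthetic_placeholder"` (rows
18, 21, 22, 26–33): rows 18/21/22 interpolate the printed soft-sound
pattern structurally, and rows 26–33 are plausible non-electroacoustic
classes (echo, muffled sound, own voice, distortion, buzzing, discomfort,
retention, battery) over cause codes the printed rows leave unused.
Placeholders are flagged by `validate_knowledge_base()` as warnings and
announced in every explanation trace that fires one, so they can never be
mistaken for published clinical content. Two cause codes (metallic sound,
itching) are intentionally left uncovered so the consultation fallback
path stays exercised; under full enumeration about 16% of the 5040
complaints fall back.

One published row is internally contradictory across its two printed
forms ("loud sound in a quiet environment": the tabulated guide says
decrease UCL, the prose narrative says decrease MCL). The tabulated guide
is taken as operative; the variant is preserved on the entry as an
`alternative` annotation for audit.

Reading note for the soft/loud rows: phrases of the form "*loud soft
sounds*" are parsed as specificity-then-cause — loud sounds (specificity)
are too soft (cause) — which is the only reading under which every printed
command agrees with its own advice text (e.g. raising UCL under "Increase
the volume").

## The step law and constraint clamping

Guide commands use symbol-count notation: `decrease--` means direction
decrease, level 2. The effective change is

    delta = sign(direction) × level × step_unit
    proposed = clamp(current + delta, effective range)

The packaged step unit for dB gain parameters is 6 dB: the one worked
magnitude documented for this guide is a 6 dB MCL decrease, and two levels
then reach 12 dB, the top of the 4–12 dB noticeable-gain range. The
literature gives the noticeable range and single magnitudes but no step
law, so the linear-in-level law with a 6 dB unit is a design choice of
this package, recorded in the adjustment policy and reported in every
trace. `nb_vol` (volume steps) and `enerFaibl` (silence detection) use a
1-unit step; both are dimensionless counts, and their step is
manufacturer-tunable in the fixture file.

Clamping is idempotent, monotone and total; an empty effective
intersection (a misconfigured override) is a configuration error naming
the parameter and device. Out-of-range *current* values are pre-clamped
before the step law is applied, with a note in the trace. The safety
property — no proposed value ever outside the effective interval — is
re-checked post hoc by an independent clamp oracle in the tests.

Fixture values not documented by the manufacturer material available
here — UCL's typical range (0–140 dB, the upper anchor of the very-noisy
band, default 90 dB), MCL's default (50 dB), the `nb_vol` (1–10, default
5) and `enerFaibl` (0–10, default 5) ranges — are realistic placeholders
chosen once and marked in the fixture; a manufacturer deployment would
replace them with catalog values. When no fitting state is supplied,
current values default to the parameter defaults.

## Sessions and feedback

The workflow is event-sourced with four phases. `open_session()` runs
inference and opens a review-pending session. `review_session()` records
the audiologist decision — approve, modify (modified EA targets are
re-validated against the device constraints and rejected with a clamp
report if they violate them), reject, refer, or request more information
(the session stays pending with follow-up questions targeting the
dimensions the matched entry left unspecified). `record_feedback()`
enforces the clinical-oversight contract (no feedback without an approving
review), advances the plan cursor on dissatisfaction — "try the next
solution" — and closes the session as resolved or, when the plan is
exhausted, as unresolved consultation. Satisfaction is a binary flag with
an optional 1–5 ordinal detail, since no scale is clinically prescribed.
Every transition appends an immutable event; `replay_session()` folds the
log back into an identical session, which is also how the CLI persists
sessions as JSON files. `resolution_stats()` recounts the log per
complaint class and flags classes whose resolution rate falls below a
configurable threshold (default 0.5 — the guide gives no threshold, so it
is an operator knob) for knowledge-base review.

## The synthetic generator

`generate_complaints()` draws complaints uniformly per dimension (optional
categorical weights let users mimic clinic-like skew; no empirical
distribution is documented, so uniform is the default). With probability
`p_inconsistent` an item instantiates the pattern of a packaged
consistency rule and is labelled inconsistent *by construction*;
consistent items are rejection-sampled until they pass screening, so the
generator's labels agree with `check_consistency()` exactly — that
agreement is itself a test oracle at `p ∈ {0, 0.5, 1}`. The generator is
deterministic under a fixed integer seed and restores the caller's RNG
state.

What the generator emulates is the *code space*, not clinical reality: it
knows nothing about which complaints co-occur in practice, how wearers
actually phrase problems, or response noise from the questionnaire UI.
Passing tests on generated data therefore demonstrate the engine's
logical properties (totality, determinism, safety, label soundness), not
field performance of the instrument.

## Numerical and design choices, in brief

* Environment band edges are half-open with inclusive upper edges;
  level 0 belongs to the first band; negative levels are domain errors.
* "Quiet environment" patterns in the guide match codes {0, 1} (very
  quiet + quiet) and "noisy" {2, 3}, since the guide phrases classes at
  that two-way granularity.
* Matching tie-break is the lowest entry id; the guide order is the
  priority order.
* Canonical JSON uses two-space indentation, sorted keys, UTF-8, full
  numeric precision.
* Problem sizes in the test suite: the matching oracle runs over the full
  5040-complaint enumeration; randomized property checks use 50–300
  seeded cases each, enough to exercise every branch while keeping the
  default run around ten seconds.

## Known limitations

* The 11 placeholder guide entries are structural stand-ins, not
  published clinical content; deployments should replace them with the
  full transcribed guide.
* The step law is linear in command level; if a manufacturer prescribes
  min/max/average semantics over the noticeable range instead, the
  policy object is the place to encode it.
* No audiogram-based first fit, acoustic measurement, or probabilistic
  learning: the system refines only through expert edits of the
  knowledge base.
* Labels ship in English and French only; other locales fall back to
  English with a warning.
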