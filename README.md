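# hafes

Rule-based, explainable decision support for hearing-aid fitting from
patient-reported complaints.

## The problem

Hearing aids need repeated post-fitting adjustments driven by wearer
feedback, and in many regions there are far too few audiologists to
provide that follow-up. `hafes` packages the translation step — from a
wearer's complaint to a concrete, safe fitting action — as an open expert
system for audiologists, tele-audiology platforms and hearing-aid
manufacturers:

* a bilingual (English/French) **six-question self-assessment
  questionnaire** encodes a complaint as six integer codes — cause,
  specificity, environment, activity, frequency, discomfort — with
  catalog sizes (18, 7, 5, 8, 7, 3), spanning 18 × 7 × 5 × 8 = **5040**
  distinct complaint descriptions over the nature/context dimensions,
  with logical-consistency screening of incoherent answers;
* a validated **knowledge base** (canonical JSON) holds the fitting
  guide, electroacoustic parameter specifications, per-device constraint
  overrides and the adjustment policy, with an optional Turtle/OWL
  export;
* a deterministic **inference engine** matches each complaint to its
  most specific guide entry (ties to the lowest entry id, total
  consultation fallback) and instantiates the entry's prioritized
  solution plan.

For an electroacoustic step the change is computed by the step law

```
delta    = sign(command) × level(command) × step_unit
proposed = clamp(current + delta, typical_range ∩ device_override)
```

with a 6 dB step unit for gain parameters (one level = 6 dB, two levels =
12 dB, the top of the 4–12 dB noticeable-gain range), and clamping to the
intersection of the parameter's typical range and the device's override —
e.g. the packaged Balafon BTE profile caps MCL at 70 dB although the
typical range runs to 120 dB. Every recommendation carries an explanation
trace (rule fired, step law, clamps, provenance), and a four-phase session
workflow adds audiologist review (approve / modify / reject / refer /
request info), patient satisfaction feedback with plan-cursor advancement,
and per-class resolution statistics.

## Worked example

A wearer of a Balafon BTE reports that the sound keeps cutting out in a
very noisy environment during group conversation, almost always, and
finds it unbearable; the silence-detection parameter `enerFaibl` is
currently at 2:

```r
library(hafes)
kb <- load_knowledge_base(system.file("extdata", "balafon_kb.json",
                                      package = "hafes"))
c0 <- complaint_descriptor(cause = 9, specificity = 0, environment = 3,
                           activity = 2, frequency = 5, discomfort = 2)
recommend(c0, kb, device = "BalafonBTE", fitting = list(enerFaibl = 2))
#> Complaint codes: cause=9 specificity=0 environment=3 activity=2 frequency=5 discomfort=2
#> Screening: complaint is logically consistent.
#> Rule fired: guide entry 24 (matched cause, environment; specificity 2)
#> Plan step (EA), provenance: manufacturer
#> Step law on enerFaibl: decrease---- at 1 per level -> requested change -4
#> Constraint on enerFaibl (BalafonBTE): requested -2, applied 0 (range [0, 10])
#> Adjustment: enerFaibl 2 -> 0 (delta -2) [clamped]
```

Reading the trace: the complaint fell into guide entry 24 ("sound cutting
in a noisy environment", matched on cause and environment), whose solution
is an electroacoustic decrease of `enerFaibl` by four levels; with a
1-unit step the requested change is −4, which from the current value 2
would land at −2, so the constraint clamp applies the parameter floor 0.

Constraint clamping is the safety backstop for gain parameters too — a
double-step MCL increase from 62 dB is capped at the BTE's 70 dB ceiling
rather than the requested 74 dB:

```r
explain(recommend(complaint_descriptor(2, 0, 1, 0, 4, 1), kb,
                  device = "BalafonBTE", fitting = list(MCL = 62)))
#> ...
#> Step law on MCL: increase++ at 6 per level -> requested change +12
#> Constraint on MCL (BalafonBTE): requested 74, applied 70 (range [0, 70])
#> Adjustment: MCL 62 -> 70 (delta +8) [clamped]
```

A coverage scan over the full enumerated complaint space shows every one
of the 33 packaged complaint classes is reachable, with unmatched
complaints routed to the consultation fallback:

```r
coverage_report(kb, full = TRUE)
#> Coverage over 5040 complaints: 33 entries hit, 784 fallbacks (15.6%)
```

## Command line

A thin launcher ships in `inst/cli/hafes`:

```sh
hafes kb validate balafon_kb.json
hafes space --count                      # 5040
hafes recommend --kb balafon_kb.json --device BalafonBTE \
      --complaint 9,0,3,2,5,2 --explain --log decisions.jsonl
hafes synth complaints --seed 42 -n 100 --p-bad 0.1
hafes session open --kb balafon_kb.json --complaint 3,0,1,0,4,1 -o s.json
```

Exit codes distinguish usage (2), validation (3), screening (4) and
constraint (5) failures; `--json` switches any subcommand to
machine-readable output, and `--log` appends one replayable JSON record
per inference.

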