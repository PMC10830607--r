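---
title: "Bottom-up gesture coding: the data model and its computations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up gesture coding: the data model and its computations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GestureKit)
```

## The problem

Great-ape gesture research codes intentional communicative movements from
video: a signaller produces one or more gesture actions towards a recipient,
and the communication ends when the recipient's behaviour changes in a way
that plausibly satisfies the signaller's goal (the apparently satisfactory
outcome) or when the attempt fails. Research groups have historically carved
this behaviour into "gesture types", "sequences" and "response latencies" in
incompatible ways, which blocks like-with-like comparison across studies and
species. The bottom-up alternative is to code minimal, theory-light
observables — precise time points, the action movement, and a set of
modifier variables — and to defer the larger constructs to analysis time,
where they can be built under explicit, switchable conventions.

GestureKit implements that second half: it takes tiered time-aligned
annotations (ELAN EAF files or their tab-delimited exports) and turns them
into validated data objects on which durations, latencies, sequences,
repertoires and coder reliability are computed under parameterised
conventions rather than baked-in ones.

## The phase model

Each gesture record carries four measured time points:

* **Gesture start** — the body part leaves its communicatively neutral
  position;
* **MAU end** — the end of the *minimum action unit*, the initial movement
  carrying the minimal information needed to recognise the gesture action;
* **Gesture action (GA) end** — the end of the action including any optional
  hold or repetition phase;
* **Gesture end** — the body part is back in a neutral position (end of
  recovery).

From these, `phaseDurations()` derives the MAU duration, the gesture-action
duration, the full gesture duration, the hold (`GA end − MAU end`) and the
recovery (`gesture end − GA end`). Gesture action *types* split into two
classes carried by the catalogue (`GestureCatalogue`): **variable** types
have an optional hold/repetition phase (reach, raise, present, hit, stomp in
the default catalogue), **stable** types do not, so their gesture action
always ends with the MAU — `validateRecords()` enforces `GA end = MAU end`
for them, and their hold is exactly zero. An instance of a variable type
that used its hold is a **continued** instance; one that did not is
**minimised** (`classifyInstance()`; stable types are always minimised).

Unknown time points are an explicit `NA`, never a sentinel value; any
duration or latency touching an unknown end point is undefined and excluded
from summaries, with the exclusion count reported (`n_excluded` in
`summariseBy()`).

## Latencies and sequences under explicit conventions

Because the MAU end is the earliest moment at which the recipient has, in
principle, all the information needed to recognise the gesture, both
response latencies and inter-gesture intervals are computed from a
configurable end point:

* `responseLatency(x, "MAU_end")` — time from the MAU end of the final
  gesture (the one whose end point is closest to the outcome) to the outcome
  time;
* `responseLatency(x, "GA_end")` — the traditional convention, measured from
  when the signaller stopped displaying the gesture.

Negative latencies are legal values — the recipient may act before the phase
completes — and the two conventions are linked by an algebraic identity
checked in the test suite: `MAU.Outcome − GA.Outcome` equals the final
gesture's hold duration whenever all quantities are defined.

`segmentSequences()` groups a signaller's gestures into sequence units by a
greedy left-to-right pass: a new unit opens whenever the interval from the
previous gesture's chosen end point to the next onset reaches the cutoff
(default 1.0 s). The comparison is `>=` — an interval of exactly the cutoff
marks response waiting — with a `strict` switch for the `>` reading, since
prior conventions do not pin down the boundary. Undecidable intervals (an
unknown end point) conservatively open a new, flagged unit. Because the MAU
end can only precede the GA end, switching the convention from GA end to MAU
end never shortens any interval and never decreases the number of units; the
test suite checks both this monotonicity and agreement with a brute-force
pair-by-pair oracle. Follow-up units classify as *persistence* (only gesture
types already used) or *persistence with elaboration* (new types) via
`classifyFollowup()`, at whatever morph resolution the caller keys the units
with.

## Morphs and repertoires

A **morph** is a recurring action-plus-modifier combination constructed
after coding. `morphKey()` canonicalises it at a chosen resolution: the
catalogue spelling of the action followed by the included modifier values in
a fixed order (body part, laterality, object used, flexion, orientation,
repetition count, contacted body part, audibility, directionality). The
order is a package convention — nothing in the coding scheme requires one —
chosen so that keys are stable and comparable across analyses. Unknown or
"no value" modifiers are omitted from the key, so missing data lump rather
than inflate repertoires; `strict_unknown = TRUE` keys them as an explicit
`?` level instead. `buildRepertoire()` counts keys per group;
coarsening the resolution can only merge keys, so repertoire size is
monotone non-increasing under coarsening (property-tested). Probabilistic
morph clustering is out of scope; `morphFeatureMatrix()` exports the
per-record feature table for external tools.

## Reliability

`icc2Single()` implements the single-score, two-way random-effects,
absolute-agreement intraclass correlation ICC(2,1), computed directly from
the two-way ANOVA mean squares:

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + k(MS_C - MS_E)/n}$$

with the `F = MS_R/MS_E` significance test on `(n−1, (n−1)(k−1))` degrees of
freedom and the standard F-based confidence interval (Satterthwaite degrees
of freedom for the rater term). The tests verify agreement with an
independent `aov()`-based sums-of-squares oracle to `1e-10`. Published CIs
from other software may differ in the last digits where a package variant of
the interval was used. Incomplete subject rows are dropped listwise with a
logged count; a zero-variance matrix yields an explicit `NA`.
`coderBiasAdjust()` estimates a systematic mean coding difference between
two coders and shifts one coder onto the other's mean exactly.

## The synthetic generator

`generateDataset(simConfig(seed = ...))` simulates communications with the
statistical structure the framework assumes, so that every computation can
be tested without field data, against *planted* ground truth:

* durations (MAU, hold, recovery) are log-normal — positive and
  right-skewed, so sample medians fall below means as real duration data do;
* stable action types get `GA end = MAU end` by construction; variable types
  use their hold with probability `p_hold` (default 0.5);
* inter-gesture gaps are a mixture of short within-sequence gaps (drawn
  below the cutoff) and response-waiting gaps (at or above it, probability
  `p_split = 0.3`), planted relative to the GA end, so the GA-end
  segmentation of the stream is known exactly;
* successful communications (probability `p_success = 0.8`) get an outcome
  time planted at a known log-normal latency after the anchor end point
  (MAU end by default) of the final gesture;
* modifiers are drawn per the action's catalogue attributes (flexion and
  orientation only for free-limb actions, repetition counts only for
  repetition actions, contacted body parts only for contact actions), so
  generated records validate cleanly;
* communications are laid out sequentially on a single media timeline, as
  on continuous video.

The default scale — 250 communications and 37 signallers — mirrors a
field-realistic single-species latency dataset. Distribution parameters not
dictated by any published quantity (MAU median 0.8 s with sdlog 0.4, hold
median 1 s with sdlog 0.8, recovery median 0.25 s, latency median 1.5 s with
sdlog 1.0) were chosen once as plausible for great-ape gesturing at
millisecond coding resolution and are not tuned. The generator deliberately
does **not** emulate recipient negotiation or turn-taking, social-network
structure, per-individual repertoire differences, or coder error; passing
tests therefore demonstrate computational correctness on cleanly structured
data, not robustness to every pathology of real field recordings.

## Numerical and format choices

* **Time** is integer milliseconds from media start (the native resolution
  of the annotation format); durations and latencies are reported in
  seconds. Exact equality tests (e.g. zero hold) are meaningful at this
  resolution, which is why the `zero_hold_tolerance` of
  `classifyInstance()` defaults to 0.
* **Intervals** are half-open `[start, end)`, so abutting annotations do not
  overlap.
* **EAF dialect**: ELAN 3.x schema; times via time-slot references; modifier
  and communication-level variables as reference annotations on their parent
  tier; MAU/GA phase ends as time-aligned child annotations sharing the
  record's onset; controlled vocabularies embedded in the header.
  `writeTemplateEAF()` emits the empty coding template.
* **Tab exports** drop reference links; `assembleRecords()` recovers them by
  shared onset (phase tiers start with their parent) and otherwise by
  midpoint temporal containment, ties to the earliest-starting candidate
  parent. Two values of the same variable on one record are an error;
  orphans warn.
* **Catalogue/vocabulary files are CSV**, not spreadsheets: plain-text
  diffs, no spreadsheet dependency. Spreadsheet-based catalogues port by
  saving each sheet as CSV with the documented columns
  (`action, phase_class, contact, repetition, free_limb, definition`;
  `variable, value, free_text`). Name and value matching is
  case-insensitive and whitespace-trimmed, with the catalogue spelling
  canonical, because hand-coded data vary in capitalisation.
* **Summaries** use the sample standard deviation (n−1) and
  midpoint-of-two medians for even n.
* **"Final gesture"** for latency purposes is the record whose chosen end
  point is latest; when the temporally last record's end point is unknown,
  the latest record with a known end point is used and the result flagged,
  rather than silently dropping the communication.
* **Success filter**: latency analyses of "successful communications"
  operationalise success as a known outcome time (`outcome_status ==
  "success"`); the `--require-outcome` switch of the CLI makes the filter
  explicit, since a stricter behavioural definition is a coding-protocol
  matter, not a computational one.

## Scope of the default catalogue

The bundled `defaultCatalogue()` covers only common, well-documented actions
(reach, raise, present, beckon, fling, hit, stomp, push, touch) with the
stable/variable assignment following the rule *variable iff the action's
description documents an optional hold or repetition phase*. It is a
starting point for demonstration and testing; real studies should load their
full, species-appropriate catalogue with `readCatalogue()` — the data model
is agnostic to the action list (adaptations for other taxa, e.g. adding
trunk and ears to the body-part vocabulary for elephants, are vocabulary
edits, not code changes).

## Problem sizes in the shipped tests

The property suites run on seeded synthetic data: 1,000 communications for
the invariants and algebraic identities, 40–80 communications for
round-trip and oracle comparisons, 100 random 5×2 matrices for the ICC
oracle, and roughly 1,900 gesture records for the distribution-recovery
check. These sizes give the oracle comparisons exact or near-exact
resolution while keeping the default test run fast.

## Known limitations

* Intentionality markers (audience checking, response waiting, goal
  persistence) are carried as coded observations and validated, never
  inferred from the time series.
* The tab-export re-linking heuristic cannot distinguish two annotations
  with identical spans on the same tier; the EAF path, which preserves
  references, is authoritative.
* ICC confidence intervals assume the two-way model's normality; with
  heavily skewed latencies they are approximate.
* Reported descriptive statistics are computed at full precision and only
  rounded for display; re-implementations that round time points before
  differencing can differ in the last digit.
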