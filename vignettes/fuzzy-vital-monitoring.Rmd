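---
title: "Fuzzy pre-diagnosis of ICU vital signs: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy pre-diagnosis of ICU vital signs: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalfuzz)
```

## The problem

Bedside multiparameter monitors in an intensive-care unit stream vital
signs once per second. Two of them dominate the short-term assessment of
clinical stability: mean arterial blood pressure (MBP, mmHg) and
peripheral oxygen saturation (SpO2, %). Threshold alarms on single
channels are noisy; clinicians instead reason jointly and linguistically
("pressure is low *and* saturation is still normal"). `vitalfuzz`
encodes that reasoning as a Mamdani fuzzy controller: crisp readings are
fuzzified into linguistic terms, a small rule base combines them, and the
result is defuzzified onto a 0–10 pre-diagnosis score and classified into
one of five situations — clinical instability, low MBP, hypoxemia,
stable, and high MBP — each with an alert message and urgency level.

## The model

### Membership functions

Both inputs use piecewise-linear (triangular/trapezoidal) membership
functions, specified by breakpoint lists and elicited directly from ICU
specialists:

* MBP, domain [0, 200] mmHg:
  * low: {(0, 1), (60, 1), (80, 0)}
  * normal: {(75, 0), (105, 1), (130, 0)}
  * high: {(126, 0), (138.7, 1), (200, 1)}
* SpO2, domain [0, 100] %:
  * low: {(0, 1), (90, 1), (94, 0)}
  * normal: {(89.2, 0), (96.2, 1), (100, 0)}

Between breakpoints the degree is interpolated linearly; beyond the first
or last breakpoint it extends as a constant at the boundary degree, so a
plateau written as two points behaves as the intended trapezoid shoulder.
A value falling exactly on a breakpoint evaluates to that breakpoint's
degree — no epsilon adjustment — so the published breakpoints are
reproduced bit-exactly.

### Rule base and inference

Six rules cover every combination of the three MBP terms with the two
SpO2 terms:

| MBP    | SpO2   | situation   | urgency |
|--------|--------|-------------|---------|
| low    | low    | instability | high    |
| low    | normal | low_MBP     | low     |
| normal | low    | hypoxemia   | high    |
| normal | normal | stable      | none    |
| high   | low    | instability | medium  |
| high   | normal | high_MBP    | low     |

Inference is classic Mamdani max–min: AND is the minimum of antecedent
degrees, each activated consequent set is clipped at its rule's strength,
and the clipped sets are merged by pointwise maximum into one output
membership function over the score domain.

### Output sets and defuzzification

The output scale assigns the five situations to the bands `< 2.5`,
`2.5–4.5`, `4–6`, `5.5–8` and `> 8` of the [0, 10] score. The band
specification fixes each situation's *support* but not its shape; the
package uses symmetric triangles on the interior bands (peaks at 3.5, 5
and 6.75) and shoulder trapezoids at the ends (instability flat to 1.25,
high MBP flat from 9). This choice preserves the band semantics and gives
the confinement property relied on below: when exactly one rule fires,
the centroid of its clipped consequent necessarily lies inside that
situation's band.

Defuzzification is the centroid (area-weighted mean abscissa), the
standard companion of Mamdani inference. Because every aggregated output
is piecewise linear, the centroid is computed in closed form from the
segment vertices — vertices of all clipped sets plus their pairwise
crossings — rather than on a sampling grid; the test suite checks the
closed form against 10,000-point trapezoidal integration to 1e-6.

The situation *label* is assigned by the maximal rule activation, not by
locating the crisp score in a band: the printed bands overlap (4.5 > 4,
6 > 5.5), so band lookup would be ambiguous. Exact ties between rule
strengths are broken safety-first — higher urgency wins, then the lower
rule id.

```{r}
eng <- default_engine()
infer(eng, mbp = 33, spo2 = 94)
infer(eng, mbp = 126, spo2 = 87)
```

### Degenerate and boundary inputs

Inputs outside the variable domains are clamped to the nearest bound with
a warning. One genuine boundary defect exists in the elicited
breakpoints: the normal-SpO2 function ends at (100, 0) while the low-SpO2
support ends at 94, so at a reading of exactly 100 % every membership is
zero and no rule would fire. Since a perfectly saturated patient is
unambiguously "normal", `fuzzify()` pulls such a zero-coverage boundary
point inward in steps of 0.01 (the resolution at which coverage is
verified) until a term covers it; 100 % therefore classifies as stable
with a weakly positive degree. Membership evaluation itself is left
untouched, so the printed breakpoints still evaluate exactly. Aggregation
and defuzzification additionally guard against an all-zero rule image and
raise a degenerate-output error rather than returning a score from zero
area.

### Ambiguous two-rule inputs

Inputs such as (MBP 36, SpO2 92) activate both the instability rule
(strength 0.5) and the low-MBP rule (strength 0.4). Under
maximal-activation labelling the engine reports instability — arguably
the safer call — and the centroid (≈ 1.99) falls below 2.5. Published
worked examples of this configuration depend on output-set shapes that
are not part of the band specification, so such two-rule cases are
documented here but deliberately not used as correctness anchors; the
engine's behaviour on them is a design consequence, not a reproduction.

## Streaming monitoring

`process_stream()` runs the engine once per record and emits an alert
whenever a patient's label changes *to* a situation whose urgency is not
"none"; the start of a stream counts as a transition, and stable periods
emit nothing. Re-alerts for the same label within `debounce_seconds`
(default 0) are suppressed — at 1 Hz, a patient oscillating across a
membership boundary would otherwise flood the log with one alert per
second. The window is a per-label cooldown rather than a minimum dwell
time: a cooldown still reports a genuinely new deterioration immediately,
whereas a dwell requirement would delay every alert by the window length.

Records without a usable pressure or saturation value keep their place in
the timeline: the last label is carried forward flagged `stale`, and
after `stale_gap_seconds` (default 30 s) of consecutive missing input a
single sensor-fault notice (urgency medium) is emitted — equipment
calibration and motion artifacts are a recognized source of false alarms,
but no published policy exists, so the gap length is a package default.

Mean pressure is taken from the `ABP_mean` channel when present;
otherwise it is reconstructed by the standard physiologic estimate
MAP = (SBP + 2·DBP)/3 and flagged `sys_dia` in the timeline's
`mbp_source` column. That fallback formula is textbook physiology, not
part of the elicited model.

## The synthetic generator

`generate_stream()` emulates the *structure* of per-second multiparameter
monitor records (timestamped multi-channel rows, 1 Hz, dropouts and
spikes) at desk scale, so every stage of the pipeline is exercisable
without access to patient data. Each scenario segment draws MBP and SpO2
from Gaussian noise around a target state's characteristic region; the
regions sit at the cores of the membership functions that define the
states (stable 105/97, low MBP 60/97, hypoxemia 105/85, instability
55/85, high MBP 150/97), since the states have no definition other than
those fuzzy sets. Systolic/diastolic channels are derived to satisfy the
MAP identity, and HR, RR and temperature are emitted at adult resting
norms as inert passthrough channels. All randomness flows from a single
mandatory seed; identical seeds give byte-identical streams.

What the generator does *not* emulate: autocorrelated physiology (each
tick is independent noise — the engine is memoryless, so temporal realism
would not change any tested property), waveform-level content (ECG,
plethysmogram), drug interventions, or inter-channel pathology
correlations. Tests passing on synthetic streams therefore demonstrate
the correctness of the inference and alerting machinery, not clinical
validity on real recordings.

`generate_labelled_dataset()` draws (MBP, SpO2) pairs per class from the
same regions (sd 8 mmHg and 1.5 %, clamped to the domains) and labels
every pair by running the engine itself, so stored labels are
engine-consistent by construction.

## The surrogate classifier

`train_surrogate()` fits a single-hidden-layer feed-forward network
(logistic hidden units, softmax output, BFGS optimization via `nnet`) to
predict the five situations from the raw (MBP, SpO2) pair, min–max
scaled to [0, 1] by the variable domains. The reference topology uses 15
hidden units; the interesting property is not the optimizer but the
agreement of the learned decision regions with the fuzzy labels, which
are simple piecewise-linear cells in 2-D — the internal bar is ≥ 95 %
held-out agreement, and the shipped configuration reaches ≈ 99 %. An
80/20 stratified split is used (no published split exists) and recorded
in the report metadata together with hidden-layer size and seed.

## Problem sizes and numerical choices

The test suite runs the oracle cross-check on 1,000 random input pairs
against an independent dense-grid Mamdani implementation (0.001-step
output grid, trapezoidal centroid), agreement required on labels and to
0.05 on scores; membership interpolation is checked against a hand-rolled
interpolator at 10,000 random points per set to 1e-9; the classifier
suite trains on 4,000 of 5,000 labelled samples. These sizes keep the
whole suite under a minute of compute while leaving each statistical
check far from its threshold.

## Limitations

* Two input variables only; additional vital signs (HR, RR, temperature)
  are carried as passthrough channels but do not enter the rules.
* The rule base and breakpoints encode one specialist elicitation; the
  package deliberately provides no membership tuning or rule learning —
  the YAML config is the editing surface.
* Alert delivery (SMS, e-mail, paging) is out of scope; alerts end at a
  JSON Lines log.
* Labels on ambiguous two-rule inputs follow the maximal-activation rule
  and are not validated against expert judgment.
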