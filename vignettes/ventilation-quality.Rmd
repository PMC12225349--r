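---
title: "Methods: ventilation-quality classification, composite scores and exposure analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ventilation-quality classification, composite scores and exposure analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventqc)
```

## The problem

Lifeguards responding to drowning-related cardiac arrest must deliver
high-quality bag-mask ventilations, and current European guidance cares
about *how* a breath is delivered — an insufflation time of roughly one
second — as much as how much air it delivers. Manikin feedback systems
report volumes in real time but expose insufflation times only as
millisecond event metadata, so evaluating training against the current
recommendations requires joint analysis of volume and time per breath.
`ventqc` implements that analysis for the standard two-minute 30:2
simulation test, repeated at three training-exposure levels (T0 before
training, T1 after one session, T2 after two).

## Event model

Everything operates on a single long-format event table: one row per
ventilation or compression, keyed by `(pair_id, test_id)`, with
millisecond integer start times and durations. Times stay integer
milliseconds until a computation needs seconds, which avoids floating
drift at the classification band edges. Ventilations carry volume (mL),
insufflation time (ms) and an effectiveness flag (the device-captured
inclusion criterion: only effective breaths enter the analysis sample);
compressions carry depth (mm), instantaneous rate (per min) and
correct-depth/recoil/rate flags. The CSV dialect is documented in
`?read_events` and round-trips exactly. Ingestion never silently drops
rows: every malformed row is reported with its line number, and in
`on_error = "report"` mode parsed rows plus reported errors always sum
to the file's data rows.

## Classification rules

A breath with volume $V$ and time $t$ is **green** when
$V \in [500, 600]$ mL and $t \in [0.85, 1.15]$ s, **red** when
$V < 400$, $V > 700$, $t < 0.55$ or $t > 1.45$, and **amber**
otherwise. Two design points deserve note:

* **All band edges are closed.** The red rules are stated as strict
  inequalities, so a breath sitting exactly on an amber edge cannot be
  red; we make the green edges inclusive as well for symmetry. The
  partition property (every $(V, t)$ gets exactly one label) is
  fuzz-tested over the plane and against a brute-force evaluation of
  the six conditions on a dense grid containing every endpoint.
* **The bands are data, not code.** They load from `thresholds.json`,
  because the tiers are deviation bands around reference values rather
  than a physiological constant, and alternative guideline bands should
  be explorable without touching code. The only structural requirement
  is nesting: the green box must lie inside the amber box, which is
  what makes the green-first/red-second/amber-otherwise precedence
  coincide with a true partition.

An "amber" condition phrased as "failing at most one green condition"
is redundant once the green rule has priority and the amber box
contains the green box; we implement the stated precedence and nothing
more.

## Composite scores

Per session: compression quality is the mean of the three
percent-correct compression components; ventilation quality is the
percent of effective breaths classified green; CPR quality is the mean
of the two. These identities are asserted exactly in the tests. The
"correct rate" component is ambiguous in per-session summaries — a
device can score each compression's instantaneous rate or the session's
mean rate. Both modes are provided (`rate_mode`): per-compression
(default, consistent with the other two per-compression components,
band 100–120/min) and all-or-nothing on the session mean. Sessions with
no ventilations score ventilation quality 0 (logged) rather than NA, so
a test in which a rescuer never achieved an effective breath counts as
zero quality, not missing.

No-flow time is the session duration minus the time occupied by
compressions, where a compression at instantaneous rate $r$ occupies
$60/r$ seconds. Published tables label no-flow in seconds while
accompanying text uses percentages; we emit both (`no_flow_s`,
`no_flow_pct`) and label them explicitly.

Group summaries report median and Q1–Q3 with `quantile(type = 7)`
(inclusive linear interpolation), fixed and documented so IQRs are
reproducible; values 1..5 give median 3, IQR 2–4.

## Repeated-measures machinery

Each session variable is compared across the three tests on paired
sessions (the rescuer pair is the unit of analysis; CPR is performed in
pairs). Routing: Shapiro–Wilk per column at $\alpha = 0.05$; any
rejection — or a degenerate column (zero variance, $n < 3$) — routes to
the nonparametric family. The parametric path is one-way
repeated-measures ANOVA (subject error strata via `aov`), pairwise
paired t tests, and paired Cohen's d ($|\bar d| / s_d$, $n-1$
denominator). The nonparametric path is the Friedman test (tie-corrected
statistic, verified against `friedman.test` and against an exhaustive
within-subject permutation oracle at small $n$), pairwise Wilcoxon
signed-rank, and Rosenthal's $r = |z| / \sqrt{N}$.

Choices made where the literature is split:

* **Zeros and ties in the signed-rank test** follow the Pratt rule:
  zero differences participate in ranking and are then discarded, with
  the null moments adjusted. This keeps $z$ well-defined under the
  heavy ties that five-pair data produce, and it is the $z$ that feeds
  Rosenthal's r. An exact sign-flip enumeration mode exists for small
  samples and is checked against an independent oracle.
* **Rosenthal's N** defaults to twice the number of pairs (total
  observations across both related samples) and can be switched to the
  number of pairs (`n_convention = "n"`).
* **Bonferroni** is implemented as p × 3 capped at 1 for the
  repeated-measures pairwise tests.
* Effect-size magnitude labels: < 0.2 Trivial, 0.2–0.5 Small, 0.5–0.8
  Moderate, 0.8–1.3 Large, ≥ 1.3 Very large (lower bounds inclusive).

Sphericity corrections (Greenhouse–Geisser) are deliberately out of
scope; with $k = 3$ and five pairs they would add machinery the design
cannot support.

## Case-control analysis

Category counts per exposure level form three 3×2 tables:
green-vs-amber, green-vs-red, amber-vs-red. Each is tested with the
**uncorrected** Pearson chi-square — with Yates' continuity correction
the published effect sizes of this design are not reproducible, and the
uncorrected statistic is the one whose Cramér's V matches printed
tables to 2 d.p. — and summarised by
$V = \sqrt{\chi^2 / (N (\min(r,c) - 1))}$ with labels 0.1–0.3 Small,
0.3–0.5 Medium, ≥ 0.5 Large (values below 0.1 are labelled Negligible;
labels are computed from the unrounded V). Pairwise decomposition runs
the three 2×2 exposure contrasts; here Bonferroni takes the
threshold-adjustment form — significance iff raw p < 0.05/3 ≈ 0.0167 —
with the raw p reported alongside the verdict, because that is the
convention of the pairwise chi-square decomposition this mirrors.

Odds ratios are the cross-product $(ad)/(bc)$ on each pairwise 2×2,
oriented so the odds of the first-listed category at the higher
exposure are compared against the lower exposure (reference: red
category, no training), with Woolf logit 95% CIs and the
Haldane–Anscombe +0.5 correction (flagged) when a cell is zero. We
report only this standard estimator; no attempt is made to reproduce
odds ratios computed by unstated alternative methods, which on these
tables differ from the cross-product by large factors.

A warning (not an error) accompanies expected counts below 5: the
pooled tables this analysis targets are large enough, and the pairwise
green tables at T0 legitimately contain structural zeros that the
chi-square handles via its expected counts.

## The synthetic-data generator

The simulator exists because the raw per-breath recordings behind
published tables are generally unavailable: it generates event-level
data with the statistical structure the analysis assumes, so every
stage is testable end to end.

* **Marginals.** Volumes, insufflation times, compression rates and
  depths are lognormal, fitted from a median and IQR:
  location $= \ln(\text{median})$, scale
  $= \ln(Q_3/Q_1) / (2 z_{0.75})$. The fit preserves the median exactly
  and the $Q_3/Q_1$ ratio in closed form; a degenerate IQR gives a
  point mass. Volume and time are sampled independently per breath —
  no joint distribution is published — and sampled values are
  independent across events.
* **Defaults are the study conditions.** Five rescuer pairs, three
  tests, 120 s per test, five initial rescue breaths, 30:2 cycles. The
  per-test profiles are fitted to the published per-test medians/IQRs
  (T0: 639 mL / 0.48 s; T1: 452 mL / 0.91 s; T2: 531 mL / 0.94 s, with
  matching rate and depth targets). Effectiveness is Bernoulli with
  p = 1 (the observed effective share), recoil-correct Bernoulli with
  p = 0.85 (a typical trained-cohort value; recoil percentages are not
  published per test).
* **Timeline constants.** The inter-breath gap (1.5 s) and the
  compression-to-ventilation hand-off pause (2.5 s) are tuning
  constants chosen so the deterministic timeline yields the observed
  modal ventilation counts — 15 at T0 (short breaths leave room for
  five full cycles) and 13 at T1/T2 (longer breaths, four cycles).
  They are documented as package choices, not measurements.
* **Reproducibility.** One global seed fans out to per-session
  substreams via a stable hash of `(pair_id, test_id)`, so a session's
  events do not depend on generation order.

What the simulator does **not** model: between-pair random effects
(sessions differ only by sampling noise, so between-session spread is
narrower than real cohorts), within-session fatigue or learning drift,
correlation between volume and time, and rescuer-level behaviour inside
a pair. Passing tests on synthetic data therefore demonstrate the
pipeline's correctness and the dose-response ordering, not the
magnitude of real between-rescuer variability.

## Numerical and testing choices

Problem sizes were chosen to keep the full suite fast while leaving no
asymptotic regime untested: exhaustive permutation oracles run at 3–5
subjects (up to $6^5$ arrangements), the type-I-error check uses 2000
null replicates at 20 subjects (the binomial 3-SE acceptance band
around 0.05 is 0.035–0.065), median-recovery checks use $10^4$ draws
(2% tolerance), and the dose-response ordering is verified over 200
seeded replicate studies. The classification oracle grid contains every
band endpoint explicitly.

## Known limitations

* The repeated-measures unit defaults to the rescuer pair; per-rescuer
  analyses of individually-attributed breaths would need participant
  identifiers the session summaries do not carry.
* The chi-square p-values on the small pairwise green tables rely on
  the asymptotic null with expected counts below 5 (flagged); an exact
  or simulated p is available through the underlying machinery if
  needed.
* Cramér's V labels near a band edge can differ from labels assigned to
  the 2-d.p. displayed value (e.g. V = 0.498 displays as 0.50 but
  labels Medium).
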