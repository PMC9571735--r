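---
title: "Methods: fast-and-frugal trees for perioperative delirium risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fast-and-frugal trees for perioperative delirium risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Postoperative delirium (POD) is an acute, fluctuating disturbance of
attention and cognition that is common, dangerous and under-screened in
older surgical patients. Guidelines call for repeated structured screening
of every patient for days after surgery, which routinely exceeds available
staff time. A practical compromise is risk stratification: a short,
memorizable decision rule that flags the patients who most need intensified
screening, applicable once pre-operatively and again after surgery when the
intraoperative course is known.

`frugalpod` implements this stratification with fast-and-frugal trees
(FFTs) and everything needed to evaluate them honestly: two FFT
construction algorithms, two stronger comparator models tuned to the same
objective, a repeated paired-split comparison protocol, the two published
screening trees, and a synthetic cohort generator calibrated to the
published patient characteristics of the development cohort (which is not
publicly deposited).

## Fast-and-frugal trees

An FFT over cues $x_1, \dots, x_k$ is an ordered list of single-cue
threshold questions. Every non-final node has exactly one *exit*: cases
satisfying the rule leave immediately with a positive (at risk) or negative
decision, everyone else descends. The final node decides both ways. The
exit-side vector is called the tree's *exit structure*; the set of all
$2^{k-1}$ exit structures over a fixed cue order is the *fan*.

All construction and evaluation target **balanced accuracy**,

$$\mathrm{bacc} = \tfrac12(\mathrm{sens} + \mathrm{spec}),$$

because POD prevalence is near 25%: maximizing raw accuracy would buy
specificity by sacrificing sensitivity, the opposite of what a screening
rule is for. The goal is exposed as a sensitivity weight $w$ (goal
$= w\,\mathrm{sens} + (1-w)\,\mathrm{spec}$, default $w = 0.5$) for
sensitivity analyses only.

Beyond the confusion-matrix metrics, `evaluate()` reports frugality: `mcu`,
the mean number of cue values looked up per case, and
`pci` $= 1 - \mathrm{mcu}/m$, the fraction of available information
ignored. The denominator $m$ is the number of cue columns in the supplied
table (23 pre-operative cues, 25 with the two intraoperative cues in the
default dictionary); published frugality figures do not pin this
denominator exactly, so it is documented here as a definition of this
package.

### Single-cue rules

`best_split_for_cue()` scans every unique observed value as a candidate
threshold, in both directions (`>` and `<=`, the satisfied side predicting
positive), and keeps the rule with the best goal. Thresholds are restricted
to observed values deliberately: the data cannot distinguish finer cuts,
and it keeps ordinal cues on their coding grid. Ties are broken
deterministically — higher sensitivity first (a screening rule should not
silently give up hits), then lower threshold, then direction `<=` before
`>`; cue-level ties in rankings fall back to alphabetical cue name. These
tie rules are normative for this package: they make every construction
reproducible to the bit.

### ifan

`build_ifan()` ranks cues once by their *marginal* single-cue goal on the
full training set, keeps the top `max_levels` (default 5) in rank order
with their marginal thresholds, and exhaustively scores the full fan: every
depth $k$ and all $2^{k-1}$ exit structures — 31 candidates at depth 5.
Ties prefer the shallower tree, then the earlier candidate in enumeration
order (positive exits enumerated first). The exhaustiveness of the fan is
testable and tested: an independent brute-force enumeration must agree
exactly.

### dfan

`build_dfan()` recurses instead: at each node it re-scores every unused cue
*on the cases that actually reach that node*, places the best cue there,
and branches over both possible exits, each branch defining different
survivors and hence a different continuation. Every completed candidate
(one per depth per exit path, default `max_levels` 4) is scored on the full
training set. A deeper tree is adopted only when it strictly improves on
the best shallower one, so when no fourth cue helps the algorithm returns a
truncated tree.

The cue placed at each node is selected greedily. Exhaustive search over
*all* cue orders with the same per-node conditional thresholds can
therefore beat dfan on adversarial or small noisy samples; on random small
binary-cue instances the greedy construction attains the all-orders
optimum most of the time, but not always. This is a property of the
algorithm, not a defect of the implementation, and the implementation is
instead verified against an independent re-derivation of the greedy
construction itself.

## Comparator models

Both comparators are deliberately adapted to the balanced-accuracy target:

* **UDT** (`fit_weighted_tree()`): an unconstrained CART-style tree via
  `rpart`, minimum split size 20, complexity parameter $10^{-5}$, with
  positive training cases weighted by the negative/positive ratio. The
  bespoke contract here is the weighting and the two control parameters;
  tree growing itself is delegated to `rpart`, the standard implementation.
* **LogReg** (`fit_threshold_logreg()`): maximum-likelihood logistic
  regression via `glm`, predicting positive when the estimated probability
  reaches the decision threshold, which is set to the *training base rate*
  rather than 0.5. Ordinal cues enter as their numeric codes, binary cues
  as 0/1. Ties at the threshold count as positive — with an
  intercept-only model every estimated probability equals the base rate
  exactly, and the convention makes that boundary case a sens = 1,
  spec = 0 screener rather than the reverse, consistent with not
  sacrificing sensitivity.

## The data model and imputation

Cohorts are plain tibbles: one row per patient, numeric cue columns, a
binary `pod` outcome, `NA` as the single missing marker (CSV: empty cell
or `.`). The default cue dictionary (`pod_cues()`) codes site of surgery
1 = intracranial, 2 = intrathoracic/intra-abdominal/pelvic, 3 = peripheral;
frailty 0 = robust, 1 = pre-frail, 2 = frail; ASA PS 1–4. The comorbidity
list contains exactly the four named conditions (hypertension, coronary
artery disease, diabetes, stroke/TIA); premedication is a single binary
cue. Both choices resolve open-ended phrasing in the source material and
are isolated in the dictionary should users need different codings.

`impute_missing()` applies deterministic single imputation **on the full
table before any splitting**, mirroring the study protocol in which the
dataset was completed once before the model comparison began. This leaks
no outcome information (imputation statistics never see the labels), though
it does mean test halves share marginal information with training halves;
per-fold imputation would be the stricter design and is intentionally not
what this package reproduces. Rules: sample median for ISCED, GDS, pack
years and anesthesia duration; constant 0 (no impairment) for the four
comorbidities, cognitive impairment, ADL, IADL and premedication; constant
3 (no impairment) for MNA; dictionary fallback elsewhere (median for
numeric, mode for ordinal/binary). Even-count medians take the mean of the
two central order statistics and are then rounded half-up onto the coding
grid for ordinal and integer-coded cues; mode ties resolve to the smallest
value. Both conventions are package decisions where the protocol is
silent.

## The comparison protocol

`run_comparison()` repeats: split the cohort into random halves of
$\lceil n/2 \rceil$ and $\lfloor n/2 \rfloor$ (394 patients → 197 + 197),
fit every model on the same training half, evaluate on both halves. The
study protocol uses 10,000 splits, with the expensive dfan restricted to
the first 1,000; both counts are parameters. Per-trial split seeds derive
from the master seed by a fixed affine counter formula kept below
$2^{31}$, so trial $t$ is reproducible in isolation and "the first 1,000
splits" means the same partitions on every machine.

A model that fails on a training half (e.g. a one-class half at small
$n$) is recorded and skipped; failing on more than 1% of its trials aborts
the run — silent degradation would bias the aggregates. Aggregates are
per-model, per-phase means with SE = SD/$\sqrt{\text{trials}}$; pairwise
win rates count strict test-bacc superiority on common trials, crediting
ties to neither model.

## The synthetic cohort generator

The development cohort is available only on request, so the generator
exists to make every pipeline property *testable*. It emulates the
published class-conditional marginals at POD prevalence 0.251: age
(discretized normal, medians 74/72, SDs from the printed IQRs, floored at
the study's inclusion age 65), ASA PS (printed 3–4 mass 56.6%/31.2%,
allocated within the 1–2 and 3–4 bands at 20/80 and 90/10 — the bands'
interior split is not published), CCI (discretized gamma matched by
moments to 2.14 ± 1.5 / 1.43 ± 1.6, negative mass impossible by
construction), frailty (printed pre-frail/frail percentages, robust as the
complement), surgery site (printed level frequencies, renormalized because
the printed percentages sum to 100.1%), and anesthesia duration
(log-normal matched to the printed median and log-IQR; a two-parameter
family cannot also match each asymmetric quartile individually, and the
quartile skew is the reason for choosing log-normal over normal). All
remaining cues are outcome-independent noise with marginals plausible for
an elective-surgery population aged 65+. Every cue is drawn by pushing one
uniform through a quantile function, which is what makes the optional
Gaussian-copula correlation hook possible without touching any marginal;
it defaults off because only marginals are published.

What the generator does **not** emulate: the real joint dependence
structure among cues (conditional independence given outcome is an
assumption, not a finding), measurement error, and cohort-specific
selection. Passing protocol tests on synthetic cohorts therefore
demonstrates correctness of the machinery and qualitative reproduction of
the study's phenomena (overfitting direction, flexibility ordering,
sens/spec trade-off), never replication of the study's numeric results —
those depend on the real data.

`generate_planted()` inverts the testing problem: cues first, outcome =
a known tree's own classification, optionally label-flipped. Zero-noise
planted cohorts are perfectly separable by construction, so a builder that
fails to reach training bacc 1.0 on them is wrong; several distinct
perfect trees usually tie, so structure recovery is asserted up to
decision equivalence on fresh data.

## The frozen screening trees

`preoperative_tree()` encodes the published four-cue rule. Only its first
node is anchored textually (CCI > 1 exits positive) along with the cue
order (CCI, site, ASA PS, frailty) and the final node's coding
(frailty ≤ 0 robust → negative). The middle nodes' exits and thresholds
were published only graphically; the defaults here (peripheral site →
negative, ASA PS > 2 → positive) are inferred from the cohort's
class-conditional marginals, documented as inferences, and overridable.
`postoperative_tree()` (duration of anesthesia, age, CCI) ships **no**
default thresholds at all: its cut points were not published in text form,
and inventing defaults would misrepresent the rule — callers must supply
all three.

## Problem sizes and numerical choices

The test suite checks oracle equivalence on 50 random instances of up to 4
binary cues and n ≤ 30 (where exhaustive enumeration over all cue orders,
exit structures and thresholds is exact and fast), planted-tree recovery
at n = 500 with 20 noise seeds, generator calibration at n = 100{,}000
with 3σ Monte-Carlo bounds, and the full four-model protocol at n = 394
with 200 paired trials — sizes chosen so the complete suite runs in a few
minutes while every bound retains its statistical meaning.
`scripts/acceptance.R` re-runs the same pipeline end to end at the same
sizes. All floating-point comparisons of construction goals use exact
equality against oracles computed by the same arithmetic, which is valid
because both routes sum the identical small integer counts.

## Known limitations

* Greedy dfan is not the all-orders optimum (see above); neither is the
  original algorithm it implements.
* Single fixed imputation before splitting slightly couples train and test
  halves; this mirrors the reproduced protocol rather than best current
  practice.
* The generator's conditional-independence assumption makes synthetic
  cohorts *easier* than real ones for flexible models; comparative results
  on synthetic data are qualitative only.
* No significance testing on trial distributions is provided, matching the
  reproduced protocol's descriptive reporting.
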