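---
title: "The priority-tag model: predictions, simulation and capacity selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The priority-tag model: predictions, simulation and capacity selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prioritytag)
```

## The model

Visual search displays in the placeholder paradigm contain `n` letters, of
which `x` appear as **abrupt onsets** (at previously empty locations) and the
remaining `n - x` as **no-onset** items (revealed by removing segments from
figure-8 placeholders). The priority-tag model explains how onsets capture
attention through three assumptions:

1. Up to `c` onsets receive a *priority tag*; when `x > c`, a uniformly
   random subset of `c` onsets is tagged.
2. Search proceeds in two stages: the tagged (priority) set is inspected
   before everything else.
3. Within each stage, items are inspected in uniformly random order, and
   search self-terminates at the target.

The quantity of interest is `y`, the expected number of item comparisons
until the target is found. Writing `t` for the target type, the expectation
dispatches on `c < x` versus `c >= x`:

| branch | target | `y` |
|---|---|---|
| `c < x` | onset | `(n + c + 1)/2 - c n / (2x)` |
| `c >= x` | onset | `(x + 1)/2` |
| `c < x` | no-onset | `(n + c + 1)/2` |
| `c >= x` | no-onset | `x + (n - x + 1)/2` |

Two degeneracies anchor the predictions: with `c = 0` every cell reduces to
the unordered scan `(n + 1)/2`, and a display consisting only of the
target's own type (`x = n` with an onset target, or `x = 0` with a no-onset
target) also yields `(n + 1)/2` at every capacity — 4.5 comparisons for
`n = 8`. At full capacity (`c = n`) both target-type curves are linear in
`x` with slope 1/2 and a constant vertical gap of `n/2` comparisons.

```{r predictions}
prediction_table(c = 1, n = 8, x_values = 0:8, mode = "mixed")
```

In the *blocked* variant the participant knows in advance which `r` items
(the search-relevant set) can contain the target, so tagging operates on the
relevant set regardless of its onset status and the onset-target formulas
apply with `x := r` to both block types
(`blocked_expected_comparisons()`).

### Exactness and the enumeration oracle

All expectations are ratios of small integers. Internally they are computed
in integer arithmetic and reduced (`exact = TRUE` exposes the fraction), so
the independent brute-force oracle — `enumerate_expected_comparisons()`,
which sums over tagged subsets, target identities and scan positions with
combinatorial weights and never touches the closed forms — can be compared
with *equality*, not a floating tolerance. The test suite sweeps all 648
valid `(c <= 8, n <= 8, x, t)` cells this way. A trial-level simulator
(`simulate_search_trial()`) realises the generative story literally and
provides a second, Monte-Carlo route to the same expectations.

Capacities above `n` are accepted and clamped to `n`: they are
prediction-identical to `c = n`, and a library should not fail on a larger
request. Invalid design cells (an onset target with `x = 0`, a no-onset
target with `x = n`) are rejected with a diagnostic naming the violated
invariant, and prediction tables omit such cells rather than imputing them.

## From comparisons to reaction times

Observed RTs are modelled linearly in the expected comparisons:

* mixed designs: `RT = a y(c; n, x, t) + b t + d`, with the indicator
  `t = 1` for onset targets;
* blocked designs: `RT = a y(c; n, r) + d`, fitted separately per
  target-type block.

`a` is the search rate (ms per comparison), `b` the onset advantage (an
encoding benefit for unmasked items, so `b < 0`), and `d` the residual
visuo-motor time. The indicator coding deserves a note: the field's
descriptions of this regression are ambiguous between coding onset targets
as 1 or 0. We code onset = 1, which makes a *negative* `b` an onset
advantage and reproduces the sign pattern of published coefficient tables.

## The synthetic-data generator

No raw behavioural data are deposited for the classic experiments, so
`build_design()` + `generate_trials()` reconstruct their statistical
structure exactly:

* **exp1** — mixed presentation, `n = 8`, onsets in `{0, 1, 2, 4, 6, 8}`,
  400 experimental trials per participant with the published per-cell
  counts; at every onset count the target is an onset on exactly `x/8` of
  trials (the inverse-probability allocation that keeps target type
  uninformative).
* **exp2** — adds onset counts 3 and 5 (560 trials).
* **exp3** — target type blocked in two counterbalanced sessions
  (alternating by participant parity), 32 trials per target type and
  relevant-set size 1–8 (512 trials).

Each participant draws individual coefficients around the population values
(truncated normals keep `a > 0` and `d > 0`); each trial draws its
comparison count from the simulator at the generating capacity `c_true` and
adds Gaussian noise (`sigma`, ms). Defaults are the scale of the published
pooled fits: `a = 31.6`, `b = -74.1`, `d = 764`, `sigma = 150` ms, a 3.7%
lapse rate and 1.1% RT outliers. The between-participant SDs
(`a_sd = 8`, `b_sd = 25`, `d_sd = 60`) are not published quantities; they
were chosen once as plausible individual-difference magnitudes (roughly a
25% coefficient of variation on the search rate) and — because every
participant contributes to every design cell — they are largely absorbed by
the regression coefficients and barely affect capacity selection.

Three deliberate simplifications:

* **The noiseless limit.** With `sigma = 0` the generator places every trial
  exactly on the model surface by substituting the *expected* comparison
  count for the sampled one. Comparison-count sampling is treated as part of
  trial noise; this makes "noiseless generation, then fitting" recover the
  generating coefficients to machine precision — the pipeline's key
  self-diagnostic — which finite sampled counts could never do.
* **Lapses are condition-independent.** Errors occur at a single rate per
  trial; the small published target-type error difference is not modelled,
  as it never enters the fitted model. Timeout trials (RT above 10 s) are
  censored at 10,000 ms and flagged as errors.
* **Gaussian trial noise** keeps OLS recovery unbiased; a log-normal option
  exists for robustness checks. The colour manipulation of the second
  experiment is not a generative mechanism — exp2 differs from exp1 only in
  its design cells.

What passing tests on these data do *not* show about real data: real RT
distributions are right-skewed with sequential dependencies, fatigue and
practice effects, and strategy differences between participants; the
generator emulates none of these, so recovery results here bound what the
designs can resolve under ideal, exchangeable noise.

## Preprocessing and fitting

`preprocess()` drops practice trials, counts error trials into per-cell
error rates while excluding them from RT means, and excludes outlier RTs
below 200 ms or above 2000 ms (strict inequalities). For every cell,
`used + errors + outliers = raw`; cells losing all trials are reported in an
attribute rather than silently dropped or zeroed.

`fit_capacity()` runs OLS on pooled cell means — the grand mean over
participants' cell means, unweighted so that each participant counts
equally (weighting by the highly unbalanced trial counts is available as an
option). Endpoint cells (`x = 0`, `x = 8`) are included wherever defined.
Capacity 0 predicts no RT variation and is flagged rather than fitted;
rank-deficient design matrices are rejected with a diagnostic. In blocked
fits the `r = 1` level can be excluded (`exclude_r = 1`): with a single
relevant item the target location is fully predictable and the serial model
does not apply.

`compare_capacities()` then:

1. fits every capacity `0..n` (capacities in the same prediction-identical
   group — see `equivalent_capacities()` — carry identical fits);
2. computes per-participant R² values, one column per *distinguishable*
   capacity level;
3. runs a one-way repeated-measures ANOVA on those R² values with the
   Greenhouse–Geisser epsilon (computed from the covariance of the
   within-participant contrasts, clamped to `[1/(k-1), 1]`), falling back to
   an explicit "inapplicable" flag when the R² columns are constant;
4. reports unadjusted pairwise paired t-tests (Fisher's LSD), the
   procedure conventionally used after this ANOVA;
5. selects the capacity with the highest pooled R², breaking exact ties
   toward the smaller capacity and always reporting the full
   prediction-identical group — parsimony arguments between near-tied
   capacities are the analyst's to make, so the full R² table is returned.

`classify_participants()` assigns each participant their argmax-R² capacity
(smallest on ties) and counts how many fall at or below a boundary
(default 2), the conventional split between small-capacity and
large-capacity searchers.

## Recovery: what the designs can and cannot resolve

`run_recovery()` closes the loop: simulate, refit, and score whether the
selected capacity lands in the generating capacity's equivalence group. Two
structural facts shape the results. First, the mixed designs cannot
distinguish capacities 6–8 at all (identical predictions on their cells),
so recovery is scored against equivalence groups. Second, *neighbouring*
capacities above the middle of the range differ only at the `x = 6` cells,
and only by 0.17–0.5 expected comparisons (≈ 5–16 ms at the default search
rate). At the default 150 ms trial noise with 22 participants, those few
milliseconds sit at the edge of the pooled cell-mean precision, so selection
at generating capacities in the upper-middle range (e.g. 4 or 8) misfires
into adjacent capacities in a nontrivial fraction of replicates, while
small generating capacities (1–2), whose predictions differ across many
cells, are recovered nearly always. The acceptance-level recovery check in
the test suite (100 replicates × 22 participants per generating capacity,
exp1 design) measures exactly this, and its outcome should be read as a
property of the design-plus-noise combination, not of the estimator:
an idealized selection given the true cell means plus cell-mean noise shows
the same ceiling.

Problem sizes throughout the packaged analyses were chosen to keep each
check sharp but cheap: 648-cell exact oracle sweeps, 10⁵-trial Monte-Carlo
per condition, and 100-replicate recovery runs.

## Numerical and design choices, in brief

* Exact integer fractions internally; floats only at the API surface.
* Capacity clamping at `n`; validation errors name the violated invariant.
* Selection ties break toward smaller capacity (exact ties only, tolerance
  `1e-12`); equivalence groups are always reported alongside.
* GG epsilon clamped to its theoretical range; LSD deliberately unadjusted.
* Every stochastic entry point takes an explicit integer seed, and every
  written artifact embeds the configuration (plus hash) that regenerates it
  bit-for-bit.

## Limitations

* The simulator has no notion of inspection durations, eye movements,
  parallel processing or target-absent displays; it is the minimal
  generative counterpart of the closed forms.
* Pooled-fit standard errors are ordinary OLS SEs on cell means; no
  mixed-effects or Bayesian machinery is provided.
* The descriptive repeated-measures ANOVAs on raw RTs and error rates that
  usually accompany such experiments are out of scope here; the package's
  ANOVA machinery exists solely for the R² model-comparison step.
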