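# prioritytag

Do abrupt visual onsets capture attention, and how many of them can the
visual system prioritise at once? `prioritytag` implements the
**priority-tag model** of attention capture in serial self-terminating
visual search, for researchers in visual attention and psychophysics who
want to fit it to reaction-time data or probe what their designs can
resolve.

## The model

A search display holds `n` items, `x` of which are abrupt onsets. Up to `c`
onsets receive a priority tag (a random subset when `x > c`); the tagged set
is scanned before everything else, each stage in random order, and search
stops at the target. The expected number of comparisons `y` to find the
target is, by target type `t`:

| | onset target | no-onset target |
|---|---|---|
| `c < x` | `y = (n + c + 1)/2 − cn/2x` | `y = (n + c + 1)/2` |
| `c ≥ x` | `y = (x + 1)/2` | `y = x + (n − x + 1)/2` |

Reaction times are then modelled as `RT = a·y(c; n, x, t) + b·t + d`
(mixed designs; `t = 1` for onset targets, so `b < 0` is an onset
advantage) or `RT = a·y(c; n, r) + d` (blocked designs with `r`
search-relevant items). Sweeping `c` from 0 to `n` and comparing fits —
pooled R² for selection, per-participant R² for a repeated-measures ANOVA
with Greenhouse–Geisser correction and LSD post-hocs — estimates the
priority-set capacity.

The package provides:

* closed-form predictions, exact in rational arithmetic
  (`expected_comparisons()`, `blocked_expected_comparisons()`,
  `prediction_table()`, `equivalent_capacities()`);
* two independent oracles: an exhaustive enumerator
  (`enumerate_expected_comparisons()`) and a trial-level stochastic
  simulator (`simulate_search_trial()`, `mc_expected_comparisons()`);
* synthetic trial-table generation matching three classic onset-search
  designs exactly (`build_design()`, `generate_trials()`);
* preprocessing, per-capacity OLS fits and capacity selection
  (`preprocess()`, `fit_capacity()`, `compare_capacities()`,
  `classify_participants()`, `run_recovery()`);
* pipeline commands (`cmd_predict()`, `cmd_simulate()`, `cmd_fit()`,
  `cmd_recover()`) and a thin Rscript front-end in `inst/cli/`.

## Worked example

Predictions for a display of eight items under a 1-tag model — the no-onset
curve saturates immediately while the onset curve climbs toward 4.5:

```r
library(prioritytag)
expected_comparisons(c = 1, n = 8, x = 0:7, target_type = "no_onset")
#> [1] 4.5 5.0 5.0 5.0 5.0 5.0 5.0 5.0
expected_comparisons(c = 1, n = 8, x = 1:8, target_type = "onset")
#> [1] 1.000000 3.000000 3.666667 4.000000 4.200000 4.333333 4.428571 4.500000
```

Simulate 22 participants through the mixed display-size-8 design at a
generating capacity of 1, then sweep all capacities:

```r
trials <- generate_trials(build_design("exp1"), generative_params(c_true = 1),
                          n_participants = 22, seed = 7)
cmp <- compare_capacities(trials, "eq5_mixed")
cmp
#> <model_comparison> eq5_mixed, capacities 0-8
#> # A tibble: 9 × 9
#>       c     a  a_se     b  b_se     d  d_se     r2 flag
#>   <int> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>  <dbl> <chr>
#> 1     0  NA   NA     NA   NA      NA   NA   NA     predicts no variation
#> 2     1  30.1  2.20 -75.4  5.28  772.  11.1  0.994 <NA>
#> 3     2  24.3  4.63 -66.5 14.3   793.  25.0  0.964 <NA>
#> 4     3  23.1  5.30 -61.4 17.7   795.  29.7  0.952 <NA>
#> 5     4  20.3  6.05 -62.1 22.2   806.  35.2  0.931 <NA>
#> 6     5  19.1  6.12 -62.9 23.3   811.  36.2  0.925 <NA>
#> 7     6  17.6  6.17 -65.3 24.6   818.  37.2  0.917 <NA>
#> 8     7  17.6  6.17 -65.3 24.6   818.  37.2  0.917 <NA>
#> 9     8  17.6  6.17 -65.3 24.6   818.  37.2  0.917 <NA>
#> selected capacity: 1 (prediction-identical group: 1)
#> R^2 ANOVA: F(5, 105) = 7.61, GG epsilon = 0.277, p_GG = 0.005317
```

Reading the table: each row is one capacity hypothesis. The generating
capacity (1) wins with the recovered search rate `a ≈ 30` ms/comparison,
onset advantage `b ≈ −75` ms and base time `d ≈ 772` ms; goodness of fit
declines monotonically for larger capacities, and capacities 6–8 carry
identical fits because this design cannot distinguish them. The capacity 0
row is flagged — a 0-tag model predicts no RT variation at all. The ANOVA
confirms the R² differences across participants are systematic.

```r
classify_participants(cmp)$n_at_or_below
#> [1] 16   # of 22 participants best fit by a capacity <= 2
```

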