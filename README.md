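# reopairs

Rank-based single-sample classifiers from within-sample relative expression
orderings (REOs) of miRNA pairs.

## The problem

Serum miRNA signatures for cancer screening are usually linear risk scores
over absolute expression values. Absolute values are fragile: they shift with
batch, platform scaling, and normalisation choices, so a risk threshold fitted
on one cohort rarely transfers to a single new sample measured elsewhere. The
*relative ordering* of two miRNAs within one sample — is E<sub>a</sub> >
E<sub>b</sub> or E<sub>a</sub> < E<sub>b</sub>? — is invariant to any
monotonic transform of that sample's values and needs no cross-sample
normalisation at all. `reopairs` builds diagnostic classifiers from such
orderings, in the top-scoring-pairs family, and applies them to one sample at
a time.

## The method

Given a large non-cancer cohort, a case/control training cohort, and the
thresholds (stability 95%, FDR q < 0.05, case reversal ≥ 70%, panel search up
to 31 pairs):

1. **Stable pairs.** For each of the M(M−1)/2 miRNA pairs, the pair (a, b) is
   *stable* if P(E_a > E_b) = m/N exceeds the stability threshold in the
   non-cancer cohort; it is stored in that control orientation. Stable pairs
   are optionally re-checked ("retained") in the training controls.
2. **Reversed pairs.** For each stable pair, the 2×2 table of strict
   orderings in controls (n₁, n₂) and cases (m₁, m₂) is tested with a
   one-sided Fisher's exact test for enrichment of the reversed ordering
   E_a < E_b in cases; p-values are BH-adjusted. Candidates must have
   q < 0.05 and a case reversal rate m₂/(m₁+m₂) ≥ 0.70.
3. **Panel search.** Each candidate pivots a greedy set-cover combination:
   pairs are added while they strictly increase the fraction of case samples
   in which at least one member is reversed. Pairs are then ranked by how
   often they occur across all combinations.
4. **Panel size.** For each odd n, the top-n panel classifies the training
   cohorts by majority vote (a sample is called cancer when more than half
   of the pairs show E_a < E_b), and the evaluation index √(PPV × NPV) is
   computed. The smallest n attaining the maximal index is the final
   single-sample classifier (SSC).

The two published serum panels — the 13-pair ovarian-cancer-vs-non-cancer
panel and the 17-pair ovarian-vs-other-cancers panel — ship with the package
(`bundled_classifier()`), along with the published linear 10-miRNA comparator
(`yokoi_index()`), which depends on absolute values and serves as the
negative control for transform invariance.

## Worked example

Cohorts are simulated with planted reversed pairs, then the full pipeline
runs on them:

```r
library(reopairs)

sim <- generate_cohorts(sim_config(n_mirnas = 100, n_controls = 150,
                                   n_cases = 80, n_planted = 11, seed = 42))

stable <- mine_stable_pairs(sim$controls, threshold = 0.95)
#> # Stable pairs: 4950 pairs (stability > 0.95, N = 150)

cand <- stable |>
  contingency_counts(sim$controls, sim$cases) |>
  fisher_reversal_test() |>
  select_candidates(q_threshold = 0.05, reversal_threshold = 0.70)
nrow(cand)
#> [1] 11

sel <- cand |>
  build_combinations(sim$cases) |>
  rank_by_frequency() |>
  select_classifier(sim$cases, sim$controls)
sel
#> # Panel selection over odd n in 1..11
#> # chosen n = 5 (eval index sqrt(PPV*NPV) = 1.0000)
#> # Pair-panel classifier 'ssc': 5 pairs, vote rule majority_reversed
```

All 11 candidates are the 11 planted pairs, and the selected 5-pair panel is
a subset of them. Applying the panel one sample at a time:

```r
classify_matrix(sim$cases, sel$classifier)
#> # A tibble: 80 x 6
#>   sample_id votes_reversed votes_conforming n_usable score label
#> 1 case_0001              4                1        5   0.8 case
#> 2 case_0002              5                0        5   1   case
#> ...
```

Each row is one independent vote: `score` is the fraction of panel pairs
showing the reversed ordering, and `label` is `case` when that fraction
exceeds one half. On the combined training cohorts,
`evaluate_predictions()` reports sensitivity, specificity, accuracy, PPV,
NPV, √(PPV×NPV) and the rank AUC (all 1.0 in this easy synthetic instance).

Expression tables read from plain TSV or GEO series-matrix text via
`read_expression_matrix()`; `autoplot(sel)`, `plot_reversal()` and
`plot_vote_scores()` visualise the selection curve, the reversal screen and
the vote distribution. A command-line front end with one subcommand per
stage lives at `inst/cli/reopairs.R`.

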