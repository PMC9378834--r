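---
title: "Rank-based single-sample miRNA pair classifiers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based single-sample miRNA pair classifiers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reopairs)
```

## The model

An expression study is a matrix E with M miRNAs and N samples; `reopairs`
uses nothing of E except, within each sample, the binary relation
E_a > E_b between pairs of miRNAs (the within-sample relative expression
ordering, REO). The working assumption is biological: in non-cancer serum,
most miRNA pairs sit in a stable ordering across individuals, and malignancy
perturbs a subset of those orderings. A classifier built only from orderings
inherits a strong practical property — invariance to any strictly increasing
transform applied to a sample's values — so it can be applied to one sample
with no reference cohort, no normalisation, and no fitted risk threshold.

The pipeline estimates three nested objects:

1. **Stable pairs.** For pair (a, b), with E_a > E_b observed in m of N
   control samples, P(E_a > E_b) = m/N. The pair is *stable* when this
   exceeds the stability threshold (default 0.95), and it is stored in its
   majority (control) orientation. When a second, independent control cohort
   is available, pairs are additionally required to hold in more than the
   same proportion of it (`retain_in_cohort()`); this guards against
   cohort-specific orderings.
2. **Reversed pairs.** For each stable pair the orderings are tabulated as
   controls (n1 with E_a > E_b, n2 with E_a < E_b) versus cases (m1, m2).
   A one-sided Fisher's exact test asks whether cases are enriched for the
   reversed ordering; BH adjustment yields q-values. Candidates must have
   q below the FDR threshold (default 0.05) and a case reversal rate
   m2/(m1+m2) of at least the reversal threshold (default 0.70).
3. **The voting panel.** Every candidate serves once as the pivot of a
   greedy set-cover combination: starting from the pivot, the pair adding
   the most not-yet-covered case samples (a sample is covered when at least
   one member pair is reversed in it) is appended until no pair strictly
   increases coverage. Pairs are then ranked by their frequency of
   occurrence across all combinations, and for each odd n the top-n panel is
   scored on the training cohorts by majority-reversed voting with the
   evaluation index sqrt(PPV x NPV). The smallest n attaining the maximal
   index becomes the final classifier.

Prediction is a per-sample majority vote: each panel pair votes "reversed"
(E_a < E_b), "conforming" (E_a > E_b), or abstains on an exact tie; the
sample is called a case when reversed votes exceed half the usable panel.
The vote fraction (reversed votes / usable pairs) is the continuous score
used for ROC ranking.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| stability threshold | 0.95 | proportion of cohort | definition of a stable pair; strict `>` |
| retention threshold | 0.95 | proportion of cohort | stability re-check in the training controls |
| q threshold | 0.05 | BH FDR | significance of reversal |
| reversal threshold | 0.70 | proportion of tie-free cases | minimum case reversal rate; inclusive `>=` |
| max_top | 31 | pairs | largest panel size searched (odd n only) |
| alternative | "greater" | – | Fisher sidedness; two-sided available |
| coverage mode | "union" | – | joint-coverage semantics in the greedy search |

The defaults are the thresholds under which the published serum panels were
derived. `max_top = 31` mirrors the published search depth; no rule for
deriving it from the data is stated, so it is exposed as a free parameter.

## Numerical and convention choices

* **Ties.** An exact tie E_a = E_b counts toward neither orientation,
  everywhere: in stability counting, in the contingency table, in coverage,
  and in voting (the pair abstains but still counts in the usable panel).
  Equality carries no ordering information, and excluding it is conservative
  against spurious stability. Microarray intensities rarely tie, so this
  convention is a declared decision rather than an inference about the
  original analysis.
* **Strict vs inclusive thresholds.** Stability uses strict `>` (a pair at
  exactly 95% is not stable), following the defining wording "greater than a
  threshold"; the candidate reversal rate uses inclusive `>=` 0.70,
  following the formal "at least k%" definition over the narrative
  "more than 70%".
* **Fisher sidedness.** The screening hypothesis is directional — only
  reversal-direction pairs are usable downstream — so the default test is
  the one-sided exact hypergeometric tail P(X >= m2) conditional on the
  margins, computed vectorised via `phyper()` and verified in the test suite
  against both `fisher.test(alternative = "greater")` and an independent
  `dhyper()` tail sum. Two-sided testing is available as an option.
* **Union coverage.** Joint coverage of a combination is the fraction of
  case samples in which *at least one* member pair is reversed. Only union
  semantics make the greedy stopping rule ("no further increase") and the
  compensation rationale coherent; the intersection reading (all members
  reversed) is implemented behind `mode = "intersection"` for sensitivity
  analysis, where it degenerates to single-pair combinations.
* **Tie-breaking.** Wherever candidates tie (equal coverage gain, equal
  frequency), preference is: smaller q-value, then higher reversal rate,
  then lexicographic (a, b). This makes the whole search a pure function of
  its inputs; repeated runs are bit-identical.
* **Degenerate inputs.** Missing expression values are rejected at read
  time (the ordering of an unobserved value is undefined); an all-zero
  contingency table is an error, not p = 1; a panel metric with a zero
  denominator is NA with a warning (and an evaluation index of 0 during
  panel search, so such panels are never selected); exact half-votes —
  possible only with ties or permissively skipped pairs — resolve to the
  non-cancer label.
* **Missing panel miRNAs.** Strict mode (error) is the default: silently
  shrinking the panel changes the effective voting threshold. Permissive
  mode skips affected pairs, decrements the usable panel, and warns.
* **AUC.** The closed-form Mann–Whitney rank statistic with midranks for
  ties, not trapezoidal integration — exact under the heavily tied vote
  fraction scores. The published panels' ROC statistic is not named in the
  source material; the vote fraction is the canonical choice for voting
  panels and is the declared scoring rule here.

## What the simulator emulates — and what it does not

`sim_config()` / `generate_cohorts()` produce the regime the method
assumes. Per-miRNA baselines sit on a log2 grid with gap `baseline_spread`
(default 1); each sample adds independent Gaussian noise (`noise_sd`,
default 0.15) on the log scale and values are exponentiated, giving
arbitrary positive units. Ordering violations come from two sources: an
explicit background process that swaps baseline-adjacent values within a
sample at rate `background_flip_rate` (default 0.02, both cohorts), and
residual noise (with the defaults, a noise-induced flip has probability
about 1e-6; configurations where noise would swamp the baseline gap are
rejected with the violated inequality). Planted pairs are the first
`n_planted` disjoint baseline-adjacent pairs; in each case sample, each
planted pair is independently reversed with probability
`reversal_rate_cases` (default 0.9) by swapping the two values, which
preserves the marginal value distribution so mean expression does not
trivially reveal the planted pairs. Generation is fully reproducible from
the seed, and the returned truth table stores realised reversal fractions
recounted directly from the emitted matrices.

The default configuration (200 miRNAs, 200 controls, 100 cases, 20 planted
pairs, case reversal 0.9, background flips 0.02) is the package's reference
recovery condition: under it, the full pipeline recovers exactly the planted
pairs as candidates and selects a panel from them with training sensitivity
and specificity above 0.95.

What the simulator does *not* emulate: batch effects and platform drift
(the method's robustness to them is precisely its ordering invariance, which
the tests exercise directly via monotone-transform checks), realistic
platform intensity distributions, correlated noise between miRNAs, and
overlapping reversal structure (planted pairs are miRNA-disjoint so that
recovery truth is unambiguous; real reversed pairs share miRNAs and
interact). Passing the recovery tests therefore shows the machinery is
correct under the model's own assumptions, not that any particular clinical
performance would be attained on new serum cohorts.

## Scale of the bundled analyses

The test suite and examples run at desk scale: oracle-equivalence checks
use matrices up to 15 miRNAs by 30 samples against exhaustive double-loop
enumerations (over 200 random instances), and the end-to-end recovery check
uses the 200-miRNA reference configuration above, which completes in
seconds. The mining kernel accumulates a single M x M ordering-count matrix
in one pass over samples, so memory is bounded by a constant number of
M x M tables; at full published scale (about 2,500 miRNAs, 5,000 samples,
3.1 million pairs) the same code path applies unchanged, with runtime
dominated by the O(N M^2) comparison count.

## Known limitations

* Panel size is selected on the training cohorts themselves, as in the
  original design; no internal cross-validation is added, so the reported
  training index is optimistic and external validation is essential.
* Exactly tied expression values reduce the effective panel; platforms that
  quantise heavily could shift the voting threshold in permissive mode.
* The 10-miRNA linear comparator is reproduced from its printed
  coefficients for comparison only; its coefficients are not re-derived,
  and it deliberately lacks ordering invariance (the package's negative
  control).
* GEO series-matrix support covers the delimited data block only; SOFT
  files and probe-level annotation remapping are out of scope, as is
  automated downloading.
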