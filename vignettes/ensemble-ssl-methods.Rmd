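---
title: "Semi-supervised balanced-subset ensembles for imbalanced splice-site classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised balanced-subset ensembles for imbalanced splice-site classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceSSL)
```

## The problem

Acceptor splice sites sit at the 3' end of introns and are marked by an
"AG" dinucleotide. Telling true acceptor sites apart from the vastly more
numerous decoy "AG" occurrences is a binary classification problem with two
defining difficulties: the classes are highly imbalanced (roughly 1% of
"AG" dimers in a genome are true sites, a 1-to-99 ratio), and labeled
examples are expensive while unlabeled candidate windows are essentially
free. This package implements a family of ensemble-based semi-supervised
learners designed for exactly this regime, together with the evaluation
protocol needed to study them and a synthetic data generator so the whole
system runs at desk scale with no external downloads.

Each instance is a fixed-length window (by default 141 nt) centred so that
the candidate "AG" starts at position 61. Two static categorical feature
views represent a window:

* **view 1 — nucleotide/position:** one feature per position, 4 categories
  each (141 features);
* **view 2 — 3-mer/position:** one feature per overlapping trinucleotide
  start, 64 categories each (139 features for a 141-nt window).

Co-training trains one classifier per view; self-training and the
supervised baseline use the 280-feature concatenation. The base learner is
categorical Naive Bayes with Laplace smoothing, chosen for speed and for
having no hyper-parameters to tune when labeled data are scarce; its
posterior for the predicted class doubles as the selection confidence.

## The ensemble family

All methods build `N` *balanced subsets* of the labeled seed set: every
subset holds all labeled positives plus an equal number of negatives,
partitioned across subsets without replacement while negatives last and
recycled from fresh shuffles afterwards. Training members on balanced
subsets keeps each member class-neutral (priors 0.5/0.5) while the ensemble
as a whole still sees the full negative diversity. The supervised **Lower
Bound Ensemble (LBE)** stops here: `N` combined-view models whose averaged
positive-class posteriors score test instances.

The eight semi-supervised variants wrap one loop around that ensemble.
Per iteration: draw a subsample `U` of size `S` from the unlabeled pool
(without replacement; consumed instances never return); refit every member
on its current subset; let each member select its most confidently
predicted instances from `U`; append the selections as pseudo-labeled
instances; discard the rest of `U`; stop when the pool is exhausted. The
variants differ along three axes:

* **learner** — co-training (CT\*: a view-1/view-2 model pair per subset)
  vs self-training (ST\*: one combined-view model per subset);
* **selection** — both classes (\*EO\*: 2 positives + 2 negatives per
  member per iteration) vs positives only (\*EP\*: 2 positives), the
  latter being *dynamic balancing*: under heavy imbalance, feeding the
  minority class only counteracts the skew;
* **routing** — shared (CTEO/STEO/CTEP/STEP: all selections pool into one
  batch appended to every subset) vs distributed (\*D: each member keeps
  its own selections), which preserves member diversity.

Co-training selection admits an instance only when both view classifiers
agree on its label; among admissible instances of the requested class, the
selecting view takes its highest-confidence instance among those the other
view labels with confidence at most `tau_low` — the confident view teaches
the uncertain one. Selection is sequential over members with immediate
removal from the shared candidate pool, which makes the per-iteration
augmentation counts exact and all selections unique: per subset and
iteration, growth is 4N (CTEO/STEO), 2N (CTEP/STEP), 4 (CTEOD/STEOD) or
2 (CTEPD/STEPD).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `N` | imbalance degree of the labeled set | balanced subsets / ensemble members |
| `alpha` | 1 | Laplace smoothing weight (add-one) |
| `tau_low` | 0.7 | co-training "low confidence" cutoff (posterior units) |
| `target_iterations` | 50 | sets the subsample size `S = ceiling(|pool| / target_iterations)` |
| `k_per_class` | 2 | self-training selections per class per member |
| `labeled_fraction` | 0.01 | labeled share of each CV training set |
| `k` (folds) | 10 | cross-validation folds |
| `signal` | 0.6 | synthetic-generator signal strength |

`N` defaults to the labeled set's imbalance degree because with `p`
positives and `N·p` negatives that choice uses every labeled negative
exactly once; it remains independently configurable (at degree 99 an
ensemble of 99 subsets is allowed but costly). `alpha = 1` is the standard
choice for sparse categorical data when nothing is known a priori.
`tau_low = 0.7` makes "low confidence" mean "closer to undecided than to
certain" on the posterior scale; when no admissible instance clears the
cutoff the selector falls back to the highest-confidence admissible
instance (counted in the ledger as a threshold fallback), and when no
admissible instance of the requested class exists at all the slot stays
empty and is counted as a shortfall — cross-view agreement is a hard
condition and is never overridden. The `S` rule makes every run take about
`target_iterations` iterations regardless of dataset size, mirroring a
fixed iteration budget with size-proportional subsamples.

## Numerical and procedural choices

* All Naive Bayes probability accumulation is in log space; 280-feature
  products underflow double precision in linear space. Posteriors are
  normalized with the log-sum-exp guard.
* Category sets are fixed at fit time from the alphabet (4 per nucleotide
  feature, 64 per 3-mer feature), not inferred from data, so smoothing
  covers categories unseen in a tiny subset.
* Confidence ties break toward the lowest candidate index everywhere
  (stable radix ordering), making runs bit-reproducible.
* The area under the precision-recall curve is computed as step-wise
  average precision — the sum of precision at each positive hit divided by
  the number of positives — because linear interpolation between PR points
  is invalid. Ties are resolved by the same stable ordering.
* The labeled split of a training fold takes `floor(fraction · n)`
  instances with the class ratio preserved, forcing at least one positive
  (the 1% budget is an upper bound, and Naive Bayes needs both classes).
  Stratification is per fold, not global.
* Paired t-tests are classical two-tailed tests on per-fold differences
  with `n - 1` degrees of freedom; all-zero differences are reported as
  "not significant" rather than an error, and numerically constant
  non-zero differences return `p = 0` with an infinite statistic.
* After the pool is exhausted every member is refit once on its final
  subset, so the returned models always reflect all pseudo-labels; with an
  empty pool the loop body never runs and a semi-supervised call is
  therefore the corresponding supervised ensemble, bit for bit (for
  self-training variants this equals LBE exactly; co-training variants
  average 2N per-view models, which is a different — though equally
  supervised — predictor than LBE's N combined-view models).
* Degenerate inputs: a labeled set lacking either class, a window of the
  wrong length, a non-ACGT character (unless the fifth-letter IUPAC policy
  is chosen), or a series degree exceeding the negative supply all fail
  fast with the offending record or degree named.

## What the synthetic generator does and does not emulate

The generator draws positives from a position probability matrix that
carries the two signals real acceptor windows offer a positional
classifier: a pyrimidine-rich tract (C/T probability 0.85 at full signal)
over the 20 positions upstream of the dimer, and a mildly G-leaning
consensus over the 3 positions downstream. Negatives are decoys: windows of
background composition that also carry the obligatory "AG" at the anchor,
exactly like decoy sites in a genome scan. One parameter `signal`
interpolates every non-dimer position between background (0) and the full
profile (1); at `signal = 0` the classes are identically distributed and
any classifier's expected average precision equals the prevalence.

What it does **not** emulate: organism-specific base composition,
branch-point or exonic structure beyond the three downstream positions,
correlations between positions (every position is independent given the
class), and the absolute auPRC levels of real genomes. Passing tests on
synthetic data therefore demonstrate that the algorithms, their accounting
and the protocol behave as specified — not that any particular real-data
performance level is reproduced.

## Scale of the shipped checks

The test suite and the acceptance script run entirely on simulated data at
sizes chosen to exercise every code path through full-length runs: the
augmentation-ledger check uses a pool of 2,550 instances with `N = 5`
(50 iterations at `S = 51`); the qualitative-trend check uses five
replicate datasets of 5,500 instances (500 positives at degree 1-to-10)
under the full 10-fold protocol with 1% labeled data and `N = 10`, the
regime in which the distributed dynamic-balancing variants are expected to
track or beat the supervised baseline. At this scale the subsample size
(`S ≈ 98`) exceeds the per-iteration consumption (up to `4N = 40`) by a
factor of about 2.5, a weaker selection pressure than a genome-scale pool
provides; the trend margins are accordingly reported and logged rather than
hard-asserted, and single runs should be read as directional.

## Known limitations

* Naive Bayes is the only base learner; the design deliberately trades
  model capacity for speed and parameter-freeness.
* Views are static; no random feature splitting into views is provided.
* Co-training assumes the two views are individually sufficient and
  roughly independent given the class; positional nucleotides and
  overlapping 3-mers share information, so the independence is only
  approximate.
* The package classifies fixed windows; it does not scan genomes to
  extract candidate "AG" windows, and donor or non-consensus sites are out
  of scope.
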