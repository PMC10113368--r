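---
title: "Mining factor-specific patterns in drug-induced expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining factor-specific patterns in drug-induced expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(factorpat)
```

## The question the package answers

Large perturbation compendia such as LINCS L1000 record, for thousands of
genes, a differential-expression z-score for every (cell line, compound)
condition. For a single gene this is an R x C grid. The scientific question
is *which biological factor explains the gene's responses*: does the gene
react to particular compounds regardless of cellular context, only in
particular cell lines regardless of compound, both, or neither? Classical
factorial models (ANOVA-style) need replicated designs; signature-level
compendia typically provide one replicate-collapsed z-score per condition.
`factorpat` instead treats the question as combinatorial pattern mining on
the dichotomized grid, which needs no replication.

## The pattern model

Dichotomize the gene's grid at |Z| > 2 (strict), giving a binary profile
$E_{ij}$. The hypothesis class is the set of **factor-specific patterns**: a
pattern selects a subset of cell-line rows $S$ and compound columns $T$ and
materializes to the binary matrix $E'_{ij} = 1$ iff $i \in S$ or $j \in T$ —
the union of full rows and columns. The empty selection is the **null
pattern** (all-zero matrix): no factor explains the profile.

The fit of a pattern is its **pattern distance**
$d = \sum_{ij} |E_{ij} - E'_{ij}|$, the Hamming mismatch count. The optimal
pattern is the one minimizing $d$ over all $2^{R+C}$ selections. Because the
null pattern is always a candidate, the optimum never exceeds $n$, the
number of significant cells. The model is deliberately coarse — a pattern
claims *whole* rows and columns — which is what makes the result directly
interpretable: each selected row is a cell-line association, each selected
column a compound association.

## Optimizers

Two optimizers share one contract and one tie-handling convention.

**Exhaustive enumeration** (`exhaustive_optimal()`) scores every
(row set, column set) pair, vectorized over subset lattices, and refuses
grids with R + C above a cap (default 26, about 67 million candidates). It
is the exact reference against which everything else is tested. Internally
the permutation-null builder uses an equivalent exact C++ enumeration over
the shorter axis only: for a fixed column set the optimal row choice
decomposes row by row (a row enters iff covering it removes more mismatches
than it adds), so only $2^{\min(R,C)}$ subsets need scoring. The test suite
verifies this shortcut equals the brute force on hundreds of random grids.

**Genetic algorithm** (`ga_optimize()`) is the scalable optimizer for grids
like 51 x 19 where enumeration is impossible. A chromosome is the R + C
membership bit string; fitness is negative distance; the operators are
tournament selection (size 3), uniform crossover (probability 0.9), per-bit
flip mutation (probability 1/(R+C)), and generational replacement with one
elite. The initial population always contains the null chromosome and every
one-hot chromosome, which (i) guarantees the d <= n bound from generation
zero and (ii) makes single-factor truths converge almost immediately. The
run stops after 500 generations or 50 without improvement. Hyperparameters
were fixed once, for tractability at 70 bits; they are exposed in
`ga_config()` because reproducibility requires pinning them, not because
tuning is expected. On every benchmarked grid up to 30 bits the GA returns
the exact optimum in effectively 100% of seeded runs. The bit-mask
implementation bounds GA grids at 64 rows and 64 columns.

**Ties.** Several patterns can achieve the minimum. Identity is judged by
materialization, not encoding — selecting all rows makes the column set
irrelevant, and all such encodings collapse to one all-one materialization —
otherwise degenerate encodings would inflate tie counts. When the minimum is
achieved by both the null pattern and non-null patterns, a non-null one is
reported (the null pattern is the no-association claim; preferring it would
silently discard the interpretable optimum). Among non-null ties the default
is a seeded uniform random choice; a deterministic mode (smallest pattern,
then lexicographic) exists for byte-stable outputs. `tie_count` reports how
many distinct materializations achieved the minimum, so downstream users can
flag ambiguous fits. For the GA, ties are the distinct best-distance
materializations *encountered* during the run — a lower bound on the true
tie count.

## Significance

A small optimal distance is only impressive relative to how well *random*
profiles with the same density can be fitted. Genes are grouped by n, the
number of significant cells; each group gets one permutation null: L
(default 10,000) profiles with exactly n ones placed uniformly at random,
each solved by the same optimizer as the observed data (consistency of the
statistic), giving the distance multiset $D_{perm}(n)$. The p-value of an
observed distance d is the fraction of null distances <= d — the
probability a random same-density profile fits at least as well. An optional
add-one pseudocount, `(1 + count) / (1 + L)`, avoids exact zeros; the
default stays with the plain count so that reported p-values are the raw
permutation estimates. p-values are BH-adjusted across *all* tested genes,
and a gene is declared significant when q < 0.05 **and** its optimal
pattern is non-null — a perfect null fit is the absence of a claim, never a
discovery.

Two design points were genuinely open and are worth recording. First,
whether to re-shuffle each gene's own grid or draw one shared null per
group: the grouped, shared reading is adopted — the null law depends only on
(n, R, C), sharing is what makes grouping meaningful, and it is the decisive
performance choice (one build per distinct n instead of one per gene).
Second, seed derivation: per-gene optimizer seeds are `base_seed + gene
index` and per-group null seeds `base_seed + 1e6 + n`, so multi-gene runs
are order-independent and reproducible end to end.

## The synthetic-data generator

`generate_dataset()` emulates the tensor the pipeline consumes: background
cells draw N(0, 1) (so a fraction 2 * pnorm(-2) ~ 4.6% of noise cells
dichotomize to 1), and a planted gene's pattern cells draw |Z| ~ N(4, 1)
with random sign, except that with probability 0.05 a pattern cell drops out
to background. The signal location 4 models a clear responder — comfortably
past the threshold (about 97.7% of pattern cells dichotomize to 1) without
being deterministic — and the 5% drop-out models the call noise of
replicate-collapsed signatures. Signs are random because the method sees
only |Z|; sign symmetry is preserved by construction. With
`single_factor_only = TRUE` planted genes carry exactly one factor, the
configuration used for power studies of pure cell- or compound-specific
truths.

What the generator does **not** emulate: replicate structure and
moderated-z collapsing upstream of level-5 signatures, correlation between
genes, dose–response, or heavier-tailed empirical z distributions. A green
calibration or recovery test therefore establishes that the statistic, the
null construction and the multiple-testing control behave as designed under
the stated noise model — not that real-compendium discovery rates will match.

## Numerical and degenerate-case choices

* |Z| > 2 is strict: a score of exactly 2.0 is not significant.
* Grids must be complete; missing tensor cells and unresolvable
  (cell, compound) conditions are hard errors, never imputed or averaged.
  When several doses exist for one condition, an explicit compound-to-dose
  filter must disambiguate.
* n = 0 genes have a degenerate null (all distances 0) and p = 1; they are
  carried through BH like every other gene but can never be significant.
* Recovery metrics use the empty-set convention precision = recall = 1 when
  nothing was planted and nothing called, keeping noise-only calibration
  runs crash-free; the convention is reported, not hidden.
* All randomness flows through explicit seeds; identical config + seed
  yields byte-identical records and exports.

## Limitations

The pattern distance weights every cell equally; weighted or real-valued
distances, and patterns over more than two factors (e.g. dose as a third
axis), are natural extensions outside the current scope. When many optima
tie, the reported pattern is one draw among them — `tie_count` should be
consulted before interpreting a single association literally. Finally, the
GA is a heuristic: its oracle-equivalence guarantees are empirical, on grids
small enough to verify exactly.
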