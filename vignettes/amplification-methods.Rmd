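---
title: "Amplifying small multi-omics feature tables: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplifying small multi-omics feature tables: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliomics)
```

## The problem

Parallel multi-omics studies of rare or hard-to-sample conditions often end
up with a matrix that is extremely wide and extremely short: thousands of
analytes (proteins, miRNAs, metabolites, lipids) quantified in a handful of
subjects. Many pattern-discovery and knowledge-base tools behave poorly, or
refuse to run meaningfully, at nine rows. The method implemented here takes
the opposite route from feature selection: it *amplifies* the subject
dimension, manufacturing thousands of "virtual subjects" per real subject
while perturbing a controlled fraction of their entries, so that downstream
tools receive an input in the size regime they were designed for.

A virtual subject is not a biological replicate, and the package is explicit
about that: every evaluation report computed on amplified data carries a
pseudo-replication flag, and nominal p-values on amplified data are not valid
inference. The evaluation harness exists to *measure* what amplification does
to a detector's output, not to endorse the inflated sample size.

## The amplification model

Let $X \in \mathbb{R}^{n \times m}$ be the cleaned source matrix ($n$
subjects, $m$ features), with per-feature minima $\min_j$, maxima $\max_j$
and ranges $R_j = \max_j - \min_j$. Amplification with replication factor $K$
and imputation level $r \in [0,1]$ proceeds as:

1. **Replication.** Each subject's row is repeated $K_g$ times ($K_g$ may
   vary by group to balance unequal class sizes), giving $N = \sum_g n_g K_g$
   rows ordered by group, subject, then replicate index.
2. **Mask allocation.** A uniform random matrix $U \in [0,1)^{N \times m}$ is
   drawn in one batch; the mask is $M_{ij} = \mathbf{1}[U_{ij} < r]$. Since
   the draws are uniform, the expected masked fraction equals $r$ exactly and
   the realized fraction is Binomial$(Nm, r)/Nm$.
3. **Imputation.** A second uniform matrix $V$ is drawn and imputation values
   $\min_j + V_{ij} R_j$ are computed for *every* entry in one vectorized
   pass; they are applied only where $M_{ij} = 1$. Mask-0 entries keep their
   source values bit-exactly. Computing values that are then discarded is
   deliberate: whole-matrix arithmetic beats per-entry branching, which is
   the point of the mask formulation.

The output therefore retains fraction $1-r$ of original values in
expectation, and every imputed value lies inside its feature's observed
range, so the amplified data inherit each feature's scale and support.

Two useful consequences that the test suite asserts:

* **Moment law.** The amplified per-feature mean converges to
  $(1-r)\,\bar{x}_j + r\,(\min_j + \max_j)/2$ as $K \to \infty$.
* **Signal dilution.** Under global statistics, imputed entries are drawn
  from the same distribution in every group, so a between-group mean
  difference $\Delta_j$ shrinks to $(1-r)\Delta_j$ in expectation. Detection
  on amplified data trades per-entry signal for (nominal) sample size: the
  two-group $t$ statistic scales roughly like $(1-r)\Delta\sqrt{nK}$, which
  is why amplified recall on planted effects meets or exceeds the original
  baseline in the sweep — at the price of pseudo-replication.

### The golden-ratio operating point

The default imputation level is $r = 2 - \varphi \approx 0.382$ with
$\varphi = (1+\sqrt 5)/2$, i.e. a 38.2% imputed : 61.8% retained split —
the reference operating point around which the levels 35%, 37.5% and 40%
are swept. `amplify_config()` stores it as 0.382 (the conventional
one-decimal percentage); `golden_imputation_level()` returns the analytic
value.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `replication_factors` (K) | copies per subject (per group) | 1 | set explicitly per study; 1000 reproduces the study scale |
| `imputation_level` (r) | expected imputed fraction | 0.382 | golden-ratio split |
| `stats_scope` | ranges pooled globally or per group | global | the source description is ambiguous; global is the conservative reading, per-group is one flag away |
| `exact_fraction` | exactly ⌊r·N·m⌋ masked entries | FALSE | the method as described uses independent thresholding; the reported retained fractions are expectations |
| `keep_originals` | prepend untouched source rows | FALSE | the method masks the whole replicated matrix, so even replicate 0 may be perturbed; the flag is an escape hatch |
| `instances_per_block` | rows per storage block | 10000 | one block holds all features for its subjects; CSV blocks are capped at 30 million entries, HDF5 blocks are uncapped |

## Preprocessing and the sentinel convention

Amplification must not propagate acquisition errors, so cleaning runs first
and in a fixed order: `fill_missing()` then `handle_exceptions()`, then
statistics.

* **Missing entries** (explicit flags, distinct from any numeric value) are
  filled with the median of the feature's observed *plausible* values —
  positive and finite — so an erroneous negative or infinite reading can
  never leak into a fill.
* **Abnormal entries** — non-finite values, and values $\le 0$, which are
  impossible for abundances — are replaced by the sentinel 0. Zero is a safe
  sentinel precisely because real abundances are never zero: sentinel
  entries stay trackable in the amplified output without a side mask, and
  all statistics (min, max, range, median, randomness) exclude them so a
  sentinel can never stretch a feature's range into the imputation step.
* A feature consisting entirely of sentinels gets min = max = range = 0: its
  imputed values are all 0 and remain recognizable as placeholders.

**Randomness score.** The per-feature "randomness" — whether values are
concentrated on a few points or spread across the range — is operationalized
as the Shannon entropy of a 32-bin equal-width histogram over
$[\min_j, \max_j]$, normalized by $\log 32$ so it lies in $[0,1]$; constant
features score 0. 32 bins resolves concentration structure at the data sizes
involved without starving bins at $n$ in the thousands. The score is
recorded in the column profile; it does not currently modulate the
imputation draw, since no concrete rule for doing so is specified — the
profile exists so users can verify that amplified data keep source-like
spread.

## Randomness and reproducibility

One seeded generator drives an entire amplification: the mask matrix is
drawn first, then the imputation-value matrix, both in row-major order. This
makes the output a bit-reproducible function of (dataset, config) and fixes
an ordering that cross-language reimplementations can match given the same
generator. `allocate_mask()` and `impute_masked()` accept `seed = NULL`,
meaning "continue the current stream", which is how `amplify_dataset()`
enforces the single-stream discipline while both operations remain
independently seedable. Ties at exactly $U_{ij} = r$ (a measure-zero event)
keep the source value, matching the strict "smaller than threshold" rule.

## Block storage

Amplified output is partitioned in row order into blocks of 10,000 instances
by default, each block self-describing (provenance columns: source subject,
replicate index, group). All blocks of a set share one imputation level.
CSV blocks refuse `instances_per_block × m > 3\times 10^7` entries; HDF5 has
no cap. A JSON manifest records block order, row counts and MD5 checksums
(an integrity check against truncation or corruption, not a cryptographic
guarantee), because a multi-file round trip without one is unsafe. The last
block may be short — padding would fabricate instances. Numeric CSV cells
are printed with 17 significant digits, which round-trips IEEE doubles
exactly; HDF5 round trips are bit-exact by construction. Multi-block
single-file CSV is deliberately not supported (one block per file).

## What the synthetic generator does and does not emulate

`generate_quadra_omics()` emulates the *structure* of the target study: 9
subjects in groups 4 (healthy) / 3 (high risk) / 2 (new onset), 2736
features in blocks of 2292 proteins, 328 miRNAs, 75 metabolites and 41
lipids, strictly positive abundances, sporadic missing values and abnormal
entries. Abundances are i.i.d. log-normal per block (`meanlog = 2`,
`sdlog = 1` by default — concentration-like, right-skewed, strictly
positive). Differential features are planted multiplicatively: disjoint sets
of `n_planted = 50` features per contrast have the affected group's values
scaled by $2^{\text{effect\_size}}$ (default 1 log2 unit, a conventional
"clearly real but not trivial" fold change). Missing flags (rate 0.01) and
abnormal values (rate 0.002, half negated and half infinite) are injected
uniformly at random at recorded addresses, so preprocessing reports can be
checked against ground truth exactly. These rates mirror the "sporadic"
character of the target data: a few hundred missing entries and a few dozen
exceptions per dataset.

What it does *not* emulate: inter-feature correlation (real omics blocks are
strongly correlated), batch effects, missingness that depends on abundance
(censoring at the detection limit), or the acquisition process itself.
Passing tests on this generator therefore demonstrate the mechanics and the
statistical laws of the amplifier, not that amplification helps on any
particular real dataset.

## Evaluation harness

The original study assessed amplified data through a commercial pathway
knowledge base, which cannot be reproduced openly. The package's harness
asks the same qualitative question on synthetic ground truth instead: does
amplification at levels around 38.2% change how much planted signal a
detector reports? `detect_differential_features()` runs per-feature Welch
$t$ tests (unequal variances are expected after imputation; Mann–Whitney is
available for robustness), adjusts with Benjamini–Hochberg across all
features, and calls at adjusted $p \le \alpha$. Degenerate features (zero
variance in both groups, equal means) get statistic 0 and $p = 1$ by
convention; zero variance with unequal means gets $p = 0$.
`sweep_imputation_levels()` amplifies at each level in
`c(0.35, 0.375, 0.382, 0.40)` and reports recall and precision against the
planted truth next to the unamplified baseline.

## Problem sizes used in the checks

The full study scale — 9 × 2736 source, thousand-fold amplification to
9000 × 2736 (about 2.5 × 10⁷ entries) — is exercised directly in the
acceptance checks; a single amplification at that scale runs in seconds.
Distributional and sweep properties are asserted on scaled-down generator
configs (tens to hundreds of features, K of 200–1000) with fixed seeds and
explicit tolerance arithmetic: binomial 4σ bands for mask fractions, delta-
method 5σ bands for the moment law, Kolmogorov–Smirnov at α = 0.001 on 10⁵
imputed draws, and a 1000-replicate simulation for BH familywise error under
the global null.

## Known limitations

* Virtual subjects are pseudo-replicates; any inferential statistic computed
  on amplified data is anticonservative. The package flags this rather than
  fixing it — fixing it is out of scope by design.
* Uniform-within-range imputation ignores each feature's shape beyond its
  support, and global scope ignores group structure in the ranges
  (`stats_scope = "per_group"` is provided, with the caveat that per-group
  ranges leak group identity into imputed entries).
* The randomness profile is descriptive only.
* Reported retained fractions are binomial realizations around $1-r$, not
  enforced counts, unless `exact_fraction = TRUE`.
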