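---
title: "Ranking driver transcription factors with transition weights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking driver transcription factors with transition weights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A differentiating cell population profiled at several time points shows
hundreds of transcription factors (TFs) changing expression. Which of them
*drive* the transition, rather than merely respond to it? The premise of
this package is that a driver should satisfy three conditions at once over
the time course: it changes expression itself, its bound target genes are
enriched among the differentially expressed genes, and its targets move in
a *consistent* direction relative to the TF interval after interval. The
transition weight (TWM) score multiplies evidence for all three, so a TF
that fails any one of them scores near zero.

The method was conceived for inducible differentiation systems — e.g. a
B cell progenitor line driven from proliferation toward cell-cycle exit by
nuclear translocation of Ikaros — but applies to any time course with at
least three time points, replicate expression measurements, and a
TF-to-target binding graph (promoter-proximal ChIP-seq peaks, accessible
chromatin footprints, or any user-supplied edge list).

## The score

Write $T = (x_1, \dots, x_A)$ for the time points. The consecutive
contrasts $\nabla T$ are the $A-1$ adjacent differences of mean log2
expression; a contrast *pair* $C\nabla_j = (\nabla_a, \nabla_b)$ is two
adjacent contrasts sharing a time point ($A-2$ pairs). For each TF $i$:

1. **Fold change.** The TF's per-contrast log2 fold changes are summed
   over each pair: $\mathrm{logFC}_{i,C\nabla_j} = \mathrm{logFC}_{i,\nabla_a}
   + \mathrm{logFC}_{i,\nabla_b}$.
2. **Target enrichment.** Per contrast, the odds ratio of the 2×2 table of
   *target of TF i* against *differentially expressed*, over the whole
   gene universe; summed over each pair the same way.
3. **Coherence.** For each target $g$ that is differentially expressed in
   *both* contrasts of a pair, the gene is coherent iff
   $\mathrm{sign}(\mathrm{logFC}_{g,\nabla_a}) \cdot
   \mathrm{sign}(\mathrm{logFC}_{g,\nabla_b}) \cdot
   \mathrm{sign}(\mathrm{logFC}_{i,\nabla_a}) \cdot
   \mathrm{sign}(\mathrm{logFC}_{i,\nabla_b}) > 0$ — it tracks the TF, or
   mirrors it, in both intervals. The pair coherence is the mean over
   eligible targets.
4. **Combination.**
   $\mathrm{comb}_i = \sum_j |\mathrm{logFC}_{i,C\nabla_j}| \cdot
   \mathrm{OR}_{i,C\nabla_j}$, the global coherence
   $\mathrm{coh}_i = \prod_j \mathrm{coh}_{i,C\nabla_j}$, and
   $\mathrm{TWM}_i = \mathrm{comb}_i \cdot \mathrm{coh}_i$.

Note the absolute value in step 4. The formula as a plain sum of signed
terms would make a strongly *down*-regulated driver score negative even
when its targets follow it perfectly — repression is as much "driving" as
activation, and repressive drivers (e.g. a repressed proto-oncogene whose
silencing permits differentiation) are among the most interesting hits.
`signed = TRUE` restores the literal signed sum for users who want the
direction in the score.

A second presentation choice: within a pair the two contrasts can be
summed (the default) or averaged (`pair_average = TRUE`). Averaging halves
both aggregates, rescaling *every* score by exactly 1/4 and leaving the
ranking untouched; the equivalence is unit-tested to exactness, so the
choice is cosmetic.

## Interpretation and edge cases

* **Coherence is multiplicative.** One incoherent interval pair zeroes the
  score: the method deliberately demands consistency along the whole
  course. A pair with *no* target DE in both of its contrasts is
  *undefined* and also contributes zero by default — a TF whose small
  target set drops out of any pair cannot be certified coherent. This is
  conservative for TFs with few targets; `skip_undefined = TRUE`
  multiplies over defined pairs only, for exploration.
* **Signs.** `sign(0) = 0`, and any zero sign makes a gene incoherent for
  that pair. An `epsilon` dead zone (default 0) can map |logFC| below a
  threshold to sign 0 to damp sign flips driven by noise; we leave it off
  by default because eligibility already requires DE in both contrasts.
* **Odds ratios.** Any zero cell triggers the Haldane–Anscombe correction
  (+0.5 to all four cells) rather than dropping the contrast, keeping the
  aggregate finite. The universe is every gene in the expression table; if
  you prefer an expressed-only universe, filter the table first.
* **Ranking ties** break by higher global coherence, then TF id, so output
  order is deterministic and independent of input order.

## Where the inputs come from

*Contrasts and DE indicators.* `compute_contrasts()` takes differences of
replicate means on the log2 scale (upstream normalization is assumed
done; a warning fires when values look like raw counts). The DE indicator
per contrast is whatever the user's modelling stack produces — the
intended sources are moderated linear models and polynomial time-course
regression, whose combined call is implemented as `consensus_de()`:
DE iff FDR < 0.001, or time-course $R^2 > 0.90$, or (FDR < 0.01 and
$R^2 > 0.60$). When no such fits exist, `fallback_de_test()` offers a
per-contrast Welch t-test with Benjamini–Hochberg correction within each
contrast. It is honest but weak: with two replicates per time point it has
almost no power, and at small n it is mildly conservative (its type-I rate
sits a little below nominal — calibrated in the test suite). Supply model
statistics whenever you have them.

*Binding graph.* `assign_peaks()` emits an edge when a peak overlaps the
promoter window of a gene, by default 2,000 bp upstream to 500 bp
downstream of the TSS, strand-aware, in 0-based half-open coordinates.
Promoter-window conventions differ across annotation tools and there is no
canonical choice; ours approximates a promoter-proximal assignment and is
fully configurable — it changes the graph, so report it alongside results.
Peaks are consumed as given (peak calling is out of scope), optionally
pre-filtered at adjusted p < 0.01.

*Candidate TFs.* `select_candidate_tfs()` labels trends from the signs of
per-contrast fold changes (monotone up/down, one sign change = up-down /
down-up, more = complex) and admits a TF when any |logFC| exceeds 1.5, an
external (in vivo) contrast calls it DE at adjusted p < 0.01, or the trend
is nonmonotonic — nonmonotonic factors can matter even when endpoint
expression is unchanged. The threshold applies to |logFC|, since both up-
and down-regulated factors are legitimate candidates. This deterministic
rule replaces model-based trend clustering, which is deliberately not
reimplemented here.

## Significance: the permutation null

The score has no closed-form null, so `twm_null()` re-scores a TF under
degree-preserving random relabelings of its target set (same target count,
drawn from the gene universe) and reports the fraction of null scores
below the observed one, ties counted half. The mid-tie fraction keeps the
percentile well behaved when many null scores coincide (e.g. collapse to
zero). With exchangeable targets the percentile is uniform — verified by
a Kolmogorov–Smirnov check in the acceptance suite — so it can be read as
one minus an empirical p-value.

## The synthetic benchmark

`simulate_bulk()` generates the structure TWM assumes, with ground truth:
a driver TF stepping `driver_effect` log2 units per contrast (monotone by
default), targets whose per-contrast step sign matches the driver's with
probability `p_coh` and magnitude $|N(\mathrm{effect}, 0.25)|$, background
TFs with random-sign steps and sign-unrelated targets
(`background_coh = 0.5`), a `de_fraction` of unbound genes changing with
random signs, and i.i.d. replicate noise. The defaults — 2,000 genes, 20
TFs, 6 time points (0–24 h) in duplicate, 100 targets per TF, effect 1.0,
`p_coh` 0.9, noise 0.5, `de_fraction` 0.3 — describe a strong induction
course of the kind the method targets: effects comfortably above replicate
noise, a third of the transcriptome responding per interval. Under this
construction the expected pair coherence of a driver is
$p^2 + (1-p)^2$ (match in both or neither contrast of a pair), which the
test suite matches against simulation by enumeration.

The generator's DE truth (a gene is DE where it has a planted nonzero
step) stands in for the upstream model fits; the recovery benchmark
therefore measures the scorer, not the fallback test. What the generator
does *not* emulate: count-level noise (effects are specified directly on
the log2 scale; no negative-binomial layer), gene–gene correlation beyond
TF–target edges, shared targets with antagonistic regulators, or batch
structure. Passing the benchmark shows the score recovers its own
generative assumption well — it cannot certify performance on real data,
where binding graphs are noisy and DE calls imperfect.

`simulate_cells()` likewise plants single-cell targets whose lognormal
location tracks the TF's empirical tertile, with uniform dropout zeros;
null genes are independent. It exists to calibrate the single-cell
association test, not to mimic any particular platform's noise model.

## Single-cell coherence

For a TF of interest, cells with zero expression are excluded and the rest
split at the empirical 0.33/0.66 quantiles (low/mid/high); each gene is
independently filtered and tertiled the same way, and a Fisher test on the
3×3 table over cells passing both filters asks whether gene level tracks
TF level across cells. Two pooled 2×2 variants (low+mid vs high; low vs
mid+high) catch threshold-like responses, and a gene counts as TF-regulated
if any of the three tests is significant at p < 0.01. Numerical choices:
quantile cuts are type-7 with right-closed assignment so ties at a cut are
deterministic; 2×2 tables always use the exact hypergeometric test; larger
tables use the exact network algorithm up to a table total of 60 and a
seeded Monte-Carlo p-value (default $10^5$ tables) beyond it, with the
method recorded in the output. `variance_partition()` then compares
ordinary least-squares fits of a gene's expression on time (categorical —
the design has discrete time points), on a 6-level TF grouping, and on
both, reporting each $R^2$ and the increment over time alone. Because all
genes are tested against the *same* TF grouping, per-gene tests are not
independent; false-positive rates fluctuate across data sets slightly more
than binomial sampling alone would suggest.

## Downstream classification

`compute_tau()` implements the tissue-specificity index
$\tau = \sum_i (1 - x_i/x_{\max}) / (n-1)$; with the conventional
thresholds, genes with $\tau < 0.25$ (passing an expression filter) are
called housekeeping-like and $\tau > 0.70$ tissue-specific.
`myc_partition()` splits the genes regulated by an induced factor into
those retaining ("resistant") or losing ("sensitive") significance when an
antagonist is co-expressed — an exact partition by construction.
`categorize_go()` maps GO term descriptions to seven broad classes by
keyword containment; since a term can match several classes, a fixed
priority order (Immune system > Adhesion > Translation > Proliferation >
Metabolism > Differentiation > Signaling, most specific first) makes the
assignment deterministic.

## Validation sizes

The test suite validates the scorer against a literal one-function
transcription of the four steps on 100 random instances (up to 200 genes,
10 TFs, 4–6 time points; agreement to $10^{-12}$), property-tests the
coherence algebra on over 1,000 generated TF cases, runs the planted-driver
benchmark over 50 seeds at the default configuration, and calibrates the
permutation null on 200 TFs with 100 permutations each. These sizes were
chosen to make the checks statistically meaningful while keeping the whole
suite fast enough to run on every change.

## A worked example

```{r, eval = FALSE}
library(twmatrix)

sim <- simulate_bulk(sim_config(seed = 3))
fit <- twm(sim$expr, sim$graph, de = sim$truth$de)
fit
#> Transition weight matrix fit
#>   20 TFs, 2020 genes, 5 contrasts (4 pairs)
#>
#>     tf n_targets   comb     coh    twm rank
#> 1 TF01       100 1009.5 0.29804 300.86    1
#> ...

twm_null(fit, "TF01", n_perm = 200, seed = 9)$percentile
#> [1] 1
```

The planted driver separates from the background through coherence (0.30
vs ≈ 0.06 here): `comb` is similar across TFs because in this simulation
every TF's targets are all DE, so enrichment alone cannot distinguish
them — exactly the situation the coherence term exists for.

## Known limitations

* The score compares TFs *within* one data set; its scale depends on the
  DE rate and the OR distribution, so scores are not comparable across
  experiments.
* TFs acting with a lag longer than one interval, or through unchanged
  protein-level activity, are invisible to expression-sign coherence.
* The multiplicative coherence makes the score sensitive to a single
  noisy interval; with many time points consider `skip_undefined` and the
  `epsilon` dead zone as sensitivity analyses.
* The binding graph is taken at face value; promoter-window assignment
  misses distal regulation entirely.
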