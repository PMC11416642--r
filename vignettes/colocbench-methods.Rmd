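---
title: "Models and design choices in colocbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in colocbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`colocbench` benchmarks strategies for assigning a molecular association
signal — here a plasma protein QTL — to its causal gene, using the coding
gene of the protein as ground truth. This vignette documents the
statistical models, every tunable parameter that matters, the synthetic
data the benchmark runs on, and the numerical decisions that make results
reproducible.

## Summary-statistic model

All methods consume per-variant marginal (or conditional) association
statistics: effect `beta` on the alt-allele dosage scale, its standard
error `se`, folded minor-allele frequency, and cohort size, held in a
`RegionStats` object. Harmonization joins two traits on (chromosome,
position), flips the sign of the second trait's effect when its ref/alt
labels are swapped, drops incompatible allele pairs, and keeps
strand-ambiguous (A/T, C/G) variants with a logged count — simulated data
have no strand ambiguity, so no transformation is attempted. The
cis-window around a gene is the closed interval `[tss − 1e6 + 1,
tss + 1e6]`: exactly 2,000,000 bp wide, centered at the strand-aware TSS
(gene start on "+", end on "−"), clipped at position 1. The source
material states the total width but not the endpoint convention, so the
convention is declared here rather than inferred.

## Fine-mapping

`susieRss()` fits a sum of `L` single effects to the z-score vector `z`
with LD matrix `R` (model `z ~ N(R b, σ² R)`), by iterative Bayesian
stepwise selection: each effect in turn is fit as a Bayesian single-effect
regression on the residualized z-vector, with per-variant inclusion
probabilities `alpha ∝ exp(lbf)` under a uniform prior over variants.
The per-variant prior effect variance `W` is interpreted on the trait's
effect-size scale, so the single-effect log Bayes factor equals the
Wakefield approximate Bayes factor

    lABF = 0.5 * (log(1 − r) + r z²),   r = W / (W + se²).

With `L = 1` the inclusion probabilities are therefore exactly
`softmax(wakefieldLabf(beta, se, W))` — the bridge that makes per-signal
Bayes-factor colocalization collapse to the marginal enumeration on
single-signal loci (asserted to 1e-6 in the tests).

Parameters (defaults follow the published conventions of the
sum-of-single-effects method for quantitative traits):

| parameter | default | meaning |
|---|---|---|
| `L` | 10 | maximum number of single effects |
| `coverage` | 0.95 | credible-set posterior mass |
| `purityMin` | 0.5 | min \|r\| over all pairs in a set (100 evenly spaced pairs sampled for large sets) |
| `W` | 0.0225 | prior effect variance (sd 0.15, suited to inverse-normal traits) |
| `tol` | 1e-4 | max absolute change in fitted single-effect means to declare convergence |
| `maxIter` | 200 | iteration cap |
| `ridge` | 1e-6 | diagonal regularization applied when `R` fails the PSD check |
| `estimateResidual` | FALSE | re-estimate σ² per iteration |

Credible sets are built per signal as the smallest prefix of variants (by
descending `alpha`) reaching `coverage`; sets failing `purityMin` are
discarded; duplicated sets from effects that converged to the same signal
are deduplicated; survivors are re-indexed 1..K by decreasing maximum
single-effect log Bayes factor. The lead variant is the member with
maximum |z| in the trait's marginal statistics, ties broken by lowest
position then lexicographic id. Residual variance is fixed at 1 by
default — correct for standardized, inverse-normal phenotypes; the
`estimateResidual` switch uses the expected-residual-sum-of-squares
update (the naive mean squared residual is biased downward because fitted
effects absorb noise, which manufactures phantom credible sets under the
null).

## Colocalization

Three methods, compared under a shared significance convention:

1. **Marginal enumeration** (`colocAbf`). Assuming at most one causal
   variant per trait, the five hypotheses (no association / trait 1 only /
   trait 2 only / two distinct variants / one shared variant) have
   unnormalized log weights

        S0 = 0
        S1 = log p1 + logsum(lABF_1)
        S2 = log p2 + logsum(lABF_2)
        S3 = log p1 p2 + logdiff(logsum lABF_1 + logsum lABF_2,
                                 logsum(lABF_1 + lABF_2))
        S4 = log p12 + logsum(lABF_1 + lABF_2)

   and `PP0..PP4 = softmax(S0..S4)`. Priors: `p1 = p2 = 1e-4`,
   `p12 = 5e-6`; significant when `PP4 > 0.8`. The implementation is
   checked against an exhaustive M×M configuration enumeration on the raw
   Bayes-factor scale to 1e-10.
2. **Per-signal enumeration** (`colocBfBf`). The identical computation
   fed one fine-mapped signal's log-Bayes-factor row per trait, applied
   to every (exposure signal, outcome signal) pair, with the same priors
   (no per-signal rescaling). This is what lets a first eQTL signal pair
   with a second pQTL signal.
3. **Credible-set product** (`clpp`). `Σ_v alpha_1(v) · alpha_2(v)` over
   the exposure credible set, variants missing from either trait
   contributing zero; significant above 0.1 (the value is not on the PP4
   scale). `clpp()` accepts any inclusion-probability vectors: the
   pipeline passes per-signal alpha rows (the reading most consistent
   with summing "for each credible set"); passing the overall PIP vector
   instead is the documented alternative for the ambiguous convention.

Pairs are skipped when fewer than 10% of the outcome region's variants
fall inside the exposure gene's cis-window. The analysis universe is
protein-coding exposure genes, and outcome traits flagged as protein
complexes are excluded (their abundance can be driven by any constituent
gene).

## Mendelian randomization

Instruments come from significant per-signal colocalizations: a
(gene, protein, dataset) triplet is retained when at least two
significant signal pairs have mutually distinct exposure indices and
mutually distinct outcome indices (greedy by descending PP4); reusing one
exposure signal in two instruments would violate instrument independence.
Per pair, the instrument variant maximizes the product of the two alpha
rows, and its marginal effects on both traits are the (bx, by) inputs —
which betas feed MR is not specified upstream, so marginal betas at the
chosen variant are the declared choice.

With ratio estimates `θ_j = by_j / bx_j`:

- **IVW, first-order**: `v_j = seBy_j²/bx_j²`, slope
  `Σ(θ_j/v_j)/Σ(1/v_j)`, `SE = (Σ 1/v_j)^(−1/2)`.
- **IVW, delta weights**: adds the exposure's sampling error,
  `v_j += by_j² seBx_j²/bx_j⁴`.
- **Multiplicative random effects**: `SE · max(1, sqrt(Q/(k−1)))` with
  Cochran's `Q` — the floor at 1 means the random model is never more
  confident than the fixed one.
- **Robust adjusted profile score**: standardized residuals
  `t_j = (by_j − α bx_j)/√(seBy_j² + α² seBx_j² + τ²)` enter a
  Tukey-biweight score equation for α (tuning constant `c = 4.685`, the
  published default) and a companion moment equation for the
  overdispersion τ², calibrated so `E[t ψ(t)]` matches its standard
  normal expectation; SE by a numerical sandwich estimate.
- **Allelic spread**: hierarchical model `α_j ~ N(α, τ²)`,
  `by_j ~ N(α_j bx_j, seBy_j²)` with `bx` fixed at observed values, i.e.
  marginally `by_j ~ N(α bx_j, seBy_j² + τ² bx_j²)`. Priors
  `α ~ N(0, 10²)`, `τ ~ half-N(0, 5²)`; the posterior is evaluated on a
  deterministic adaptive grid over (α, τ) with trapezoidal
  marginalization and one refinement pass — no stochastic sampler, so
  runs are exactly reproducible. Reported: posterior median, central 80%
  credible interval, posterior median τ. Discordant instruments inflate τ
  and widen the interval toward zero instead of producing spuriously
  precise estimates.

All intervals use level 0.80 (normal quantile 1.281552);
"significant" means the interval excludes zero.

Numerical notes: the Tukey score redescends to zero far from the truth,
so the α equation is solved by IRLS from the delta-weighted IVW start and
polished by a local root search — global bracketing would latch onto the
spurious zeros in the tails. The τ² moment function is likewise negative
at *both* extremes under gross overdispersion, so its solver scans a grid
up to a moment-based ceiling for the upper sign change rather than
assuming monotonicity from zero. Exact scale equivariance of the
grid-based estimator is broken (slightly) by its fixed priors; the
property test asserts it at moderate scales where the priors are
effectively flat.

## The synthetic benchmark

`simulateBenchmarkCatalog()` builds one locus per synthetic protein:

- **LD** by a first-order haplotype copy process: within an LD block each
  variant copies the previous variant's allele on the same haplotype with
  probability `rho`, else draws fresh from the block's allele frequency.
  One frequency per block keeps marginal frequencies exact. This yields
  valid dosages, block structure, and an exact empirical LD matrix —
  unlike a thresholded Gaussian model. Adjacent-variant correlation is
  ≈ `rho`, decaying with distance within a block and vanishing across
  blocks.
- **Cohorts**: disjoint exposure (eQTL) and outcome (pQTL) individuals
  from one pool — the two-sample design of an eQTL-catalog-vs-biobank
  analysis. Defaults: `nExp = 500` (the well-powered end of typical eQTL
  datasets, and the regime where secondary signals are detectable at
  all), `nOut = 3000` (plasma pQTL scale), `m = 200` variants,
  `rho = 0.9`, blocks of 20, MAF in [0.05, 0.5].
- **Effects** parameterized by variance explained so power is comparable
  across allele frequencies: defaults 10% (primary eQTL), 8% (secondary
  eQTL), 4% (primary pQTL), 2.5% (secondary pQTL) — calibration choices
  emulating typical cis-QTL effect sizes, with secondary signals weaker
  than primary ones; no published effect-size distribution exists for
  these data, so these are choices, not estimates. The outcome phenotype
  is rank-inverse-normal transformed, as in protein-abundance pipelines.
- **Truth structure**: the coding gene always shares the protein's
  primary causal variant, which lies inside the coding gene's body (the
  empirical pattern that median distance from a primary pQTL to its gene
  body is zero). Each neighbor gene is co-regulated by that variant with
  probability `pleiotropyRate` — the confound that creates false-positive
  colocalizations — or else carries its own causal in a different LD
  block. With probability `multiSignalRate` the protein and coding gene
  share a second, conditionally distinct causal; neighbors never share
  the second signal, which is what lets the multi-signal filter buy
  precision. All sharing, signal ranks, and slope signs are recorded.

What the generator does **not** emulate: realistic human LD maps (real LD
has near-1 plateaus; the copy process decays geometrically with
distance), demography, imputation error, trans effects, aptamer binding
artifacts, or tissue heterogeneity. Passing benchmarks here show the
machinery behaves as designed under known truth — not that real-data
precision/recall would match any particular values.

## Evaluation conventions

- Precision is over unique (protein, gene) pairs pooled across datasets;
  MR slopes are per (gene, protein, dataset) triplet — the two units are
  deliberately different.
- A protein enters the recall denominator iff it has at least one
  purity-filtered credible set.
- Closest-gene baseline: distance to the gene body (0 inside the closed
  interval, else distance to the nearer edge) or to the strand-aware TSS;
  all distance ties are returned, at most one being a true positive.
- Single-signal method comparisons restrict to the first outcome signal;
  `by_cs_index` stratification reports per outcome credible-set rank.
- Percentages are reported to one decimal with half-up rounding.

## Problem sizes

The test suite and the acceptance script size their simulations for a
single CPU: 200 loci for the credible-set coverage check (m = 100,
n = 500, 10% variance explained), 200 random 8–12-variant loci for the
enumeration oracle, 500 simulated loci for the MR calibration contrast,
and a 40–60-protein catalog (m = 120, 3 genes per locus, pleiotropy 0.4,
multi-signal 0.6) for the end-to-end ordering. These sizes give stable
orderings across seeds while keeping a full run in minutes.

## Known limitations

- The LD-aware fine-mapping operates on z-scores with a fixed prior
  variance; no per-effect prior-variance optimization is attempted.
- Correlated-instrument IVW (LD-aware covariance between instruments) and
  multivariable MR are out of scope.
- The allelic-spread estimator targets qualitative parity (wide intervals
  under discordance), not numerical parity with any external sampler.
- CLPP's outcome-side convention (per-signal rows vs overall PIPs) is
  genuinely ambiguous upstream; both are supported, the per-signal row is
  the default.
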