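---
title: "Per-mutation error bounds for FoldX stability predictions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-mutation error bounds for FoldX stability predictions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddgbounds)
library(dplyr)
```

## The problem

FoldX predicts the change in folding or binding free energy upon a missense
mutation, $\Delta\Delta G$ (kcal/mol), as a linear combination of empirical
energy terms. The prediction carries substantial, mutation-dependent error,
and published benchmark correlations vary too widely to convert into a usable
per-mutation uncertainty. `ddgbounds` models that uncertainty directly.

Taking the experimental value as the truth, define the response

$$\mathrm{Error} = \left|\Delta\Delta G_{\mathrm{FoldX}} -
\Delta\Delta G_{\mathrm{exp}}\right|,$$

and regress it on quantities available *without* knowing the truth: the 16
constituent FoldX energy terms plus the total, their standard deviations over
an ensemble of molecular-dynamics (MD) snapshots (the study design uses 100
snapshots, 1 ns apart, averaged into the final prediction), and biochemical
properties of the mutated residue. A fitted model converts, for each new
mutation, into an upper prediction bound $B$ on its Error: the true
$\Delta\Delta G$ then lies in $\Delta\Delta G_{\mathrm{FoldX}} \pm B$ with
the nominal probability.

## The model ladder

Five nested predictor pools probe what the MD ensemble and the residue-level
biochemistry buy:

| rung | $\Delta\Delta G$ source | candidate predictors |
|---|---|---|
| model1 | single structure | 17 energy terms |
| model2 | single structure | + biochemical properties |
| model3 | MD-snapshot mean | 17 energy terms |
| model4 | MD-snapshot mean | + biochemical properties |
| model5 | MD-snapshot mean | + per-term snapshot SDs (full model) |

The biochemical properties are: a proline involvement flag; absolute changes
in van der Waals volume (Zamyatnin), hydrophobicity index at pH 7 (Monera),
and side-chain charge; DSSP secondary-structure class (dummy-coded against
reference level B); and relative solvent accessibility, the DSSP
accessibility normalized by the residue-specific maximum (Tien, theoretical
set by default, empirical available). The tables ship as a versioned CSV with
citations (`aa_properties()`). Histidine charge defaults to 0 (it sits near
its pKa at pH 7); a fractional convention is available via `his_charge`.
For models 1–2 both the response and the term predictors come from the
single-structure FoldX run; for models 3–5 both come from the MD means — each
rung is internally consistent about its structure source, and
`build_predictor_table(term_source =)` can override this pairing.

## Selection, BIC and its conventions

Candidate subsets are ranked by
$\mathrm{BIC} = -2\,\mathrm{loglike} + \log(n)\,d$ with the Gaussian maximum
log-likelihood and $d$ equal to the number of fitted slope coefficients —
dummy columns counted individually, intercept excluded. A `plus_intercept`
convention is available; at fixed $n$ the two differ by a constant and can
never reorder candidates.

`best_subset_select()` finds the minimum-RSS subset of predictor *blocks* at
every size and then the BIC-minimizing size, with the intercept-only model
always in the running. The search is branch-and-bound: RSS is monotone
non-increasing in the predictor set, so the RSS of the relaxed model holding
all still-undecided blocks bounds every completion of a branch. A greedy
forward pass seeds the incumbents so pruning engages early; `max_size`
(default 12 blocks) caps the explored sizes on wide pools.
`stepwise_select()` is the greedy alternative: single-block additions and
removals, always taking the largest BIC decrease, stopping when no move
improves. Ties break toward fewer predictors, then lexicographic block
order, making both searches deterministic.

The secondary-structure dummies form one block — the categorical predictor
enters or leaves whole, matching how the final models retain all of its
levels despite individually weak coefficients. Exactly aliased columns (for
example, the dummy of a level absent from a training fold; the rare π-helix
class I is a valid level that the generator never emits) are dropped with a
warning rather than failing the fit; predictions for rows carrying such a
level fall back to the reference-level contribution and are flagged.

## The bound and its calibration

For a new mutation with predictor vector $x_0$, the prediction error of the
fitted response is $s\sqrt{1 + x_0^{\top}(X^{\top}X)^{-1}x_0}$ on
$n - p$ degrees of freedom, and the bound is

$$B = x_0^{\top}\hat\beta + t_{q}\, s \sqrt{1 + x_0^{\top}(X^{\top}X)^{-1}x_0}.$$

Because the Error is an unsigned magnitude only the upper limit matters, and
the package's default places it at the level-quantile ($q = 0.95$): a
one-sided upper prediction bound, for which
$P(\mathrm{Error} < B) = 0.95$ exactly when the model is correct. The
alternative `side = "two_sided"` reproduces the common construction that
takes the upper limit of the central 95% interval; its capture rate is the
97.5th predictive percentile and matches 95% only for responses with no
effective lower tail — which real Error data, being non-negative and
right-skewed, approximately are. The distinction is invisible on such data
and decisive on correctly specified synthetic data; we verified the
two-sided bound captures ~97.5% there, which is why the calibrated one-sided
form is the default. Lower limits are reported raw, never clamped at zero.

## Leave-one-system-out validation

Mutations from one protein system share structure, preparation and
measurement provenance; rows are not independent across a system boundary.
Model assessment therefore holds out entire systems: for each system, the
model — *including the subset search* — is re-fit on the remaining systems
and evaluated on the held-out mutations, so nothing leaks from the held-out
system into selection (a fixed-predictor mode evaluates one pre-chosen
formula instead, for the variant of the workflow that selects once on all
data). Coverage is the pooled fraction of held-out mutations whose Error
falls strictly below its bound,

$$\mathrm{Coverage} = \frac{1}{N}\sum_i \sum_{j=1}^{n_i}
I(\mathrm{Error}_j < B_j),$$

identically equal to the $n_i$-weighted mean of per-system coverages. The
headline precision metric is the *median* of the upper bounds — robust to the
handful of very wide intervals — read as "± so many kcal/mol";
`width_kind = "full"` switches to upper-minus-lower for sensitivity
analyses. Ties ($\mathrm{Error} = B$) count as misses; they have measure
zero in practice.

Outliers (uncaptured mutations) concentrated in particular systems signal
system-specific failure modes. `outlier_gof_test()` compares observed
outlier counts with size-proportional expectations via
$\sum (O-E)^2/E$; the default Monte-Carlo p-value simulates multinomial
allocations and reports $(b+1)/(\mathrm{reps}+1)$ with 2000 replicates, so
the most extreme attainable value is $1/2001 \approx 0.00050$. The
asymptotic $\chi^2_{k-1}$ reference is available where counts are large.

## Classification with bounds

With thresholds at ±0.5 kcal/mol (stabilizing below −0.5, neutral on the
closed band, destabilizing above +0.5), `classify_with_bounds()` widens each
prediction to $\Delta\Delta G_{\mathrm{FoldX}} \pm B$ and reports every class
the interval touches; only single-class intervals are called with
confidence. At $B = 0$ this reduces exactly to the point classification, and
the touched set grows monotonically with $B$. `bin_frequencies()` profiles
truth classes or bounded calls along 1 kcal/mol bins aligned to the
thresholds (…, −1.5, −0.5, 0.5, …; left-open, right-closed; the alignment
and width are configurable because any histogram convention is defensible).
`resample_uniform_bins()` redraws a fixed number of mutations (1000 by
default) from every nonempty experimental-ddG bin to decouple classification
accuracy from the destabilizing-skewed sampling of mutation databases; one
master seed spawns per-bin child seeds so bins stay decoupled yet the whole
draw is bit-reproducible.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` reproduces the statistical shape the analysis assumes:
10 systems of 19–190 mutations (uniform), residue pairs drawn over the real
property tables with a 10% proline rate, secondary-structure frequencies
typical of globular proteins (no π-helix), RSA from a buried-skewed Beta(1.2,
2.5), log-normal clash terms, Gaussian signed terms, a total correlated with
— but not aliased to — its constituents, and per-term SDs sharing a per-row
conformational-variability factor. The Error is generated on the linear
scale, $\mathrm{Error} = 1.5 + X\beta + u_{\mathrm{system}} + \varepsilon$,
$\varepsilon \sim N(0, 0.6^2)$, with true coefficients on the van der Waals
term, side-chain entropy, van der Waals clash, the SD of the total energy and
the proline flag (0.35–0.7 kcal/mol per unit, echoing the magnitudes the
real folding model recovers). These defaults place the linear predictor
about 2.5 residual SDs above zero, so the resampling that keeps the
magnitude response non-negative touches well under 1% of draws and OLS
recovery stays effectively unbiased; a clamp flag exists to *study* the
truncation as a deliberate misspecification. The experimental ddG is then
reconstructed as $\Delta\Delta G_{\mathrm{FoldX}} - s\cdot\mathrm{Error}$
with the sign drawn destabilizing-side with probability 0.7, giving the
destabilizing-heavy class mix seen in mutation databases.

Passing calibration and recovery tests on these data shows the machinery is
correct *given its assumptions*. Real data differ in ways the generator
deliberately omits: correlations among energy terms, heteroscedastic and
heavier-tailed errors, system-level idiosyncrasies (supported via
`system_effect_sd`, default off), and any dependence of Error on unmodeled
structure quality. Coverage on real systems is an empirical question the
leave-one-system-out machinery answers per dataset.

## Numerical choices and degenerate inputs

* Sample SD (divisor $n-1$) for snapshot aggregation; the population
  convention is a flag.
* A perfect fit (RSS = 0) keeps its zero-width intervals but has no
  log-likelihood; BIC refuses unless `rss_floor = TRUE` substitutes
  $10^{-12} n \,\mathrm{var}(y)$ (degenerate synthetic cases only).
* Near-ties in the searches are resolved with a $10^{-9}$ slack toward
  smaller, lexicographically earlier models, keeping both searches
  deterministic under floating-point noise.
* RSA values above 1 (DSSP accessibility exceeding the tabulated maximum)
  are clipped with a warning.
* Duplicate mutation keys are an error, never silently averaged.

## Problem sizes used in the shipped checks

The test-suite simulations run at sizes chosen to make their Monte-Carlo
error small relative to the tolerance being asserted while keeping the suite
quick: 20 randomized oracle fixtures; 50 exhaustive-search comparisons at
5–7 blocks; 50 calibration replicates of 10 × 60 mutations (binomial SE of
the mean coverage ≈ 0.1 pp against a 2 pp band); and 100 recovery replicates
at n = 1000. The acceptance script reruns the calibration study from scratch
at the same size.
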