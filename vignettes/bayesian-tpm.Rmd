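---
title: "Estimating transition probability matrices with expert-elicited Dirichlet priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating transition probability matrices with expert-elicited Dirichlet priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesTPM)
```

## The model

A Markov cohort model over K mutually exclusive health states needs a
row-stochastic transition probability matrix (TPM) per treatment arm and
cycle length. Row *i* of the matrix is a probability vector
`p_i = (p_i1, ..., p_iK)`; the trial evidence for it is a vector of
transition counts `x_i` with total `n_i`, modelled as multinomial. With a
Dirichlet prior `p_i ~ Dir(alpha_i)`, conjugacy gives the posterior in
closed form,

\[ p_i \mid x_i \sim \mathrm{Dir}(\alpha_i + x_i), \qquad
   \mathrm{E}[p_{ij} \mid x_i] = \frac{\alpha_{ij} + x_{ij}}{\alpha_{i0} + n_i},
   \quad \alpha_{i0} = \sum_j \alpha_{ij}. \]

Rows are a priori and a posteriori independent, so the whole matrix
posterior is a product of row Dirichlets and `fit_tpm()` never needs
simulation for point estimates. The assumptions inherited from the
multinomial likelihood are worth stating: person-week transitions pooled
over observation weeks are treated as exchangeable (no within-patient
correlation, no time trend within a phase), which is exactly the assumption
the count data's published form (row percentages plus `n`) encodes.

Three strategies are exposed, differing only in `alpha`:

* `trial_only`: no prior; `x/n` with structural zeros. Rows never observed
  (`n = 0`) are made absorbing so the matrix stays stochastic — such states
  are unreachable from any cohort started outside them, so this choice
  cannot affect model output, but it keeps every matrix testable against
  the same invariants.
* `vague`: flat `alpha_ij = mass/K`.
* `informative`: expert-elicited row means scaled to `mass`.

### Why the vague prior has total mass 1, not K

A flat Dirichlet can be parameterised as `Dir(1, ..., 1)` (mass K) or as
`Dir(1/K, ..., 1/K)` (mass 1). The published posterior estimates this
package reproduces are only consistent with mass 1: for the risperidone
state-1 row (2 observations, both stays) the published vague posterior is
about 71% for staying, which is `(1/8 + 2) / (1 + 2) = 70.8%`; a
`Dir(1, ..., 1)` prior would have given `(1 + 2) / (8 + 2) = 30%`. Mass 1
is therefore the default, and it also puts the vague and informative
strategies on an equal footing — same prior weight, different location.
`make_vague_prior(K, total_mass = K)` selects the other convention when
wanted.

## Count reconstruction

Published transition tables print row-wise relative frequencies at two
decimals plus the row count `n`. `reconstruct_counts()` inverts the
printing: each count starts at `round(percent/100 * n)`, exact rounding
ties (half-unit residuals) may be shifted to restore `sum(x) = n`, and the
result must satisfy `|x_j/n - percent_j/100| <= 0.5/n` per cell. Any row
that cannot be inverted under these constraints is an error, deliberately:
it means the table was transcribed wrongly, and one packaged row (a
rendering that prepends the row label to the first cell, turning 3.31 into
23.31) is caught exactly this way. A property test draws random `(p, n)`
with `n` up to 10,000, prints at two decimals, and checks recovery of the
original counts.

## Prior elicitation

Experts cannot state a coherent K-dimensional Dirichlet directly; they can
answer quartile questions about one transition at a time. The pipeline is:

1. **Marginal beta fit** (`fit_beta_quartiles`). For each destination, find
   `Beta(a, b)` minimising the squared error of its CDF at the elicited
   quartiles, `sum((pbeta(q, a, b) - c(.25, .5, .75))^2)`. The fit targets
   CDF values rather than moments because quartiles are what was elicited.
   Optimisation is Nelder-Mead on log shapes from three fixed starts (a
   moment-style start using the normal quartile spacing `sd ~ IQR/1.349`,
   plus `(1,1)` and `(2,2)`), polished by up to eight damped Gauss-Newton
   steps. All starts are deterministic; the objective at the optimum is
   reported as `residual`. Exact quartiles of any beta with shapes in
   `[0.2, 10]` are recovered to about `1e-5`; the tests assert `1e-3`.
2. **Reconciliation** (`reconcile_dirichlet`). A Dirichlet forces every
   marginal to be `Beta(alpha_j, N - alpha_j)` with one shared
   `N = sum(alpha)`. The coherent prior is the least-squares projection
   `min_alpha sum_j (a_j - alpha_j)^2 + (b_j - (N - alpha_j))^2`, which is
   quadratic in `alpha` and solved exactly by linear least squares (QR);
   coherent inputs pass through unchanged and a non-positive component is
   an error naming the category. The implied coherent quartiles are
   returned so a caller can re-present them to the expert and iterate —
   the feedback loop is modelled as a pure function, not a GUI.
3. **Pooling and scaling**. Experts are pooled by simple averaging
   (`pool_experts`), the standard recommendation for small panels, and the
   pooled row is scaled to total mass 1 (`scale_prior`), i.e. one notional
   prior observation per source state, so that high prior uncertainty is
   guaranteed and trial data dominates wherever it exists. Pooling and
   scaling commute (tested).

The elicitation software used for the original panel offered several
reconciliation variants and did not document which each expert chose; this
package fixes the least-squares objective above so results are exactly
reproducible, and accepts pre-pooled mean matrices directly for the case
where only pooled values are authoritative.

## Cohort model

`build_schedule()` enforces the two-phase cycle structure — six one-week
cycles then 12-week cycles, so horizons are `6 + 12m` weeks (54 and 258 are
the horizons of interest). Numerical conventions, each chosen once:

* **Cycle timing.** State membership is counted at the end of each cycle
  (occupancy after the transition), with `half_cycle_correction = TRUE`
  available for sensitivity analysis (average of start and end occupancy).
* **Weeks to years** uses 52 weeks/year, because the horizons are defined
  in weeks and only weeks make `54 = 6 + 4 x 12` exact.
* **Mortality** is a per-cycle probability (scalar or per-cycle sequence),
  routed to an absorbing death state by scaling each living row by
  `1 - p_death`. The helper `cycle_mortality(annual, weeks)` converts an
  annual probability to cycle length c as `1 - (1 - annual)^(c/52)`; weekly
  and 12-week cycles need different values, so a realistic configuration
  passes a sequence. Death accrues zero utility. Life-table processing
  itself is out of scope.
* **Discounting** defaults to 0 (one-year horizons are conventionally
  undiscounted); an annual rate discounts each cycle to its end week.
* **Phase-2 matrix.** The maintenance matrix is a per-12-week matrix. If
  none is supplied, the twelfth power of the weekly matrix is used (time
  homogeneity); a separately estimated matrix can be passed instead, which
  is how the original two-phase analysis is structured.

The worked example's utilities (monotone from 0.85 down to 0.35 across the
eight severity states) and initial distribution (proportional to the pooled
person-week exposure of the two arms, states 7-8 empty) are illustrative
choices made once: the original analysis's utility set, mortality table and
baseline distribution are not in the public domain. Consequently the
package asserts the *structure* of the QALY comparison — zero incremental
QALY under identical inputs, occupancy conservation to 1e-9, and the
qualitative ordering of the three strategies (informative between
trial-only and vague) — rather than the original's absolute QALY values.

## Monte-Carlo cross-check

`mc_posterior_mean()` exists to demonstrate that simulation and the closed
form agree, mirroring a chain-based estimation of the same posterior
without reimplementing one: rows are sampled exactly by inverse-CDF stick
breaking (each stick a beta quantile), draws are generated in antithetic
pairs (`u`, `1 - u`) — a standard variance-reduction device that matters
here because small-alpha cells are extremely right-skewed — and the
standard error is computed over independent pair means, keeping "within 3
standard errors" an exact statement. Burn-in draws are generated and
discarded purely for interface fidelity. The acceptance test runs 50,000
draws against the case-study posteriors, per cell, both arms.

## Probabilistic sensitivity analysis

`run_psa()` draws one matrix per arm per phase per run from the row
Dirichlets, runs both arms through the cohort model under the shared
specification, and records the incremental QALY; estimation uncertainty
and sensitivity analysis happen in one step. Rows with zero observations
in both arms have identical posteriors under the shared prior, and by
default share a single draw per run, so no spurious between-arm difference
is manufactured for states the trial never saw (`share_unobserved = FALSE`
switches to fully independent draws). Rows are a priori independent, so
independent row draws sample the exact joint posterior. 1000 runs is the
default. The toy oracle test checks the PSA mean and SD against direct
1-D quadrature over a beta posterior.

## Synthetic-data generator

The generator provides ground truth the real data cannot:

* `gen_true_tpm(K, concentration = 30, stay = 0.6)` draws rows from a
  Dirichlet centred on a diagonal-weighted base. The defaults emulate the
  dominant diagonals of weekly severity-state matrices (observed stay
  probabilities in the case study run roughly 0.4-0.9); concentration 30
  gives realistic row-to-row variation while keeping rows well away from
  the simplex boundary.
* `simulate_trial()` pools person-week multinomial transitions over a
  4-week observation window by default, matching the inferential model
  exactly — deliberately *not* simulating within-patient correlation,
  dropout or dosing. Passing tests therefore validates the estimator under
  its own assumptions; it does not show robustness to correlated real
  panels.
* `simulate_expert()` computes the exact marginal quartiles implied by a
  true Dirichlet row and perturbs them with centred Gaussian noise on the
  log-odds scale, which respects the (0,1) range without truncation
  artifacts; triples are re-sorted so quartile ordering always holds. At
  noise 0 the elicitation round trip recovers the true hyperparameters to
  1e-2 (tested over random rows with components in `[0.2, 10]`).

Problem sizes used by the test-suite simulation studies — 20 replicate
seeds over trial sizes of 100, 1,000 and 10,000 person-weeks for the
parameter-recovery study; 50,000 draws for the Monte-Carlo agreement
check; 10,000 draws for generator-mean checks — were chosen to make the
Monte-Carlo error comfortably smaller than the effects being asserted
while keeping the full suite around ten seconds.

## Known limitations

* The conjugate treatment is exact for this model but deliberately narrow:
  no hierarchical pooling across rows or arms, no covariates, no
  time-inhomogeneity beyond the two-phase structure.
* Expert reconciliation fixes one least-squares objective; other
  reconciliation rules (e.g. weighted, or in quartile space) would give
  slightly different priors, and individual expert choices in the original
  elicitation are unrecoverable.
* The cost side of cost-effectiveness (and hence ICERs) is out of scope;
  the model reports QALYs only.
* The absolute QALY outputs depend on user-supplied utilities, mortality
  and baseline distribution; only the comparison structure is validated.
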