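---
title: "Methods: EQ-5D-3L scoring, grading and cohort inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EQ-5D-3L scoring, grading and cohort inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eq5dhrqol)
```

This vignette documents the models, conventions and numerical choices behind
the package, and what its synthetic data can and cannot establish. The
motivating setting is a cross-sectional HRQoL survey of 250 pregnant women
(133 HIV-positive, 117 HIV-negative) in an impoverished prefecture in
south-west China; the package generalises that analysis into a reusable,
tested pipeline.

## 1. Utility scoring and the constant-C convention

A state `q = (MO, SC, UA, PD, AD)` with levels in {1,2,3} is valued under a
3-level time trade-off tariff as

$$F(q) = 1 - C - \sum_{d} \delta_d(q_d) - N3 \cdot \mathbf{1}\{\max_d q_d = 3\},$$

with level-1 decrements $\delta_d(1) = 0$. The shipped Chinese TTO
coefficients are:

| dimension | level 2 | level 3 |
|---|---|---|
| mobility | 0.099 | 0.246 |
| self-care | 0.105 | 0.208 |
| usual activities | 0.074 | 0.193 |
| pain/discomfort | 0.092 | 0.236 |
| anxiety/depression | 0.086 | 0.205 |

with $C = 0.039$ and $N3 = 0.022$.

The standard published convention charges $C$ only when some dimension
exceeds level 1, so full health scores exactly 1. The motivating study's
published medians (0.961 for the whole cohort, whose majority state is
11111; 0.875 for the HIV-positive group, whose median state is 11112) are
arithmetically consistent only with charging $C$ unconditionally:
$1 - 0.039 = 0.961$ and $1 - 0.039 - 0.086 = 0.875$. The package therefore
defaults to `constant = "always"` and exposes `constant = "standard"` for
the conventional behaviour. Utilities are carried at full double precision;
rounding (to the conventional 3 decimals) happens only in reports. Negative
utilities (worst state: $-0.149$) are never truncated.

## 2. Health-state grading

With distance $D(q) = \sum_d q_d - 5$:

* **full**: $D = 0$;
* **mild**: $1 \le D \le 4$, no dimension at level 3, at most three
  dimensions at level 2;
* **severe**: $7 \le D \le 9$, no dimension at level 1, at least two
  dimensions at level 3;
* **moderate**: everything else (the explicit residual).

Applied in that order the rules are mutually exclusive and, as the test
suite verifies by brute force, partition all 243 states. Note the rule set
is not monotone in utility: 12321 (distance 4, contains a 3) is moderate
while 22221 (distance 4, four 2s) is also moderate, yet some mild states
have lower utility than some moderate ones; only `severe` is uniformly
below `mild` in utility, which is checked exhaustively.

## 3. Test battery conventions

* **Chi-square**: Pearson $\sum (O-E)^2/E$, $df = (r-1)(c-1)$. Yates
  continuity correction ($|O-E|$ reduced by 0.5, floored at 0) is applied
  to 2x2 tables and only there. This mixed policy is the one that
  reproduces every baseline statistic of the motivating study from its
  printed counts (7.709, 1.692, 0.032, 1.692 on 2x2 with Yates; 3.797 and
  0.265 on 4x2/3x2 without).
* **Freeman–Halton exact test**: all tables with the observed margins are
  enumerated; the p-value is the total conditional probability of tables no
  more probable than the observed one, with a relative tie tolerance of
  1e-7 (standard practice — exact ties in table probabilities are common
  with balanced margins). The enumeration guard is the upper bound
  $\prod_{i<r, j<c} (\min(r_i, c_j)+1)$ on the table count (default cap
  1e6); beyond it the error message recommends the chi-square.
* **Test selection in the pipeline**: group-comparison tables of the
  baseline use the chi-square policy above; the five dimension tables
  always use the exact test (their level-3 cells are tiny); grade-by-factor
  tables use the exact test when any expected count falls below
  `exact_threshold = 5` and enumeration is affordable, else chi-square.
* **Welch t** from summary statistics, with Welch–Satterthwaite df. From
  the printed age summaries (32.37 ± 5.62 vs 28.41 ± 7.07) Welch gives
  4.857 where the pooled statistic gives 4.928; the study printed 4.85
  (a truncation of the Welch value) with the pooled df 248. The package
  reports the Welch df (≈ 220.8) and treats the printed df as a
  presentation artefact.
* **Median/IQR**: linear interpolation (R type 7) by default,
  nearest-rank (type 1) as an option. Whenever one value holds a strict
  majority — as full health does here — the median is that value under
  either convention, which is why the headline medians are
  convention-free.
* **Multiple testing**: none, matching the motivating analysis
  (α = .05 throughout).

## 4. Proportional-odds regression

The cumulative-logit model $P(Y \le k \mid x) = \text{logit}^{-1}(\alpha_k -
x'\beta)$ is maximised by Newton iteration: analytic score, observed
information obtained by central differences of that score (the parameter
count is at most a handful, so this is cheap and avoids a long third-level
derivation), step-halving to keep thresholds strictly increasing and the
log-likelihood non-decreasing, convergence at $\|\nabla \ell\|_\infty <
10^{-8}$. Standard errors are from the inverse observed information;
OR = $e^\beta$ with Wald 95% CIs. With two outcome categories the model *is*
binary logistic regression and the tests verify coefficient agreement with
`glm` to 1e-6; at three categories it agrees with `MASS::polr` to 1e-5.

Degenerate inputs: zero-variance covariates are reported with coefficient 0
and `NA` standard error and excluded from the optimisation (the
intercept-only fit's thresholds are then the empirical cumulative logits,
which the closed form confirms). Coefficients diverging past |β| > 30 are
diagnosed as complete/quasi-complete separation and raised as an error;
non-convergence within 100 iterations is flagged and the estimates are
withheld rather than reported half-baked.

In the pipeline the outcome is the grade, ordered full < mild < moderate
with severe respondents excluded (below), and the covariates are an
age-band indicator (35–53 vs 18–35) and the prenatal-visit band scored
1–4. The motivating study does not state its coding; this one is the
simplest consistent with its variable list, and is a documented assumption,
not a reproduction. Its published regression table is internally
inconsistent (OR printed equal to B, CIs symmetric about B), so no numeric
agreement is claimed or tested; the package reports the standard
OR = exp(B).

## 5. The synthetic-cohort generator

`sample_cohort()` draws, per respondent, a shared latent severity
$z \sim N(0,1)$ and per dimension $z_d = \sqrt{\rho}\, z +
\sqrt{1-\rho}\, \varepsilon_d$, then cuts $z_d$ at the Gaussian quantiles of
the target level probabilities. This one-factor Gaussian copula preserves
the marginal level distribution *exactly in expectation for every* $\rho$,
while $\rho > 0$ induces positive association between dimensions, as real
EQ-5D data show. Defaults: the study's observed per-group marginals
(`study_cohort_spec()`), $\rho = 0.4$ — an arbitrary but realistic midpoint,
chosen once; the study publishes no joint information that could calibrate
it. Demographics are drawn independently of the state, uniform ages within
the drawn band; group sizes default to 133/117.

What a green test on synthetic data establishes: that the pipeline's
counting, test selection, exclusion handling and estimation are correct for
data with the study's marginal structure. What it does not establish:
anything about the true joint dependence of dimensions, demographic–state
association, or age effects in the real population — the generator is
deliberately agnostic there.

## 6. The fixture cohort and the margin infeasibility

`fixture_cohort()` is a deterministic 250-row reconstruction used as the
package's reference dataset. Its demographic and per-dimension level counts
equal the study's printed marginal tables exactly, and its full-health
counts (55 positive / 75 negative) and single severe negative respondent
are exact.

The study's printed *grade* margins, however, cannot all hold at once. A
counting argument for the positive group: its dimension table leaves 126
level-2 cells and 6 level-3 cells across the 78 non-full respondents. A
moderate state without a level 3 requires at least four level-2 cells, and
at most 6 moderates can carry a level 3, so the printed 45 mild + 33
moderate would require at least $45 \cdot 1 + 27 \cdot 4 = 153 > 126$
level-2 cells. The feasibility frontier (also accounting for the scarce
self-care and mobility level-2 supply) is 23 moderates; the analogous bound
for the negative group is 18. The fixture therefore pins grade counts at
(55, 55, 23, 0) and (75, 23, 18, 1) against the printed (55, 45, 33, 0) and
(75, 22, 19, 1). This also explains why the printed grade-comparison
$\chi^2_2 = 12.5$ is not recoverable from the printed grade table itself
(recomputation gives 13.6); neither number is part of the acceptance
surface.

The joint completion is greedy and documented: full states first; the
severe state takes level 3 in the highest-supply level-3 dimension and in
the scarcest-level-2 dimension still holding a level 3, level 2 elsewhere;
remaining level-3 cells become single-level-3 moderate states; the number
of four-level-2 moderates is the largest feasible; all remaining level-2
cells spread over mild states (1–3 each), always drawing from the dimension
with the largest remaining supply, ties broken lexicographically by
dimension code. The construction is re-verified against the margins on
every call and pinned byte-for-byte by the test suite. Demographic
categories are allocated by systematic interleaving (category $j$ occupies
evenly spaced quantile positions), which keeps them near-independent of the
state sequence; consequently grade-by-factor tables and the regression on
the fixture describe the fixture, not the original respondents.

Two further printed numbers are documented as not reproducible and are
excluded: the self-care dimension p-value (printed < .001, but the groups
differ by one respondent in one cell — every exact test gives ≈ 1) and the
whole-cohort first quartile (printed −0.046, which contradicts the printed
grade distribution; −0.046 is exactly the tariff of 32333, suggesting a
transcription from a different summary).

## 7. Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `constant` | `"always"` | — | consistency with the published medians (§1) |
| `rho` | 0.4 | latent correlation | realistic positive association; uncalibratable (§5) |
| `n_per_group` | 133 / 117 | respondents | the study's group sizes |
| `exact_threshold` | 5 | expected count | the classical small-expected-cell rule |
| `max_tables` | 1e6 | tables | keeps exact enumeration under a second |
| `tie_tol` | 1e-7 | relative | Freeman–Halton tie handling (§3) |
| `tol` (polr) | 1e-8 | gradient norm | near machine-precision optimum |
| `quantile_type` | `"linear"` | — | R's default convention; `"nearest"` available |

## 8. Known limitations

* The fixture is *one* consistent joint completion of the published
  margins; real respondent-level data would almost surely differ jointly.
* The exact test is full enumeration only — no Monte-Carlo or mid-p
  variants — so very large sparse tables are out of scope by design.
* The regression on the fixture cannot recover the study's (internally
  inconsistent) published estimates; parameter recovery is instead
  demonstrated on simulated cohorts where the truth is known.
* EQ-5D-5L, crosswalks, non-Chinese value sets and VAS scoring are out of
  scope, though `value_set_3l()` accepts any coefficient system with the
  same structure.
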