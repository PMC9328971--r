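---
title: "Expression-level-free prognostic signatures from lncRNA pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-level-free prognostic signatures from lncRNA pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferropair)
```

## The model

`ferropair` fits survival signatures whose covariates are *within-sample
rank comparisons* rather than expression levels. For two genes $a$, $b$
and sample $s$ with expression $x_a(s)$, $x_b(s)$, the pair indicator is

$$ I_{ab}(s) = \mathbf{1}\{x_a(s) \ge x_b(s)\}, $$

with ties scored 1 (the indicator is 0 only when the first gene is
strictly *lower*). Pairs are stored in one canonical orientation — the
lexicographically smaller gene id first — because the Cox coefficients
attached to a pair depend on its orientation, and reproducibility demands
a fixed convention. The payoff is the package's central invariance: for
any strictly increasing $f_s$ applied per sample,
$I_{ab}(f_s(x)) = I_{ab}(x)$, so the fitted signature, the risk scores,
and the risk groups are bit-identical whether the input is raw counts,
FPKM, a log transform, or within-sample ranks. This is a property of the
encoding, not an approximation; the test suite asserts it end to end.

The risk model itself is a Cox proportional-hazards model on a selected
subset of indicators,

$$ h(t \mid s) = h_0(t)\, \exp\Big(\sum_i \beta_i I_i(s)\Big), $$

and the per-sample **risk score** is the linear predictor
$R(s) = \sum_i \beta_i I_i(s)$. The hazard model text leaves the score
formula implicit; the linear predictor is the only definition consistent
with multivariate Cox output, and it is what `risk_score()` and
`score_cohort()` compute.

## Pipeline stages and their parameters

**Coexpression screen** (`pearson_screen`). Candidate lncRNAs are kept
when they correlate with at least one ferroptosis-related gene at
`r > r_min` (default 0.4) and `p < p_max` (default 0.001, unadjusted —
the screen is a filter, not an inference). Correlation is computed on
`log2(x + 1)` across all samples. Two open choices are resolved as
defaults and exposed as arguments: the threshold applies to *signed* r
(positive coexpression, matching the screen's purpose of finding
FRG-driven lncRNAs; `absolute_r = TRUE` switches to $|r|$), and all
samples — tumor and normal — enter the correlation.

**Differential expression** (`differential_expression`). Fold change is
computed on linear-scale group means with a pseudocount of 1,
$\log_2\frac{\bar x_T + 1}{\bar x_N + 1}$, which is defined even for
zero-mean genes; significance comes from a two-sided Wilcoxon rank-sum
test with Benjamini–Hochberg adjustment, and a gene is called at
`q < 0.05` and `|log2FC| >= 1.5`. The rank-sum + BH combination was
chosen over a moderated-statistics engine deliberately: it is
self-contained and exactly testable against enumeration oracles, and the
DE stage sits behind a single function so a different engine can be
swapped in. The fold-change threshold is exposed because reasonable
analyses use 1 or 1.5 at this step.

**Pair encoding and frequency filter** (`build_pair_matrix`,
`filter_pairs`). All $\binom{n}{2}$ pairs are encoded; a pair whose
indicator frequency $f$ (its mean over samples) lies outside the *open*
interval $(0.20, 0.80)$ is dropped — a pair that is 1 (or 0) in nearly
every sample cannot separate risk groups. Boundary values are excluded
(`f = 0.20` is dropped); the bounds are arguments for anyone wanting a
different convention. The tie-scores-1 rule matters only for rounded or
synthetic data; with continuous expression, ties have measure zero.

**Univariate Cox screen** (`univariate_cox_screen`). One
single-covariate Cox fit per pair, Efron tie handling, retaining
`p < 0.05` (Wald). The threshold is an argument; 0.05 is the
conventional screening level.

**LASSO-Cox** (`lasso_cox_select`). L1-penalised Cox over the retained
indicators; the penalty is chosen by 10-fold cross-validated
partial-likelihood deviance at `lambda.min` (`rule = "1se"` available).
The fold split is drawn from the user seed, so selection is reproducible;
`lambda = 0` is the documented unpenalised escape hatch that keeps every
candidate.

**Stepwise multivariate Cox** (`multivariate_cox_fit`). Starting from
the model with every LASSO candidate, the single add-or-drop move that
most reduces $AIC = 2k - 2\log PL$ is applied until no move improves it.
The search is written in the package (a ~30-line loop over `coxph` fits
with memoisation) rather than delegated, so that moves are enumerated in
a deterministic order over indicator columns; `stepwise = FALSE` returns
the full fit, and a single-candidate call reduces exactly to the
univariate fit.

**Risk cutoff** (`choose_cutoff`). The published genre describes picking
the cutoff at the "maximum inflection point of the AIC values" along the
five-year ROC curve — not a defined mathematical procedure. It is
operationalised here as: for every candidate threshold (midpoints between
consecutive sorted unique scores), dichotomise the cohort, fit a
one-covariate Cox model on the binary group, and take the threshold
minimising the model AIC, ties going to the smallest threshold. This is
the only reading we found that actually uses an AIC per ROC operating
point, and it is exactly reproducible (the test suite checks equality
with exhaustive search). The full AIC-versus-threshold profile is kept
for plotting. Group assignment is strict: high risk iff
`score > cutoff`.

**Time-dependent ROC** (`time_dependent_roc`). Discrimination at horizon
$t$ uses the cumulative-case/dynamic-control definition: cases are
subjects with an observed event by $t$, controls those still at risk
after $t$. Censoring is handled with inverse-probability-of-censoring
weights from the Kaplan–Meier estimate of the censoring distribution
($1/\hat G(T_i^-)$ for cases, $1/\hat G(t)$ for controls), which keeps
the sensitivity/specificity sweep monotone by construction; the AUC is
the trapezoidal integral. With no censoring this reduces *exactly* to the
empirical probability that a case outranks a control, ties counted
$\tfrac12$ — the oracle the tests compare against. Horizons default to
1/3/5 years expressed in days (`365.25 * k`), matching day-denominated
follow-up.

**Evaluation** (`km_estimate`, `logrank_test`, `clinical_association`,
`independence_cox`, `decision_curve`, `build_nomogram`,
`panel_group_compare`). Kaplan–Meier and log-rank delegate to the
`survival` package. Clinical association uses a chi-squared test without
continuity correction on group × category tables, plus a rank-sum
(two strata) or Kruskal–Wallis (more) test of the score across strata.
The genre sometimes labels the two-group score comparison a "signed-rank"
test; risk groups are independent samples, so the rank-sum test is what
is actually computable and is what we implement. Decision curves use the
standard survival construction: predicted horizon risk from a
one-covariate Cox fit on the score, event fractions among the "treated"
estimated by Kaplan–Meier, and
$NB(p_t) = TP/n - FP/n \cdot p_t/(1-p_t)$ against treat-all/treat-none
references. The nomogram maps each covariate's contribution
$\beta_j (x_j - r_j)$ (reference $r_j$: first factor level, observed
minimum for continuous terms) linearly to points, scaled so the widest
contribution spans 100 points; total points map to survival through the
Breslow baseline evaluated at the reference profile,
$S(t \mid x) = S_{\mathrm{ref}}(t)^{\exp(\mathrm{lp} - \mathrm{lp}_{ref})}$,
an identity the tests verify to 1e-9.

## The synthetic cohort

`simulate_cohort()` generates exactly the structure the method assumes,
and nothing more. On the log2 scale, gene $g$ in sample $s$ is
$y_{gs} = \mu_g + b_s + \varepsilon_{gs}$ with gene means
$\mu_g \sim N(4, 1)$, a small shared sample effect
$b_s \sim N(0, 0.2)$, and unit noise; expression is $2^y$ (linear,
positive). Each coexpressed lncRNA copies its partner FRG's log signal
plus noise calibrated so the population Pearson correlation equals
`target_r`; differentially expressed lncRNAs gain `de_log2fc` log2 units
in tumor samples. Tumor survival is exponential with hazard
$\lambda_0 \exp(\sum_j \beta_j I_j)$ over the planted pairs, and
censoring is an independent exponential whose rate is solved numerically
(`uniroot`) so the expected censored fraction hits `censoring_rate`;
exponential forms were chosen because sampling is closed-form,
calibration is a one-dimensional root find, and proportional hazards
holds exactly — the assumption the Cox stages make. Clinical covariates
are drawn from categorical distributions matching a typical HNSCC cohort
table (age dichotomised at 65, ~27% female, stage IV-heavy, M mostly
unknown); they are independent of survival by construction, which is
what the independence-Cox calibration tests need. Normal samples carry
expression only — as in public tumor cohorts, they contribute to the DE
contrast but never to survival models.

Defaults are the package's reference recovery conditions, fixed once:
300 tumor / 30 normal samples, 300 lncRNAs and 300 mRNAs with 60 FRGs,
a quarter of lncRNAs coexpressed at $r = 0.6$, 4% of lncRNAs shifted by
3 log2 units (so ~12 DEFRlncRNAs and ~66 pairs, three of them planted
with $\beta = 1$), $\lambda_0 = 4\times10^{-4}$/day and 30% censoring.
The shift of 3 was chosen so that fold-change estimates — which the
pseudocount and the lognormal tail both attenuate — sit clearly above
the 1.5 calling threshold; $\lambda_0$ came from a closed-form design
calculation: with $\mathrm{lp} \sim \mathrm{Binomial}(3, \tfrac12)$ and
exponential event times, the population 5-year cumulative/dynamic AUC of
the true predictor is 0.86 at $\lambda_0 = 4\times10^{-4}$ (it would be
0.78 at $1\times10^{-4}$), leaving honest headroom for estimation noise
in the recovery experiments. Planted-pair genes are given a common base
mean so their indicator frequency sits near 0.5, inside the filter band.

A single integer seed drives everything; each generation stage
(gene means, expression noise, survival, censoring, clinical covariates)
reseeds from a deterministic function of the seed and the stage index, so
adding a stage never perturbs the draws of earlier ones.

What the generator does **not** emulate: library-size or GC biases,
batch structure, count discreteness, non-proportional hazards,
informative censoring, or correlated clinical covariates. Passing tests
on this cohort therefore demonstrate that the algorithms do what they
claim under the model's own assumptions — not that the signature
generalises to real tumor data, where screening thresholds interact with
technical artefacts the simulation deliberately omits.

## Numerical choices and degenerate inputs

* Correlations with a guard $\max(1 - r^2, \epsilon)$ in the t transform
  so perfect correlation yields $p = 0$ rather than NaN; constant genes
  are skipped with a warning (their correlation is undefined).
* Fully tied rank-sum comparisons return $p = 1$ (no evidence) rather
  than NA, so BH adjustment over a panel never fails.
* Duplicate gene rows collapse by mean on input (common after annotation
  joins); duplicate sample columns are an error (corrupt input).
* The stepwise search memoises fits by variable set and bounds the number
  of moves; AIC comparisons use an absolute tolerance of 1e-8 so
  floating-point ties cannot cycle.
* Every selection stage can come up empty on null data; the pipeline
  returns a `ferropair_result` with `empty = TRUE` and the stage that
  emptied, rather than erroring — the test suite exercises this path.
* Problem sizes in the test suite (cohorts of 150-500 tumor samples,
  10-20 recovery seeds, 1000-instance encoding oracles) were chosen as
  the smallest sizes at which the statistical properties under test are
  stable, keeping the default run fast on a single CPU.

## Known limitations

* The DE engine is a plain rank-sum test; variance-moderated engines can
  be more sensitive at small n, and the stage is pluggable if that
  matters.
* The coexpression screen uses unadjusted p-values by design (a filter),
  so its false-positive behaviour is controlled by the joint r-and-p
  rule, not an FDR guarantee.
* The AIC cutoff search refits a Cox model per candidate threshold
  (O(n) fits); for very large cohorts a coarsened threshold grid would
  be the first optimisation.
* `read_gtf_biotypes` reads only `gene` feature lines and ignores
  coordinates — it is a biotype extractor, not a general GTF parser.
* Nomogram and independence models drop covariates that become constant
  after unknown-removal, and refuse horizons beyond the last event time
  rather than extrapolating the baseline.
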