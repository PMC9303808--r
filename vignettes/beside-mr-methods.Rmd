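---
title: "Model averaging over instrument subsets for summary-data MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model averaging over instrument subsets for summary-data MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two-sample summary-data Mendelian randomization estimates the causal
effect of an exposure on an outcome from per-SNP GWAS summary statistics:
SNP-exposure estimates $\hat\gamma_j$ with standard errors $\sigma_{Xj}$
from one study, SNP-outcome estimates $\hat\Gamma_j$ with standard errors
$\sigma_{Yj}$ from an independent study. Under the instrumental-variable
assumptions each Wald ratio $\hat\Gamma_j/\hat\gamma_j$ estimates the same
causal slope $\beta$, and the inverse-variance weighted (IVW) average is
efficient. Two failure modes dominate practice: *horizontal pleiotropy*
(a SNP affects the outcome through a path other than the exposure, so its
ratio targets $\beta + \alpha_j/\gamma_j$) and *weak instruments*
(non-negligible $\sigma_{Xj}$, which both attenuates IVW and inflates
naive heterogeneity statistics). When pleiotropy acts through a confounder
shared with instrument strength, the InSIDE condition
($\mathrm{Cov}(\alpha_j,\gamma_j)=0$) fails and even directionally
"balanced" pleiotropy biases every averaging estimator.

## The model

The package works on the summary-data model
$$\hat\gamma_j \sim N(\gamma_j, \sigma_{Xj}^2), \qquad
  \hat\Gamma_j \sim N(\alpha_j + \beta\gamma_j, \sigma_{Yj}^2),
  \qquad \alpha_j \sim N(0, \tau^2),$$
with standard errors treated as fixed and known and SNPs independent
(LD-clumped and allele-harmonized upstream). Profiling the $L$ nuisance
parameters $\gamma_j$ out of the joint normal likelihood gives, per SNP,
$$\ell_j(\beta,\tau^2) = -\tfrac12\log 2\pi
  - \tfrac12\log(\sigma_{Yj}^2+\tau^2)
  - \tfrac12\,\frac{(\hat\Gamma_j - \beta\hat\gamma_j)^2}
       {\beta^2\sigma_{Xj}^2 + \sigma_{Yj}^2 + \tau^2}.$$
Two things about this expression matter numerically. First, the
denominator of the quadratic form carries $\beta^2\sigma_{Xj}^2$, which is
what makes the estimator weak-instrument robust. Second, the
log-determinant is *free of* $\beta$: profiling contributes
$\log(\sigma_{Yj}^2+\tau^2)$ only. We also implement the variant that
repeats the full variance inside the logarithm
(`variance_mode = "full"`), but its score gains a term
$-\beta\sum_j \sigma_{Xj}^2/v_j$ that re-introduces exactly the
weak-instrument attenuation the profile form removes; in our Scenario-2
benchmarks it shifts the maximum-likelihood slope by $-0.017$ on a true
effect of $0.05$. The asymmetric printed form is therefore the default,
and the symmetric-looking variant is kept only for A/B comparison. This
was a genuinely open design point, and the simulation evidence decided
it.

## Model averaging over instrument subsets

Each SNP carries an inclusion indicator $I_j$; only included SNPs
contribute their $\ell_j$. The posterior over
$\theta = (\beta, \tau^2, I)$ combines the penalized likelihood
$\sum_j I_j \ell_j + (\eta/2)\sum_j I_j$ with a zero-centered normal
prior on $\beta$ (SD 10 by default — weakly informative on the
standardized scale of typical MR effects), a vague gamma prior (shape =
rate = 0.01) on the precision $1/\tau^2$, and independent Bernoulli(½)
priors on the $I_j$, so inclusion is decided by the likelihood. The
penalty $\eta$ (default 0) tilts the sampler toward larger ($\eta>0$) or
smaller ($\eta<0$) instrument sets and is exposed for sensitivity
analysis.

A random-walk Metropolis–Hastings sweep updates, in order, (a) $\beta$,
(b) $\tau^2$, (c) one uniformly chosen indicator. Moves that would leave
fewer than `min_instruments` (default 5) SNPs included are rejected
outright: tiny instrument sets both invite chance InSIDE violations and
make $\tau^2$ unidentifiable. Two treatments of $\tau^2$ are provided:

* **DL plug-in** (default): $\tau^2$ is set, every sweep, to the
  closed-form DerSimonian–Laird moment estimate over the currently
  included SNPs (first-order weights $\hat\gamma_j^2/\sigma_{Yj}^2$,
  truncated at zero). This sidesteps the known inconsistency of the
  profile-ML variance estimate, mixes fast, and is the implementation the
  coverage benchmarks use.
* **Full Bayes**: a random walk on $\log(1/\tau^2)$ with the gamma prior
  and the appropriate Jacobian.

The two-component extension gives each SNP a state in
$\{S_0, S_1, S_2\}$: excluded, or contributing to slope
$(\beta_1, \tau_1^2)$ or $(\beta_2, \tau_2^2)$. This models data where a
large InSIDE-violating cluster identifies a second, biased slope. The
indicator move proposes a uniformly chosen *different* state for one SNP,
so $I_{1j} + I_{2j} \le 1$ holds structurally. The minimum-instrument
rule is enforced on the total included count, and a component may empty
entirely, in which case its slope samples its prior — mirroring the
observed tendency of the plug-in variant to concentrate on one slope when
the clusters are very unbalanced.

### Sampler engineering

The sweep kernels are compiled (Rcpp); an R-level `log_posterior()`
mirrors the target density and the test suite checks the two agree to
1e-12 and that the compiled chain's indicator-state frequencies match a
quadrature-enumerated posterior on a 5-SNP problem. Proposal scales are
set by a pilot adaptation phase (8 batches of 400 sweeps, rescaling by
$\exp(2.5(a - 0.28))$ (clamped) toward the 20–40% acceptance band) and frozen
before the retained run, preserving detailed balance of the stored
draws. All randomness flows from one seeded R RNG stream in a documented
order, so a seed plus a configuration reproduces a chain bit for bit.
Convergence is flagged by split R-hat ($<1.1$) when several chains are
run, otherwise by a Geweke comparison of the first 10% and last 50% of
the slope trace ($|z| \le 2.5$); the Monte-Carlo harness excludes and
counts flagged fits, as the benchmark protocol prescribes.

### Label switching

Two-component chains can swap component identities mid-run. Following
the K-means prescription, `kmeans_relabel()` pools both slope traces and
splits them by an exact one-dimensional 2-means (the optimal 2-partition
of sorted scalars is a threshold cut, found deterministically by a prefix-
sum scan — no random restarts needed). Component 1 is identified as the
cluster holding the majority of the pre-relabeling $\beta_1$ draws, which
makes the operation the identity on chains that never switched, and each
iteration then assigns the draw nearer each center to that component,
swapping $\tau^2$ and indicator labels in tandem; ties keep the original
labels. The operation is idempotent and conserves the pooled multiset of
draws. Whether the reference analysis pooled draws or clustered
iteration pairs is not stated; pooling is consistent with its reported
cluster counts and is what we implement.

## Comparators

* `ivw()`: fixed-effect, first-order weights, no overdispersion scaling —
  deliberately the naive estimator whose failures motivate the method.
* `mr_aps()`: joint maximization of the profile likelihood in
  $(\beta, \tau^2 \ge 0)$ (L-BFGS-B from the IVW and null starts, with a
  Nelder–Mead fallback on $(\beta, \sqrt{\tau^2})$), Wald interval from
  the observed information in $\beta$ at the optimum.
* `mr_raps()`: robustified profile score with Huber (tuning 1.345,
  default) or Tukey (4.685) $\psi$, solved by alternating a bracketed
  root search in $\beta$ with the moment condition
  $\mathrm{mean}_j\,\psi(t_j)^2 = E[\psi(Z)^2]$ for $\tau^2$; sandwich
  standard error with standard-normal moments. Which loss produced the
  published comparator columns is unstated; Huber is the default.

One benchmark row deserves comment: the published coverage of the L2
profile-score estimator under 100% balanced pleiotropy (70.4%) is far
below what any internally consistent variance formula yields for this
estimator (we measure ~92% with $\tau^2$ estimated and ~81–85% with
$\tau^2 \equiv 0$, against 85.4% for IVW in the same table). The
published collapse is consistent with a global-search optimizer
occasionally settling on spurious roots of the multimodal profile score —
the very identifiability failure that motivates model averaging — and is
not reconstructible from formulas alone. We report what our estimator
computes.

## The synthetic-data generator

`generate_dataset()` simulates directly at the summary level from the
model above, with $\gamma_j = \delta_j + \kappa_x\psi_j$ and
$\alpha_j = \upsilon_j + \kappa_y\psi_j$ ($\kappa_x = \kappa_y = 1$), so
a shared $\psi_j$ component produces InSIDE violation. The six presets
encode the benchmark study conditions: 50 SNPs, $\beta = 0.05$,
$\delta_j \sim U(0.34, 1.1)$; invalid SNPs draw
$\alpha_j \sim N(\mu_\alpha, \mathrm{SD}\ 0.04)$ with $\mu_\alpha = 0$
(balanced) or $0.05$ (directional); the two-cluster scenarios give S2
SNPs $\psi_j \sim U(0.34, 1.1)$ with $\delta_j = \upsilon_j = 0$, so
their Wald ratios identify $\beta + 1$. Exposure-side standard errors
are $U(0.06, 0.095)$ for mean F $\approx 100$ and $U(0.06, 0.4)$ for
mean F $\approx 25$; those two ranges and the outcome-side
$\sigma_{Yj} \sim U(0.03, 0.06)$ reproduce the published mean-F,
heterogeneity (mean exact Q $\approx 49$ at the null) and
weak-instrument-bias levels, while the weak-instrument range
$U(0.06, 0.95)$ (mean F $\approx 10$) is a calibrated reconstruction —
the source's exact choices are not in its main text. Invalid SNPs are
placed at uniformly random positions; estimators are permutation
invariant, and the labels feed the PPI-discrimination analysis. A
pluggable `alpha_rng` hook supports non-normal pleiotropy studies.

What the generator does *not* emulate: LD between instruments, sample
overlap between the two GWAS, allele-harmonization errors, effect-size–
dependent standard errors (winner's curse), or binary-outcome log-odds
scales. Passing benchmarks therefore certifies the estimators under the
stated sampling model, not robustness to those real-data features.

## Monte-Carlo harness and problem sizes

`run_mc_study()` repeats generate → fit → summarize with replicate
seeds `master + 1000 r`, so every estimator sees identical data streams
and results are bit-reproducible. Bias and coverage are measured for the
posterior mean and equal-tailed 95% credible interval (quantile, not
HPD — the convention the coverage benchmarks are stated against). The
package's own evaluation runs use 1000 replicates for the closed-form
estimators and a scaled-down Bayesian design of 200 replicates at 20000
iterations (5000 burn-in) — one-fifth of the reference design in both
chain length and replication, chosen so a full table row reproduces in
minutes on one core; the published protocol (1000 × 50000/10000) is a
flag away. The widened Monte-Carlo error this implies is reflected in
the test tolerances (±4 coverage points for sampler rows vs ±3 for
closed-form rows).

## Numerical choices and edge cases

* The exact heterogeneity statistic `exact_q()` is minimized by golden-
  section/parabolic search (`stats::optimize`, tolerance 1e-10) started
  at the IVW estimate with bounds $\pm(10|\hat\beta_{IVW}|+1)$, widening
  on bracket-edge hits; the objective flattens at $\sum_j F_j$ for
  $|\beta| \to \infty$, so an unbracketed minimum is an error, not a
  silent boundary value.
* `dl_tau2()` truncates at zero (it equals zero whenever the first-order
  Q is below $k-1$) and requires $k \ge 2$; inside the sampler the
  minimum-instrument rule keeps it defined, and an emptied component in
  the two-slope model uses $\tau^2 = 0$.
* Wald ratios and IVW refuse $\hat\gamma_j = 0$ by name; the likelihood
  itself needs no such guard.
* Equal-tailed intervals use type-7 quantiles; ties in the relabeling
  distance rule keep original labels.
* `read_summary_table()` accepts tab- or comma-separated files in three
  header dialects (or an explicit column map), parses numerics strictly
  (a bad cell reports its row), rejects missing values — the model has
  no missing-data mechanism — and the writer emits 17-significant-digit
  TSV so round-trips preserve doubles.

## Known limitations

Correlated instruments, overlapping samples, multivariable exposures and
more than two slope components are out of scope. The full-Bayes
two-component sampler mixes noticeably worse than the plug-in variant at
unbalanced cluster sizes (as its reference behavior also shows); the
plug-in variant is the default and the one the acceptance benchmarks
exercise. The Geweke flag at $|z| > 2.5$ is conservative on slowly
mixing indicator chains and excludes some healthy runs (7–30% at the
scaled-down design, vs ~1% non-convergence reported for the full
design); excluded counts are always reported alongside the aggregates.
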