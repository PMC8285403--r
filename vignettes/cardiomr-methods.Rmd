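---
title: "Methods: two-sample Mendelian randomization in cardiomr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in cardiomr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomr)
```

## The model

Mendelian randomization (MR) uses genetic variants as instrumental variables
to estimate the causal effect of an exposure (here, cardioembolic risk
factors such as atrial fibrillation liability, myocardial-infarction
liability or resting heart rate) on an outcome (ischemic stroke and its
TOAST subtypes) from GWAS summary statistics alone. For variant $j$, let
$\hat\gamma_j$ (se $\sigma_{Xj}$) be its estimated per-allele effect on the
exposure in one cohort and $\hat\Gamma_j$ (se $\sigma_{Yj}$) its estimated
effect on the outcome (log-odds) in an independent cohort. If the variant is
a valid instrument — associated with the exposure, independent of
confounders, and affecting the outcome only through the exposure — then
$\Gamma_j = \beta\,\gamma_j$ and every ratio $\hat\Gamma_j/\hat\gamma_j$
estimates the same causal log-odds $\beta$.

The package estimates $\beta$ four ways:

* **IVW**: $\hat\beta = \sum_j w_j \hat\gamma_j \hat\Gamma_j \big/ \sum_j
  w_j \hat\gamma_j^2$ with $w_j = 1/\sigma_{Yj}^2$, i.e. weighted
  through-origin regression of outcome on exposure effects. The
  fixed-effect standard error is $(\sum_j w_j\hat\gamma_j^2)^{-1/2}$; the
  default multiplicative random-effects model inflates it by
  $\max\!\left(1, \sqrt{Q/(k-1)}\right)$, where $Q$ is the weighted residual
  sum of squares, so heterogeneity can widen but never narrow the interval.
* **MR-Egger**: the same regression with a free intercept, after recoding
  alleles so all $\hat\gamma_j \ge 0$. Under the InSIDE assumption the slope
  remains a consistent causal estimate when pleiotropy is directional, and
  the intercept estimates the average direct (pleiotropic) effect; its
  two-sided $t_{k-2}$ test is the directional-pleiotropy diagnostic.
  Standard errors use the same $\max(1,\cdot)$ residual inflation.
* **Weighted and simple median**: the (weighted) median of the per-variant
  ratios, interpolating between order statistics at standardized cumulative
  weight $1/2$ (weights $\hat\gamma_j^2/\sigma_{Yj}^2$, or equal). The
  weighted median is consistent while valid instruments carry more than half
  the weight. Standard errors come from a parametric bootstrap: exposure and
  outcome effects are redrawn from $N(\hat\gamma_j, \sigma_{Xj}^2)$ and
  $N(\hat\Gamma_j, \sigma_{Yj}^2)$ and the estimator recomputed; the
  bootstrap standard deviation is the reported se.

Instrument strength is screened per variant with $F_j =
(\hat\gamma_j/\sigma_{Xj})^2 > 10$ and summarised for the set by
$F = \frac{r^2}{1-r^2}\cdot\frac{n-k-1}{k}$, with $r^2$ the exposure
variance explained. Power for a binary outcome uses the normal
approximation with noncentrality $|\ln \mathrm{OR}|\sqrt{n\,r^2\,cf(1-cf)}$
($cf$ the case fraction), which returns exactly $\alpha$ at the null OR.

## Pipeline and tunable parameters

1. `select_instruments()` keeps genome-wide-significant variants
   ($p < 5\times10^{-8}$, strict).
2. `ld_prune()` clumps greedily at $r^2 < 0.01$: candidates sorted by
   ascending p (ties by variant id), the best survivor discards everything
   linked to it. Variants absent from the LD reference count as independent
   unless `strict = TRUE`.
3. `substitute_proxies()` replaces instruments missing from the outcome
   study by the outcome-present variant with the highest $r^2$ strictly
   above 0.9 (ties: smaller exposure p, then lexicographic id).
4. `harmonize()` expresses both studies on the exposure's effect allele:
   swapped allele labels negate the outcome beta; palindromic (A/T, C/G)
   pairs are oriented by allele frequency under the default
   `infer_by_eaf` policy and dropped when either frequency lies in
   $0.5 \pm 0.08$ (the `eaf_ambiguity_band`) or is missing. The band
   default reflects common MR practice: within it, sampling noise in
   frequencies can no longer distinguish strands reliably. Proxy rows skip
   cross-variant allele matching (phase information is out of scope) and
   carry `proxy_id` and $r^2$ as provenance.
5. Estimation (`mr_ivw()`, `mr_egger()`, `mr_median()`, or all via
   `mr_estimates()`), then `leave_one_out()` (IVW on each $k-1$ subset,
   flagging variants whose omission moves the association across the
   significance boundary) and `pleiotropy_report()`.
6. `bonferroni_threshold()`/`classify_estimates()` classify each
   association as significant ($p <$ corrected threshold; $0.05/35 \approx
   0.00142$ for a 7-exposure $\times$ 5-outcome grid), suggestive
   (corrected threshold $\le p < 0.05$) or null, and `compile_report()`
   assembles a deterministic, order-independent results bundle with odds
   ratios per a configurable number of exposure units (e.g. per 10 units
   for continuous ECG traits; per 1 log-odds unit for binary exposures,
   where a 10-unit contrast would not be interpretable).

## The synthetic-data generator

`generate_dataset()` simulates the summary statistics directly — no
individual-level genotypes — because the analysis consumes nothing else and
desk-scale runtimes matter. Defaults mirror a well-powered atrial
fibrillation → cardioembolic stroke analysis: exposure GWAS of 65,556 with
$k = 100$ variants jointly explaining $r^2 = 0.15$ of a standardized
exposure; binary outcome GWAS of 463,456 at case fraction 9006/463,456;
true causal effect 0.2 on the log-odds scale.

Per variant: MAF uniform in (0.05, 0.5); true exposure effects positive with
magnitudes $\propto U(0.5, 1.5)$, exactly rescaled so
$\sum_j 2p_j(1-p_j)\gamma_j^2$ meets the target $r^2$ (`realized_r2()`
verifies this to $10^{-10}$). Effects are positive by the convention that
the effect allele is the exposure-increasing allele, as published
instrument tables are oriented; this also makes "directional" pleiotropy
well-defined under the Egger recode. The uniform magnitude floor reflects
that genome-wide-significant instruments have effects bounded away from
zero. Direct effects $\alpha_j$ are zero, $N(0,\sigma^2)$ (balanced) or
$N(\mu,\sigma^2)$ (directional), optionally restricted to a random
`pleiotropy_fraction` of variants; $\Gamma_j = \beta\gamma_j + \alpha_j$.
Sampling noise follows $\sigma^2 = 1/(2np(1-p))$ per study (divided by
$cf(1-cf)$ for a binary outcome). The outcome file swaps allele labels and
negates betas for 30% of variants and 15% of variants are palindromic, so
harmonization is exercised on every run; the LD reference is block-diagonal.
Everything is a pure function of the seed.

What the generator does **not** emulate: winner's curse in instrument
selection, sample overlap between cohorts, allele-frequency differences
between ancestries, true strand-flip errors (label swaps only), multi-allelic
sites, and nonlinear exposure–outcome relationships. Passing tests therefore
certify the estimators and plumbing under the stated statistical model, not
robustness to those real-data pathologies.

## Simulation studies and their sizes

Four replicated studies (exported as `study_*()`) back the package's
statistical claims; sizes were chosen to keep the full suite in a few
minutes on one core:

* `study_coverage()` — 500 replicates, $k = 100$, no pleiotropy,
  $\beta = 0.2$, 300 bootstrap draws per median: 95% interval coverage per
  estimator.
* `study_egger_calibration()` — 1000 null replicates for the intercept
  test's type-I error; 200 replicates with $\mu = 0.02$ injected for
  recovery. These use an exposure GWAS of 500,000 so instrument effects are
  essentially noise-free and the test is assessed under its own
  assumptions; with noisier exposure effects, regression dilution leaks
  into the intercept and inflates the test slightly.
* `study_median_robustness()` — 200 replicates, 30% of instruments given
  directional pleiotropy ($\mu = 0.02$, sd $\mu/2$) against a continuous
  outcome, so per-variant ratios are precise and the IVW-vs-median contrast
  is attributable to the estimators rather than to noise.
* `study_power_mc()` — 2000 replicates at $n = 50{,}000$, case fraction
  0.1, $r^2 = 0.05$, OR 1.2, $k = 20$: empirical IVW rejection rate versus
  the analytic formula.

The studies bypass the allele-encoding layer (swap/palindromic fractions 0,
harmonized table assembled directly); encoding round-trips are covered by
their own tests.

## Numerical choices and known limitations

* **Random-effects floor.** Both IVW (random) and Egger floor the residual
  inflation at 1, the convention of the standard MR toolchain: observed
  underdispersion never narrows intervals. The measurable cost is a mildly
  conservative Egger intercept test (type-I error near 4% rather than 5%).
* **Median bootstrap conservatism.** Re-noising already-noisy effects
  flattens the ratio density at the median, so the bootstrap se
  overestimates the sampling sd by roughly 10–20% when instruments are
  homogeneous; median intervals then overcover (about 98% instead of 95% in
  the coverage study). This is a property of the standard procedure itself,
  kept deliberately; interpret median CIs as conservative.
* **First-order weighting.** IVW/median weights ignore $\sigma_{Xj}$ (the
  usual first-order convention); with strong instruments (per-variant
  $F \approx 100$ in the defaults) the neglected term is negligible, but
  with weak instruments the estimators inherit the usual regression-dilution
  bias. No Steiger filtering, modal estimators, MR-PRESSO or Cochran's Q
  reporting is included; $Q$ appears only inside the random-effects
  inflation.
* **p-value floor.** Wald p-values are floored at the smallest normalized
  double so extremely strong associations remain representable in (0, 1]
  across file round-trips.
* **Ties and determinism.** All orderings that could be ambiguous
  (LD-pruning ties, proxy ties, report row order) have stated tie-breaks,
  so identical inputs — in any row order — give byte-identical reports; the
  median bootstrap requires an explicit seed and leaves the caller's RNG
  state untouched.
* **Degenerate inputs.** Zero exposure effects are rejected where a ratio
  is undefined (Wald, medians) or unidentifiable (all-equal Egger designs);
  missing outcome rows, allele mismatches and unorientable palindromes are
  logged per variant rather than fatal.

## A worked run

```{r example, eval = FALSE}
sim <- generate_dataset(sim_config(n_variants = 80, seed = 2024))
instruments <- sim$exposure |>
  select_instruments(p_threshold = 5e-8) |>
  ld_prune(sim$ld, r2_threshold = 0.01)
h <- harmonize(instruments, sim$outcome,
               exposure_label = "AF", outcome_label = "CES")
est <- mr_estimates(h, seed = 1)
verdicts <- classify_estimates(est, threshold = bonferroni_threshold(7, 5))
compile_report(verdicts)
```

The README shows this run's printed output; `autoplot()` methods provide
the scatter, forest and leave-one-out views of the same objects.
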