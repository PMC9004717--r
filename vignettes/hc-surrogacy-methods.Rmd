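---
title: "Havrda-Charvat entropy surrogacy measures: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Havrda-Charvat entropy surrogacy measures: models, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcsurrogacy)
```

## The problem

A surrogate endpoint $S$ (a biomarker that is cheaper, earlier, or
repeatable) stands in for a true clinical endpoint $T$ in a trial with
treatment indicator $Z$. The information-theoretic view of surrogacy asks:
how much uncertainty about $T$ is removed by knowing $S$? With mutual
information $I(T,S)$, the information-theoretic measure of association
(ITMA)

$$R^2 = 1 - e^{-2 I(T,S)} \in [0, 1)$$

is zero exactly under independence, symmetric, and invariant to bijective
recodings. Shannon entropy, however, does not exist for every
distribution: `solve_heavy_tail_constants()` builds a valid density (a
standard normal core with a $c_2/(|x| (\log|x|)^2)$ tail, $c_1 \approx
1.44$, $c_2 \approx 0.027$) whose differential Shannon entropy is
infinite. The Havrda-Charvat (H-C) family

$$HC_\alpha(X) = \int \varphi_\alpha(f(x))\, f(x)\,dx, \qquad
  \varphi_\alpha(x) = \frac{x^{\alpha-1} - 1}{1 - \alpha}\ (\alpha \neq 1),
  \quad \varphi_1(x) = -\log x,$$

always exists for $\alpha > 1$ whenever the density is bounded, and
recovers Shannon entropy as $\alpha \to 1$. It is non-additive: for
independent $T, S$, $HC_\alpha(T,S) = HC_\alpha(T) + HC_\alpha(S) +
(1-\alpha) HC_\alpha(T) HC_\alpha(S)$. The order-$\alpha$ mutual
information is defined by the same combination with the true joint entropy
subtracted, and the order-$\alpha$ ITMA is $R^2_\alpha = 1 - e^{-2
I_\alpha}$.

## Closed forms

Three parametric families have closed forms in this package.

**Gaussian pair** (`gaussian_mutual_info`). For a bivariate normal with
correlation $\rho$,

$$I_\alpha = \frac{(2\pi\sigma_T\sigma_S)^{1-\alpha}}{\alpha(1-\alpha)}
 \left[1 - (1-\rho^2)^{(1-\alpha)/2}\right] \ (\alpha \neq 1), \qquad
 I_1 = -\tfrac12\log(1-\rho^2).$$

Away from $\alpha = 1$ the value depends on the scale prefactor
$(2\pi\sigma_T\sigma_S)^{1-\alpha}$, not only on $\rho$; only the exponent
$(1-\alpha)/2$ on $(1-\rho^2)$ is compatible with the $\alpha \to 1$
limit, which fixes the formula unambiguously. For $\alpha < 1$ the
information is bounded by the supremum
$(2\pi\sigma_T\sigma_S)^{1-\alpha}/(\alpha(1-\alpha))$ attained as
$|\rho| \to 1$. That supremum equals 1 only for particular $\sigma$
values, so the package normalizes the $\alpha<1$ ITMA by the ITMA at the
*computed* supremum — this always lands in $[0,1]$, reaches 1 at perfect
correlation, and reduces to dividing by $1 - e^{-2}$ exactly when the
supremum is 1.

**Binary pair** (`binary_mutual_info`). For a $2\times2$ table,
$I_\alpha = \frac{1}{1-\alpha}\sum_{t,s}\{p_{t+}^\alpha p_{+s}^\alpha -
p_{ts}^\alpha\}$, with the exact $p\log p$ decomposition at $\alpha=1$.
Cells are reconstructed from margins and the point correlation $\rho$
(`binary_table_from_margins_rho`), whose admissible range is determined by
cell non-negativity (`binary_rho_bounds`). Two facts about this family
deserve emphasis because they are easy to get wrong:

* For fixed margins the information is maximised at one of the two
  admissible boundaries of $\rho$ (`binary_mi_max`). The boundary is
  selected by evaluating both; a derivative sign test degenerates under
  symmetric margins, and evaluating two closed forms costs nothing.
* Away from $\alpha = 1$ the non-additive information is **not
  sign-definite**: discordant tables (implied $\rho < 0$, e.g. cells
  $(0.1, 0.2, 0.3, 0.4)$ at $\alpha = 2$) give slightly negative values,
  even though independence gives exactly zero. For $\alpha > 1$ the
  information is capped by $\min(HC_\alpha(T), HC_\alpha(S))$; no
  analogous lower bound by the marginal entropies exists for $\alpha < 1$
  (independence is already a counterexample). `binary_mutual_info`
  returns negative values as computed — a negative ITMA reads as "no
  positive association" — while the Gaussian and probit families, which
  are provably non-negative, treat anything below $-10^{-12}$ as an
  internal error.

**Latent-probit pair** (`probit_mutual_info`). A binary endpoint defined
by thresholding a latent normal $U \sim N(\Phi^{-1}(p_1), 1)$ correlated
(with coefficient $\rho$) with a Gaussian surrogate. The closed form runs
through the Gaussian-weighted CDF-power integral
$\Im_\alpha(a,b) = \int \Phi^\alpha(a+by)\phi(y)\,dy$
(`imath_integral`). At $\alpha = 2$ it collapses to an Owen's-T
expression (`probit_mi_alpha2_owen`), which doubles as an analytic
cross-check of the quadrature to about $10^{-14}$. At $|\rho| = 1$ the
Shannon information diverges while $\alpha \neq 1$ converges to a finite
limit (`probit_mi_rho_limit`); the boundary gap closes like
$\sqrt{1-\rho^2}$.

## The longitudinal pipeline

For a trial with a repeatedly measured surrogate (visit weeks $t_0 = 0 <
t_1 < \dots$) and one binary endpoint per subject, two quantities are
computed per visit-schedule design:

**Trial-level surrogacy** $I_\alpha(T, S \mid Z)$
(`arm_conditional_mi`): within each arm, the surrogate vector is reduced
to a scalar index and scored with the probit closed form, then arms are
averaged with empirical weights. The reduction
(`single_index_reduction`) is the design choice that deserves scrutiny: a
probit fit of $T$ on the surrogate vector gives the fitted index $V =
\hat\gamma' S$; because a linear combination of jointly normal
measurements is normal, $(T, V)$ is itself a latent-probit pair, and the
probit slope $b$ on the standardized index identifies the latent
correlation $\hat\rho = b/\sqrt{1+b^2}$, with $(\mu_S, \sigma_S)$ the raw
moments of $V$ and $p_1$ the arm's endpoint rate. This is the unique
single-index Gaussian latent model consistent with the fitted probit.
Whether the analysis of record used this reduction or a full multivariate
latent model is not determinable from the outside; the reduction is
labelled as such everywhere.

**Prentice check** $I_\alpha(T, Z \mid S)$ (`prentice_conditional_mi`): a
valid surrogate makes $Z \to S \to T$ Markov, so treatment and endpoint
should be conditionally independent given the trajectory. A bivariate
probit of $(T, Z)$ on the surrogate vector supplies conditional margins
and cells; the outer expectation over $S$ is taken as the empirical mean
over observed trajectories — the natural numerical integration against
the empirical law of $S$, avoiding a parametric model for the surrogate
distribution. "Approximately zero" is calibrated by a permutation null
(`prentice_permutation_null`): the endpoint is permuted within arm, which
preserves arm sizes and arm-specific endpoint rates while severing the
surrogate-endpoint link. The default is 200 permutations under a fixed
seed.

Subjects missing any visit of a design are dropped from that design's fit
(complete case, with counts reported); no imputation is attempted.
Reports (`design_sweep`, `write_report`) render 4 decimals in text and
keep full (`%.17g`) precision in CSV so that re-reading reproduces values
exactly.

## The synthetic trial generator

`generate_trial` simulates the structure the pipeline expects:

* surrogate trajectories $S_{ij} = \mu_S + \alpha_1 Z_i + \alpha_2 t_j +
  \alpha_3 Z_i t_j + \beta_j T_i + \epsilon_{S,ij}$ with
  compound-symmetry residual correlation (a single parameter; nothing in
  the target data structure identifies a richer covariance, and one
  parameter is enough to exercise every code path);
* a latent-probit endpoint $T_i = 1\{a_0 + a_1 Z_i + a_2 X_i + e_i \ge
  0\}$, where $X_i$ is the standardized subject-level mean of the
  pre-endpoint trajectory. This makes the generator an exact member of
  the latent-probit family, so population information values are
  computable and convergence of the plug-in pipeline can be tested
  against truth. `generate_markov_trial` sets $a_1 = 0$, making the
  surrogate a perfect mediator by construction.

Defaults emulate a two-arm progressive multiple-sclerosis imaging trial:
104/99 subjects, visits at weeks 0/24/48/72/96, a brain-parenchymal-
fraction-like surrogate (mean 0.8023, SD 0.0301, small negative slopes of
$-0.0008$ and $-0.0004$ per 24 weeks), endpoint response rates near 48%
and 71% ($a_0 = -0.112$, $a_1 = 1.35$, $a_2 = 2$ give
$\Phi(a_0/\sqrt{1+a_2^2}) \approx 0.48$ and
$\Phi((a_0+a_1)/\sqrt{1+a_2^2}) \approx 0.71$), and within-subject
correlation 0.9 — a calibration choice, since repeated MRI-derived
fractions are very strongly tracked within subject, but not a quantity
recoverable from published summaries. What the generator does **not**
emulate: dropout and intermittent missingness, measurement-batch effects,
non-Gaussian tails in the biomarker, and site heterogeneity. Tests
passing on this generator therefore certify the estimators under the
stated parametric conditions, not robustness to those real-data features.

## Numerical choices

* **Shannon branch routing.** Orders with $|\alpha - 1| < 10^{-8}$ use
  the exact Shannon formulas (with a message); the generic branch loses
  all significant digits to cancellation there. Continuity at the switch
  is tested at $|\alpha - 1| = 10^{-4}$ with absolute tolerance
  $10^{-4}$.
* **$\Im_\alpha$ quadrature.** Adaptive quadrature (absolute tolerance
  $10^{-13}$) rather than a fixed Gauss-Hermite rule: $\Phi^\alpha(a+by)$
  contributes its own Gaussian-like factor on a scale set by $b$, and a
  128-node Hermite rule leaves errors near $10^{-4}$ for $\alpha < 1$,
  $|b| > 2$ — far above the $10^{-10}$ target that the Owen's-T identity
  shows is attainable.
* **Owen's T and the bivariate normal CDF.** $T(h,k)$ is evaluated by
  48-node Gauss-Legendre on its defining integral after folding
  $|k| \le 1$ with the classical reduction identity; agreement with
  adaptive quadrature is at machine precision. $\Phi_2$ is assembled from
  Owen's T with the standard sign rules, special-casing $h = k = 0$ and
  $|\rho| \to 1$.
* **Divergence detection.** Continuous entropies over infinite supports
  are accumulated over truncations $[-M, M]$ with doubling $M$; if the
  total still changes by more than a relative $10^{-3}$ per doubling at
  $M = 2^{20}$, the integral is declared divergent (`Inf` with a
  `divergent` attribute). The Shannon integral of the heavy-tail density
  diverges like $c_2 \log\log M$ — slowly enough that no fixed
  truncation "looks infinite", which is why the plateau test, not a
  magnitude threshold, is the right runtime criterion.
* **Bivariate probit.** The likelihood (cells from $\Phi_2$, floored at
  $10^{-300}$) is maximised by BFGS with its analytic gradient over
  $(\beta_T, \beta_Z, \mathrm{atanh}\,\rho)$, started from the univariate
  fits with $\rho = 0$, then polished with up to 10 Newton steps — BFGS
  terminates on function change and can leave a residual gradient when
  predictors are badly scaled (biomarker SDs of 0.03 produce coefficients
  in the hundreds). Up to 3 jittered restarts; non-convergence is an
  error carrying the best log-likelihood. Standard errors come from the
  numerically differentiated Hessian of the polished solution, with a
  delta-method transform for $\rho$.
* **Degenerate inputs.** One-class outcomes, rank-deficient designs and
  perfectly separated probits raise errors naming the offending
  predictor; a constant fitted index (all-zero coefficients) falls back
  to $\rho = 0$; table constructions clamp roundoff-scale negatives and
  renormalize.

## Problem sizes used by the test suite

Monte-Carlo oracle comparisons use $10^6$ draws per setting with
batch-means standard errors (20 batches), five parameter settings per
family at $\alpha \in \{0.5, 2\}$. Longitudinal checks run at roughly 200
subjects with 200 within-arm permutations; parameter-recovery checks use
20 replicates at $n = 5000$. These sizes give the oracle standard errors
(about $10^{-3}$) and permutation resolution (5% tail of 200) that the
assertions actually need; convergence-to-truth checks run at
$n \in \{500, 2000, 8000\}$.

## Known limitations

Single-trial surrogacy only — no meta-analytic (multi-trial) extension,
no time-to-event endpoints, no causal-estimand (principal surrogacy)
framing. The Prentice measure inherits the bivariate probit's parametric
assumptions; a misspecified index model biases both measures. The
$\alpha < 1$ normalization is a package convention (documented above)
wherever the literature's fixed $1 - e^{-2}$ cap conflicts with
scale-dependent suprema. ITMA values reported for designs are raw
$R^2_\alpha$; normalized variants are available from the closed-form
layer but are intentionally not the default in reports, where
cross-design comparison at fixed $\alpha$ is the use case.
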