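---
title: "Methods: separating total and direct effects with two-sample MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separating total and direct effects with two-sample MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mrdirect)
library(dplyr)
```

## The problem

Observational studies link childhood adiposity to later-life colorectal
cancer, but children with large body size usually remain large as
adults, so the observational signal cannot say whether early-life body
size matters *per se* or only through its persistence into adulthood.
Two-sample Mendelian randomization (MR) attacks this with germline
variants as instruments: SNP–exposure associations $\hat\gamma_j$ (per
body-size category) from one GWAS, SNP–outcome associations
$\hat\Gamma_j$ (log odds of colorectal cancer) from an independent
case–control GWAS. Univariable MR estimates the **total** effect of one
exposure; multivariable MR (MVMR) jointly instruments early-life and
adult body size and estimates each exposure's **direct** effect
conditional on the other. If the early-life total effect is positive but
its direct effect vanishes once adult body size enters the model, the
early-life association is mediated by adult body size — the package
exists to make that comparison, with its diagnostics, reproducible.

## Estimators

All estimators consume a `harmonized_set`: SNP-aligned
$(\hat\gamma_{1j}, \hat\gamma_{2j}, \hat\Gamma_j)$ with standard errors,
everything expressed on a shared effect allele per SNP.

**IVW.** With weights $w_j = 1/\sigma^2_{Yj}$,
$$\hat\theta_{IVW} = \frac{\sum_j w_j \hat\gamma_j \hat\Gamma_j}
{\sum_j w_j \hat\gamma_j^2},$$
the weighted regression of $\hat\Gamma$ on $\hat\gamma$ through the
origin. The fixed-effect SE is $(\sum_j w_j\hat\gamma_j^2)^{-1/2}$.
Cochran's $Q=\sum_j w_j(\hat\Gamma_j-\hat\theta\hat\gamma_j)^2$ on
$L-1$ df measures heterogeneity; in the multiplicative random-effects
model the SE is inflated by $\max(1,\sqrt{Q/(L-1)})$. `mode = "auto"`
(the default) uses the random-effects SE when the $Q$ test rejects at
p < 0.05. The source analysis states the fixed-to-random switch rule
without a numeric threshold; 0.05 is this package's choice, and the
point estimate is identical either way.

**MR-Egger.** The same regression with a free intercept, after
orienting every record so $\hat\gamma_j > 0$ (Egger fits are not
orientation-invariant; the positive-exposure-beta convention is the
standard one and matches common implementations). The intercept
estimates the average directional pleiotropic effect; its test is the
directional-pleiotropy diagnostic. Residual $Q$ has $L-2$ df and feeds
the same multiplicative SE inflation.

**Weighted median.** Per-SNP ratios $\hat\theta_j=\hat\Gamma_j/
\hat\gamma_j$ with weights $(\hat\gamma_j/\sigma_{Yj})^2$, sorted; the
estimate interpolates the cumulative-weight polyline at probability
one half, and is consistent while valid instruments carry more than
half the weight. The SE is a parametric bootstrap — betas resampled
from $N(\hat\beta, se)$ — with `n_boot = 1000` by default and a
**mandatory seed**; the source analysis does not state its replicate
count or variance method, so the bootstrap (the common choice for this
estimator) is used and made reproducible by construction.

**MVMR.** Weighted least squares of $\hat\Gamma_j$ on
$(\hat\gamma_{1j},\hat\gamma_{2j})$ with no intercept and weights
$w_j$; coefficients are direct effects. SEs are inflated by
$\max(1,\sqrt{RSS_w/(L-2)})$, keeping the univariable convention.
`mvmr_egger()` adds the intercept (df $L-3$).

P-values are two-sided normal throughout — the large-$L$ summary-data
convention — and intervals are $\hat\theta \pm z_{1-\alpha/2}\,se$,
exponentiated for the odds-ratio scale.

## Instrument-strength diagnostics

Univariable strength uses $F = R^2(N-2)/(1-R^2)$ per instrument, with
the conventional weak-instrument flag at $F<10$. When per-SNP $R^2$ is
not supplied it is approximated by $2\,\mathrm{eaf}(1-\mathrm{eaf})
\hat\beta^2/\mathrm{var}(trait)$; whether the source analysis used
source-GWAS $R^2$ or this approximation is unstated, so the
approximation is the fallback, never a silent override of user input.

Conditional strength for exposure 1 given exposure 2 minimizes
$$Q_{x1}(\delta)=\sum_j \frac{(\hat\gamma_{1j}-\delta\hat\gamma_{2j})^2}
{\sigma^2_{x1j}+\delta^2\sigma^2_{x2j}-2\delta c_j}$$
over the nuisance slope $\delta$, and reports
$F_{cond}=Q_{x1}(\hat\delta)/(L-1)$. Numerically this is bounded scalar
minimization on $[-100, 100]$ with tolerance $10^{-8}$, verified against
a dense grid search in the tests. One genuine design decision hides
here: when the other exposure carries no signal
($\hat\gamma_{2}\approx 0$), $Q_{x1}$ has no interior minimum — growing
$|\delta|$ only inflates the denominator, and the "minimum" runs to the
search boundary with $Q\to 0$, which is statistical nonsense. The
package detects boundary solutions and falls back to the
inverse-variance projection slope of $\hat\gamma_1$ on $\hat\gamma_2$
(zero for a null second exposure), recovering the unconditional mean
chi-squared in the degenerate case and leaving interior minima
untouched.

The per-SNP covariance $c_j$ between the two exposures' betas defaults
to 0. Both body-size exposures come from the same sample, so a nonzero
covariance is plausible; the source analysis states no correction, so
the default is none, and `conditional_strength(cov_correlation = r)`
populates $c_j = r\,\sigma_{x1j}\sigma_{x2j}$ for sensitivity analysis.
The reported conditional F of about 8 for early-life body size in men
may depend on that unstated treatment, which is why the option exists
but is off.

Pleiotropy in the multivariable model is measured by
$$Q_a=\sum_j\frac{(\hat\Gamma_j-\hat\theta_1\hat\gamma_{1j}
-\hat\theta_2\hat\gamma_{2j})^2}
{\sigma^2_{Yj}+\hat\theta_1^2\sigma^2_{x1j}
+\hat\theta_2^2\sigma^2_{x2j}}
\;\sim\;\chi^2_{L-2}.$$

## Harmonization

SNPs are matched by rsid only (the motivating tables are rsid-keyed).
Records are aligned to the first exposure's effect allele; a table
reporting the swapped allele pair has its beta sign flipped and its
effect-allele frequency complemented; irreconcilable pairs are dropped
with a reason code kept in the `dropped` attribute. All GWAS are
assumed coded on the forward strand, so palindromic (A/T, C/G) SNPs are
*not* dropped and allele frequency is not used to infer strand — that
matches the stated processing of the motivating analysis. Because
forward-strand coding is an assumption, a strict mode
(`strict_palindromes = TRUE`) drops palindromic SNPs whose exposure
frequency is missing or in (0.42, 0.58); it is off by default:
fidelity first, safety switch second.

Multivariable instruments are the union of the two exposures'
instruments, optionally LD-pruned against a user-supplied r² matrix:
SNP pairs above the threshold (default r² = 0.001) are resolved
greedily in order of increasing exposure p-value. The package never
computes LD itself — post-clumping instruments are treated as
independent.

## Power

A priori power for a binary outcome uses the two-stage normal
approximation
$$z=|\log OR|\sqrt{N R^2 K(1-K)},\qquad
\text{power}=\Phi(z - z_{1-\alpha/2}),$$
with $N$ the outcome sample, $K$ the case fraction and $R^2$ the
instrumented exposure variance (unit-variance exposure scale). The
motivating analysis cites an online calculator rather than a formula;
formula variants differ negligibly at these sample sizes, and the
package grounds its choice in simulation: `mr_power_empirical()`
simulates the outcome sample at the individual level — genotypes, a
unit-variance exposure with the requested $R^2$, a logistic outcome —
runs each replicate through `mr_ivw()`, and reports the rejection
rate. Per-SNP log-odds betas in that oracle come from
linear-probability regressions rescaled by $1/(K(1-K))$; at per-SNP
effects this small the equivalence with logistic fits is exact to well
below Monte-Carlo resolution, and it keeps 2,000 replicates inside a
desk-scale budget. With the printed case/control counts
(52,775 / 45,940) the formula gives 88.7% power at OR 1.10 for
$R^2=0.045$ and 92.7% at OR 1.09 for $R^2=0.064$, consistent with the
published ">80%" statements. `min_detectable_or()` inverts the formula
by bisection to $10^{-6}$.

## The synthetic-data generator

`simulate_mr_summary()` emulates the statistical structure the
estimators assume, with defaults pinned to the motivating study design:

| parameter | default | meaning |
|---|---|---|
| `n_snps` | 300 | instrument size (305 and 557 in the source instruments) |
| `rho` | 0.61 | correlation of true per-SNP effects on the two exposures |
| `r2_target_1`, `r2_target_2` | 0.045, 0.064 | instrumented variance per exposure |
| `n_exposure_gwas` | 453,169 | exposure GWAS size (drives $\sigma_{xj}$) |
| `n_cases`, `n_controls` | 52,775 / 45,940 | outcome sample (drives $\sigma_{Yj}$) |
| `theta1`, `theta2` | 0, log 1.3 | true direct log-odds effects per category |
| `pleio_mean`, `pleio_sd` | 0, 0 | per-SNP direct outcome effects |

True effects $(g_{1j}, g_{2j})$ are bivariate normal with correlation
`rho`, each column rescaled so $\sum_j 2p_j(1-p_j)g_j^2$ hits its
variance target exactly; outcome truth is
$\theta_1 g_{1j}+\theta_2 g_{2j}+\text{pleio}_j$; observed betas add
Normal noise with $se_{xj}=(2p_j(1-p_j)N_x)^{-1/2}$ and
$se_{Yj}=\sqrt{(1/n_{cases}+1/n_{controls})/(2p_j(1-p_j))}$, the
standard case–control log-odds approximation shared with the power
module. Emitted tables follow the canonical TSV schema with the effect
allele oriented to increase exposure 1; the truth table keeps the
orientation sign so that unfolded true effects retain their generated
joint distribution. Identical config and seed give byte-identical
output.

`simulate_mr_individual()` is the slow oracle path: genotypes
$\mathrm{Bin}(2, p_j)$, latent continuous traits cut into three ordered
categories at the 25th/75th latent percentiles (a dominant middle
group; the real category proportions of the motivating cohort are not
published, so these placeholders are configurable), a logistic outcome,
and per-SNP GWAS regressions. GWAS on the category scale attenuates
per-allele betas by the category-on-latent projection slope; causal
estimates are per category on both paths, so the two paths agree on
$\theta$ — an equality the tests exercise.

What the generator does **not** emulate: LD between instruments
(instruments are independent by construction, as after clumping),
sample overlap between exposure and outcome GWAS, allele-frequency
differences between the two samples, recall bias in the self-reported
childhood exposure, and population stratification. Passing tests
therefore demonstrate correctness of the estimators under the model's
own assumptions, not robustness of the scientific conclusion to those
real-data threats.

## Calibration checks and problem sizes

The test suite ties everything together at sizes chosen to keep a full
run in a few minutes on one CPU:

- estimator exactness against `lm()`-based normal-equation oracles,
  polyline evaluation, and dense $\delta$ grid search on 50 random
  instances with $L \in \{3,\dots,30\}$ (tolerance $10^{-10}$; $10^{-3}$
  for the grid);
- the headline attenuation scenario — true early-life direct effect 0,
  adult direct effect $\log 1.3$, $\rho = 0.61$, 300 SNPs, study-scale
  SEs, 200 replicates: the univariable early-life estimate is reliably
  positive (the mediated total effect) while the MVMR direct effect is
  statistically indistinguishable from 0 and the adult direct effect
  recovers $\log 1.3$, with 95% CI coverage inside [0.92, 0.98];
- diagnostic calibration at $\alpha=0.05$ over 1,000 replicates, each
  statistic under *its own* null: the Egger intercept test under
  balanced pleiotropy (`pleio_mean = 0`, `pleio_sd = 0.01` — pleiotropy
  present but non-directional, which is exactly what the intercept
  tests), and $Q_a$ under no pleiotropy (any pleiotropy, balanced or
  not, is a genuine $Q_a$ alternative, so calibrating it under balanced
  pleiotropy would conflate size with power);
- the analytic power formula against the individual-level oracle at
  10,000/10,000 and $R^2=0.02$, 2,000 replicates, agreement within
  0.03.

The full reproduction of the published odds ratios needs the per-SNP
supplementary tables of the source publication, which have no public
accession and are not redistributed here; `reproduce_study()` runs that
pipeline when pointed at user-exported TSVs, and the corresponding
acceptance test reports the gap honestly when the tables are absent.

## Degenerate inputs and numerical conventions

Zero exposure betas abort ratio-based estimators; all-equal exposure
betas abort Egger (degenerate design); rank-deficient two-exposure
designs abort MVMR with an explicit error, and grid runs convert such
per-cell errors into a failure table instead of aborting the study.
Weighted-median interpolation clamps at the extreme ratios when the
midpoint falls outside the polyline. Ties in LD pruning are broken by
rsid for determinism. No multiple-testing adjustment is applied
anywhere, matching the motivating analysis, which reports unadjusted
estimates and flags the multiplicity caveat in its discussion.

## A worked run

```{r example}
study <- simulate_mr_summary(sim_config(seed = 2024))
hs_uv <- harmonize(study$exposure1, study$outcome)
mr_ivw(hs_uv)

hs_mv <- harmonize(study$exposure1, study$outcome,
                   exposure2 = study$exposure2)
mvmr_ivw(hs_mv)
conditional_strength(hs_mv)
```

The univariable estimate is clearly positive although the simulated
direct early-life effect is zero — the total effect inherited through
the correlated adult exposure — and the multivariable fit attributes
the signal to the adult exposure, which is the methodological point of
the whole design. (With equal exposure-side standard errors the two
conditional F statistics coincide exactly: substituting
$\delta \to 1/\delta$ maps one objective onto the other.)

## Limitations

Only two simultaneous exposures are supported; there is no MR-PRESSO,
mode-based estimation, leave-one-out, or Steiger filtering (none were
part of the motivating analysis); LD matrices must be supplied, never
computed; and the weighted-median SE is bootstrap-only. The
individual-level simulator caps itself at $10^6$ individuals and
refuses genotype matrices beyond a memory guard — it is an oracle, not
a cohort simulator.
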