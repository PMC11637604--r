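---
title: "Partitioning dyadic mating behaviour into direct and indirect genetic effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning dyadic mating behaviour into direct and indirect genetic effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igemate)
```

## The model

When a behaviour is expressed inside a male-female dyad, its phenotypic
variance carries contributions from both participants. For a male-expressed
trait (say, latency to start courtship song) scored in a trial pairing male
$m$ with female $f$:

$$
y_{mf} = \mathbf{x}'\boldsymbol\beta
  + a_m + a'_f + p_m + p'_f + \varepsilon_{mf},
$$

where $a_m$ is the male's **direct genetic effect** (DGE, variance
$V_{Am}$), $a'_f$ the female partner's **indirect genetic effect** (IGE,
variance $V_{Af}$) — the heritable component of her influence on his
behaviour, i.e. her *attractiveness* at the genetic level —
$p_m$ and $p'_f$ the corresponding permanent-environment effects
($V_{PEm}$, $V_{PEf}$), and $\varepsilon$ the trial residual ($V_R$).
Female-expressed traits swap the roles. The joint vector of direct and
indirect breeding values over all pedigree members is multivariate normal
with covariance $\mathbf{G}_0 \otimes \mathbf{A}$, where $\mathbf{A}$ is the
numerator relationship matrix of the paternal half-sib pedigree and
$\mathbf{G}_0$ holds the channel (co)variances, including
$\mathrm{COV}_{Am,Af}$.

Because a dyad has group size $n = 2$, the variance in *total breeding
value* — what selection on the social phenotype can act on — is

$$
V_{TBV} = V_{Am} + V_{Af} + 2\,\mathrm{COV}_{Am,Af},
$$

implemented in `total_heritable_variance()`. At the genetic level the
responsiveness matrix linking partner traits to focal expression is
$\boldsymbol\Psi = \mathbf{C}_{ID}\,\mathbf{G}_D^{-1}$
(`psi_matrix()`), the product of the IGE-DGE covariance block and the
inverse of the DGE block.

Morphological traits (body mass, mandible size, testis size) are modelled
without indirect channels: a partner cannot influence a dissected
morphology. Once-measured traits (mandible, testis) additionally carry no
permanent-environment channel — with a single record per individual a PE
variance is not separable from the residual.

All traits are z-transformed before partitioning so components are
comparable across traits; the two latencies are reverse-scored (multiplied
by $-1$) so that larger values mean greater motivation or attractiveness.
Variances are invariant to the sign flip; covariances between a latency
channel and any other channel change sign with it.

## Estimation

`fit()` maximises the restricted likelihood (REML) of the variance
components over a dense phenotypic covariance
$\mathbf{V} = \sum_{cd} g_{cd}\, \mathbf{Z}_c \mathbf{A} \mathbf{Z}_d' +
\sum_c \sigma^2_{PE,c}\, \mathbf{Z}_c\mathbf{Z}_c' + \mathbf{R}$.
The likelihood convention is the error-contrast (orthonormal null-space
basis) log density, so the value is invariant to the fixed-effect basis and
to translations $y \mapsto y + X c$; this is tested against an
independently coded error-contrast oracle.

Numerical choices:

* **Parameterisation.** Variances are optimised on the log scale (floored
  at $10^{-9}$, which is also the boundary-flag threshold region), each
  free genetic covariance as a correlation-scale coefficient
  $z_{ij} = g_{ij}/\sqrt{g_{ii}g_{jj}}$ boxed to $[-1, 1]$, with an
  eigenvalue penalty keeping the full correlation block positive
  semidefinite when more than two channels are active. We chose this over
  a Cholesky factorisation because the significance machinery must pin
  *individual* covariances to exactly zero (a constraint with no sparse
  representation in a Cholesky factor), and because $z$ *is* the genetic
  correlation, so its curvature-based standard error is directly the SE
  reported for $r$.
* **Search.** A Nelder-Mead warm start from the first starting point,
  followed by a bounded quasi-Newton (PORT) polish; additional restarts are
  seed-jittered and go straight to the quasi-Newton stage. The best
  restricted likelihood wins. Convergence: relative likelihood change
  below $10^{-10}$. On a balanced paternal half-sib design this reproduces
  the closed-form ANOVA estimator $\hat\sigma^2_A = 4\hat\sigma^2_{sire}$
  to $10^{-6}$.
* **Constrained fits.** A variance constrained to zero removes its channel
  (and all covariances touching it) from the parameterisation; a pinned
  covariance fixes $z_{ij} = 0$. Warm starts from the parent fit keep the
  nesting inequality $\ell_{reduced} \le \ell_{full}$; if optimiser noise
  ever reverses it, the full model is refit from the reduced solution
  before the test statistic is formed.
* **Standard errors** come from the observed curvature (numerical Hessian)
  at the optimum, delta-mapped to the natural scale. Parameters pinned at a
  box bound carry no curvature information and give `NA` SEs; correlations
  whose parent variances are boundary-pinned are reported as `NA` with a
  flag rather than a number.

## Significance machinery

Variances live on the boundary of the parameter space, so removing one is
tested against the 50:50 mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$:
$p = \tfrac12 P(\chi^2_1 \ge \mathrm{LRT})$ for a positive statistic and
$p = 0.5$ at exactly zero (the $\chi^2_0$ component is a point mass, handled
with strict inequality). Covariances and correlations are interior
parameters and use a plain $\chi^2_1$. No multiple-testing correction is
applied anywhere: the analysis trades Type I for Type II error control
deliberately, and corrected and uncorrected users can apply their own
adjustment to the reported p-values.

Two subtleties matter for calibration experiments. First, in the full
dyadic model the direct-indirect covariance $\mathrm{COV}_{Am,Af}$ is
estimated; dropping the indirect *channel* then removes **two** parameters
(the variance and the covariance), and the null distribution of the
statistic is closer to $\tfrac12\chi^2_1 + \tfrac12\chi^2_2$ than to the
1-df mixture — judged against the 1-df mixture such a test rejects a true
null at roughly three times the nominal rate. The package's calibration
experiment therefore pins the covariance in both models so that exactly
one boundary parameter is removed, which is the situation the mixture
convention is built for; the reported pipeline keeps the covariance in the
model and tests it separately with its own 1-df chi-square.

Second, the 50:50 mixture is itself an asymptotic result that assumes many
independent replicates of the random structure. A pedigree couples every
individual into a single correlated system, and the indirect variance is
informed mainly by the between-family resemblance of partners most of whom
appear in a single assay. In our simulations the machinery reproduces the
textbook behaviour exactly where theory says it should — testing one
additive variance on a balanced half-sib design gives a point mass of
$\approx 0.5$ at zero and nominal-level rejections — while the same test
for an *indirect* variance at reduced scales (6 and 8 sires, and a
variant that keeps all 66 families but thins offspring within them)
rejects a true null at roughly 9% rather than 5%, insensitively to how the
design is scaled down, with almost no point mass at zero. Users testing
IGE variances on designs of this size should read p-values near the 0.05
boundary with that inflation in mind, or calibrate by simulation with the
tools in this package.

## The synthetic-data generator

`study_scale_preset()` encodes the study design the analysis is meant for:
35 sires each mated to 2 dams, a 5.7% family failure rate leaving about 66
full-sib families, 16 offspring per surviving family, and a female-biased
tested sex ratio (70.7% female) so that roughly 310 males and 747 females
are phenotyped across 826 sequential assays — each male meeting 1-3
distinct unmated females, one per day, with partner reuse only after the
female pool is exhausted. Per-male trial counts are drawn from
probabilities $(0.06, 0.215, 0.725)$ for 1, 2, 3 trials (mean 2.66) and
then minimally adjusted to land exactly on the target assay count.

Genetic defaults place $V_{Am} = 0.15$, $V_{Af} = 0.10$,
$\mathrm{COV}_{Am,Af} = 0.05$ on each latency trait (so $V_{TBV} = 0.35$),
$V_{PE} = 0.10$ per behavioural channel, residuals $0.60$, strong direct
variance in morphology (0.30-0.40), and **zero** additive variance in
guarding distance — emulating a trait whose genetic components are null, so
that correlation estimates involving it are reported as `NA` with a flag.

Traits are simulated directly on the z-score scale: the analysis operates
on standardised scores, so the generative scale is the analysis scale and
no raw-latency back-transformation is modelled. Censoring (trials in which
singing or mounting never happens) is not simulated; every trait value is
observed. Residuals are independent across traits by default, with an
option to couple the residuals of behaviours scored on the same trial.
These are the main senses in which passing parameter-recovery tests speaks
to the estimator, not to every feature of real trial data: real latencies
are censored, non-Gaussian before transformation, and their residuals are
likely trial-correlated.

Scale choices for the validation experiments (problem sizes picked once,
as a balance between Monte-Carlo resolution and the cost of replicate REML
fits): parameter recovery runs 30 replicates of a 15-sire version of the
design (~354 assays each); the LRT calibration runs 200 null and 60 power
replicates of an 8-sire version (~189 assays); the acceptance script uses
12 recovery and 60/40 calibration replicates at the same scales.

## Pair selection and reporting

`fit_univariate()` partitions each trait and tests every genetic variance
(mixture convention) and the direct-indirect covariance ($\chi^2_1$).
`select_pairs()` then gates the bivariate suite: under the default
`significant_both` policy a declared channel pair enters bivariate estimation
only if *both* member channels showed a significant additive variance at
$\alpha = 0.05$ univariately; traits with all-zero or constrained genetic
variance (guarding, under the preset) can never enter a pair.
`fit_bivariate_pair()` fits the intercept-only two-trait animal model
(fixed effects beyond intercepts are dropped in bivariate fits to ease
convergence of the constrained refits), reports
$r = g_{ij}/\sqrt{g_{ii}g_{jj}}$ with its curvature SE, and tests the focal
covariance by pinning it. The cross-trait residual covariance is estimated
only when the two traits are scored on the same trials; for a behaviour
paired with a dissected morphology it is structurally zero.

## Known limitations

* Female permanent environment is weakly identified under the study
  design: most females serve in a single assay, so $V_{PEf}$ separates
  from $V_R$ only through the ~10% of reused females. Its estimates are
  correspondingly noisy, and slices of variance can drift between the two
  components in any single fit.
* Dense linear algebra bounds practical model sizes to a few thousand
  records; the sparse inverse-relationship path is provided but the mixed
  model equations are not.
* Bivariate fits with several channels near their boundaries can be
  multimodal at small sample sizes; the restart machinery mitigates but
  does not eliminate this, which is why non-converged pairs are reported
  flagged rather than silently dropped.
* Only bivariate (not higher-dimensional) genetic fits are supported; a
  full correlation table is assembled pair by pair.
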