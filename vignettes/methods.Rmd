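---
title: "Variance-components heritability and test-retest reliability of bilateral morphometric traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-components heritability and test-retest reliability of bilateral morphometric traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`sulcherit` implements the statistical pipeline used to characterize
brain sulcal shape descriptors (length, mean depth, width, surface area,
measured per hemisphere) in family-based cohorts: test-retest
reliability, pedigree-based heritability, and the cross-hemisphere
genetic architecture of homologous left/right trait pairs. Because the
MRI cohorts this kind of study draws on are access-restricted, the
package ships a synthetic cohort generator with known generative truth;
every stage of the pipeline is exercised end to end against that truth.

## The quantitative genetic model

For a trait vector $y$ measured on $n$ individuals with expected additive
relationship matrix $K = 2\Phi$ (twice the kinship matrix), the
univariate polygenic AE model is

$$ y = X\beta + g + e, \qquad
   \mathrm{Cov}(g) = K\sigma_g^2, \qquad \mathrm{Cov}(e) = I\sigma_e^2, $$

and narrow-sense heritability is $h^2 = \sigma_g^2 / \sigma_p^2$ with
$\sigma_p^2 = \sigma_g^2 + \sigma_e^2$. MZ twins share all additive
genetic influences — their entry in $K$ equals the diagonal — while DZ
twins and full siblings share one half on expectation ($K_{ij} = 0.5$).
There is no shared-environment (C) component: the model is additive
genetic plus unique environment plus fixed covariates.

**Kinship.** $\Phi$ is computed by the recursive tabular method over a
topological order of each connected pedigree component
($\phi_{ii} = \tfrac12(1+\phi_{fm})$,
$\phi_{ij} = \tfrac12(\phi_{f(i)j}+\phi_{m(i)j})$), which is exact for
arbitrary extended pedigrees including inbreeding. MZ twin groups are
handled by overriding within-group pairwise kinship with the
self-kinship value after the recursion. An independent gene-dropping
Monte Carlo oracle (Mendelian sampling of founder alleles) cross-checks
the recursion in the tests; it is an oracle only and never feeds the
fits. The model is autosomal; sex is carried as a covariate, not used
for X-linked kinship.

**Estimation.** Fitting is maximum likelihood (not REML), matching the
convention of pedigree packages whose likelihood-ratio tests the field
reports. Each connected pedigree component is rotated into the
eigenbasis of its relationship block, after which the covariance
$\sigma_p^2\{h^2 K + (1-h^2)I\}$ is diagonal with weights
$h^2 d_i + (1-h^2)$; a likelihood evaluation is $O(n)$ after a one-off
per-family eigendecomposition (cubic per family, never per cohort).
$\beta$ and $\sigma_p^2$ have closed-form profile estimates at each
candidate $h^2$, so the fit reduces to a one-dimensional search on
$[0,1]$, done with golden-section/parabolic bracketing to a relative
tolerance of $10^{-9}$ (a bracketing method is more robust here than the
multi-start quasi-Newton a multi-parameter problem would need). The
boundary null $h^2 = 0$ uses the 50:50 mixture of $\chi^2_0$ and
$\chi^2_1$, i.e. $p = \tfrac12 P(\chi^2_1 > \Lambda)$ and $p = 1$ when
$\Lambda \le 0$. The SE of $h^2$ comes from the numerical curvature of
the profile log-likelihood, stepped inward at the boundary; simulated
95% Wald coverage on twin cohorts sits inside [0.92, 0.98].

**Bivariate model.** For homologous left/right traits the genetic and
environmental cross-covariances are parameterized by correlations
$\rho_G$ and $\rho_E$:

$$ \mathrm{Cov}\!\begin{pmatrix} y_L \\ y_R \end{pmatrix} =
   \begin{pmatrix}
   K\sigma_{gL}^2 + I\sigma_{eL}^2 &
   K\rho_G\sigma_{gL}\sigma_{gR} + I\rho_E\sigma_{eL}\sigma_{eR} \\
   \cdot & K\sigma_{gR}^2 + I\sigma_{eR}^2
   \end{pmatrix} $$

In the same per-family eigenbasis this factorizes into $n$ independent
$2\times2$ blocks, one per eigenvalue, with both mean vectors profiled
out by GLS. The six free parameters
$(h^2_L, h^2_R, \log\sigma^2_{pL}, \log\sigma^2_{pR}, \rho_G, \rho_E)$
are maximized by box-constrained quasi-Newton (L-BFGS-B) from three
deterministic moment-based starts; whenever a constrained refit beats
the free fit, the free fit is restarted from the constrained solution.
The implied phenotypic correlation is reported through the invariant
$\rho_P = \rho_G\sqrt{h^2_Lh^2_R} + \rho_E\sqrt{(1-h^2_L)(1-h^2_R)}$,
with the sample Pearson correlation of the OLS-residualized traits
alongside.

Two tests accompany $\rho_G$: against 0 (interior null, $\chi^2_1$) and
against 1 (complete pleiotropy; boundary null $\tfrac12\chi^2_1$,
calibrated by simulation in the tests — empirical size at $\alpha=0.05$
stays at or below 0.07). A Wald $z$-test of $\rho_G$ against 0 is
reported as a secondary statistic. The genetic variance of the
laterality difference $L-R$,
$\sigma_g^2(L)+\sigma_g^2(R)-2\rho_g\sqrt{\sigma_g^2(L)\sigma_g^2(R)}$,
is exposed as a formula because incomplete overlap ($\rho_G<1$) and
unequal per-side variances are confounded in it; the difference trait is
used only as a test oracle, never as a user-facing analysis.

Measurement error, being uncorrelated between relatives, loads on the
environmental component: it depresses $h^2$, $\rho_E$ and $\rho_P$ but
not the maximum-likelihood $\rho_G$ estimate. This is a model property,
and the test suite verifies it by refitting simulated cohorts after
adding noise of variance $0.5\sigma_p^2$.

**Missing data.** Fits are complete-case: a subject missing the trait or
any design column is dropped, and the bivariate fit requires both traits
on the overlapping subject set. The per-family eigen-rotation that makes
the fits fast assumes both traits share the rotated coordinates, which
is why an unbalanced (one-trait-observed) bivariate likelihood is not
offered; at the missingness levels the QC stage produces (a few percent)
the efficiency loss is negligible.

## Reliability

With $k$ exchangeable scan sessions per subject the population target is
$\mathrm{ICC} = \sigma^2_{BS} / (\sigma^2_{BS} + \sigma^2_{WS})$,
estimated by the one-way random-effects ANOVA form ICC(1,1)
$= (\mathrm{MSB}-\mathrm{MSW})/(\mathrm{MSB}+(k-1)\mathrm{MSW})$, with
$p$ from $F = \mathrm{MSB}/\mathrm{MSW}$ on $(n-1, n(k-1))$ df. The
one-way variant is the right one because sessions are unordered repeats,
not fixed raters. Negative ANOVA estimates are reported as-is, not
truncated, but carry no weight in the meta-analysis. The SE follows the
convention $\mathrm{SE} = \mathrm{ICC}/Z$ with
$Z = \Phi^{-1}(1-p/2)$; entries with $p = 1$ or non-positive ICC are
excluded from meta-analysis with a warning. Classification bands: below
0.4 "poor", 0.4 to 0.75 "fair to good" (lower-inclusive at 0.4), 0.75
and above "excellent".

Percent bias per subject is
$b = 100\,(\mathrm{test}-\mathrm{retest})/\{(\mathrm{test}+\mathrm{retest})/2\}$;
the per-trait summary is the mean of $|b|$ (the formula itself is
signed, and the signed values feed the Bland-Altman analysis, whose
limits of agreement are the mean difference $\pm 1.96$ SD). Bias values
above 10 percent are conventionally flagged as high; the threshold is a
configurable convention, not a model quantity.

Cross-cohort ICC synthesis weights by $\mathrm{SE}^{-2}$ and is reported
only when the trait was estimable in at least 3/4 of the cohorts
(`ceiling(0.75 * n_cohorts)`); with four cohorts that means at least
three. ICC is computed on raw within-cohort session values, not
covariate-adjusted ones.

## Cross-cohort synthesis

*Meta-analysis of $h^2$* is the fixed-effect inverse-variance mean
$\sum_j se_j^{-2} h^2_j / \sum_j se_j^{-2}$ with combined SE
$(\sum_j se_j^{-2})^{-1/2}$. *Meta-analysis of $\rho_G$* weights by
cohort sample size, $\sum_j N_j \rho_{G_j} / \sum_j N_j$; this weighting
has no analytic combined SE, so the sample-size-weighted mean of the
per-cohort SEs is reported as an approximate spread. Combined p-values
use Edgington's additive method, the Irwin-Hall tail
$P(\sum_i U_i \le S) = \sum_{j=0}^{\lfloor S\rfloor}
(-1)^j \binom{k}{j} (S-j)^k / k!$ with $S = \sum_i p_i$ — a compromise
between methods dominated by the smallest p-value (Fisher) and by the
largest (Pearson). It is validated against a Monte Carlo uniform-sum
oracle in the tests. Applying Edgington to both the heritability and the
correlation p-value profiles keeps the two syntheses consistent; the
choice is recorded in the output metadata.

*Mega-analysis* pools subject-level data instead: each cohort's traits
are residualized on its own covariate design, rank-inverse-normal
transformed within cohort (so cohorts with different scanners and age
structures land on a common N(0,1) scale — variance-components LRTs
assume normality), concatenated under a union pedigree with no
cross-cohort genetic links, and fitted with an intercept-only design
(the covariates having been removed within cohort). Profile agreement
between meta- and mega-analysis is summarized by Pearson correlation.

Bonferroni thresholds are $0.05/(m \times 4)$ with $m = 61$ bilateral
sulci (or $m = 123$ for separate hemispheres) in the nomenclature of the
sulcal atlas; the synthetic workflows use the generated trait counts.

*Gate ordering.* The bivariate analysis set is the intersection of two
gates applied after QC: meta-analyzed ICC above 0.75 ("good"
reliability; applied only when reliability input exists) and
Bonferroni-significant univariate meta heritability on both hemispheres.
The workflow asserts the resulting set is exactly that intersection.

## Quality control

Within each cohort, hemisphere and sulcus, z-scores are computed across
subjects for each descriptor; a subject with $|z| > 2.5$ for *any*
descriptor loses *all four* descriptors of that sulcus, so missingness
is aligned across descriptors of a unit. The filter runs once, not
iterated — repeated application would converge to a trimmed sample with
a different, unintended breakdown point. Z-scoring is done within
cohort because sites differ in scanner and age structure. Bilateral
averaging $(L+R)/2$ (missing if either side is missing) happens after
filtering and before covariate adjustment. The covariate set is
intracranial volume, sex, age, age², age×sex and age²×sex; age is
centered before squaring and before forming interactions to reduce
collinearity, and constant or rank-deficient columns (e.g. sex in a
single-sex cohort) are dropped with a warning.

## The synthetic cohort generator

`simulate_pedigree()` builds twin cohorts (MZ/DZ pairs with parents and
optional extra siblings; MZ status random with configurable probability,
or deterministic when an exact zygosity split is wanted), sib-pair
families, three-generation extended pedigrees (defaults: 71 families of
mean size 15, the scale of published extended-pedigree cohorts), and
unrelated samples. `simulate_traits()` draws genetic values per family
block from $N(0, \sigma_g^2 K_b)$ — MZ members receive identical values
because their relationship entries equal the diagonal — with bilateral
pairs drawn from the Kronecker covariance
$\mathrm{kron}(G, K_b)$, $G$ the $2\times2$ genetic covariance implied
by $\rho_G$. Covariates are drawn from plausible ranges (age uniform in
a configurable window, ICV normal around $1.5\times10^6$ mm³) and
retest sessions add independent Gaussian noise, the simplest structure
consistent with the one-way ICC model. All randomness flows from the
single config seed; identical configs give byte-identical tables.

What the generator does **not** emulate: non-Gaussian trait
distributions, shared (household) environment, genotype data, realistic
sulcal geometry, scanner batch effects beyond a per-cohort scale, or
session noise that correlates with trait level. Passing tests therefore
demonstrate the estimators are correct under the model the analysis
assumes, not that the model captures every property of real MRI-derived
measurements.

## Numerical choices and problem sizes

- Univariate search tolerance $10^{-9}$ on $[0,1]$; candidate boundary
  values 0 and 1 are always compared against the interior optimum.
- Bivariate box constraints keep $|\rho| \le 1 - 10^{-6}$ during free
  optimization (constrained refits pin $\rho_G$ exactly to 0 or 1);
  exactly collinear trait pairs drive the likelihood along a singular
  ridge, and the fit then reports the boundary estimate with
  $p_{\rho_G=1} = 1$.
- Relatedness matrices are validated PSD per family block to $10^{-8}$;
  external matrices are symmetrized and flagged when the smallest
  eigenvalue is below $-10^{-6}$.
- The test suite runs its simulation checks at the designs they
  describe (e.g. 500 MZ + 500 DZ pairs with 200 replicates for
  univariate recovery; 1000 twin pairs with 200 replicates for
  bivariate recovery; 150 replicates for the $\rho_G=1$ size check; 60
  replicates at 1500 pairs for power; 3 cohorts × 20 traits for the
  end-to-end closure), sizes chosen so the whole suite completes in
  minutes on a single core while leaving every tolerance with a
  comfortable margin over its Monte Carlo error.
- The ML-vs-Falconer consistency check compares the replicate means:
  the per-replicate difference between the efficient ML estimator and
  the classical $2(r_{MZ}-r_{DZ})$ oracle has sampling SD ≈ 0.08 at 500
  pairs per zygosity (Falconer's noise is dominated by the DZ
  correlation), so only the means are comparable at the 0.05 level.

## Known limitations

- No shared-environment or dominance components; heritability estimates
  from twin-only samples absorb any common-environment variance into
  $\sigma_g^2$.
- The bivariate likelihood is complete-case (see above).
- The sample-size-weighted $\rho_G$ meta-analysis reports only an
  approximate SE.
- Standard errors at parameter boundaries ($\hat h^2 \in \{0, 1\}$,
  $|\hat\rho_G| \to 1$) are one-sided approximations and flagged.
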