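# sulcherit

Reliability and pedigree-based heritability of paired bilateral
morphometric traits.

## The problem

Cortical sulcal shape descriptors — length, mean depth, width and
surface area of each labeled fold, per hemisphere — are candidate
imaging phenotypes for genetic studies. Before a descriptor is worth
mapping, two questions must be answered: *is it measured reliably*
(does a repeat scan give the same number?) and *is it heritable* (does
genetic relatedness predict phenotypic similarity?). A third question
follows for bilateral traits: *do the left and right homologs share the
same genetic influences*, or are there lateralized genetic effects?

`sulcherit` implements the full statistical pipeline for these
questions as used with twin and extended-pedigree cohorts:

- **Kinship**: expected additive relationship matrices (2Φ) from
  SOLAR-style or .fam-style pedigrees via the recursive tabular method,
  with monozygotic-twin groups made genetically identical; an
  independent gene-dropping Monte Carlo oracle for validation; ingestion
  of precomputed (e.g. genomic) relatedness matrices.
- **QC**: per-sulcus |z| > 2.5 outlier removal (a subject flagged for
  any descriptor loses all descriptors of that sulcus), bilateral
  averaging, covariate designs (ICV, sex, age, age², age×sex, age²×sex),
  and within-cohort residualization + rank-inverse-normal transform for
  pooled analysis.
- **Univariate genetics**: maximum-likelihood AE polygenic model;
  h² = σ²g/σ²p with profile-likelihood SEs and the boundary LRT
  (½χ²₁) against h² = 0; per-family eigendecomposition so cost is cubic
  per family, not per cohort; Falconer's 2(r_MZ − r_DZ) as a test
  oracle.
- **Bivariate genetics**: joint left/right AE model partitioning the
  phenotypic correlation as
  ρP = ρG·√(h²L·h²R) + ρE·√((1−h²L)(1−h²R)), with LRTs of ρG = 0 and of
  complete pleiotropy ρG = 1, and the genetic variance of the
  laterality difference L−R.
- **Reliability**: one-way ICC(1,1) = (MSB−MSW)/(MSB+(k−1)MSW)
  targeting σ²BS/(σ²BS+σ²WS), percent bias
  b = 100·(test−retest)/((test+retest)/2), Bland–Altman limits of
  agreement, poor/fair-to-good/excellent bands at 0.4 and 0.75, and
  SE-weighted meta-ICC with the ≥3/4-cohorts rule.
- **Synthesis**: inverse-variance meta-analysis of h², sample-size
  weighted meta-analysis of ρG, Edgington's additive combined p-value,
  pooled-pedigree mega-analysis, Bonferroni thresholds
  0.05/(m×4), and meta-vs-mega profile correlation.
- **Synthetic cohorts**: a generator for twin / sib-pair /
  extended-pedigree / unrelated designs with known h², ρG, ρE,
  covariate effects and test-retest session noise, so the whole
  pipeline is testable end to end without restricted MRI data.

## Worked example

```r
library(sulcherit)

cfg <- sim_config(seed = 7, design = "mz_dz_twins", n_families = 500,
                  true_h2 = 0.5, true_rhoG = 0.9, true_rhoE = 0.3,
                  bilateral = TRUE, mz_exact = TRUE)
ped <- simulate_pedigree(cfg)     # 250 MZ + 250 DZ twin pairs (+ sibs)
K   <- compute_kinship(ped)       # expected additive relationship, 2*phi
tab <- simulate_traits(ped, cfg, K = K)

yL <- setNames(tab[["sulcus01|left|length"]],  tab$subject_id)
yR <- setNames(tab[["sulcus01|right|length"]], tab$subject_id)

fit_univariate(yL, K = K)
#> Univariate AE variance-components fit
#>   n = 1047, h2 = 0.4708 (SE 0.0447), p[h2=0] = 3.85e-19
#>   sigma_g2 = 0.4406, sigma_e2 = 0.4952, logLik = -1410.382

fit_bivariate(yL, yR, K = K)
#> Bivariate AE variance-components fit
#>   n = 1047, h2_L = 0.473, h2_R = 0.507
#>   rhoG = 0.934 (SE 0.044), rhoE = 0.271, rhoP = 0.595
#>   p[rhoG=0] = 7.06e-28, p[rhoG=1] = 0.071
```

The univariate fit recovers the generative h² = 0.5 (0.47 ± 0.04) and
rejects h² = 0 decisively. The bivariate fit recovers the
cross-hemisphere genetic correlation (0.93 against a truth of 0.9):
ρG differs sharply from 0 (shared genetic influences) but not from 1 at
the 5% level (no evidence for lateralized genetic effects at this
sample size — as expected, since the truth is close to 1).

Cross-cohort synthesis uses the printed weighting formulas exactly:

```r
meta_h2(c(0.4, 0.2), se = c(0.1, 0.2))$value   # inverse-variance mean
#> [1] 0.36
edgington_combine(c(0.1, 0.2, 0.3))            # P(U1+U2+U3 <= 0.6)
#> [1] 0.036
```

## The analysis workflow

The `analysis/` scripts run the two studies over synthetic cohorts that
mirror the scale of published family-based morphometry samples (two
twin cohorts of ~450 and ~350 families, one extended-pedigree cohort of
71 families of mean size 15; four test-retest cohorts of 20–35 subjects
with two sessions; 20 bilateral traits with heritabilities from 0.1 to
0.7 and ρG = 0.9):

```sh
Rscript analysis/01_simulate_cohorts.R   # writes results/cohorts/
Rscript analysis/02_reliability.R        # per-cohort ICC/bias + meta-ICC
Rscript analysis/03_heritability.R       # per-cohort h2, meta, mega, rhoG
```

Each stage prints what it found and writes its tables under `results/`.
On the default configuration the reliability stage reports a meta-ICC
interquartile range of [0.50, 0.82] with the estimated profile tracking
the generative one at r = 0.95, and the heritability stage reports
meta- and mega-analysis profiles correlating with the generative truth
at r = 0.99 and with each other at r = 1.00, with the bivariate
analysis set restricted to the sulci passing both the ICC > 0.75 and
bilateral Bonferroni-significance gates.

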