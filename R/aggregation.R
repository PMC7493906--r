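#' Inverse-variance meta-analysis of heritability
#'
#' Fixed-effect weighted mean of per-cohort heritability estimates with
#' weights se^-2; the combined SE is (sum of weights)^-1/2.
#'
#' @param h2 Numeric vector of per-cohort heritability estimates.
#' @param se Positive per-cohort standard errors.
#' @return List with `value`, `se`, `n_cohorts_used`, `method`.
#' @export
meta_h2 <- function(h2, se) {
  if (!length(h2)) stop("no estimates supplied")
  if (length(h2) != length(se)) stop("h2 and se must align")
  if (any(!is.finite(se)) || any(se <= 0)) stop("all se must be positive")
  w <- se^-2
  list(value = sum(w * h2) / sum(w),
       se = sum(w)^-0.5,
       n_cohorts_used = length(h2),
       method = "inverse_variance_se")
}

#' Sample-size-weighted meta-analysis of genetic correlation
#'
#' Weighted mean of per-cohort genetic correlations with weights equal to
#' cohort sample size. No analytic combined SE exists for this weighting;
#' the sample-size-weighted SE of the inputs is reported as an approximate
#' spread when per-cohort SEs are supplied.
#'
#' @param rhoG Numeric vector of per-cohort genetic correlations.
#' @param n_sub Cohort sample sizes (>= 1).
#' @param se Optional per-cohort SEs for the approximate combined SE.
#' @return List with `value`, `se` (approximate, possibly NA),
#'   `n_cohorts_used`, `method`.
#' @export
meta_rhoG <- function(rhoG, n_sub, se = NULL) {
  if (!length(rhoG)) stop("no estimates supplied")
  if (length(rhoG) != length(n_sub)) stop("rhoG and n_sub must align")
  if (any(n_sub < 1)) stop("all n_sub must be >= 1")
  w <- n_sub / sum(n_sub)
  se_out <- if (!is.null(se)) sum(w * se) else NA_real_
  list(value = sum(w * rhoG),
       se = se_out,
       n_cohorts_used = length(rhoG),
       method = "sample_size_weighted")
}

#' Edgington's additive combined p-value
#'
#' Combines k independent p-values through the distribution of their sum:
#' with S = sum(p) the combined value is
#' P(U1 + ... + Uk <= S) = sum_{j=0}^{floor(S)} (-1)^j C(k,j) (S-j)^k / k!
#' for independent uniforms (the Irwin-Hall CDF). The method weighs large
#' and small p-values more evenly than Fisher's or Pearson's.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Combined p-value in [0, 1].
#' @export
edgington_combine <- function(pvalues) {
  if (!length(pvalues)) stop("no p-values supplied")
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  k <- length(pvalues)
  s <- sum(pvalues)
  j <- 0:floor(s)
  j <- j[s - j > 0]
  if (!length(j)) return(0)
  # factorials on the log scale to stay finite for large k
  terms <- (-1)^j * exp(lchoose(k, j) + k * log(s - j) - lfactorial(k))
  p <- sum(terms)
  min(max(p, 0), 1)
}

#' Pooled-pedigree mega-analysis of heritability
#'
#' Adjusts each cohort for its covariates, rank-normalizes within cohort,
#' concatenates the cohorts into one sample with a union pedigree (no
#' cross-cohort genetic links), and fits the univariate AE model per trait
#' on the pooled data with an intercept-only design (covariates having been
#' removed within cohort).
#'
#' @param tabs List of per-cohort `phenotype_table`s.
#' @param peds List of per-cohort [pedigree]s (same order).
#' @param covariates Covariate set for within-cohort adjustment.
#' @param traits Trait columns to fit (default: all shared trait columns).
#' @return Data frame with one row per trait: `trait`, `n`, `h2`, `se`,
#'   `p`, `loglik`, `converged`.
#' @export
mega_fit <- function(tabs, peds,
                     covariates = c("icv", "sex", "age", "age2", "agexsex",
                                    "age2xsex"),
                     traits = NULL) {
  stopifnot(length(tabs) == length(peds))
  ids <- unlist(lapply(peds, function(p) p$individual_id))
  if (anyDuplicated(ids))
    stop("subject id collision across cohorts: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  pooled <- residualize_and_normalize(tabs, covariates)
  ped_all <- pedigree(do.call(rbind, lapply(peds, as.data.frame)))
  K <- compute_kinship(ped_all)
  traits <- traits %||% trait_cols(pooled)
  rows <- lapply(traits, function(tc) {
    y <- stats::setNames(pooled[[tc]], pooled$subject_id)
    fit <- tryCatch(fit_univariate(y, K = K), error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(trait = tc, n = NA_integer_, h2 = NA_real_,
                        se = NA_real_, p = NA_real_, loglik = NA_real_,
                        converged = FALSE))
    data.frame(trait = tc, n = fit$n_used, h2 = fit$h2, se = fit$se_h2,
               p = fit$p_h2, loglik = fit$loglik, converged = fit$converged)
  })
  do.call(rbind, rows)
}

#' Bonferroni significance threshold
#'
#' alpha = 0.05 / (m_traits * n_descriptors): with 61 bilateral sulci and 4
#' shape descriptors the threshold is 0.05/244; with 123 unilateral sulci,
#' 0.05/492.
#'
#' @param m_traits Number of sulci tested.
#' @param n_descriptors Number of descriptors per sulcus (default 4).
#' @return The corrected alpha threshold.
#' @export
bonferroni_threshold <- function(m_traits, n_descriptors = 4) {
  stopifnot(m_traits >= 1, n_descriptors >= 1)
  0.05 / (m_traits * n_descriptors)
}

#' Pearson correlation between two per-trait profiles
#'
#' Used to compare meta- against mega-analysis heritability profiles and
#' reliability against heritability profiles.
#'
#' @param a,b Paired numeric vectors (>= 3 complete pairs).
#' @return List with `r` and `p` (two-sided).
#' @export
correlate_profiles <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  ct <- stats::cor.test(a[ok], b[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
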