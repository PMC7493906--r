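# End-to-end drivers for the two studies: test-retest reliability across
# cohorts, and heritability / cross-hemisphere genetic correlation across
# family-based cohorts. Both operate on in-memory cohort objects (tables
# from load_phenotypes() or simulate_traits(), pedigrees from
# read_pedigree() or simulate_pedigree()) and optionally write TSV reports
# plus a JSON run manifest.

run_manifest <- function(out_dir, config_list, seed) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  js <- jsonlite::toJSON(config_list, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(js, tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(seed = seed, config_md5 = h, config = config_list)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(h)
}

write_tsv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.table(df, file.path(out_dir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Run the test-retest reliability study
#'
#' For every cohort with at least two sessions and every trait: one-way
#' ICC(1,1) with p-value and SE = ICC/Z, percent bias, and Bland-Altman
#' limits of agreement. Per-trait estimates are then combined across
#' cohorts by inverse-SE^2 weighting, reported only where the trait was
#' estimable in at least 3/4 of the cohorts. The per-trait correlation
#' between mean |bias| and ICC is reported as a cross-check (lower bias
#' should track higher reproducibility).
#'
#' @param cohorts Named list of `phenotype_table`s, each with sessions
#'   1 and 2 (k >= 2 supported).
#' @param out_dir Optional directory for TSV reports and the JSON manifest.
#' @param seed Seed recorded in the manifest (the computation itself is
#'   deterministic).
#' @return List with `per_cohort` (data frame), `meta` (data frame or NULL
#'   for a single cohort), `bias_icc_cor`.
#' @export
run_reliability_study <- function(cohorts, out_dir = NULL, seed = 0) {
  multi <- vapply(cohorts, function(tb) max(tb$session) >= 2, TRUE)
  if (!any(multi)) stop("no cohort has two or more sessions")
  cohorts <- cohorts[multi]
  rows <- list()
  for (cn in names(cohorts)) {
    tab <- cohorts[[cn]]
    for (tc in trait_cols(tab)) {
      wide <- stats::reshape(
        tab[c("subject_id", "session", tc)],
        direction = "wide", idvar = "subject_id", timevar = "session")
      mat <- as.matrix(wide[, -1, drop = FALSE])
      mat <- mat[stats::complete.cases(mat), , drop = FALSE]
      rs <- tryCatch(reliability_summary(mat), error = function(e) NULL)
      if (is.null(rs)) next
      rows[[length(rows) + 1]] <- data.frame(
        trait = tc, cohort = cn, n = rs$n_subjects, icc = rs$icc,
        p = rs$p_icc, se = rs$se_icc, band = rs$band,
        mean_abs_bias = rs$mean_abs_bias, ba_mean = rs$ba_mean_diff,
        ba_low = rs$ba_loa_low, ba_high = rs$ba_loa_high,
        stringsAsFactors = FALSE)
    }
  }
  per_cohort <- do.call(rbind, rows)
  meta <- NULL
  if (length(cohorts) > 1) {
    mrows <- lapply(unique(per_cohort$trait), function(tc) {
      sub <- per_cohort[per_cohort$trait == tc, ]
      m <- suppressWarnings(meta_icc(sub, n_cohorts_available = length(cohorts)))
      data.frame(trait = tc, icc = m$icc, se = m$se,
                 band = if (is.na(m$icc)) NA_character_ else classify_icc(m$icc),
                 n_cohorts_used = m$n_cohorts_used,
                 stringsAsFactors = FALSE)
    })
    meta <- do.call(rbind, mrows)
  }
  bias_icc_cor <- NULL
  if (length(unique(per_cohort$trait)) >= 3) {
    agg <- stats::aggregate(cbind(icc, mean_abs_bias) ~ trait,
                            data = per_cohort, FUN = mean)
    bias_icc_cor <- tryCatch(
      correlate_profiles(agg$icc, agg$mean_abs_bias),
      error = function(e) NULL)
  }
  run_manifest(out_dir, list(study = "reliability",
                             cohorts = names(cohorts)), seed)
  write_tsv(per_cohort, out_dir, "reliability_per_cohort.tsv")
  if (!is.null(meta)) write_tsv(meta, out_dir, "reliability_meta.tsv")
  list(per_cohort = per_cohort, meta = meta, bias_icc_cor = bias_icc_cor)
}

fit_cohort_h2 <- function(tab, ped, covariates, traits = NULL) {
  tab1 <- tab[tab$session == 1, , drop = FALSE]
  K <- compute_kinship(ped)
  X <- tryCatch(suppressWarnings(build_design_matrix(tab1, covariates)),
                error = function(e) NULL)
  if (is.null(X))
    X <- matrix(1, nrow(tab1), 1,
                dimnames = list(tab1$subject_id, "intercept"))
  rownames(X) <- tab1$subject_id
  traits <- traits %||% trait_cols(tab)
  rows <- lapply(traits, function(tc) {
    y <- stats::setNames(tab1[[tc]], tab1$subject_id)
    fit <- tryCatch(fit_univariate(y, X, K), error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(trait = tc, n = NA_integer_, h2 = NA_real_,
                        se = NA_real_, p = NA_real_, loglik = NA_real_,
                        converged = FALSE, stringsAsFactors = FALSE))
    data.frame(trait = tc, n = fit$n_used, h2 = fit$h2, se = fit$se_h2,
               p = fit$p_h2, loglik = fit$loglik, converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the heritability and genetic-correlation study
#'
#' Pipeline: per-sulcus z-score outlier QC, bilateral averaging, per-cohort
#' univariate AE fits with the full covariate set, inverse-variance
#' meta-analysis with Edgington combined p-values, pooled-pedigree
#' mega-analysis on adjusted rank-normalized traits, and - for the traits
#' passing the reliability and significance gates - bivariate left/right
#' fits with tests of rhoG = 0 and rhoG = 1 plus the sample-size-weighted
#' rhoG meta-analysis. The bivariate gate requires meta-analyzed ICC above
#' `icc_gate` (when reliability input is supplied) and Bonferroni-significant
#' univariate meta heritability on both hemispheres.
#'
#' @param cohorts Named list of lists, each `list(tab = phenotype_table,
#'   ped = pedigree)`.
#' @param covariates Covariate set for the design matrices.
#' @param z_threshold Outlier threshold passed to [zscore_outlier_filter].
#' @param reliability_meta Optional data frame (`trait`, `icc`) from
#'   [run_reliability_study].
#' @param icc_gate Reliability gate (default 0.75, "good" reliability).
#' @param m_traits,n_descriptors Bonferroni correction inputs; default to
#'   the number of sulci and descriptors in the data.
#' @param out_dir Optional directory for TSV reports and JSON manifest.
#' @param seed Seed recorded in the manifest.
#' @return List with `per_cohort_h2`, `meta_h2`, `mega_h2`, `rhoG`
#'   (possibly empty), `gate` (per sulcus-descriptor gate bookkeeping),
#'   `qc_reports`, `bonferroni_alpha`.
#' @export
run_heritability_study <- function(cohorts,
                                   covariates = c("icv", "sex", "age", "age2",
                                                  "agexsex", "age2xsex"),
                                   z_threshold = 2.5,
                                   reliability_meta = NULL,
                                   icc_gate = 0.75,
                                   m_traits = NULL, n_descriptors = NULL,
                                   out_dir = NULL, seed = 0) {
  if (!length(cohorts)) stop("no cohorts supplied")
  qc_reports <- list()
  for (cn in names(cohorts)) {
    flt <- zscore_outlier_filter(cohorts[[cn]]$tab, z_threshold)
    cohorts[[cn]]$tab <- bilateral_average(flt$table)
    qc_reports[[cn]] <- flt$report
    ped_ids <- cohorts[[cn]]$ped$individual_id
    phen_ids <- unique(cohorts[[cn]]$tab$subject_id)
    if (!any(phen_ids %in% ped_ids))
      stop("cohort ", cn, ": no phenotype subjects found in pedigree (e.g. ",
           paste(utils::head(phen_ids, 3), collapse = ", "), ")")
  }
  info <- parse_trait_name(unique(unlist(
    lapply(cohorts, function(co) trait_cols(co$tab)))))
  m_traits <- m_traits %||% length(unique(info$sulcus))
  n_descriptors <- n_descriptors %||% length(unique(info$descriptor))
  alpha <- bonferroni_threshold(m_traits, n_descriptors)

  per_cohort <- do.call(rbind, lapply(names(cohorts), function(cn) {
    res <- fit_cohort_h2(cohorts[[cn]]$tab, cohorts[[cn]]$ped, covariates)
    res$cohort <- cn
    res
  }))

  meta_rows <- lapply(unique(per_cohort$trait), function(tc) {
    sub <- per_cohort[per_cohort$trait == tc & !is.na(per_cohort$h2) &
                        is.finite(per_cohort$se) & per_cohort$se > 0, ]
    if (!nrow(sub))
      return(data.frame(trait = tc, h2 = NA_real_, se = NA_real_,
                        p_combined = NA_real_, n_cohorts = 0L,
                        significant = NA, stringsAsFactors = FALSE))
    m <- meta_h2(sub$h2, sub$se)
    p <- edgington_combine(sub$p)
    data.frame(trait = tc, h2 = m$value, se = m$se, p_combined = p,
               n_cohorts = nrow(sub), significant = p <= alpha,
               stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, meta_rows)

  mega <- mega_fit(lapply(cohorts, function(co) co$tab),
                   lapply(cohorts, function(co) co$ped),
                   covariates = covariates)

  # bivariate gate: reliability (when supplied) and bilateral significance
  gate_rows <- list()
  rho_rows <- list()
  sulci_desc <- unique(info[info$hemisphere == "left", c("sulcus", "descriptor")])
  for (k in seq_len(nrow(sulci_desc))) {
    su <- sulci_desc$sulcus[k]; de <- sulci_desc$descriptor[k]
    tl <- trait_name(su, "left", de)
    tr <- trait_name(su, "right", de)
    if (!tr %in% meta$trait) next
    icc_ok <- TRUE
    icc_val <- NA_real_
    if (!is.null(reliability_meta)) {
      cand <- reliability_meta$icc[reliability_meta$trait %in%
                                     c(trait_name(su, "bilateral_avg", de), tl, tr)]
      cand <- cand[is.finite(cand)]
      icc_val <- if (length(cand)) min(cand) else NA_real_
      icc_ok <- length(cand) > 0 && all(cand > icc_gate)
    }
    pl <- meta$p_combined[meta$trait == tl]
    pr <- meta$p_combined[meta$trait == tr]
    sig_ok <- isTRUE(pl <= alpha) && isTRUE(pr <= alpha)
    gate_rows[[length(gate_rows) + 1]] <- data.frame(
      sulcus = su, descriptor = de, icc = icc_val, icc_pass = icc_ok,
      significance_pass = sig_ok, selected = icc_ok && sig_ok,
      stringsAsFactors = FALSE)
    if (!(icc_ok && sig_ok)) next
    fits <- lapply(names(cohorts), function(cn) {
      tab1 <- cohorts[[cn]]$tab
      tab1 <- tab1[tab1$session == 1, , drop = FALSE]
      if (!all(c(tl, tr) %in% names(tab1))) return(NULL)
      K <- compute_kinship(cohorts[[cn]]$ped)
      X <- tryCatch(suppressWarnings(build_design_matrix(tab1, covariates)),
                    error = function(e) matrix(1, nrow(tab1), 1,
                      dimnames = list(tab1$subject_id, "intercept")))
      rownames(X) <- tab1$subject_id
      tryCatch(fit_bivariate(stats::setNames(tab1[[tl]], tab1$subject_id),
                             stats::setNames(tab1[[tr]], tab1$subject_id),
                             X, K),
               error = function(e) NULL)
    })
    ok <- !vapply(fits, is.null, TRUE)
    if (!any(ok)) next
    fits <- fits[ok]
    cns <- names(cohorts)[ok]
    mrg <- meta_rhoG(vapply(fits, function(f) f$rhoG, 0),
                     vapply(fits, function(f) f$n_used, 0),
                     se = vapply(fits, function(f) f$se_rhoG, 0))
    p0 <- edgington_combine(vapply(fits, function(f) f$p_rhoG_vs0, 0))
    p1 <- edgington_combine(vapply(fits, function(f) f$p_rhoG_vs1, 0))
    rho_rows[[length(rho_rows) + 1]] <- data.frame(
      sulcus = su, descriptor = de,
      n_total = sum(vapply(fits, function(f) f$n_used, 0)),
      n_cohorts = length(fits),
      rhoG_meta = mrg$value, se_approx = mrg$se,
      p_vs0_combined = p0, p_vs1_combined = p1,
      incomplete_pleiotropy = p1 < 0.05,
      rhoE_mean = mean(vapply(fits, function(f) f$rhoE, 0)),
      rhoP_mean = mean(vapply(fits, function(f) f$rhoP, 0)),
      stringsAsFactors = FALSE)
  }
  gate <- do.call(rbind, gate_rows) %||%
    data.frame(sulcus = character(), descriptor = character(),
               icc = numeric(), icc_pass = logical(),
               significance_pass = logical(), selected = logical())
  rho <- do.call(rbind, rho_rows) %||%
    data.frame(sulcus = character(), descriptor = character(),
               n_total = integer(), n_cohorts = integer(),
               rhoG_meta = numeric(), se_approx = numeric(),
               p_vs0_combined = numeric(), p_vs1_combined = numeric(),
               incomplete_pleiotropy = logical(), rhoE_mean = numeric(),
               rhoP_mean = numeric())

  run_manifest(out_dir, list(study = "heritability",
                             cohorts = names(cohorts),
                             covariates = covariates,
                             z_threshold = z_threshold,
                             icc_gate = icc_gate,
                             m_traits = m_traits,
                             n_descriptors = n_descriptors), seed)
  write_tsv(per_cohort, out_dir, "h2_per_cohort.tsv")
  write_tsv(meta, out_dir, "h2_meta.tsv")
  write_tsv(mega, out_dir, "h2_mega.tsv")
  write_tsv(rho, out_dir, "rhoG_meta.tsv")
  write_tsv(gate, out_dir, "bivariate_gate.tsv")
  list(per_cohort_h2 = per_cohort, meta_h2 = meta, mega_h2 = mega,
       rhoG = rho, gate = gate, qc_reports = qc_reports,
       bonferroni_alpha = alpha)
}
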