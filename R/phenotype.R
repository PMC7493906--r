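#' Load long-format trait and covariate tables
#'
#' Traits arrive in long format (one measurement per row) and are pivoted to
#' a wide phenotype table with one row per (subject, cohort, session) and one
#' column per trait, where a trait is a (sulcus, hemisphere, descriptor)
#' triple encoded as `sulcus|hemisphere|descriptor`. Covariates (age, sex,
#' ICV) are joined by subject id; subjects without covariates are kept in the
#' table but flagged in the `unmatched_subjects` attribute and excluded from
#' model-ready views downstream.
#'
#' @param trait_path TSV with columns subject, cohort, session, sulcus,
#'   hemisphere, descriptor, value ("NA" for missing).
#' @param covar_path TSV keyed by subject with covariate columns
#'   (age, sex, icv).
#' @return A `phenotype_table` data frame; trait column names are recorded in
#'   attribute `trait_cols`.
#' @export
load_phenotypes <- function(trait_path, covar_path) {
  tr <- utils::read.table(trait_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("subject", "cohort", "session", "sulcus", "hemisphere",
            "descriptor", "value")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("trait file lacks columns: ", paste(miss, collapse = ", "))
  suppress <- is.na(tr$value) | tr$value %in% c("NA", "")
  val <- suppressWarnings(as.numeric(tr$value))
  bad <- which(is.na(val) & !suppress)
  if (length(bad))
    stop("non-numeric trait value at line ", bad[1] + 1, ": ", tr$value[bad[1]])
  tr$value <- val
  key <- paste(tr$subject, tr$session, tr$sulcus, tr$hemisphere,
               tr$descriptor, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, session, sulcus, hemisphere, descriptor) rows")
  cv <- utils::read.table(covar_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"subject" %in% names(cv)) stop("covariate file lacks column: subject")
  tab <- pivot_phenotypes(tr)
  m <- match(tab$subject_id, as.character(cv$subject))
  for (col in setdiff(names(cv), "subject")) tab[[col]] <- cv[[col]][m]
  unmatched <- unique(tab$subject_id[is.na(m)])
  attr(tab, "unmatched_subjects") <- unmatched
  tab
}

#' Compose a trait column name
#'
#' Trait columns are identified by the triple
#' `sulcus|hemisphere|descriptor`; this helper builds (vectorized) names in
#' that convention.
#'
#' @param sulcus,hemisphere,descriptor Character vectors.
#' @return Character vector of trait column names.
#' @export
trait_name <- function(sulcus, hemisphere, descriptor) {
  paste(sulcus, hemisphere, descriptor, sep = "|")
}

parse_trait_name <- function(x) {
  parts <- strsplit(x, "|", fixed = TRUE)
  data.frame(trait = x,
             sulcus = vapply(parts, `[`, "", 1),
             hemisphere = vapply(parts, `[`, "", 2),
             descriptor = vapply(parts, `[`, "", 3),
             stringsAsFactors = FALSE)
}

pivot_phenotypes <- function(tr) {
  tr$trait <- trait_name(tr$sulcus, tr$hemisphere, tr$descriptor)
  rows <- unique(tr[c("subject", "cohort", "session")])
  rows <- rows[order(rows$subject, rows$session), ]
  traits <- unique(tr$trait)
  out <- data.frame(subject_id = as.character(rows$subject),
                    cohort_id = as.character(rows$cohort),
                    session = as.integer(rows$session),
                    stringsAsFactors = FALSE)
  ridx <- match(paste(tr$subject, tr$session),
                paste(out$subject_id, out$session))
  for (tn in traits) out[[tn]] <- NA_real_
  for (k in seq_len(nrow(tr)))
    out[[tr$trait[k]]][ridx[k]] <- tr$value[k]
  as_phenotype_table(out, traits)
}

as_phenotype_table <- function(df, trait_cols) {
  attr(df, "trait_cols") <- trait_cols
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' @export
trait_cols <- function(tab) attr(tab, "trait_cols")

#' Per-sulcus z-score outlier filter
#'
#' For each sulcus (within cohort and hemisphere) z-scores are computed
#' across subjects for every descriptor; a subject whose |z| exceeds the
#' threshold for ANY descriptor of that sulcus has ALL descriptors of that
#' sulcus-hemisphere set to missing, so filtering removes whole
#' subject-sulcus units. The filter is applied once, not iterated.
#'
#' @param tab A `phenotype_table` (session-1 rows are filtered; other
#'   sessions are left untouched).
#' @param threshold Positive z-score threshold (default 2.5).
#' @return List with elements `table` (filtered) and `report` (data frame of
#'   discard counts per cohort/sulcus/hemisphere, plus attributes
#'   `n_subject_sulcus_removed` and `frac_removed`).
#' @export
zscore_outlier_filter <- function(tab, threshold = 2.5) {
  if (threshold <= 0) stop("threshold must be positive")
  tcols <- trait_cols(tab)
  info <- parse_trait_name(tcols)
  rows1 <- which(tab$session == 1)
  rep_list <- list()
  n_removed <- 0
  n_units <- 0
  for (co in unique(tab$cohort_id[rows1])) {
    rco <- rows1[tab$cohort_id[rows1] == co]
    for (su in unique(info$sulcus)) {
      for (he in unique(info$hemisphere[info$sulcus == su])) {
        cols <- info$trait[info$sulcus == su & info$hemisphere == he]
        vals <- as.matrix(tab[rco, cols, drop = FALSE])
        if (sum(stats::complete.cases(vals)) < 3) next
        mu <- colMeans(vals, na.rm = TRUE)
        sd_ <- apply(vals, 2, stats::sd, na.rm = TRUE)
        sd_[!is.finite(sd_) | sd_ == 0] <- Inf
        z <- sweep(sweep(vals, 2, mu), 2, sd_, "/")
        flag <- apply(abs(z) > threshold, 1, any, na.rm = TRUE)
        n_units <- n_units + sum(rowSums(!is.na(vals)) > 0)
        if (any(flag)) {
          tab[rco[flag], cols] <- NA_real_
          n_removed <- n_removed + sum(flag)
        }
        rep_list[[length(rep_list) + 1]] <- data.frame(
          cohort_id = co, sulcus = su, hemisphere = he,
          n_discarded = sum(flag), stringsAsFactors = FALSE)
      }
    }
  }
  report <- do.call(rbind, rep_list) %||%
    data.frame(cohort_id = character(), sulcus = character(),
               hemisphere = character(), n_discarded = integer())
  attr(report, "n_subject_sulcus_removed") <- n_removed
  attr(report, "frac_removed") <- if (n_units > 0) n_removed / n_units else 0
  list(table = tab, report = report)
}

#' Bilateral averaging of left and right traits
#'
#' Adds, for every (sulcus, descriptor) with both hemispheres present, a
#' `bilateral_avg` trait equal to (L + R)/2 per subject; missing whenever
#' either side is missing.
#'
#' @param tab A `phenotype_table`.
#' @return The table with bilateral-average trait columns appended.
#' @export
bilateral_average <- function(tab) {
  info <- parse_trait_name(trait_cols(tab))
  left <- info[info$hemisphere == "left", ]
  for (k in seq_len(nrow(left))) {
    rcol <- trait_name(left$sulcus[k], "right", left$descriptor[k])
    if (!rcol %in% names(tab)) next
    bcol <- trait_name(left$sulcus[k], "bilateral_avg", left$descriptor[k])
    tab[[bcol]] <- (tab[[left$trait[k]]] + tab[[rcol]]) / 2
    attr(tab, "trait_cols") <- c(attr(tab, "trait_cols"), bcol)
  }
  tab
}

#' Build a fixed-effects design matrix
#'
#' Assembles the covariate design used for trait adjustment: any of
#' `icv`, `sex`, `age`, `age2`, `agexsex`, `age2xsex`, always with an
#' intercept. Age is centered before squaring and before forming
#' interactions; sex is coded male = 1, female = -1 (0 when unknown).
#' Columns that are constant or complete the matrix to rank deficiency are
#' dropped with a warning.
#'
#' @param tab A `phenotype_table` restricted to the subjects being modeled.
#' @param covariates Character vector from the set above.
#' @return Numeric matrix with rownames = subject ids.
#' @export
build_design_matrix <- function(tab,
                                covariates = c("icv", "sex", "age", "age2",
                                               "agexsex", "age2xsex")) {
  n <- nrow(tab)
  X <- matrix(1, n, 1, dimnames = list(tab$subject_id, "intercept"))
  need_age <- any(c("age", "age2", "agexsex", "age2xsex") %in% covariates)
  need_sex <- any(c("sex", "agexsex", "age2xsex") %in% covariates)
  if (need_age) {
    if (is.null(tab$age)) stop("covariate 'age' not present")
    if (all(is.na(tab$age))) stop("covariate 'age' is all-missing")
    agec <- tab$age - mean(tab$age, na.rm = TRUE)
  }
  if (need_sex) {
    if (is.null(tab$sex)) stop("covariate 'sex' not present")
    sx <- normalize_sex(tab$sex)
    sexc <- ifelse(sx == "male", 1, ifelse(sx == "female", -1, 0))
  }
  for (cv in covariates) {
    v <- switch(cv,
      icv = {
        if (is.null(tab$icv)) stop("covariate 'icv' not present")
        if (all(is.na(tab$icv))) stop("covariate 'icv' is all-missing")
        tab$icv - mean(tab$icv, na.rm = TRUE)
      },
      sex = sexc,
      age = agec,
      age2 = agec^2 - mean(agec^2, na.rm = TRUE),
      agexsex = agec * sexc,
      age2xsex = (agec^2 - mean(agec^2, na.rm = TRUE)) * sexc,
      stop("unknown covariate: ", cv))
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  # drop constant columns (e.g. sex in a single-sex cohort)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && diff(range(v)) > 0
  }))
  if (any(!keep)) {
    warning("dropping constant design columns: ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  q <- qr(X[stats::complete.cases(X), , drop = FALSE])
  if (q$rank < ncol(X)) {
    drop_idx <- q$pivot[(q$rank + 1):ncol(X)]
    warning("dropping rank-deficient design columns: ",
            paste(colnames(X)[drop_idx], collapse = ", "))
    X <- X[, -drop_idx, drop = FALSE]
  }
  X
}

#' Covariate adjustment and cross-cohort normalization
#'
#' Prepares traits for pooled (mega) analysis: within each cohort every
#' trait is residualized by ordinary least squares on that cohort's design
#' matrix, then mapped through the rank-based inverse-normal transform, so
#' all cohorts end up on a common N(0,1) scale. Only session-1 rows are used.
#'
#' @param tabs List of `phenotype_table`, one per cohort.
#' @param covariates Passed to [build_design_matrix].
#' @return A single `phenotype_table` of adjusted traits with cohort labels
#'   retained.
#' @export
residualize_and_normalize <- function(tabs,
                                      covariates = c("icv", "sex", "age",
                                                     "age2", "agexsex",
                                                     "age2xsex")) {
  if (!length(tabs)) stop("no cohorts supplied")
  pieces <- lapply(tabs, function(tab) {
    tab <- tab[tab$session == 1, , drop = FALSE]
    X <- build_design_matrix(tab, covariates)
    if (nrow(tab) <= ncol(X))
      stop("cohort ", tab$cohort_id[1], " has fewer subjects (", nrow(tab),
           ") than design columns (", ncol(X), ")")
    out <- tab
    for (tc in trait_cols(tab)) {
      y <- tab[[tc]]
      ok <- !is.na(y) & stats::complete.cases(X)
      res <- rep(NA_real_, length(y))
      if (sum(ok) > ncol(X)) {
        fit <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
        res[ok] <- fit$residuals
      }
      out[[tc]] <- inverse_normal(res)
    }
    out
  })
  all_traits <- unique(unlist(lapply(pieces, trait_cols)))
  pieces <- lapply(pieces, function(p) {
    for (tc in setdiff(all_traits, names(p))) p[[tc]] <- NA_real_
    p[c("subject_id", "cohort_id", "session", all_traits)]
  })
  as_phenotype_table(do.call(rbind, pieces), all_traits)
}
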