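#' Simulation configuration
#'
#' Bundles the generative truth for a synthetic cohort: pedigree design,
#' heritability, cross-hemisphere genetic/environmental correlations,
#' covariate effects and test-retest session noise. All randomness in the
#' generators flows from `seed`; an identical config reproduces identical
#' output.
#'
#' Defaults mirror the scale and structure of published family-based
#' morphometry cohorts: twin designs of several hundred families of young
#' adults (age window 20-30, ICV around 1.5e6 mm^3), and extended-pedigree
#' designs of ~71 families of mean size ~15 with a wide age range.
#'
#' @param seed Integer seed.
#' @param design One of `"mz_dz_twins"`, `"sib_pairs"`,
#'   `"extended_pedigree"`, `"unrelated"`.
#' @param n_families Number of families (or subjects, for `"unrelated"`).
#' @param mz_prob Probability a twin-design family is MZ (default 0.5).
#' @param mz_exact When `TRUE`, assign zygosity deterministically so the MZ
#'   family count equals `round(mz_prob * n_families)` exactly.
#' @param extra_sib_prob Probability a twin family carries one extra
#'   singleton sibling.
#' @param family_size Mean sibship+grandchild size for the extended design.
#' @param n_sulci Number of independent sulci (traits) to simulate.
#' @param true_h2 Narrow-sense heritability, scalar or one per sulcus.
#' @param true_rhoG,true_rhoE Cross-hemisphere genetic/environmental
#'   correlations (used when `bilateral = TRUE`), scalar or per sulcus.
#' @param sigma_p2 Total phenotypic variance per trait.
#' @param trait_mean Additive constant so raw traits are positive.
#' @param bilateral Generate homologous left/right trait pairs when `TRUE`,
#'   a single left-hemisphere trait when `FALSE`.
#' @param descriptor Descriptor label used in trait column names.
#' @param covariate_effects Named numeric vector of fixed effects applied to
#'   centered covariates; names among icv, sex, age, age2, agexsex,
#'   age2xsex.
#' @param age_range Two-element age window (years) for phenotyped subjects.
#' @param icv_mean,icv_sd Intracranial-volume distribution (mm^3).
#' @param n_sessions Number of scan sessions (>= 2 gives test-retest data).
#' @param session_noise_sd Within-subject SD of repeat-session noise.
#' @param cohort_label Cohort id; also namespaces subject ids.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       design = c("mz_dz_twins", "sib_pairs",
                                  "extended_pedigree", "unrelated"),
                       n_families = 400,
                       mz_prob = 0.5,
                       mz_exact = FALSE,
                       extra_sib_prob = 0.1,
                       family_size = 15,
                       n_sulci = 1,
                       true_h2 = 0.5,
                       true_rhoG = 0.9,
                       true_rhoE = 0.3,
                       sigma_p2 = 1,
                       trait_mean = 10,
                       bilateral = FALSE,
                       descriptor = "length",
                       covariate_effects = NULL,
                       age_range = c(20, 30),
                       icv_mean = 1.5e6,
                       icv_sd = 1.5e5,
                       n_sessions = 1,
                       session_noise_sd = 0,
                       cohort_label = "sim") {
  design <- match.arg(design)
  cfg <- list(seed = seed, design = design, n_families = n_families,
              mz_prob = mz_prob, mz_exact = mz_exact,
              extra_sib_prob = extra_sib_prob,
              family_size = family_size, n_sulci = n_sulci,
              true_h2 = true_h2, true_rhoG = true_rhoG,
              true_rhoE = true_rhoE, sigma_p2 = sigma_p2,
              trait_mean = trait_mean, bilateral = bilateral,
              descriptor = descriptor,
              covariate_effects = covariate_effects,
              age_range = age_range, icv_mean = icv_mean, icv_sd = icv_sd,
              n_sessions = n_sessions,
              session_noise_sd = session_noise_sd,
              cohort_label = cohort_label)
  check_corr_psd(cfg)
  class(cfg) <- "sim_config"
  cfg
}

check_corr_psd <- function(cfg) {
  for (r in c(cfg$true_rhoG, cfg$true_rhoE)) {
    if (abs(r) > 1) stop("correlations must lie in [-1, 1]")
  }
  h2 <- cfg$true_h2
  if (any(h2 < 0 | h2 > 1)) stop("true_h2 must lie in [0, 1]")
  invisible(TRUE)
}

#' Simulate a pedigree
#'
#' Builds the family structures the analysis expects: twin cohorts (MZ/DZ
#' pairs with parents and optional extra siblings), sib-pair families,
#' three-generation extended pedigrees, or unrelated singletons. Subject ids
#' are namespaced by the cohort label. Parents in twin/sib designs exist for
#' kinship bookkeeping but are not phenotyped; [simulate_traits] returns
#' rows only for phenotyped individuals.
#'
#' @param config A [sim_config].
#' @return A [pedigree] with a logical attribute-column `phenotyped`.
#' @export
simulate_pedigree <- function(config) {
  set.seed(config$seed)
  lab <- config$cohort_label
  rows <- list()
  add <- function(fam, id, fa, mo, sex, mz, phen) {
    rows[[length(rows) + 1]] <<- data.frame(
      individual_id = sprintf("%s_%s", lab, id),
      family_id = sprintf("%s_f%04d", lab, fam),
      father_id = if (is.na(fa)) NA_character_ else sprintf("%s_%s", lab, fa),
      mother_id = if (is.na(mo)) NA_character_ else sprintf("%s_%s", lab, mo),
      sex = sex, mz_group = mz, cohort_id = lab,
      phenotyped = phen, stringsAsFactors = FALSE)
  }
  rsex <- function(n = 1) sample(c("male", "female"), n, replace = TRUE)
  if (config$design == "unrelated") {
    for (i in seq_len(config$n_families))
      add(i, sprintf("s%05d", i), NA, NA, rsex(), NA_character_, TRUE)
  } else if (config$design %in% c("mz_dz_twins", "sib_pairs")) {
    nf <- config$n_families
    mz_flags <- if (config$design != "mz_dz_twins") {
      rep(FALSE, nf)
    } else if (isTRUE(config$mz_exact)) {
      # deterministic zygosity split: exactly round(mz_prob * n) MZ families
      seq_len(nf) <= round(config$mz_prob * nf)
    } else {
      stats::runif(nf) < config$mz_prob
    }
    fam <- sprintf("%s_f%04d", lab, seq_len(nf))
    p1 <- sprintf("%s_f%04d_p1", lab, seq_len(nf))
    p2 <- sprintf("%s_f%04d_p2", lab, seq_len(nf))
    t1_sex <- rsex(nf)
    t2_sex <- ifelse(mz_flags, t1_sex, rsex(nf))
    mzg <- ifelse(mz_flags, sprintf("%s_mz%04d", lab, seq_len(nf)),
                  NA_character_)
    has_sib <- stats::runif(nf) < config$extra_sib_prob
    sib_sex <- rsex(nf)
    rows <- list(
      data.frame(individual_id = p1, family_id = fam,
                 father_id = NA_character_, mother_id = NA_character_,
                 sex = "male", mz_group = NA_character_, cohort_id = lab,
                 phenotyped = FALSE, stringsAsFactors = FALSE),
      data.frame(individual_id = p2, family_id = fam,
                 father_id = NA_character_, mother_id = NA_character_,
                 sex = "female", mz_group = NA_character_, cohort_id = lab,
                 phenotyped = FALSE, stringsAsFactors = FALSE),
      data.frame(individual_id = sprintf("%s_f%04d_t1", lab, seq_len(nf)),
                 family_id = fam, father_id = p1, mother_id = p2,
                 sex = t1_sex, mz_group = mzg, cohort_id = lab,
                 phenotyped = TRUE, stringsAsFactors = FALSE),
      data.frame(individual_id = sprintf("%s_f%04d_t2", lab, seq_len(nf)),
                 family_id = fam, father_id = p1, mother_id = p2,
                 sex = t2_sex, mz_group = mzg, cohort_id = lab,
                 phenotyped = TRUE, stringsAsFactors = FALSE))
    if (any(has_sib)) {
      w <- which(has_sib)
      rows <- c(rows, list(
        data.frame(individual_id = sprintf("%s_f%04d_s1", lab, w),
                   family_id = fam[w], father_id = p1[w], mother_id = p2[w],
                   sex = sib_sex[w], mz_group = NA_character_,
                   cohort_id = lab, phenotyped = TRUE,
                   stringsAsFactors = FALSE)))
    }
  } else { # extended_pedigree: three generations
    # expected family size: 2 founders + n_kids * (kid + spouse + n_gc);
    # n_kids = max(2, Pois(3)) has mean ~3.25, so the grandchild mean
    # solves 2 + 3.25*(2 + g) = family_size
    gc_mean <- max(0, (config$family_size - 2) / 3.25 - 2)
    for (f in seq_len(config$n_families)) {
      g1a <- sprintf("f%04d_g1a", f); g1b <- sprintf("f%04d_g1b", f)
      add(f, g1a, NA, NA, "male", NA_character_, TRUE)
      add(f, g1b, NA, NA, "female", NA_character_, TRUE)
      n_kids <- max(2, stats::rpois(1, 3))
      for (k in seq_len(n_kids)) {
        kid <- sprintf("f%04d_g2k%02d", f, k)
        kid_sex <- rsex()
        add(f, kid, g1a, g1b, kid_sex, NA_character_, TRUE)
        sp <- sprintf("f%04d_g2s%02d", f, k)
        sp_sex <- if (kid_sex == "male") "female" else "male"
        add(f, sp, NA, NA, sp_sex, NA_character_, TRUE)
        n_gc <- stats::rpois(1, gc_mean)
        for (g in seq_len0(n_gc)) {
          fa_id <- if (kid_sex == "male") kid else sp
          mo_id <- if (kid_sex == "male") sp else kid
          add(f, sprintf("f%04d_g3k%02d_%02d", f, k, g), fa_id, mo_id,
              rsex(), NA_character_, TRUE)
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  pedigree(df)
}

seq_len0 <- function(n) if (n < 1) integer(0) else seq_len(n)

#' Simulate trait values on a pedigree
#'
#' Draws traits under the generative AE model the estimators assume:
#' trait = mean + X beta + g + e, with genetic values sampled jointly per
#' family block from N(0, sigma_g2 * 2*Phi) (MZ members receive identical
#' genetic values because their relationship entries equal the diagonal)
#' and environmental deviates iid N(0, sigma_e2). With
#' `bilateral = TRUE` homologous left/right pairs are generated with
#' genetic cross-correlation `true_rhoG` and environmental
#' cross-correlation `true_rhoE`. Sessions beyond the first equal the
#' session-1 value plus independent N(0, session_noise_sd^2) noise.
#'
#' @param ped A [pedigree] from [simulate_pedigree].
#' @param config The same [sim_config].
#' @param K Optional precomputed relatedness matrix for `ped` (recomputed
#'   when `NULL`); passing it avoids repeated kinship computation when many
#'   trait replicates are drawn on one pedigree.
#' @return A `phenotype_table` with one row per phenotyped subject per
#'   session, covariates age/sex/icv, and attribute `truth` carrying the
#'   generative parameters.
#' @export
simulate_traits <- function(ped, config, K = NULL) {
  set.seed(config$seed + 499979L)
  n <- nrow(ped)
  kin_blocks <- if (is.null(K) ||
                    identical(attr(K, "source"), "pedigree")) {
    # pedigree-derived relatedness: blocks come straight from the pedigree
    kinship_block_list(ped)
  } else {
    lapply(split(seq_len(n), vc_components(unclass(K))), function(ii)
      list(members = ii, K = unclass(K)[ii, ii, drop = FALSE]))
  }
  h2 <- rep_len(config$true_h2, config$n_sulci)
  rG <- rep_len(config$true_rhoG, config$n_sulci)
  rE <- rep_len(config$true_rhoE, config$n_sulci)
  sp2 <- config$sigma_p2

  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  icv <- stats::rnorm(n, config$icv_mean, config$icv_sd)
  sexc <- ifelse(ped$sex == "male", 1, ifelse(ped$sex == "female", -1, 0))
  agec <- age - mean(age)
  icvc <- icv - mean(icv)
  eff <- config$covariate_effects
  fixed <- rep(0, n)
  if (!is.null(eff)) {
    parts <- list(icv = icvc, sex = sexc, age = agec,
                  age2 = agec^2 - mean(agec^2),
                  agexsex = agec * sexc,
                  age2xsex = (agec^2 - mean(agec^2)) * sexc)
    for (nm in names(eff)) {
      if (!nm %in% names(parts)) stop("unknown covariate effect: ", nm)
      fixed <- fixed + eff[[nm]] * parts[[nm]]
    }
  }

  sulci <- sprintf("sulcus%02d", seq_len(config$n_sulci))
  # Per-family-block square roots of the relationship submatrix, cached by
  # pattern (twin designs repeat a handful of block shapes). A genetic draw
  # for a block is then sqrt(K_b) %*% Z %*% sqrt(G): its covariance is the
  # Kronecker product kron(G, K_b) required by the bivariate AE model.
  sqrt_cache <- new.env(parent = emptyenv())
  block_sqrt <- function(Kb) {
    key <- paste(round(Kb, 8), collapse = ",")
    got <- sqrt_cache[[key]]
    if (is.null(got)) {
      got <- mat_sqrt(Kb)
      sqrt_cache[[key]] <- got
    }
    got
  }
  vals <- list()
  for (t in seq_len(config$n_sulci)) {
    sg2 <- h2[t] * sp2
    se2 <- (1 - h2[t]) * sp2
    if (config$bilateral) {
      sqG <- mat_sqrt(sg2 * matrix(c(1, rG[t], rG[t], 1), 2))
      sqE <- mat_sqrt(se2 * matrix(c(1, rE[t], rE[t], 1), 2))
      g <- matrix(0, n, 2)
      for (b in kin_blocks) {
        Z <- matrix(stats::rnorm(2 * length(b$members)), ncol = 2)
        g[b$members, ] <- block_sqrt(b$K) %*% Z %*% sqG
      }
      e <- matrix(stats::rnorm(2 * n), ncol = 2) %*% sqE
      y <- g + e + fixed + config$trait_mean
      vals[[trait_name(sulci[t], "left", config$descriptor)]] <- y[, 1]
      vals[[trait_name(sulci[t], "right", config$descriptor)]] <- y[, 2]
    } else {
      g <- numeric(n)
      for (b in kin_blocks) {
        g[b$members] <- sqrt(sg2) *
          (block_sqrt(b$K) %*% stats::rnorm(length(b$members)))
      }
      e <- stats::rnorm(n, 0, sqrt(se2))
      vals[[trait_name(sulci[t], "left", config$descriptor)]] <-
        g + e + fixed + config$trait_mean
    }
  }

  phen <- ped$phenotyped %||% rep(TRUE, n)
  idx <- which(phen)
  base <- data.frame(subject_id = ped$individual_id[idx],
                     cohort_id = config$cohort_label,
                     session = 1L,
                     stringsAsFactors = FALSE)
  tcols <- names(vals)
  for (tc in tcols) base[[tc]] <- vals[[tc]][idx]
  base$age <- age[idx]; base$sex <- ped$sex[idx]; base$icv <- icv[idx]
  out <- base
  if (config$n_sessions >= 2) {
    for (s in 2:config$n_sessions) {
      rep_rows <- base
      rep_rows$session <- as.integer(s)
      for (tc in tcols)
        rep_rows[[tc]] <- base[[tc]] +
          stats::rnorm(nrow(base), 0, config$session_noise_sd)
      out <- rbind(out, rep_rows)
    }
  }
  out <- as_phenotype_table(out, tcols)
  attr(out, "truth") <- list(h2 = stats::setNames(h2, sulci),
                             rhoG = stats::setNames(rG, sulci),
                             rhoE = stats::setNames(rE, sulci),
                             sigma_p2 = sp2)
  out
}

#' Test-retest battery with graded reliability
#'
#' Generates a multi-trait two-session (or more) battery of unrelated
#' subjects in which each trait's within-subject noise is set to hit a
#' target population ICC = sigma2_BS / (sigma2_BS + sigma2_WS), with
#' sigma2_BS = 1. Used to exercise the reliability estimators against known
#' ground truth.
#'
#' @param n_subjects Number of subjects.
#' @param icc_targets Vector of population ICC values in (0, 1]; one trait
#'   is generated per target.
#' @param n_sessions Sessions per subject (>= 2).
#' @param seed Integer seed.
#' @param cohort_label Cohort id.
#' @return A `phenotype_table` with attribute `truth` (the target ICCs).
#' @export
make_trt_battery <- function(n_subjects = 30,
                             icc_targets = seq(0.3, 0.95, length.out = 8),
                             n_sessions = 2, seed = 1,
                             cohort_label = "trt") {
  stopifnot(n_sessions >= 2, all(icc_targets > 0), all(icc_targets <= 1))
  set.seed(seed)
  sulci <- sprintf("sulcus%02d", seq_along(icc_targets))
  tcols <- trait_name(sulci, "left", "length")
  rows <- list()
  u <- matrix(stats::rnorm(n_subjects * length(icc_targets)), n_subjects)
  for (s in seq_len(n_sessions)) {
    df <- data.frame(subject_id = sprintf("%s_s%04d", cohort_label,
                                          seq_len(n_subjects)),
                     cohort_id = cohort_label, session = as.integer(s),
                     stringsAsFactors = FALSE)
    for (t in seq_along(icc_targets)) {
      ws_sd <- sqrt((1 - icc_targets[t]) / icc_targets[t])
      df[[tcols[t]]] <- 10 + u[, t] + stats::rnorm(n_subjects, 0, ws_sd)
    }
    rows[[s]] <- df
  }
  out <- as_phenotype_table(do.call(rbind, rows), tcols)
  attr(out, "truth") <- stats::setNames(icc_targets, tcols)
  out
}
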