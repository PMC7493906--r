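#!/usr/bin/env Rscript
# Stage 3: heritability and cross-hemisphere genetic correlation study.
#
# Loads the three family-based cohorts (two twin designs, one extended
# pedigree), applies the per-sulcus |z| > 2.5 outlier filter and bilateral
# averaging, fits the univariate AE model per trait and cohort with the
# full covariate set, combines cohorts by inverse-variance meta-analysis
# (Edgington combined p-values) and by pooled-pedigree mega-analysis, and
# runs the bivariate left/right model (rhoG with tests against 0 and 1) for
# the traits passing the reliability (meta-ICC > 0.75) and bilateral
# Bonferroni-significance gates. Prints the profile correlations against
# the generative truth.

suppressPackageStartupMessages(library(sulcherit))

root <- "results/cohorts"
labs <- c("twinA", "twinB", "extended")
cohorts <- setNames(lapply(labs, function(lab) {
  long <- read.table(file.path(root, lab, "traits.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  tab <- sulcherit:::pivot_phenotypes(long)
  cov <- read.table(file.path(root, lab, "covariates.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  m <- match(tab$subject_id, cov$subject)
  tab$age <- cov$age[m]; tab$sex <- cov$sex[m]; tab$icv <- cov$icv[m]
  ped <- read_pedigree(file.path(root, lab, "pedigree.tsv"), "solar_like",
                       cohort_id = lab)
  list(tab = tab, ped = ped)
}), labs)

rel_path <- "results/reliability/reliability_meta.tsv"
rel <- NULL
if (file.exists(rel_path)) {
  rel <- read.table(rel_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  message("using meta-ICC reliability gate from ", rel_path)
} else {
  message("no reliability table found; ICC gate disabled")
}

res <- run_heritability_study(
  cohorts,
  covariates = c("icv", "sex", "age", "age2", "agexsex", "age2xsex"),
  z_threshold = 2.5,
  reliability_meta = rel,
  icc_gate = 0.75,
  m_traits = 20, n_descriptors = 1,
  out_dir = "results/heritability", seed = 42)

truth <- unlist(jsonlite::read_json(file.path(root, "twinA", "truth.json"))$h2)
sulci <- names(truth)
left <- trait_name(sulci, "left", "length")
meta_prof <- res$meta_h2$h2[match(left, res$meta_h2$trait)]
mega_prof <- res$mega_h2$h2[match(left, res$mega_h2$trait)]
message(sprintf("meta vs truth:  r = %.3f", correlate_profiles(meta_prof, truth)$r))
message(sprintf("mega vs truth:  r = %.3f", correlate_profiles(mega_prof, truth)$r))
message(sprintf("meta vs mega:   r = %.3f",
                correlate_profiles(meta_prof, mega_prof)$r))
message(sprintf("Bonferroni threshold: %.2e; %d/%d left traits significant",
                res$bonferroni_alpha,
                sum(res$meta_h2$significant[match(left, res$meta_h2$trait)],
                    na.rm = TRUE), length(left)))
message(sprintf("bivariate gate: %d sulci selected; mean meta-rhoG = %.3f",
                nrow(res$rhoG),
                if (nrow(res$rhoG)) mean(res$rhoG$rhoG_meta) else NA))
n_incomplete <- sum(res$rhoG$incomplete_pleiotropy)
message(sprintf("incomplete pleiotropy (p[rhoG=1] < 0.05): %d of %d sulci",
                n_incomplete, nrow(res$rhoG)))
message("tables under results/heritability/")
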