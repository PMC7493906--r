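#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohorts.
#
# Three family-based cohorts mirror the designs of published sulcal
# morphometry samples: two twin cohorts of young adults (one QTIM-like with
# ~500 twin families, one HCP-like with ~400) and one extended-pedigree
# cohort (GOBS-like: 71 families of mean size 15, wide age range). Four
# small test-retest cohorts (n = 20-35, two sessions) mirror the
# reliability samples. Twenty bilateral traits are simulated per cohort
# with a heterogeneous heritability profile (0.1-0.7), cross-hemisphere
# genetic correlation 0.9 and environmental correlation 0.3, plus age and
# sex covariate effects.
#
# Writes pedigree/trait/covariate TSVs plus truth.json per cohort under
# results/cohorts/.

suppressPackageStartupMessages(library(sulcherit))

seed <- 20260925 %% 1000
out_root <- "results/cohorts"
dir.create(out_root, showWarnings = FALSE, recursive = TRUE)

h2_true <- seq(0.1, 0.7, length.out = 20)

family_cfgs <- list(
  twinA = sim_config(seed = seed + 1, design = "mz_dz_twins",
                     n_families = 450, mz_prob = 0.58, extra_sib_prob = 0.1,
                     n_sulci = 20, true_h2 = h2_true, true_rhoG = 0.9,
                     true_rhoE = 0.3, bilateral = TRUE,
                     covariate_effects = c(age = 0.05, sex = 0.1),
                     age_range = c(18, 30), cohort_label = "twinA"),
  twinB = sim_config(seed = seed + 2, design = "mz_dz_twins",
                     n_families = 350, mz_prob = 0.49, extra_sib_prob = 0.3,
                     n_sulci = 20, true_h2 = h2_true, true_rhoG = 0.9,
                     true_rhoE = 0.3, bilateral = TRUE,
                     covariate_effects = c(age = 0.05, sex = 0.1),
                     age_range = c(22, 36), cohort_label = "twinB"),
  extended = sim_config(seed = seed + 3, design = "extended_pedigree",
                        n_families = 71, family_size = 15, n_sulci = 20,
                        true_h2 = h2_true, true_rhoG = 0.9, true_rhoE = 0.3,
                        bilateral = TRUE,
                        covariate_effects = c(age = 0.05, sex = 0.1),
                        age_range = c(18, 85), cohort_label = "extended"))

write_cohort <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  tab <- simulate_traits(ped, cfg)
  dir <- file.path(out_root, cfg$cohort_label)
  dir.create(dir, showWarnings = FALSE)
  ped_out <- data.frame(famid = ped$family_id, id = ped$individual_id,
                        fa = ifelse(is.na(ped$father_id), "0", ped$father_id),
                        mo = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                        sex = ped$sex,
                        mztwin = ifelse(is.na(ped$mz_group), "", ped$mz_group))
  write.table(ped_out, file.path(dir, "pedigree.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  long <- do.call(rbind, lapply(trait_cols(tab), function(tc) {
    parts <- strsplit(tc, "|", fixed = TRUE)[[1]]
    data.frame(subject = tab$subject_id, cohort = tab$cohort_id,
               session = tab$session, sulcus = parts[1],
               hemisphere = parts[2], descriptor = parts[3],
               value = tab[[tc]])
  }))
  write.table(long, file.path(dir, "traits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cov <- unique(tab[tab$session == 1, c("subject_id", "age", "sex", "icv")])
  names(cov)[1] <- "subject"
  write.table(cov, file.path(dir, "covariates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(lapply(attr(tab, "truth"), as.list),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("cohort %-9s: %4d individuals, %4d phenotyped",
                  cfg$cohort_label, nrow(ped), length(unique(tab$subject_id))))
  invisible(NULL)
}

for (cfg in family_cfgs) write_cohort(cfg)

# test-retest cohorts with graded per-site reliability
trt_sizes <- c(kki_like = 21, hcp_like = 35, oasis_like = 20, qtim_like = 34)
icc_targets <- seq(0.45, 0.95, length.out = 20)
for (i in seq_along(trt_sizes)) {
  lab <- names(trt_sizes)[i]
  tab <- make_trt_battery(n_subjects = trt_sizes[[i]],
                          icc_targets = icc_targets,
                          n_sessions = 2, seed = seed + 10 + i,
                          cohort_label = lab)
  dir <- file.path(out_root, lab)
  dir.create(dir, showWarnings = FALSE)
  long <- do.call(rbind, lapply(trait_cols(tab), function(tc) {
    parts <- strsplit(tc, "|", fixed = TRUE)[[1]]
    data.frame(subject = tab$subject_id, cohort = tab$cohort_id,
               session = tab$session, sulcus = parts[1],
               hemisphere = parts[2], descriptor = parts[3],
               value = tab[[tc]])
  }))
  write.table(long, file.path(dir, "traits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(attr(tab, "truth")),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("TRT cohort %-10s: %2d subjects x 2 sessions",
                  lab, trt_sizes[[i]]))
}

message("wrote cohorts under ", out_root)
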