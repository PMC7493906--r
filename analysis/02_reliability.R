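#!/usr/bin/env Rscript
# Stage 2: test-retest reliability study.
#
# For each of the four two-session cohorts written by 01_simulate_cohorts.R:
# per-trait one-way ICC(1,1) with p-value and SE = ICC/Z, percent bias and
# Bland-Altman limits of agreement; then the inverse-SE^2 meta-analysis of
# ICC across cohorts (reported only for traits estimable in >= 3/4
# cohorts). Prints the ICC interquartile range across traits and the
# correlation between the estimated and generative ICC grid.

suppressPackageStartupMessages(library(sulcherit))

root <- "results/cohorts"
labs <- c("kki_like", "hcp_like", "oasis_like", "qtim_like")
cohorts <- setNames(lapply(labs, function(lab) {
  long <- read.table(file.path(root, lab, "traits.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  sulcherit:::pivot_phenotypes(long)
}), labs)

res <- run_reliability_study(cohorts, out_dir = "results/reliability",
                             seed = 42)

meta <- res$meta
q <- quantile(meta$icc, c(0.25, 0.75), na.rm = TRUE)
message(sprintf("meta-ICC across %d traits: IQR [%.2f, %.2f]",
                sum(!is.na(meta$icc)), q[1], q[2]))
message(sprintf("reliability bands: %s",
                paste(names(table(meta$band)), table(meta$band),
                      collapse = ", ", sep = "=")))

truth <- unlist(jsonlite::read_json(file.path(root, labs[1], "truth.json")))
m <- match(meta$trait, names(truth))
cc <- correlate_profiles(meta$icc, truth[m])
message(sprintf("estimated vs generative ICC profile: r = %.3f (p = %.2g)",
                cc$r, cc$p))
if (!is.null(res$bias_icc_cor))
  message(sprintf("mean |bias| vs ICC across traits: r = %.3f (p = %.2g)",
                  res$bias_icc_cor$r, res$bias_icc_cor$p))
message("tables under results/reliability/")
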