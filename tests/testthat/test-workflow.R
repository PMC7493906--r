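trt_cohorts <- function(n_cohorts = 4, seed = 81) {
  # per-cohort quality differs so ICC varies across sites
  setNames(lapply(seq_len(n_cohorts), function(i) {
    make_trt_battery(n_subjects = 25,
                     icc_targets = c(0.85, 0.6, 0.9),
                     seed = seed + i,
                     cohort_label = paste0("trt", i))
  }), paste0("trt", seq_len(n_cohorts)))
}

test_that("reliability study produces per-cohort and meta tables", {
  out_dir <- withr::local_tempdir()
  res <- run_reliability_study(trt_cohorts(), out_dir = out_dir, seed = 7)
  expect_equal(sort(unique(res$per_cohort$cohort)), paste0("trt", 1:4))
  expect_equal(nrow(res$meta), 3)
  expect_true(all(res$meta$n_cohorts_used >= 3 | is.na(res$meta$icc)))
  expect_true(all(c("manifest.json", "reliability_per_cohort.tsv",
                    "reliability_meta.tsv") %in% list.files(out_dir)))
  # single-cohort run has no meta table
  solo <- run_reliability_study(trt_cohorts(1))
  expect_null(solo$meta)
  # no multi-session cohort is an error
  tab <- trt_cohorts(1)[[1]]
  tab1 <- tab[tab$session == 1, ]
  attr(tab1, "trait_cols") <- trait_cols(tab)
  expect_error(run_reliability_study(list(a = tab1)), "sessions")
})

test_that("traits estimable in fewer than 3/4 cohorts are dropped from the meta table", {
  cohorts <- trt_cohorts()
  # remove one trait from three of the four cohorts
  tc <- trait_cols(cohorts[[1]])[1]
  for (i in 2:4) {
    cohorts[[i]][[tc]] <- NULL
    attr(cohorts[[i]], "trait_cols") <-
      setdiff(trait_cols(cohorts[[i]]), tc)
  }
  res <- run_reliability_study(cohorts)
  expect_true(is.na(res$meta$icc[res$meta$trait == tc]))
  expect_false(anyNA(res$meta$icc[res$meta$trait != tc]))
})

herit_cohorts <- function(h2_vec, seed = 91, n_families = 150,
                          n_cohorts = 2) {
  setNames(lapply(seq_len(n_cohorts), function(i) {
    lab <- paste0("coh", i)
    cfg <- sim_config(seed = seed + i, design = "mz_dz_twins",
                      n_families = n_families, n_sulci = length(h2_vec),
                      true_h2 = h2_vec, true_rhoG = 0.9, true_rhoE = 0.3,
                      bilateral = TRUE, mz_exact = TRUE, extra_sib_prob = 0,
                      cohort_label = lab)
    ped <- simulate_pedigree(cfg)
    list(tab = simulate_traits(ped, cfg), ped = ped)
  }), paste0("coh", seq_len(n_cohorts)))
}

test_that("heritability study wires QC, fits, meta, mega and the rhoG gate", {
  cohorts <- herit_cohorts(c(0.6, 0.0), seed = 92, n_families = 250)
  # reliability input: sulcus01 passes the ICC gate, sulcus02 fails it
  rel <- data.frame(
    trait = c(trait_name("sulcus01", "left", "length"),
              trait_name("sulcus01", "right", "length"),
              trait_name("sulcus02", "left", "length"),
              trait_name("sulcus02", "right", "length")),
    icc = c(0.9, 0.88, 0.5, 0.55))
  out_dir <- withr::local_tempdir()
  res <- run_heritability_study(cohorts, covariates = c("age", "sex"),
                                reliability_meta = rel,
                                m_traits = 2, n_descriptors = 1,
                                out_dir = out_dir, seed = 11)
  expect_equal(res$bonferroni_alpha, 0.05 / 2)
  # per-cohort fits exist for left, right and bilateral traits
  expect_true(all(table(res$per_cohort_h2$cohort) == 6))
  # heritable sulcus found, null sulcus not
  m <- res$meta_h2
  s1L <- m[m$trait == trait_name("sulcus01", "left", "length"), ]
  s2L <- m[m$trait == trait_name("sulcus02", "left", "length"), ]
  expect_true(s1L$significant)
  expect_gt(s1L$h2, 0.35)
  expect_lt(s2L$h2, 0.25)
  # the rhoG set equals the joint gate exactly
  sel <- res$gate$sulcus[res$gate$selected]
  expect_equal(res$rhoG$sulcus, sel)
  expect_equal(sel, "sulcus01")
  expect_false("sulcus02" %in% res$rhoG$sulcus)  # ICC gate exclusion
  expect_lt(abs(res$rhoG$rhoG_meta - 0.9), 0.15)
  expect_true(file.exists(file.path(out_dir, "rhoG_meta.tsv")))
  # mega table covers the same traits
  expect_setequal(res$mega_h2$trait, m$trait)
})

test_that("gate logic uses both reliability and bilateral significance", {
  cohorts <- herit_cohorts(c(0.6, 0.6), seed = 93, n_families = 200)
  # both sulci reliable, but we nuke sulcus02's right-hemisphere trait to
  # destroy its significance
  for (cn in names(cohorts)) {
    tc <- trait_name("sulcus02", "right", "length")
    set.seed(1)
    cohorts[[cn]]$tab[[tc]] <- sample(cohorts[[cn]]$tab[[tc]])
  }
  rel <- data.frame(
    trait = as.vector(outer(c("sulcus01", "sulcus02"), c("left", "right"),
                            function(s, h) trait_name(s, h, "length"))),
    icc = 0.9)
  res <- run_heritability_study(cohorts, covariates = c("age", "sex"),
                                reliability_meta = rel,
                                m_traits = 2, n_descriptors = 1)
  g <- res$gate
  expect_true(all(g$icc_pass))
  expect_true(g$significance_pass[g$sulcus == "sulcus01"])
  expect_false(g$significance_pass[g$sulcus == "sulcus02"])
  expect_equal(res$rhoG$sulcus, "sulcus01")
})

test_that("study outputs are reproducible for a fixed config", {
  cohorts <- trt_cohorts(2, seed = 95)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_reliability_study(cohorts, out_dir = d1, seed = 3)
  r2 <- run_reliability_study(cohorts, out_dir = d2, seed = 3)
  expect_identical(r1$per_cohort, r2$per_cohort)
  f1 <- file.path(d1, "reliability_per_cohort.tsv")
  f2 <- file.path(d2, "reliability_per_cohort.tsv")
  expect_identical(readLines(f1), readLines(f2))
})
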