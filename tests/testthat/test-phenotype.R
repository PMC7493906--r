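write_long_traits <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

long_row <- function(subject, sulcus, hemisphere, descriptor, value,
                     cohort = "c1", session = 1) {
  data.frame(subject = subject, cohort = cohort, session = session,
             sulcus = sulcus, hemisphere = hemisphere,
             descriptor = descriptor, value = value,
             stringsAsFactors = FALSE)
}

test_that("long trait files pivot to one row per subject-session", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  cf <- withr::local_tempfile(fileext = ".tsv")
  rows <- do.call(rbind, lapply(c("s1", "s2"), function(s)
    do.call(rbind, lapply(c("length", "mean_depth", "width", "surface_area"),
      function(d) long_row(s, "S.C.", "left", d, runif(1, 10, 20))))))
  write_long_traits(rows, tf)
  writeLines(c("subject\tage\tsex\ticv",
               "s1\t25\tmale\t1500000",
               "s2\t30\tfemale\t1400000"), cf)
  tab <- load_phenotypes(tf, cf)
  expect_equal(nrow(tab), 2)
  expect_length(trait_cols(tab), 4)
  expect_equal(sum(!is.na(as.matrix(tab[trait_cols(tab)]))), 8)
  expect_equal(tab$age, c(25, 30))

  # missing covariate subject is flagged
  writeLines(c("subject\tage\tsex\ticv", "s1\t25\tmale\t1500000"), cf)
  tab2 <- load_phenotypes(tf, cf)
  expect_equal(attr(tab2, "unmatched_subjects"), "s2")
  expect_true(is.na(tab2$age[tab2$subject_id == "s2"]))

  # "NA" becomes an explicit missing value, not zero
  rows$value <- as.character(rows$value)
  rows$value[1] <- "NA"
  write_long_traits(rows, tf)
  tab3 <- load_phenotypes(tf, cf)
  expect_true(is.na(tab3[[rows$sulcus[1] |>
    trait_name("left", rows$descriptor[1])]][tab3$subject_id == "s1"]))

  # duplicates and non-numeric values are rejected
  write_long_traits(rbind(rows, rows[2, ]), tf)
  expect_error(load_phenotypes(tf, cf), "duplicate")
  rows$value[1] <- "abc"
  write_long_traits(rows, tf)
  expect_error(load_phenotypes(tf, cf), "line 2")
})

make_qc_table <- function(n = 10, seed = 1, outlier_at = NULL, z = 6) {
  set.seed(seed)
  desc <- c("length", "mean_depth", "width", "surface_area")
  df <- data.frame(subject_id = sprintf("s%02d", 1:n), cohort_id = "c1",
                   session = 1L, stringsAsFactors = FALSE)
  cols <- trait_name("S.C.", "left", desc)
  for (cc in cols) df[[cc]] <- rnorm(n, 10, 1)
  if (!is.null(outlier_at)) {
    v <- df[[cols[outlier_at$col]]]
    df[[cols[outlier_at$col]]][outlier_at$row] <-
      mean(v[-outlier_at$row]) + z * sd(v[-outlier_at$row])
  }
  as_phenotype_table <- sulcherit:::as_phenotype_table
  as_phenotype_table(df, cols)
}

test_that("z-score filter removes whole subject-sulcus units", {
  tab <- make_qc_table(outlier_at = list(row = 3, col = 1))
  res <- zscore_outlier_filter(tab, 2.5)
  cols <- trait_cols(tab)
  # subject 3 outlying only in length loses all four descriptors
  expect_true(all(is.na(res$table[3, cols])))
  expect_false(anyNA(res$table[-3, cols]))
  expect_equal(attr(res$report, "n_subject_sulcus_removed"), 1)

  # brute-force z-score recomputation agrees on who is discarded
  vals <- as.matrix(tab[, cols])
  z <- sweep(sweep(vals, 2, colMeans(vals)), 2, apply(vals, 2, sd), "/")
  expect_equal(which(apply(abs(z) > 2.5, 1, any)), 3L)

  # clean table is untouched
  tab2 <- make_qc_table(seed = 2)
  res2 <- zscore_outlier_filter(tab2, 2.5)
  expect_identical(as.data.frame(res2$table), as.data.frame(tab2))
  expect_equal(attr(res2$report, "n_subject_sulcus_removed"), 0)

  expect_error(zscore_outlier_filter(tab, -1), "positive")
})

test_that("post-filter missingness is identical across descriptors of a sulcus", {
  set.seed(11)
  tab <- make_qc_table(n = 40)
  cols <- trait_cols(tab)
  for (cc in cols) tab[[cc]][sample(40, 1)] <- tab[[cc]][1] + 8
  res <- zscore_outlier_filter(tab, 2.5)
  miss <- lapply(cols, function(cc) which(is.na(res$table[[cc]])))
  expect_true(all(vapply(miss, identical, TRUE, miss[[1]])))
})

test_that("bilateral averaging is the L/R mean with missing propagation", {
  df <- data.frame(subject_id = c("s1", "s2", "s3"), cohort_id = "c1",
                   session = 1L)
  df[[trait_name("S.C.", "left", "length")]] <- c(2, NA, 7)
  df[[trait_name("S.C.", "right", "length")]] <- c(4, 5, 7)
  tab <- sulcherit:::as_phenotype_table(
    df, c(trait_name("S.C.", "left", "length"),
          trait_name("S.C.", "right", "length")))
  out <- bilateral_average(tab)
  b <- out[[trait_name("S.C.", "bilateral_avg", "length")]]
  expect_equal(b, c(3, NA, 7))
})

test_that("design matrices encode the covariate set with centered age", {
  tab <- data.frame(subject_id = sprintf("s%d", 1:4),
                    age = c(20, 24, 28, 32),
                    sex = c("male", "female", "male", "female"),
                    icv = c(1.4e6, 1.5e6, 1.6e6, 1.5e6))
  X <- build_design_matrix(tab, c("age", "sex"))
  expect_equal(colnames(X), c("intercept", "age", "sex"))
  expect_equal(unname(X[, "age"]), c(-6, -2, 2, 6))

  tab8 <- data.frame(subject_id = sprintf("s%d", 1:8),
                     age = c(20, 24, 28, 32, 21, 26, 29, 35),
                     sex = rep(c("male", "female"), 4),
                     icv = c(1.4, 1.5, 1.6, 1.5, 1.45, 1.55, 1.38, 1.62) * 1e6)
  X2 <- build_design_matrix(tab8)
  expect_equal(ncol(X2), 7)
  # interaction column is the elementwise product of centered age and sex
  sexc <- rep(c(1, -1), 4)
  expect_equal(unname(X2[, "agexsex"]), unname(X2[, "age"]) * sexc)
  expect_equal(unname(X2[, "age2xsex"]), unname(X2[, "age2"]) * sexc)

  # single-sex cohort: sex column dropped with a warning
  tab$sex <- "male"
  expect_warning(X3 <- build_design_matrix(tab, c("age", "sex")), "constant")
  expect_equal(colnames(X3), c("intercept", "age"))

  tab$age <- NA_real_
  expect_error(build_design_matrix(tab, "age"), "all-missing")
})

test_that("residualize-and-normalize yields N(0,1) traits per cohort", {
  set.seed(5)
  mk <- function(cohort, scale) {
    n <- 80
    df <- data.frame(subject_id = sprintf("%s_s%02d", cohort, 1:n),
                     cohort_id = cohort, session = 1L,
                     age = runif(n, 20, 30),
                     sex = sample(c("male", "female"), n, TRUE),
                     icv = rnorm(n, 1.5e6, 1e5))
    df[[trait_name("S.C.", "left", "length")]] <-
      scale * (5 + 0.5 * df$age + rnorm(n))
    sulcherit:::as_phenotype_table(df, trait_name("S.C.", "left", "length"))
  }
  t1 <- mk("c1", 1); t2 <- mk("c2", 10)  # 10x trait scale difference
  out <- residualize_and_normalize(list(t1, t2), covariates = c("age", "sex"))
  tc <- trait_name("S.C.", "left", "length")
  for (co in c("c1", "c2")) {
    v <- out[[tc]][out$cohort_id == co]
    expect_lt(abs(mean(v)), 1e-10)
    expect_lt(abs(var(v) - 1), 0.05)
  }
  # single cohort equals inverse-normal of own residuals
  solo <- residualize_and_normalize(list(t1), covariates = c("age", "sex"))
  X <- build_design_matrix(t1, c("age", "sex"))
  res <- lm.fit(X, t1[[tc]])$residuals
  expect_equal(solo[[tc]], inverse_normal(res))

  # too-few-subjects cohort is named in the error
  t3 <- mk("tiny", 1)[1:3, ]
  attr(t3, "trait_cols") <- tc
  expect_error(residualize_and_normalize(list(t3), c("age", "sex")), "tiny")
})
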