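# Small pedigree fixtures built in code.

ped_df <- function(id, fam, fa, mo, sex, mz = NA_character_) {
  data.frame(individual_id = id, family_id = fam, father_id = fa,
             mother_id = mo, sex = sex, mz_group = mz,
             stringsAsFactors = FALSE)
}

# founders a,b with children c,d (full sibs)
nuclear_ped <- function(mz = FALSE) {
  pedigree(ped_df(
    id = c("a", "b", "c", "d"), fam = "f1",
    fa = c(NA, NA, "a", "a"), mo = c(NA, NA, "b", "b"),
    sex = c("male", "female", "male", "male"),
    mz = if (mz) c(NA, NA, "T1", "T1") else NA_character_))
}

# three generations incl. a first-cousin mating; 20 members
cousin_mating_ped <- function() {
  pedigree(ped_df(
    id = c("g1", "g2",                       # generation 1 couple
           "c1", "c2", "c3",                 # their children
           "s1", "s2", "s3",                 # spouses marrying in
           "k1", "k2", "k3", "k4", "k5",     # grandchildren
           "s4", "s5",                       # spouses of k-branch
           "m1", "m2",                       # first-cousin couple children
           "x1", "x2", "x3"),                # great-grandchildren (m1 x m2 inbred)
    fam = "f1",
    fa = c(NA, NA,
           "g1", "g1", "g1",
           NA, NA, NA,
           "c1", "c1", "c2", "c2", "c3",
           NA, NA,
           "c1", "c2",
           "m1", "m1", "m1"),
    mo = c(NA, NA,
           "g2", "g2", "g2",
           NA, NA, NA,
           "s1", "s1", "s2", "s2", "s3",
           NA, NA,
           "s1", "s2",
           "m2", "m2", "m2"),
    sex = c("male", "female",
            "male", "male", "female",
            "female", "female", "male",
            "male", "female", "male", "female", "male",
            "female", "male",
            "male", "female",
            "male", "female", "male")))
}

# random 3-generation pedigree for property tests
random_3gen_ped <- function(seed) {
  set.seed(seed)
  rows <- list()
  add <- function(id, fa, mo, sex) {
    rows[[length(rows) + 1]] <<- ped_df(id, "f1", fa, mo, sex)
  }
  add("g1a", NA, NA, "male"); add("g1b", NA, NA, "female")
  n_kids <- sample(2:4, 1)
  for (k in seq_len(n_kids)) {
    kid <- paste0("k", k)
    add(kid, "g1a", "g1b", sample(c("male", "female"), 1))
    add(paste0("sp", k), NA, NA, "female")
    for (g in seq_len(sample(0:3, 1))) {
      add(paste0("gc", k, "_", g), kid, paste0("sp", k),
          sample(c("male", "female"), 1))
    }
  }
  pedigree(do.call(rbind, rows))
}

twin_cohort <- function(seed, n_families = 200, true_h2 = 0.5, ...) {
  cfg <- sim_config(seed = seed, design = "mz_dz_twins",
                    n_families = n_families, true_h2 = true_h2,
                    extra_sib_prob = 0, mz_exact = TRUE, ...)
  ped <- simulate_pedigree(cfg)
  K <- compute_kinship(ped)
  list(cfg = cfg, ped = ped, K = K)
}

trait_vec <- function(tab, col, session = 1) {
  sub <- tab[tab$session == session, ]
  stats::setNames(sub[[col]], sub$subject_id)
}
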