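#' Pedigree objects
#'
#' A `pedigree` is a validated data frame of individuals with parent links,
#' sex, optional monozygotic (MZ) twin group membership, and family/cohort
#' labels. Founders have missing parents. All members of one MZ group are
#' treated as genetically identical when kinship is computed.
#'
#' @param df Data frame with columns `individual_id`, `family_id`,
#'   `father_id`, `mother_id`, `sex`, and optionally `mz_group`, `cohort_id`.
#'   Missing parents are `NA`; `"0"` and `""` are also accepted as absent.
#' @return An object of class `pedigree` (a data frame).
#' @export
pedigree <- function(df) {
  req <- c("individual_id", "family_id", "father_id", "mother_id", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("pedigree is missing columns: ", paste(miss, collapse = ", "))
  df$individual_id <- as.character(df$individual_id)
  df$family_id <- as.character(df$family_id)
  for (col in c("father_id", "mother_id")) {
    v <- as.character(df[[col]])
    v[v %in% c("0", "", "NA") | is.na(v)] <- NA_character_
    df[[col]] <- v
  }
  df$sex <- normalize_sex(df$sex)
  if (is.null(df$mz_group)) df$mz_group <- NA_character_
  v <- as.character(df$mz_group)
  v[v %in% c("0", "", "NA") | is.na(v)] <- NA_character_
  df$mz_group <- v
  if (is.null(df$cohort_id)) df$cohort_id <- "cohort1"
  df$cohort_id <- as.character(df$cohort_id)

  dup <- df$individual_id[duplicated(df$individual_id)]
  if (length(dup))
    stop("duplicate individual_id in pedigree: ", paste(unique(dup), collapse = ", "))
  for (col in c("father_id", "mother_id")) {
    bad <- setdiff(stats::na.omit(df[[col]]), df$individual_id)
    if (length(bad))
      stop(sub("_id", "", col), " id not found in pedigree: ",
           paste(bad, collapse = ", "))
  }
  check_acyclic(df)
  check_mz_groups(df)
  structure(df, class = c("pedigree", "data.frame"))
}

normalize_sex <- function(x) {
  x <- tolower(as.character(x))
  out <- rep("unknown", length(x))
  out[x %in% c("m", "male", "1")] <- "male"
  out[x %in% c("f", "female", "2")] <- "female"
  out
}

# Kahn-style topological sort over parent->child edges; reports one
# individual on a cycle if no such order exists.
pedigree_order <- function(df) {
  ids <- df$individual_id
  idx <- stats::setNames(seq_along(ids), ids)
  fa <- idx[df$father_id]
  mo <- idx[df$mother_id]
  indeg <- (!is.na(fa)) + (!is.na(mo))
  children <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < length(ids)) {
    on_cycle <- ids[setdiff(seq_along(ids), ord)][1]
    stop("pedigree contains a cycle involving individual ", on_cycle)
  }
  ord
}

check_acyclic <- function(df) invisible(pedigree_order(df))

check_mz_groups <- function(df) {
  grp <- df$mz_group
  for (g in unique(stats::na.omit(grp))) {
    rows <- df[which(grp == g), ]
    same <- function(v) length(unique(ifelse(is.na(v), "<NA>", v))) == 1
    if (!same(rows$father_id) || !same(rows$mother_id))
      stop("MZ group ", g, " members do not share both parents")
    if (!same(rows$sex))
      stop("MZ group ", g, " members do not share sex")
  }
  invisible(TRUE)
}

#' Read a pedigree file
#'
#' Reads SOLAR-style (`famid,id,fa,mo,sex,mztwin`) or PLINK .fam-style
#' (`famid,id,fa,mo,sex`) pedigree tables. `"0"` or empty parent ids mean
#' founder. MZ twin groups are populated only by the `solar_like` dialect.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param dialect `"solar_like"` or `"fam_like"`.
#' @param cohort_id Cohort label attached to every individual.
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path, dialect = c("solar_like", "fam_like"),
                          cohort_id = "cohort1") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("famid", "id", "fa", "mo", "sex")
  if (dialect == "solar_like") need <- c(need, "mztwin")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("pedigree file lacks required columns: ", paste(miss, collapse = ", "))
  df <- data.frame(
    individual_id = raw$id,
    family_id = raw$famid,
    father_id = raw$fa,
    mother_id = raw$mo,
    sex = raw$sex,
    mz_group = if (dialect == "solar_like") raw$mztwin else NA_character_,
    cohort_id = cohort_id,
    stringsAsFactors = FALSE
  )
  pedigree(df)
}

#' Expected additive relationship matrix from a pedigree
#'
#' Computes kinship coefficients phi by the recursive tabular method over a
#' topological order (parents before children): phi_ii = (1 + phi_fa,mo)/2
#' and phi_ij = (phi_fa(i),j + phi_mo(i),j)/2, with absent parents
#' contributing zero. Every within-MZ-group pair is then overridden with the
#' self-kinship value, so MZ covariance equals self covariance. The returned
#' matrix holds the expected additive relationship 2*phi (1 on the diagonal
#' for non-inbred individuals, 0.5 for parent-offspring and full sibs).
#'
#' @param ped A [pedigree].
#' @return A `relatedness_matrix`: square symmetric numeric matrix with
#'   subject ids as dimnames and attribute `source = "pedigree"`.
#' @export
compute_kinship <- function(ped) {
  blocks <- kinship_block_list(ped)
  n <- nrow(ped)
  ids <- ped$individual_id
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (b in blocks) M[b$members, b$members] <- b$K
  new_relatedness(M, source = "pedigree")
}

# Expected additive relationship (2*phi) per connected pedigree component,
# as a list of (members, K) blocks; the building block behind
# compute_kinship() and the trait simulator (which never needs the dense
# cohort-wide matrix).
kinship_block_list <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  ids <- ped$individual_id
  idx <- stats::setNames(seq_len(n), ids)
  fa <- idx[ped$father_id]
  mo <- idx[ped$mother_id]
  # connected components through parent links: kinship is zero across
  # components, so the tabular recursion runs per component (cubic in
  # family size, not cohort size)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  for (i in seq_len(n)) {
    if (!is.na(fa[i])) link(i, fa[i])
    if (!is.na(mo[i])) link(i, mo[i])
  }
  comp <- vapply(seq_len(n), find, 0L)
  ord_global <- pedigree_order(ped)
  rank_global <- integer(n)
  rank_global[ord_global] <- seq_len(n)
  mz <- ped$mz_group
  lapply(split(seq_len(n), comp), function(members) {
    list(members = members,
         K = 2 * kinship_component(members, fa, mo, rank_global, mz))
  })
}

# Recursive tabular kinship over one connected component (global indices
# `members`), parents before children: phi_ii = (1 + phi_fa,mo)/2 and
# phi_ij = (phi_fa(i),j + phi_mo(i),j)/2, absent parents contributing 0.
kinship_component <- function(members, fa, mo, rank_global, mz) {
  m <- length(members)
  ms0 <- members
  members <- members[order(rank_global[members])]
  loc <- integer(max(members))
  loc[members] <- seq_len(m)
  lf <- ifelse(is.na(fa[members]), NA_integer_, loc[fa[members]])
  lm_ <- ifelse(is.na(mo[members]), NA_integer_, loc[mo[members]])
  phi <- matrix(0, m, m)
  for (i in seq_len(m)) {
    f <- lf[i]; mo_i <- lm_[i]
    phi[i, i] <- if (!is.na(f) && !is.na(mo_i)) 0.5 * (1 + phi[f, mo_i]) else 0.5
    if (i > 1L) {
      dn <- seq_len(i - 1L)
      pf <- if (!is.na(f)) phi[f, dn] else 0
      pm <- if (!is.na(mo_i)) phi[mo_i, dn] else 0
      v <- 0.5 * (pf + pm)
      phi[i, dn] <- v
      phi[dn, i] <- v
    }
  }
  mzl <- mz[members]
  for (g in unique(stats::na.omit(mzl))) {
    grp <- which(mzl == g)
    for (i in grp) for (j in grp) {
      if (i != j) phi[i, j] <- phi[i, i]
    }
  }
  # restore the caller's member order
  back <- match(ms0, members)
  phi[back, back, drop = FALSE]
}

new_relatedness <- function(M, source, psd_warn = FALSE) {
  structure(M, class = c("relatedness_matrix", "matrix"),
            source = source, psd_warning = psd_warn)
}

#' Read a precomputed relatedness matrix
#'
#' Ingests an externally computed expected additive relationship matrix
#' (for example a genomic relationship matrix) from a TSV with subject ids
#' as both header row and first column. The matrix is symmetrized as
#' (M + t(M))/2; a warning is raised (and recorded in the `psd_warning`
#' attribute) when the smallest eigenvalue is below -1e-6.
#'
#' @param path Path to the TSV file.
#' @return A `relatedness_matrix` with attribute `source = "external"`.
#' @export
read_relatedness_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  M <- as.matrix(raw)
  if (nrow(M) != ncol(M))
    stop("relatedness matrix is not square: ", nrow(M), " x ", ncol(M))
  if (!identical(rownames(M), colnames(M)))
    stop("relatedness matrix row ids do not match column ids")
  M <- (M + t(M)) / 2
  ev_min <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  psd_warn <- ev_min < -1e-6
  if (psd_warn)
    warning("relatedness matrix is not positive semi-definite (min eigenvalue ",
            signif(ev_min, 3), ")")
  if (all(abs(M[upper.tri(M)]) < 1e-12))
    warning("all off-diagonal relatedness is zero: subjects appear unrelated")
  new_relatedness(M, source = "external", psd_warn = psd_warn)
}

#' Monte Carlo relatedness by gene dropping
#'
#' Independent check of [compute_kinship]: founders receive unique allele
#' labels, alleles propagate down the pedigree by Mendelian sampling, and the
#' expected additive relationship is estimated as twice the average
#' probability that randomly drawn alleles from two individuals are identical
#' by descent. MZ group members copy the same gamete outcomes.
#'
#' @param ped A [pedigree].
#' @param n_drops Number of independent allele drops.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return A `relatedness_matrix` with attribute `source = "gene_drop"` and
#'   attribute `mc_se` holding the per-entry Monte Carlo standard error.
#' @export
gene_drop_oracle <- function(ped, n_drops = 10000, seed = 1) {
  stopifnot(inherits(ped, "pedigree"), n_drops >= 1)
  set.seed(seed)
  n <- nrow(ped)
  ids <- ped$individual_id
  idx <- stats::setNames(seq_len(n), ids)
  ord <- pedigree_order(ped)
  fa <- idx[ped$father_id]
  mo <- idx[ped$mother_id]
  # allele labels per (individual, drop); founders get unique labels
  a1 <- matrix(0L, n, n_drops)
  a2 <- matrix(0L, n, n_drops)
  next_label <- 1L
  # MZ members reuse their group representative's gametes
  mz_rep <- seq_len(n)
  for (g in unique(stats::na.omit(ped$mz_group))) {
    members <- which(ped$mz_group == g)
    mz_rep[members] <- members[1]
  }
  for (i in ord) {
    r <- mz_rep[i]
    if (r != i) { a1[i, ] <- a1[r, ]; a2[i, ] <- a2[r, ]; next }
    f <- fa[i]; m <- mo[i]
    if (is.na(f)) {
      a1[i, ] <- next_label; next_label <- next_label + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      a1[i, ] <- ifelse(pick, a1[f, ], a2[f, ])
    }
    if (is.na(m)) {
      a2[i, ] <- next_label; next_label <- next_label + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      a2[i, ] <- ifelse(pick, a1[m, ], a2[m, ])
    }
  }
  est <- matrix(0, n, n, dimnames = list(ids, ids))
  mc_se <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      share <- (a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
        (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])
      est[i, j] <- est[j, i] <- mean(share) / 2
      mc_se[i, j] <- mc_se[j, i] <- stats::sd(share) / (2 * sqrt(n_drops))
    }
  }
  out <- new_relatedness(est, source = "gene_drop")
  attr(out, "mc_se") <- mc_se
  out
}
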