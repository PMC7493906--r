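# Shared machinery: partition subjects into connected pedigree components
# from the relatedness matrix and rotate each block into the eigenbasis of
# its relationship submatrix. In the rotated coordinates the AE covariance
# sigma_p2 * (h2*K + (1-h2)*I) is diagonal with weights h2*d + (1-h2), so
# every likelihood evaluation is O(n) after a one-off per-block
# eigendecomposition (cubic per family, not per cohort).

vc_components <- function(K, tol = 1e-10) {
  n <- nrow(K)
  nz <- which(abs(K) > tol)  # linear indices, fast C scan
  ri_all <- (nz - 1L) %% n + 1L
  rj_all <- (nz - 1L) %/% n + 1L
  keep <- ri_all < rj_all
  ri_all <- ri_all[keep]; rj_all <- rj_all[keep]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(ri_all)) {
    ri <- find(ri_all[e]); rj <- find(rj_all[e])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), find, 0L)
}

vc_rotate <- function(y_mat, X, K) {
  n <- nrow(K)
  comp <- vc_components(K)
  d <- numeric(n)
  Ys <- matrix(0, n, ncol(y_mat))
  Xs <- matrix(0, n, ncol(X))
  pos <- 0L
  ev_min <- Inf
  # eigendecompositions cached by block pattern: twin cohorts repeat a few
  # small relationship blocks thousands of times
  eig_cache <- new.env(parent = emptyenv())
  for (ii in split(seq_len(n), comp)) {
    m <- length(ii)
    sl <- pos + seq_len(m)
    if (m == 1L) {
      ev_min <- min(ev_min, K[ii, ii])
      d[sl] <- max(K[ii, ii], 0)
      Ys[sl, ] <- y_mat[ii, , drop = FALSE]
      Xs[sl, ] <- X[ii, , drop = FALSE]
    } else {
      Kb <- K[ii, ii]
      key <- paste(round(Kb, 8), collapse = ",")
      ee <- eig_cache[[key]]
      if (is.null(ee)) {
        ee <- eigen(Kb, symmetric = TRUE)
        eig_cache[[key]] <- ee
      }
      ev_min <- min(ev_min, ee$values)
      d[sl] <- pmax(ee$values, 0)
      Ys[sl, ] <- crossprod(ee$vectors, y_mat[ii, , drop = FALSE])
      Xs[sl, ] <- crossprod(ee$vectors, X[ii, , drop = FALSE])
    }
    pos <- pos + m
  }
  if (ev_min < -1e-8 * n)
    stop("relatedness matrix is not positive semi-definite")
  list(y = Ys, X = Xs, d = d, n = n)
}

# Profile log-likelihood of the univariate AE model at a given h2:
# beta by GLS, sigma_p2 by its closed-form ML value.
uni_profile_ll <- function(h2, rot) {
  w <- h2 * rot$d + (1 - h2)
  if (any(w <= 0)) return(list(ll = -Inf))
  sw <- sqrt(w)
  Xw <- rot$X / sw
  yw <- rot$y[, 1] / sw
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  n <- rot$n
  s2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + sum(log(w)) + n)
  list(ll = ll, beta = fit$coefficients, sigma_p2 = s2)
}

#' Univariate polygenic (AE) model fit
#'
#' Maximum-likelihood fit of the additive-genetic plus unique-environment
#' model: y = X beta + g + e with Cov(g) = K sigma_g2 and Cov(e) = I
#' sigma_e2, where K is the expected additive relationship matrix (2*phi).
#' Narrow-sense heritability h2 = sigma_g2 / sigma_p2 is profiled on [0, 1]
#' with beta and sigma_p2 estimated in closed form at each candidate value.
#' Significance of h2 uses the likelihood-ratio test against h2 = 0 with the
#' boundary null 0.5*chi2_0 + 0.5*chi2_1 (p = 1 when the LR statistic is 0).
#' The standard error of h2 comes from the curvature of the profile
#' log-likelihood (observed information), one-sided at the boundary.
#'
#' @param y Named numeric vector of trait values (names = subject ids).
#' @param X Design matrix with rownames = subject ids (intercept-only matrix
#'   is constructed when `NULL`).
#' @param K A `relatedness_matrix` covering the subjects.
#' @return Object of class `univariate_vc_fit`: list with `h2`, `sigma_g2`,
#'   `sigma_e2`, `sigma_p2`, `beta`, `se_h2`, `loglik`, `loglik_null`,
#'   `p_h2`, `n_used`, `converged`, `diagnostics`.
#' @export
fit_univariate <- function(y, X = NULL, K) {
  if (is.null(names(y))) stop("trait vector must carry subject ids as names")
  if (is.null(X)) {
    X <- matrix(1, length(y), 1, dimnames = list(names(y), "intercept"))
  }
  ids <- Reduce(intersect, list(names(y), rownames(X), rownames(K)))
  keep <- ids[!is.na(y[ids]) & stats::complete.cases(X[ids, , drop = FALSE])]
  n <- length(keep)
  if (n <= ncol(X) + 2)
    stop("too few complete observations (", n, ") for the design")
  Ksub <- unclass(K)[keep, keep, drop = FALSE]
  off <- Ksub[upper.tri(Ksub)]
  if (all(abs(off) < 1e-10))
    stop("heritability unidentifiable for unrelated sample (K is identity)")
  rot <- vc_rotate(cbind(y[keep]), X[keep, , drop = FALSE], Ksub)

  obj <- function(h2) uni_profile_ll(h2, rot)$ll
  opt <- stats::optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-9)
  # guard the bracketing optimum against the boundaries
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, obj(0), obj(1))
  h2_hat <- cand[which.max(lls)]
  at <- uni_profile_ll(h2_hat, rot)
  ll0 <- obj(0)
  lambda <- 2 * (at$ll - ll0)
  p_h2 <- if (lambda <= 0) 1 else 0.5 * stats::pchisq(lambda, 1, lower.tail = FALSE)

  se_h2 <- profile_se(obj, h2_hat, lower = 0, upper = 1)
  structure(list(
    h2 = h2_hat,
    sigma_g2 = h2_hat * at$sigma_p2,
    sigma_e2 = (1 - h2_hat) * at$sigma_p2,
    sigma_p2 = at$sigma_p2,
    beta = stats::setNames(at$beta, colnames(X)),
    se_h2 = se_h2,
    loglik = at$ll,
    loglik_null = ll0,
    p_h2 = p_h2,
    n_used = n,
    converged = TRUE,
    diagnostics = list(
      boundary = h2_hat %in% c(0, 1),
      single_relative_class = length(unique(round(off[abs(off) > 1e-10], 6))) == 1
    )
  ), class = "univariate_vc_fit")
}

# SE from numerical curvature of a 1-D profile log-likelihood, stepping
# inward when the estimate sits on a box boundary.
profile_se <- function(obj, x, lower, upper, h = 1e-3) {
  x0 <- min(max(x, lower + h), upper - h)
  d2 <- (obj(x0 + h) - 2 * obj(x0) + obj(x0 - h)) / h^2
  if (!is.finite(d2) || d2 >= 0) return(NA_real_)
  sqrt(-1 / d2)
}

#' @export
print.univariate_vc_fit <- function(x, ...) {
  cat("Univariate AE variance-components fit\n")
  cat(sprintf("  n = %d, h2 = %.4f (SE %.4f), p[h2=0] = %.3g\n",
              x$n_used, x$h2, x$se_h2, x$p_h2))
  cat(sprintf("  sigma_g2 = %.4f, sigma_e2 = %.4f, logLik = %.3f\n",
              x$sigma_g2, x$sigma_e2, x$loglik))
  invisible(x)
}

#' Falconer twin-correlation heritability estimate
#'
#' Classical approximation used as an independent check on the
#' likelihood-based fit: under the AE model the MZ pair correlation equals
#' h2 and the DZ pair correlation equals h2/2, so h2 ~ 2 (r_MZ - r_DZ).
#' The value is not clamped and may fall outside [0, 1].
#'
#' @param mz_pairs,dz_pairs Two-column matrices, one pair per row.
#' @return Numeric heritability estimate.
#' @export
falconer_estimate <- function(mz_pairs, dz_pairs) {
  mz_pairs <- as.matrix(mz_pairs); dz_pairs <- as.matrix(dz_pairs)
  if (nrow(mz_pairs) < 2 || nrow(dz_pairs) < 2)
    stop("need at least 2 pairs of each zygosity")
  r_mz <- stats::cor(mz_pairs[, 1], mz_pairs[, 2])
  r_dz <- stats::cor(dz_pairs[, 1], dz_pairs[, 2])
  2 * (r_mz - r_dz)
}
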