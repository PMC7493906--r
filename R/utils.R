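#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Symmetric matrix square root via eigendecomposition; eigenvalues below
# `tol` are clipped to zero so exactly-singular covariances (MZ twins) work.
mat_sqrt <- function(S, tol = 1e-10) {
  ee <- eigen(S, symmetric = TRUE)
  lam <- pmax(ee$values, 0)
  if (min(ee$values) < -tol * max(abs(ee$values), 1))
    stop("covariance matrix is not positive semi-definite")
  ee$vectors %*% (sqrt(lam) * t(ee$vectors))
}

# Draw n iid N(0, S) vectors (rows) without requiring S to be full rank.
rmvn_psd <- function(n, S) {
  R <- mat_sqrt(S)
  z <- matrix(stats::rnorm(n * ncol(S)), n, ncol(S))
  z %*% t(R)
}

#' Rank-based inverse-normal transform
#'
#' Maps a numeric vector to normal quantiles of its mid-ranks
#' (Blom offset 3/8), preserving missing values.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length with mean approximately 0 and
#'   variance approximately 1 among non-missing entries.
#' @export
inverse_normal <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n > 0) {
    r <- rank(x[ok], ties.method = "average")
    out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  }
  out
}
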