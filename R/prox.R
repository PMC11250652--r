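# Proximal / orthogonalization primitives: singular value thresholding
# and thin-QR orthonormalization.

#' Singular value thresholding (SVT)
#'
#' Soft-thresholds the singular values of a matrix:
#' `SVT_tau(Z) = U diag(max(sigma - tau, 0)) V^T`.  This is the proximal
#' operator of the nuclear norm, i.e. the unique minimizer of
#' `tau * ||W||_* + 0.5 * ||W - Z||_F^2`.
#'
#' @param z numeric matrix with finite entries.
#' @param tau nonnegative threshold.
#' @return a list of class `"shrinkage_result"` with elements
#'   `matrix` (the thresholded matrix, same shape as `z`) and
#'   `rank_after` (number of singular values surviving the threshold).
#' @export
svt <- function(z, tau) {
  if (!is.matrix(z)) z <- as.matrix(z)
  if (!all(is.finite(z))) stop_shape("`z` contains non-finite entries")
  if (length(tau) != 1L || !is.finite(tau) || tau < 0)
    stop_shape("`tau` must be a single nonnegative number")
  sv <- svd(z)
  d <- pmax(sv$d - tau, 0)
  keep <- d > 0
  r <- sum(keep)
  out <- if (r == 0L) {
    matrix(0, nrow(z), ncol(z))
  } else {
    sv$u[, keep, drop = FALSE] %*%
      (d[keep] * t(sv$v[, keep, drop = FALSE]))
  }
  structure(list(matrix = out, rank_after = r), class = "shrinkage_result")
}

#' Thin-QR orthonormalization
#'
#' Returns the Q factor of the thin QR decomposition of an `I x R` matrix
#' (`I >= R`), under the sign convention that the R factor has a
#' nonnegative diagonal, which makes the result unique and deterministic
#' for full-column-rank input.  If the input is (numerically) rank
#' deficient, the deficient directions are completed deterministically by
#' the Householder construction (base [qr()] without pivoting yields
#' exactly orthonormal Q columns regardless of rank) and a warning is
#' emitted.
#'
#' @param m numeric matrix with `nrow(m) >= ncol(m)`.
#' @param tol relative tolerance for rank-deficiency detection.
#' @return an `I x R` matrix with orthonormal columns spanning (at least)
#'   the column space of `m`.
#' @export
orthonormalize_qr <- function(m, tol = 1e-12) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (nrow(m) < ncol(m))
    stop_shape("thin QR needs nrow >= ncol (got %d x %d)", nrow(m), ncol(m))
  qrm <- qr(m)
  q <- qr.Q(qrm)
  rdiag <- diag(qr.R(qrm))
  scale <- max(abs(rdiag), .Machine$double.xmin)
  if (any(abs(rdiag) <= tol * scale))
    warning(sprintf(
      "rank-deficient input (%d of %d columns); deficient directions completed deterministically",
      sum(abs(rdiag) <= tol * scale), ncol(m)), call. = FALSE)
  s <- sign(rdiag)
  s[s == 0] <- 1
  sweep(q, 2L, s, `*`)
}
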