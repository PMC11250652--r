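# Tucker model container and reconstruction.

#' Construct a Tucker model
#'
#' Bundles a core tensor `C` of shape `(R_1, ..., R_N)` with N factor
#' matrices `U_i` of shape `I_i x R_i`, each required to have orthonormal
#' columns (`t(U_i) %*% U_i = I_{R_i}` within `tol`).
#'
#' @param core numeric array, the core tensor.
#' @param factors list of factor matrices, one per mode.
#' @param tol orthonormality tolerance for validation.
#' @return an object of class `"tucker_model"`.
#' @export
tucker_model <- function(core, factors, tol = 1e-10) {
  check_tensor(core, "core")
  rank <- dim(core)
  if (length(factors) != length(rank))
    stop_shape("need %d factor matrices, got %d", length(rank), length(factors))
  for (i in seq_along(factors)) {
    u <- factors[[i]]
    if (!is.matrix(u) || ncol(u) != rank[i])
      stop_shape("factor %d must be a matrix with %d columns", i, rank[i])
    if (nrow(u) < ncol(u))
      stop_shape("factor %d has more columns (%d) than rows (%d)",
                 i, ncol(u), nrow(u))
    dev <- max(abs(crossprod(u) - diag(ncol(u))))
    if (dev > tol)
      stop_shape("factor %d columns are not orthonormal (deviation %.2e > %.1e)",
                 i, dev, tol)
  }
  structure(list(core = core, factors = factors), class = "tucker_model")
}

#' Reconstruct the full tensor from a Tucker model
#'
#' Returns `C x_1 U_1 x_2 ... x_N U_N`.  Its mode-n unfolding equals
#' `U_n C_(n) (U_N \%x\% ... \%x\% U_{n+1} \%x\% U_{n-1} \%x\% ... \%x\% U_1)^T`.
#'
#' @param model a [tucker_model()], or a core array if `factors` is given.
#' @param factors optional list of factor matrices (when `model` is a core).
#' @return the reconstructed array of shape `(I_1, ..., I_N)`.
#' @export
tucker_reconstruct <- function(model, factors = NULL) {
  if (inherits(model, "tucker_model")) {
    core <- model$core
    factors <- model$factors
  } else {
    core <- model
  }
  multi_mode_product(core, factors, transpose = FALSE)
}

#' @export
print.tucker_model <- function(x, ...) {
  cat("Tucker model\n")
  cat("  core:   ", paste(dim(x$core), collapse = " x "), "\n")
  cat("  factors:",
      paste(vapply(x$factors, function(u) paste(dim(u), collapse = "x"),
                   character(1)), collapse = ", "), "\n")
  invisible(x)
}

#' Weighted tensor nuclear norm
#'
#' Sum over modes of `alpha[i]` times the nuclear norm (sum of singular
#' values) of the mode-i unfolding.  Used to verify that an orthonormal
#' Tucker model's reconstruction and core share the same tensor nuclear
#' norm.
#'
#' @param x numeric array.
#' @param alpha nonnegative mode weights summing to 1; default uniform.
#' @return a scalar.
#' @export
tensor_nuclear_norm <- function(x, alpha = NULL) {
  N <- length(dim(x))
  if (is.null(alpha)) alpha <- rep(1 / N, N)
  sum(vapply(seq_len(N), function(i) {
    alpha[i] * sum(svd(unfold(x, i), nu = 0, nv = 0)$d)
  }, numeric(1)))
}
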