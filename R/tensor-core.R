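#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm sd
#' @importFrom utils write.csv head modifyList
NULL

# ---- validation helpers -----------------------------------------------------

stop_shape <- function(...) stop(sprintf(...), call. = FALSE)

check_tensor <- function(x, arg = deparse(substitute(x))) {
  if (!is.array(x) || !is.numeric(x))
    stop_shape("`%s` must be a numeric array", arg)
  if (length(dim(x)) < 2L)
    stop_shape("`%s` must have order >= 2 (got order %d)", arg, length(dim(x)))
  if (!all(is.finite(x)))
    stop_shape("`%s` contains non-finite entries", arg)
  invisible(x)
}

check_mode <- function(x, n) {
  N <- length(dim(x))
  if (length(n) != 1L || !is.numeric(n) || n != round(n) || n < 1L || n > N)
    stop_shape("mode index must be a single integer in 1..%d (got %s)",
               N, paste(n, collapse = ","))
  as.integer(n)
}

# ---- unfolding / folding ----------------------------------------------------

#' Mode-n unfolding (matricization) of a tensor
#'
#' Rearranges an order-N array into an `I_n x prod(I_j, j != n)` matrix.
#' Tensor entry `(i_1, ..., i_N)` lands at row `i_n` and column
#' `j = 1 + sum_{k != n} (i_k - 1) J_k` with `J_k = prod_{m < k, m != n} I_m`
#' (the Kolda-Bader convention: the remaining modes enumerate columns in
#' increasing order, earlier modes varying fastest).
#'
#' @param x numeric array of order N >= 2.
#' @param n mode along which to unfold (1-based).
#' @return a matrix of dimension `dim(x)[n]` by `prod(dim(x)[-n])`.
#' @seealso [fold()], [mode_product()]
#' @examples
#' x <- array(1:24, c(3, 4, 2))
#' dim(unfold(x, 1))  # 3 x 8
#' @export
unfold <- function(x, n) {
  check_tensor(x)
  n <- check_mode(x, n)
  d <- dim(x)
  if (n == 1L) {
    dim(x) <- c(d[1L], prod(d[-1L]))
    return(x)
  }
  perm <- c(n, seq_along(d)[-n])
  y <- aperm(x, perm)
  dim(y) <- c(d[n], prod(d[-n]))
  y
}

#' Fold a matrix back into a tensor along mode n
#'
#' Exact inverse of [unfold()] under the same index map.
#'
#' @param m matrix of dimension `shape[n]` by `prod(shape[-n])`.
#' @param n mode along which `m` was unfolded (1-based).
#' @param shape integer vector giving the target tensor extents.
#' @return a numeric array with `dim(shape)`.
#' @export
fold <- function(m, n, shape) {
  if (!is.matrix(m)) m <- as.matrix(m)
  shape <- as.integer(shape)
  N <- length(shape)
  if (length(n) != 1L || n < 1L || n > N)
    stop_shape("mode index must be in 1..%d", N)
  n <- as.integer(n)
  if (nrow(m) != shape[n] || ncol(m) != prod(shape[-n]))
    stop_shape("matrix %d x %d is inconsistent with shape (%s) at mode %d",
               nrow(m), ncol(m), paste(shape, collapse = ","), n)
  if (n == 1L) {
    dim(m) <- shape
    return(m)
  }
  dim(m) <- c(shape[n], shape[-n])
  aperm(m, order(c(n, seq_len(N)[-n])))
}

# ---- mode products ----------------------------------------------------------

#' Mode-n product of a tensor with a matrix
#'
#' Computes `Y = X x_n U`, defined through the unfolding identity
#' `Y_(n) = U X_(n)`: mode n of extent `I_n` is replaced by extent
#' `nrow(u)`.
#'
#' @param x numeric array.
#' @param u matrix with `ncol(u) == dim(x)[n]`.
#' @param n mode index (1-based).
#' @return array with mode-n extent `nrow(u)`.
#' @export
mode_product <- function(x, u, n) {
  n <- check_mode(x, n)
  if (!is.matrix(u)) u <- as.matrix(u)
  d <- dim(x)
  if (ncol(u) != d[n])
    stop_shape("matrix has %d columns but mode %d has extent %d",
               ncol(u), n, d[n])
  out_shape <- d
  out_shape[n] <- nrow(u)
  fold(u %*% unfold(x, n), n, out_shape)
}

#' Apply matrices along several modes at once
#'
#' Sequentially applies [mode_product()] along each non-skipped mode
#' (distinct modes commute, so the order does not affect the result).
#' With `transpose = TRUE` the transposed matrices are applied, e.g.
#' projecting a tensor onto Tucker factor subspaces.
#'
#' @param x numeric array of order N.
#' @param factors list of N matrices; `factors[[i]]` acts on mode i.
#'   A skipped mode's entry is ignored (may be NULL).
#' @param transpose apply `t(factors[[i]])` instead of `factors[[i]]`.
#' @param skip optional single mode index to leave untouched.
#' @return the multi-mode product array.
#' @export
multi_mode_product <- function(x, factors, transpose = FALSE, skip = NULL) {
  d <- dim(x)
  N <- length(d)
  if (length(factors) != N)
    stop_shape("need one factor per mode: got %d factors for order %d",
               length(factors), N)
  modes <- seq_len(N)
  if (!is.null(skip)) modes <- modes[modes != check_mode(x, skip)]
  for (i in modes) {
    u <- factors[[i]]
    if (transpose) u <- t(u)
    x <- mode_product(x, u, i)
  }
  x
}

# ---- inner product / norms --------------------------------------------------

#' Tensor inner product and Frobenius norm
#'
#' `tensor_inner(x, y)` is the sum of elementwise products of two
#' same-shaped tensors; `fnorm(x)` is `sqrt(tensor_inner(x, x))`.
#'
#' @param x,y numeric arrays of identical shape.
#' @return a scalar.
#' @export
tensor_inner <- function(x, y) {
  if (!identical(dim(x), dim(y)))
    stop_shape("inner product requires identical shapes")
  sum(x * y)
}

#' @rdname tensor_inner
#' @export
fnorm <- function(x) sqrt(sum(x^2))
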