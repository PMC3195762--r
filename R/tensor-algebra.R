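#' Mode-n unfolding (matricization) of a tensor
#'
#' Rearranges an order-N array into a matrix whose rows index mode `n` and
#' whose columns run over all remaining modes in increasing mode order, with
#' the earliest remaining mode varying fastest.  This is the fixed convention
#' used throughout the package; [fold()] is its exact inverse.
#'
#' @param x numeric array (any order >= 1); all entries must be finite.
#' @param mode integer mode index in `1..length(dim(x))`.
#' @return matrix of shape `(dim(x)[mode], prod(dim(x)[-mode]))`.
#' @seealso [fold()], [ttm()], [tucker_reconstruct()]
#' @examples
#' a <- array(1:8, c(2, 2, 2))
#' unfold(a, 1)  # [[1,3,5,7],[2,4,6,8]]
#' @export
unfold <- function(x, mode) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  n <- length(d)
  if (!is.numeric(mode) || length(mode) != 1L || is.na(mode) ||
      mode < 1L || mode > n || mode != round(mode)) {
    stop("'mode' must be a single integer in 1..", n)
  }
  mode <- as.integer(mode)
  perm <- c(mode, seq_len(n)[-mode])
  matrix(aperm(x, perm), nrow = d[mode])
}

#' Fold a matricization back into a tensor
#'
#' Exact inverse of [unfold()] under the same column-ordering convention.
#'
#' @param m matrix with `shape[mode]` rows and `prod(shape[-mode])` columns.
#' @param mode integer mode index the matrix was unfolded along.
#' @param shape integer vector of target tensor dimensions.
#' @return array with `dim = shape`.
#' @examples
#' a <- array(rnorm(30), c(2, 3, 5))
#' identical(fold(unfold(a, 2), 2, dim(a)), a)
#' @export
fold <- function(m, mode, shape) {
  shape <- as.integer(shape)
  n <- length(shape)
  if (mode < 1L || mode > n || mode != round(mode)) {
    stop("'mode' must be a single integer in 1..", n)
  }
  mode <- as.integer(mode)
  expected <- c(shape[mode], prod(shape[-mode]))
  if (!all(dim(m) == expected)) {
    stop(sprintf("matrix has shape (%s); expected (%s) for mode %d and shape (%s)",
                 paste(dim(m), collapse = ", "),
                 paste(expected, collapse = ", "),
                 mode, paste(shape, collapse = ", ")))
  }
  perm <- c(mode, seq_len(n)[-mode])
  aperm(array(m, dim = shape[perm]), order(perm))
}

#' Mode-n product of a tensor with a matrix
#'
#' Multiplies `u` against the mode-`mode` unfolding of `x` and folds back:
#' `unfold(ttm(x, u, n), n) == u %*% unfold(x, n)`.  The output replaces the
#' size of mode `n` by `nrow(u)`.  This is the `x_n` operator of Tucker
#' algebra.
#'
#' @param x numeric array.
#' @param u matrix with `ncol(u) == dim(x)[mode]`.
#' @param mode integer mode index.
#' @return array with mode-`mode` extent `nrow(u)`.
#' @export
ttm <- function(x, u, mode) {
  d <- dim(x)
  if (ncol(u) != d[mode]) {
    stop(sprintf("matrix has %d columns but tensor extent along mode %d is %d",
                 ncol(u), mode, d[mode]))
  }
  newd <- d
  newd[mode] <- nrow(u)
  fold(u %*% unfold(x, mode), mode, newd)
}

#' Tucker reconstruction from a core tensor and factor matrices
#'
#' Applies the mode products `core x_1 U1 x_2 U2 ... x_N UN`.  Factor `n`
#' must have as many columns as the core's extent along mode `n`; the output
#' extent along mode `n` is `nrow(factors[[n]])`.
#'
#' @param core numeric array (the Tucker core).
#' @param factors list of factor matrices, one per mode.
#' @return array of shape `sapply(factors, nrow)`.
#' @export
tucker_reconstruct <- function(core, factors) {
  d <- dim(core)
  if (length(factors) != length(d)) {
    stop("need one factor matrix per mode: core has ", length(d),
         " modes but ", length(factors), " factors supplied")
  }
  out <- core
  for (n in seq_along(factors)) {
    out <- ttm(out, factors[[n]], n)
  }
  out
}

#' Frobenius norm of a tensor
#'
#' @param x numeric array.
#' @return `sqrt(sum(x^2))`.
#' @export
fnorm <- function(x) sqrt(sum(x^2))

#' Normalized correlation between two same-shape tensors
#'
#' Pearson correlation of the flattened intensities, the similarity measure
#' used to compare an original volume with its low-rank reconstruction.
#'
#' @param a,b numeric arrays of identical shape.
#' @return scalar in `[-1, 1]`.
#' @export
normalized_correlation <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("tensors must have identical shape")
  }
  a <- as.vector(a); b <- as.vector(b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("normalized correlation undefined for zero-variance input")
  }
  stats::cor(a, b)
}

# Check a set of tensors: list of same-shape finite numeric arrays.
check_tensor_set <- function(samples) {
  if (!is.list(samples) || length(samples) == 0L) {
    stop("'samples' must be a non-empty list of same-shape numeric arrays")
  }
  d <- dim(samples[[1L]])
  if (is.null(d)) stop("samples must be arrays with a dim attribute")
  for (i in seq_along(samples)) {
    if (!identical(dim(samples[[i]]), d)) {
      stop(sprintf("sample %d has shape (%s); expected (%s)", i,
                   paste(dim(samples[[i]]), collapse = ", "),
                   paste(d, collapse = ", ")))
    }
    if (!all(is.finite(samples[[i]]))) {
      stop(sprintf("sample %d contains non-finite values", i))
    }
  }
  d
}
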