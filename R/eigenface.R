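#' Classical vectorized PCA ("eigenface") baseline
#'
#' Fits ordinary PCA to the flattened (vectorized) training volumes, the
#' baseline that GND-PCA is compared against.  Flattening uses the same
#' column-major mode ordering as [unfold()] with mode 1.  The eigenvectors
#' are computed by the M x M Gram-matrix trick, never materializing the
#' voxel-by-voxel covariance; components with eigenvalue below
#' `1e-12 * largest` are dropped, so at most `M - 1` components remain after
#' centering.
#'
#' @param x list of >= 2 same-shape numeric arrays.
#' @return object of class `"eigenface"`: list with `mean` (flattened mean
#'   vector), `basis` (matrix of orthonormal eigen-volume columns),
#'   `eigenvalues` (descending), `dims`, `n_train`.
#' @seealso [gndpca()], [predict.eigenface()]
#' @export
eigenface <- function(x) {
  d <- check_tensor_set(x)
  M <- length(x)
  if (M < 2L) stop("eigenface PCA needs at least 2 samples")
  X <- vapply(x, as.vector, numeric(prod(d)))     # p x M
  mu <- rowMeans(X)
  Xc <- X - mu
  G <- crossprod(Xc)                               # M x M Gram matrix
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > 1e-12 * max(e$values, .Machine$double.eps)
  vals <- e$values[keep]
  V <- e$vectors[, keep, drop = FALSE]
  basis <- Xc %*% V %*% diag(1 / sqrt(vals), nrow = length(vals))
  for (j in seq_len(ncol(basis))) {                # sign convention as gndpca
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) basis[, j] <- -basis[, j]
  }
  structure(list(mean = mu, basis = basis, eigenvalues = vals,
                 dims = d, n_train = M),
            class = "eigenface")
}

#' @rdname project
#' @export
project.eigenface <- function(object, newdata, ...) {
  if (!identical(dim(newdata), object$dims)) {
    stop("tensor shape does not match training shape")
  }
  drop(crossprod(object$basis, as.vector(newdata) - object$mean))
}

#' @rdname reconstruct
#' @export
reconstruct.eigenface <- function(object, core, ...) {
  k <- length(core)
  if (k > ncol(object$basis)) stop("more coefficients than basis vectors")
  v <- object$mean
  if (k > 0) {
    v <- v + object$basis[, seq_len(k), drop = FALSE] %*% core
  }
  array(v, dim = object$dims)
}

#' Predict method for eigenface models
#'
#' @param object an `"eigenface"` fit.
#' @param newdata a tensor of the training shape, or a list of them.
#' @param k number of leading components to use (0 gives the mean volume;
#'   default: all retained components).
#' @param type `"coefficients"` or `"reconstruction"`.
#' @param ... unused.
#' @export
predict.eigenface <- function(object, newdata, k = ncol(object$basis),
                              type = c("reconstruction", "coefficients"),
                              ...) {
  type <- match.arg(type)
  if (k < 0 || k > ncol(object$basis)) {
    stop("'k' must be between 0 and ", ncol(object$basis))
  }
  one <- function(t) {
    coefs <- project(object, t)[seq_len(k)]
    if (type == "coefficients") coefs else reconstruct(object, coefs)
  }
  if (is.list(newdata)) lapply(newdata, one) else one(newdata)
}

#' @export
print.eigenface <- function(x, ...) {
  cat("Eigenface (vectorized PCA) model\n")
  cat(sprintf("  training samples : %d volumes of shape (%s)\n",
              x$n_train, paste(x$dims, collapse = " x ")))
  cat(sprintf("  components       : %d (eigenvalues %.3g .. %.3g)\n",
              ncol(x$basis), max(x$eigenvalues), min(x$eigenvalues)))
  invisible(x)
}
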