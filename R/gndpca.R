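#' Generalized N-dimensional principal component analysis
#'
#' Fits per-mode orthonormal bases to a cohort of same-shape order-3 tensors
#' (volumes) under Tucker's model.  The cohort mean is subtracted, then the
#' factor matrices `U^(n)` are estimated by alternating per-mode eigen-updates
#' minimizing the total squared reconstruction error
#' \deqn{C = \sum_{i=1}^{M} \| A_i - B_i \times_1 U^{(1)} \times_2 U^{(2)}
#'   \times_3 U^{(3)} \|^2,}
#' where `B_i` is the core tensor (multilinear projection) of centered sample
#' `A_i`.  Each sweep updates, for every mode `n` in turn, `U^(n)` to the top
#' eigenvectors of the aggregate scatter of the samples' mode-n unfoldings
#' after projection onto the other modes' current factors; each such update
#' cannot increase the cost, so the recorded cost history is non-increasing.
#'
#' Initialization is deterministic by default: a HOSVD-style start where
#' `U^(n)` holds the leading left singular vectors of the concatenated mode-n
#' unfoldings of all centered samples.  Eigenvectors are sorted by descending
#' eigenvalue, with each vector's sign fixed so that its largest-magnitude
#' entry is positive; equal eigenvalues are left in index order.  This makes
#' results reproducible at the subspace level (the fitted subspaces are
#' unique; individual basis vectors are unique up to rotation only when
#' eigenvalues are distinct).
#'
#' @param x a list of numeric arrays, all of the same shape — the training
#'   cohort.  Works for any tensor order >= 1; the intended use is order 3.
#' @param ranks integer vector of per-mode ranks `(J1, ..., JN)`,
#'   `ranks[n] <= dim(x[[1]])[n]`.
#' @param max_iter maximum number of full alternating sweeps (>= 1).
#' @param tol relative cost-change convergence threshold (> 0); iteration
#'   stops when `(C_prev - C) <= tol * C_prev`.
#' @param init `"hosvd"` (deterministic, default) or `"random"` (orthonormal
#'   bases from a seeded Gaussian draw; for robustness experiments).
#' @param seed integer seed, used only when `init = "random"`.
#' @return an object of class `"gndpca"`: a list with components
#'   \item{mean}{training mean tensor;}
#'   \item{factors}{list of per-mode factor matrices with orthonormal
#'     columns;}
#'   \item{ranks}{the per-mode ranks;}
#'   \item{dims}{the training tensor shape;}
#'   \item{scores}{list of core tensors of the training samples;}
#'   \item{fit_history}{cost after every full sweep (non-increasing);}
#'   \item{converged}{logical, whether the tolerance was reached before
#'     `max_iter`;}
#'   \item{n_train}{number of training samples.}
#' @seealso [predict.gndpca()], [project()], [reconstruct()],
#'   [gndpca_cost()], [eigenface()]
#' @examples
#' set.seed(1)
#' cohort <- replicate(6, array(rnorm(8 * 8 * 4), c(8, 8, 4)),
#'                     simplify = FALSE)
#' fit <- gndpca(cohort, ranks = c(4, 4, 2))
#' fit
#' core <- project(fit, cohort[[1]])
#' rec  <- reconstruct(fit, core)
#' @export
gndpca <- function(x, ranks, max_iter = 50L, tol = 1e-6,
                   init = c("hosvd", "random"), seed = NULL) {
  init <- match.arg(init)
  d <- check_tensor_set(x)
  N <- length(d)
  ranks <- as.integer(ranks)
  if (length(ranks) != N) stop("'ranks' must have one entry per mode")
  if (any(ranks < 1L)) stop("all ranks must be >= 1")
  if (any(ranks > d)) {
    stop(sprintf("ranks (%s) exceed tensor shape (%s)",
                 paste(ranks, collapse = ", "), paste(d, collapse = ", ")))
  }
  if (max_iter < 1L) stop("'max_iter' must be >= 1")
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be > 0")

  M <- length(x)
  ctr <- tensor_center(x)
  mean_t <- ctr$mean
  xc <- ctr$centered
  energy <- sum(vapply(xc, function(t) sum(t^2), numeric(1)))

  factors <- if (init == "hosvd") {
    init_factors(xc, ranks, centered = TRUE)
  } else {
    if (!is.null(seed)) {
      old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
      set.seed(as.integer(seed))
    }
    lapply(seq_len(N), function(n) {
      qr.Q(qr(matrix(stats::rnorm(d[n] * ranks[n]), d[n], ranks[n])))
    })
  }

  history <- numeric(0)
  cost_prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (n in seq_len(N)) {
      # scatter of mode-n unfoldings after projecting the *other* modes
      # onto their current bases; shape I_n x I_n
      S <- matrix(0, d[n], d[n])
      for (i in seq_len(M)) {
        z <- xc[[i]]
        for (m in seq_len(N)[-n]) z <- ttm(z, t(factors[[m]]), m)
        zu <- unfold(z, n)
        S <- S + tcrossprod(zu)
      }
      factors[[n]] <- top_eigvec(S, ranks[n])
    }
    # Tucker projection is orthogonal, so cost = energy - sum ||core||^2
    core_energy <- 0
    for (i in seq_len(M)) {
      z <- xc[[i]]
      for (m in seq_len(N)) z <- ttm(z, t(factors[[m]]), m)
      core_energy <- core_energy + sum(z^2)
    }
    cost <- max(energy - core_energy, 0)
    history <- c(history, cost)
    if (is.finite(cost_prev) &&
        (cost_prev - cost) <= tol * max(cost_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    cost_prev <- cost
  }

  obj <- structure(list(
    mean = mean_t,
    factors = factors,
    ranks = ranks,
    dims = d,
    fit_history = history,
    converged = converged,
    n_train = M
  ), class = "gndpca")
  obj$scores <- lapply(x, function(t) project(obj, t))
  obj
}

#' Center a tensor cohort
#'
#' @param x list of same-shape numeric arrays.
#' @return list with `mean` (entrywise average) and `centered` (list of
#'   mean-subtracted samples, which sum to the zero tensor).
#' @export
tensor_center <- function(x) {
  d <- check_tensor_set(x)
  mean_t <- Reduce(`+`, x) / length(x)
  dim(mean_t) <- d
  list(mean = mean_t, centered = lapply(x, function(t) t - mean_t))
}

#' HOSVD-style initial factor matrices for a tensor cohort
#'
#' For each mode `n`, returns the top-`ranks[n]` left singular vectors of the
#' concatenated mode-n unfoldings of all (centered) samples — equivalently
#' the leading eigenvectors of the per-mode scatter.  This is the
#' deterministic starting point of the alternating iteration in [gndpca()].
#'
#' @param x list of same-shape numeric arrays (normally centered).
#' @param ranks integer vector of per-mode ranks.
#' @param centered ignored hint; kept for clarity at call sites.
#' @return list of matrices with orthonormal columns.
#' @export
init_factors <- function(x, ranks, centered = TRUE) {
  d <- check_tensor_set(x)
  ranks <- as.integer(ranks)
  if (any(ranks > d)) {
    stop(sprintf("ranks (%s) exceed tensor shape (%s)",
                 paste(ranks, collapse = ", "), paste(d, collapse = ", ")))
  }
  lapply(seq_along(d), function(n) {
    S <- matrix(0, d[n], d[n])
    for (t in x) {
      tu <- unfold(t, n)
      S <- S + tcrossprod(tu)
    }
    top_eigvec(S, ranks[n])
  })
}

# Leading k eigenvectors of a symmetric PSD matrix, eigenvalues descending,
# sign of each vector fixed so its largest-|entry| is positive.
top_eigvec <- function(S, k) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  U
}

#' Project a tensor onto a fitted GND-PCA model (core-tensor feature)
#'
#' Subtracts the training mean and applies `x_n U^(n)T` along every mode.
#' The resulting core tensor is the sample's low-dimensional feature.
#'
#' @param object a fitted model ([gndpca()] or [eigenface()]).
#' @param newdata a tensor of the training shape.
#' @param ... passed to methods.
#' @return core tensor with `dim = ranks` (for `gndpca`).
#' @export
project <- function(object, newdata, ...) UseMethod("project")

#' @rdname project
#' @export
project.gndpca <- function(object, newdata, ...) {
  if (!identical(dim(newdata), object$dims)) {
    stop(sprintf("tensor shape (%s) does not match training shape (%s)",
                 paste(dim(newdata), collapse = ", "),
                 paste(object$dims, collapse = ", ")))
  }
  z <- newdata - object$mean
  for (n in seq_along(object$factors)) z <- ttm(z, t(object$factors[[n]]), n)
  z
}

#' Reconstruct a tensor from a core-tensor feature
#'
#' Applies the Tucker reconstruction `core x_1 U1 ... x_N UN` and adds the
#' training mean back.
#'
#' @param object a fitted model ([gndpca()] or [eigenface()]).
#' @param core a core tensor of shape `ranks` (for `gndpca`) or a coefficient
#'   vector (for `eigenface`).
#' @param ... passed to methods.
#' @return tensor of the training shape.
#' @export
reconstruct <- function(object, core, ...) UseMethod("reconstruct")

#' @rdname reconstruct
#' @export
reconstruct.gndpca <- function(object, core, ...) {
  if (!identical(as.integer(dim(core)), object$ranks)) {
    stop(sprintf("core shape (%s) does not match model ranks (%s)",
                 paste(dim(core), collapse = ", "),
                 paste(object$ranks, collapse = ", ")))
  }
  tucker_reconstruct(core, object$factors) + object$mean
}

#' Predict method for GND-PCA models
#'
#' @param object a `"gndpca"` fit.
#' @param newdata a tensor of the training shape, or a list of such tensors.
#' @param type `"core"` for the core-tensor feature(s), `"reconstruction"`
#'   for the low-rank reconstruction(s).
#' @param ... unused.
#' @return a tensor (or list of tensors, matching `newdata`).
#' @export
predict.gndpca <- function(object, newdata,
                           type = c("core", "reconstruction"), ...) {
  type <- match.arg(type)
  one <- function(t) {
    core <- project(object, t)
    if (type == "core") core else reconstruct(object, core)
  }
  if (is.list(newdata)) lapply(newdata, one) else one(newdata)
}

#' Total reconstruction cost of a cohort under a fitted model
#'
#' The quantity minimized by [gndpca()]: the sum over samples of the squared
#' Frobenius distance between the centered sample and its Tucker
#' reconstruction at the model's ranks.
#'
#' @param object a `"gndpca"` fit.
#' @param x list of tensors of the training shape.
#' @return nonnegative scalar.
#' @export
gndpca_cost <- function(object, x) {
  d <- check_tensor_set(x)
  if (!identical(d, object$dims)) {
    stop("samples do not match the model's training shape")
  }
  sum(vapply(x, function(t) {
    z <- t - object$mean
    sum((z - tucker_reconstruct(project(object, t), object$factors))^2)
  }, numeric(1)))
}

#' @export
fitted.gndpca <- function(object, ...) {
  lapply(object$scores, function(core) reconstruct(object, core))
}

#' @export
coef.gndpca <- function(object, ...) object$factors

#' @export
print.gndpca <- function(x, ...) {
  cat("Generalized N-dimensional PCA model\n")
  cat(sprintf("  training samples : %d tensors of shape (%s)\n",
              x$n_train, paste(x$dims, collapse = " x ")))
  cat(sprintf("  ranks            : (%s)  [%d coefficients per sample]\n",
              paste(x$ranks, collapse = " x "), prod(x$ranks)))
  cat(sprintf("  sweeps           : %d (%s)\n", length(x$fit_history),
              if (x$converged) "converged" else "max_iter reached"))
  cat(sprintf("  final cost       : %.6g\n", utils::tail(x$fit_history, 1)))
  invisible(x)
}

#' @export
summary.gndpca <- function(object, ...) {
  energy <- sum(vapply(object$scores, function(b) sum(b^2), numeric(1))) +
    utils::tail(object$fit_history, 1)
  out <- list(
    dims = object$dims, ranks = object$ranks, n_train = object$n_train,
    sweeps = length(object$fit_history), converged = object$converged,
    cost = object$fit_history,
    explained = 1 - utils::tail(object$fit_history, 1) / max(energy, .Machine$double.eps),
    orthonormality = max(vapply(object$factors, function(U) {
      max(abs(crossprod(U) - diag(ncol(U))))
    }, numeric(1)))
  )
  class(out) <- "summary.gndpca"
  out
}

#' @export
print.summary.gndpca <- function(x, ...) {
  cat("GND-PCA model summary\n")
  cat(sprintf("  shape (%s), ranks (%s), M = %d\n",
              paste(x$dims, collapse = " x "),
              paste(x$ranks, collapse = " x "), x$n_train))
  cat(sprintf("  sweeps: %d, converged: %s\n", x$sweeps, x$converged))
  cat(sprintf("  centered energy explained at fitted ranks: %.4f\n",
              x$explained))
  cat(sprintf("  max factor orthonormality defect: %.2e\n", x$orthonormality))
  cat("  cost per sweep:\n")
  print(x$cost)
  invisible(x)
}

#' @export
plot.gndpca <- function(x, ...) {
  graphics::plot(seq_along(x$fit_history), x$fit_history, type = "b",
                 xlab = "sweep", ylab = "reconstruction cost",
                 main = "GND-PCA alternating iteration", ...)
  invisible(x)
}

#' Save / load a fitted model archive
#'
#' The archive is a single RDS file (serialization version 2) holding the
#' model list unchanged: components `mean`, `factors`, `ranks`, `dims`,
#' `scores`, `fit_history`, `converged`, `n_train` for GND-PCA models, and
#' the corresponding fields for [eigenface()] models.
#'
#' @param object a fitted `"gndpca"` or `"eigenface"` model.
#' @param path file path for the archive.
#' @return `read_model` returns the model object; `write_model` returns
#'   `path` invisibly.
#' @export
write_model <- function(object, path) {
  saveRDS(object, path, version = 2)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, c("gndpca", "eigenface"))) {
    stop("'", path, "' does not contain a gndpca or eigenface model")
  }
  obj
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run fn with a private RNG stream seeded by `seed`, restoring global state.
with_seed <- function(seed, fn) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  fn()
}
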