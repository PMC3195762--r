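#' Centered cubic B-spline kernel
#'
#' The standard third-order B-spline basis function: a piecewise cubic,
#' nonnegative, C2-continuous, supported on `[-2, 2]`, with `beta(0) = 2/3`,
#' `beta(1) = 1/6`, and the partition-of-unity property
#' `sum_k beta(a - k) = 1`.
#'
#' @param a numeric vector of evaluation points.
#' @return numeric vector of kernel values.
#' @export
bspline_kernel <- function(a) {
  a <- abs(a)
  out <- numeric(length(a))
  i1 <- a < 1
  i2 <- !i1 & a < 2
  out[i1] <- (4 - 6 * a[i1]^2 + 3 * a[i1]^3) / 6
  out[i2] <- (2 - a[i2])^3 / 6
  out
}

#' Rigid (rotation + translation) transform parameters
#'
#' Six parameters: rotation angles `theta = (theta_x, theta_y, theta_z)` in
#' radians and a translation `t` in physical units.  The rotation matrix is
#' composed as `R = Rz %*% Ry %*% Rx` and applied about the rotation
#' `center` (normally the physical center of the reference volume):
#' `T(x) = R (x - center) + center + t`.
#'
#' @param theta length-3 numeric, rotation angles in radians.
#' @param t length-3 numeric, translation in physical units.
#' @return object of class `"rigid_params"`.
#' @export
rigid_params <- function(theta = c(0, 0, 0), t = c(0, 0, 0)) {
  theta <- as.numeric(theta); t <- as.numeric(t)
  if (length(theta) != 3L || length(t) != 3L ||
      any(!is.finite(c(theta, t)))) {
    stop("'theta' and 't' must each be 3 finite numbers")
  }
  structure(list(theta = theta, t = t), class = "rigid_params")
}

rotation_matrix <- function(theta) {
  cx <- cos(theta[1]); sx <- sin(theta[1])
  cy <- cos(theta[2]); sy <- sin(theta[2])
  cz <- cos(theta[3]); sz <- sin(theta[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to points
#'
#' @param p numeric matrix of points, one per row (n x 3), or a length-3
#'   vector.
#' @param params a [rigid_params()] object.
#' @param center length-3 rotation center in physical coordinates.
#' @return transformed points, same shape as `p`.
#' @export
rigid_apply <- function(p, params, center = c(0, 0, 0)) {
  vec <- is.null(dim(p))
  if (vec) p <- matrix(p, nrow = 1)
  R <- rotation_matrix(params$theta)
  out <- sweep(p, 2, center) %*% t(R)
  out <- sweep(out, 2, center + params$t, `+`)
  if (vec) drop(out) else out
}

#' Cubic B-spline free-form deformation lattice
#'
#' A regular lattice of displacement control points over a reference
#' volume's physical extent.  `dims` gives the number of control intervals
#' per axis; the control spacing is `rho = extent / dims` where the extent
#' spans the reference voxel centers.  One padding layer of control points
#' is added on each side so every point of the domain has a full 4 x 4 x 4
#' support neighborhood, giving `dims + 3` control points per axis.
#'
#' @param dims length-3 integer, control intervals per axis (>= 1).
#' @param reference a [volume()] (or 3D array) defining the physical domain.
#' @param lambda optional coefficient array of shape
#'   `c(dims + 3, 3)` (per-control-point displacement vectors, physical
#'   units); defaults to all zeros (identity deformation).
#' @return object of class `"bspline_grid"` with fields `rho`, `dims`,
#'   `origin`, `lambda`.
#' @export
bspline_grid <- function(dims, reference, lambda = NULL) {
  reference <- as_volume(reference)
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) {
    stop("'dims' must be 3 integers >= 1")
  }
  extent <- (dim(reference$data) - 1) * reference$spacing
  rho <- extent / dims
  nctl <- dims + 3L
  if (is.null(lambda)) {
    lambda <- array(0, dim = c(nctl, 3L))
  } else {
    if (!identical(as.integer(dim(lambda)), c(nctl, 3L))) {
      stop(sprintf("lambda must have shape (%s); got (%s)",
                   paste(c(nctl, 3L), collapse = ", "),
                   paste(dim(lambda), collapse = ", ")))
    }
  }
  structure(list(rho = rho, dims = dims, origin = reference$origin,
                 lambda = lambda),
            class = "bspline_grid")
}

#' @export
print.bspline_grid <- function(x, ...) {
  cat(sprintf("B-spline FFD lattice: %s control intervals (+1 pad/side), rho = (%s)\n",
              paste(x$dims, collapse = " x "),
              paste(format(x$rho, digits = 4), collapse = ", ")))
  cat(sprintf("  max |coefficient| = %.4g\n", max(abs(x$lambda))))
  invisible(x)
}

#' FFD displacement at arbitrary points
#'
#' Evaluates the tensor-product cubic B-spline displacement
#' `sum_ijk lambda_ijk beta((x - phi_x)/rho_x) beta((y - phi_y)/rho_y)
#' beta((z - phi_z)/rho_z)` at each point, summing over the 4 x 4 x 4 active
#' control points.
#'
#' @param p points (n x 3 matrix or length-3 vector), physical coordinates.
#' @param grid a [bspline_grid()].
#' @param outside `"error"` (default) to reject points outside the padded
#'   lattice support, or `"zero"` to return zero displacement there.
#' @return displacement vectors, same shape as `p`.
#' @export
ffd_displacement <- function(p, grid, outside = c("error", "zero")) {
  outside <- match.arg(outside)
  vec <- is.null(dim(p))
  if (vec) p <- matrix(p, nrow = 1)
  u <- sweep(sweep(p, 2, grid$origin), 2, grid$rho, `/`)
  inside <- u[, 1] >= 0 & u[, 1] <= grid$dims[1] &
            u[, 2] >= 0 & u[, 2] <= grid$dims[2] &
            u[, 3] >= 0 & u[, 3] <= grid$dims[3]
  if (any(!inside)) {
    if (outside == "error") {
      stop("point(s) outside the B-spline lattice support")
    }
  }
  base <- pmin(pmax(floor(u), 0), matrix(grid$dims - 1L, nrow(u), 3,
                                         byrow = TRUE))
  disp <- matrix(0, nrow(p), 3)
  # 64 active control points: offsets -1..2 around the containing interval
  for (di in -1:2) for (dj in -1:2) for (dk in -1:2) {
    ci <- base[, 1] + di; cj <- base[, 2] + dj; ck <- base[, 3] + dk
    w <- bspline_kernel(u[, 1] - ci) * bspline_kernel(u[, 2] - cj) *
         bspline_kernel(u[, 3] - ck)
    # padded array index: control index -1 maps to 1
    lin <- (ci + 2L) +
           (cj + 1L) * dim(grid$lambda)[1] +
           (ck + 1L) * dim(grid$lambda)[1] * dim(grid$lambda)[2]
    for (d in 1:3) {
      disp[, d] <- disp[, d] +
        w * grid$lambda[lin + (d - 1L) * prod(dim(grid$lambda)[1:3])]
    }
  }
  disp[!inside, ] <- 0
  if (vec) drop(disp) else disp
}

# Per-axis B-spline basis matrix for all reference voxels: entry [v, c] is
# the kernel weight of (padded) control point c at voxel v along this axis.
bspline_basis_matrix <- function(nvox, spacing, rho, axis_dims) {
  u <- (seq_len(nvox) - 1) * spacing / rho          # lattice coordinates
  ctl <- seq.int(-1L, axis_dims + 1L)               # padded control indices
  outer(u, ctl, function(a, c) bspline_kernel(a - c))
}

# Dense displacement field of an FFD over a reference volume's voxel grid,
# evaluated separably: D_d = lambda_d x_1 Bx x_2 By x_3 Bz.
displacement_field <- function(grid, reference) {
  reference <- as_volume(reference)
  d <- dim(reference$data)
  B <- lapply(1:3, function(ax) {
    bspline_basis_matrix(d[ax], reference$spacing[ax], grid$rho[ax],
                         grid$dims[ax])
  })
  lapply(1:3, function(dd) {
    f <- grid$lambda[, , , dd, drop = FALSE]
    dim(f) <- dim(grid$lambda)[1:3]
    ttm(ttm(ttm(f, B[[1]], 1), B[[2]], 2), B[[3]], 3)
  })
}

#' Composite (rigid + FFD) transform
#'
#' The mapping `T(x) = T_global(x) + T_local(x)`: the rigid transform of the
#' point plus the B-spline displacement evaluated at the same point.
#'
#' @param rigid a [rigid_params()] (identity if omitted).
#' @param ffd a [bspline_grid()] or `NULL` for no local deformation.
#' @param center rigid rotation center (physical coordinates).
#' @return object of class `"composite_transform"`.
#' @export
composite_transform <- function(rigid = rigid_params(), ffd = NULL,
                                center = c(0, 0, 0)) {
  structure(list(rigid = rigid, ffd = ffd, center = as.numeric(center)),
            class = "composite_transform")
}

#' Apply a composite transform to points
#'
#' @param p points (n x 3 matrix or length-3 vector).
#' @param transform a [composite_transform()].
#' @param outside passed to [ffd_displacement()].
#' @return mapped points, same shape as `p`.
#' @export
composite_apply <- function(p, transform, outside = "error") {
  out <- rigid_apply(p, transform$rigid, transform$center)
  if (!is.null(transform$ffd)) {
    out <- out + ffd_displacement(p, transform$ffd, outside = outside)
  }
  out
}

#' Save / load a composite transform as JSON
#'
#' Serializes rigid parameters, rotation center, and (if present) the FFD
#' lattice (interval counts, spacing, origin, coefficient array flattened in
#' column-major order) to a structured JSON file.
#'
#' @param transform a [composite_transform()].
#' @param path JSON file path.
#' @export
write_transform <- function(transform, path) {
  obj <- list(rigid = list(theta = transform$rigid$theta,
                           t = transform$rigid$t),
              center = transform$center)
  if (!is.null(transform$ffd)) {
    g <- transform$ffd
    obj$ffd <- list(dims = g$dims, rho = g$rho, origin = g$origin,
                    lambda_dim = dim(g$lambda),
                    lambda = as.vector(g$lambda))
  }
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ffd <- NULL
  if (!is.null(obj$ffd)) {
    g <- obj$ffd
    ffd <- structure(list(rho = as.numeric(g$rho),
                          dims = as.integer(g$dims),
                          origin = as.numeric(g$origin),
                          lambda = array(as.numeric(g$lambda),
                                         dim = as.integer(g$lambda_dim))),
                     class = "bspline_grid")
  }
  composite_transform(rigid_params(obj$rigid$theta, obj$rigid$t),
                      ffd = ffd, center = as.numeric(obj$center))
}
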