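# Precompute the corner indices and weights of trilinear interpolation at
# continuous 0-based voxel indices (n x 3), so several arrays of the same
# shape can be sampled at the same points cheaply.
trilinear_prepare <- function(d, idx) {
  n <- nrow(idx)
  lo <- floor(idx)
  f <- idx - lo
  at_top <- idx == matrix(d - 1L, n, 3, byrow = TRUE)
  lo[at_top] <- lo[at_top] - 1
  f[at_top] <- 1
  valid <- lo[, 1] >= 0 & lo[, 1] <= d[1] - 2 &
           lo[, 2] >= 0 & lo[, 2] <= d[2] - 2 &
           lo[, 3] >= 0 & lo[, 3] <= d[3] - 2
  lo <- lo[valid, , drop = FALSE]
  fv <- f[valid, , drop = FALSE]
  base <- 1 + lo[, 1] + lo[, 2] * d[1] + lo[, 3] * d[1] * d[2]
  wx1 <- fv[, 1]; wx0 <- 1 - wx1
  wy1 <- fv[, 2]; wy0 <- 1 - wy1
  wz1 <- fv[, 3]; wz0 <- 1 - wz1
  list(n = n, valid = valid, base = base,
       sx = 1L, sy = d[1], sz = d[1] * d[2],
       w = list(wx0 * wy0 * wz0, wx1 * wy0 * wz0,
                wx0 * wy1 * wz0, wx1 * wy1 * wz0,
                wx0 * wy0 * wz1, wx1 * wy0 * wz1,
                wx0 * wy1 * wz1, wx1 * wy1 * wz1))
}

trilinear_apply <- function(arr, prep, background = 0) {
  out <- rep(background, prep$n)
  if (length(prep$base) == 0L) return(out)
  b <- prep$base; sx <- prep$sx; sy <- prep$sy; sz <- prep$sz
  w <- prep$w
  out[prep$valid] <-
    arr[b]                * w[[1]] + arr[b + sx]           * w[[2]] +
    arr[b + sy]           * w[[3]] + arr[b + sx + sy]      * w[[4]] +
    arr[b + sz]           * w[[5]] + arr[b + sx + sz]      * w[[6]] +
    arr[b + sy + sz]      * w[[7]] + arr[b + sx + sy + sz] * w[[8]]
  out
}

# Vectorized trilinear interpolation of a 3D array at continuous 0-based
# voxel indices (n x 3).  Points outside the array get `background`.
trilinear_interp <- function(arr, idx, background = 0) {
  d <- dim(arr)
  n <- nrow(idx)
  lo <- floor(idx)
  f <- idx - lo
  # valid if the full 8-corner cell is inside (allow exact upper boundary)
  at_top <- idx >= matrix(d - 1L, n, 3, byrow = TRUE) &
            idx <= matrix(d - 1L, n, 3, byrow = TRUE)
  lo[at_top] <- lo[at_top] - 1
  f[at_top] <- 1
  valid <- lo[, 1] >= 0 & lo[, 1] <= d[1] - 2 &
           lo[, 2] >= 0 & lo[, 2] <= d[2] - 2 &
           lo[, 3] >= 0 & lo[, 3] <= d[3] - 2
  out <- rep(background, n)
  if (!any(valid)) return(out)
  lo <- lo[valid, , drop = FALSE]
  fv <- f[valid, , drop = FALSE]
  # 1-based linear index of the low corner
  base <- 1 + lo[, 1] + lo[, 2] * d[1] + lo[, 3] * d[1] * d[2]
  sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
  wx1 <- fv[, 1]; wx0 <- 1 - wx1
  wy1 <- fv[, 2]; wy0 <- 1 - wy1
  wz1 <- fv[, 3]; wz0 <- 1 - wz1
  acc <- arr[base]                      * wx0 * wy0 * wz0 +
         arr[base + sx]                 * wx1 * wy0 * wz0 +
         arr[base + sy]                 * wx0 * wy1 * wz0 +
         arr[base + sx + sy]            * wx1 * wy1 * wz0 +
         arr[base + sz]                 * wx0 * wy0 * wz1 +
         arr[base + sx + sz]            * wx1 * wy0 * wz1 +
         arr[base + sy + sz]            * wx0 * wy1 * wz1 +
         arr[base + sx + sy + sz]       * wx1 * wy1 * wz1
  out[valid] <- acc
  out
}

# Physical coordinates of every voxel center of a volume, as an n x 3
# matrix in array (column-major) order.
voxel_coordinates <- function(v) {
  d <- dim(v$data)
  g <- expand.grid(x = seq_len(d[1]) - 1, y = seq_len(d[2]) - 1,
                   z = seq_len(d[3]) - 1)
  sweep(sweep(as.matrix(g), 2, v$spacing, `*`), 2, v$origin, `+`)
}

physical_center <- function(v) {
  v$origin + (dim(v$data) - 1) / 2 * v$spacing
}

#' Resample a moving volume through a transform onto a reference grid
#'
#' For every voxel `x` of the reference grid, samples the moving volume at
#' `T(x)` by trilinear interpolation (pull-back warping); points falling
#' outside the moving volume get the background value 0.  With the identity
#' transform and a common grid this reproduces the moving volume exactly.
#'
#' @param moving a [volume()] (or 3D array) to resample.
#' @param transform a [composite_transform()], [rigid_params()] (applied
#'   about the reference center) or [bspline_grid()].
#' @param reference a [volume()] defining the output grid (defaults to the
#'   moving volume's own grid).
#' @return a [volume()] on the reference grid.
#' @export
warp <- function(moving, transform, reference = moving) {
  moving <- as_volume(moving); reference <- as_volume(reference)
  if (inherits(transform, "rigid_params")) {
    transform <- composite_transform(transform,
                                     center = physical_center(reference))
  } else if (inherits(transform, "bspline_grid")) {
    transform <- composite_transform(ffd = transform,
                                     center = physical_center(reference))
  }
  pts <- voxel_coordinates(reference)
  mapped <- composite_apply(pts, transform, outside = "zero")
  idx <- sweep(sweep(mapped, 2, moving$origin), 2, moving$spacing, `/`)
  vals <- trilinear_interp(moving$data, idx)
  volume(array(vals, dim = dim(reference$data)),
         spacing = reference$spacing, origin = reference$origin)
}

# Separable Gaussian smoothing (sigma in voxels per axis); returns a volume
# with the same geometry.  Used to widen the capture range of registration.
smooth_volume <- function(v, sigma = c(1, 1, 1)) {
  v <- as_volume(v)
  sigma <- rep_len(sigma, 3)
  arr <- v$data
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    r <- max(1L, ceiling(3 * sigma[ax]))
    k <- stats::dnorm(seq.int(-r, r), sd = sigma[ax])
    k <- k / sum(k)
    n <- dim(arr)[ax]
    # banded convolution matrix with renormalized (truncated) edge rows
    K <- matrix(0, n, n)
    for (o in seq.int(-r, r)) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + k[o + r + 1]
    }
    K <- K / rowSums(K)
    arr <- ttm(arr, K, ax)
  }
  volume(arr, spacing = v$spacing, origin = v$origin)
}

# Central-difference gradient of a 3D array w.r.t. voxel index (one-sided
# at the boundaries); returns a list of 3 arrays.
array_gradient <- function(arr) {
  d <- dim(arr)
  lapply(1:3, function(ax) {
    n <- d[ax]
    D <- matrix(0, n, n)
    if (n >= 3) {
      i <- 2:(n - 1)
      D[cbind(i, i + 1)] <- 0.5
      D[cbind(i, i - 1)] <- -0.5
    }
    D[1, 1:2] <- c(-1, 1)
    D[n, (n - 1):n] <- c(-1, 1)
    ttm(arr, D, ax)
  })
}
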