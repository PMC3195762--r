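#' Registration settings
#'
#' Collects the tunable settings of [register_rigid()] and
#' [register_bspline()].
#'
#' @param smooth_sigma Gaussian pre-smoothing (voxels) applied to both
#'   images before *rigid* registration, widening its capture range; the
#'   FFD stage runs on the unsmoothed images.
#' @param rigid_maxit iteration cap of the rigid optimizer.
#' @param ffd_maxit iteration cap (L-BFGS-B) of the FFD optimizer.
#' @param ffd_pgtol projected-gradient tolerance of the FFD optimizer.
#' @param regularization optional coefficient-magnitude penalty weight
#'   (adds `w * sum(lambda^2)` to the cost); 0 disables it.
#' @return a list of class `"registration_config"`.
#' @export
registration_config <- function(smooth_sigma = 1.5, rigid_maxit = 500L,
                                ffd_maxit = 100L, ffd_pgtol = 0,
                                regularization = 0) {
  structure(list(smooth_sigma = smooth_sigma,
                 rigid_maxit = as.integer(rigid_maxit),
                 ffd_maxit = as.integer(ffd_maxit),
                 ffd_pgtol = ffd_pgtol,
                 regularization = regularization),
            class = "registration_config")
}

ssd <- function(a, b) sum((a - b)^2)

#' Rigid registration by sum-of-squared-differences
#'
#' Estimates the 6 rigid parameters (rotations about the fixed volume's
#' physical center, then translation) minimizing the SSD between the fixed
#' volume and the resampled moving volume.  Both images are Gaussian
#' pre-smoothed (see [registration_config()]); optimization is
#' derivative-free Nelder-Mead followed by a quasi-Newton polish, and is
#' deterministic for a given configuration.
#'
#' @param moving,fixed [volume()] objects (or 3D arrays) with overlapping
#'   content.
#' @param config a [registration_config()].
#' @return a [rigid_params()] with attribute `"info"` (initial/final SSD,
#'   convergence codes).
#' @export
register_rigid <- function(moving, fixed, config = registration_config()) {
  moving <- as_volume(moving); fixed <- as_volume(fixed)
  if (stats::sd(moving$data) == 0 || stats::sd(fixed$data) == 0) {
    stop("cannot register constant (degenerate) images")
  }
  ms <- smooth_volume(moving, config$smooth_sigma)
  fs <- smooth_volume(fixed, config$smooth_sigma)
  ctr <- physical_center(fs)
  pts <- voxel_coordinates(fs)
  fvec <- as.vector(fs$data)
  obj <- function(p) {
    mapped <- rigid_apply(pts, rigid_params(p[1:3], p[4:6]), ctr)
    idx <- sweep(sweep(mapped, 2, ms$origin), 2, ms$spacing, `/`)
    sum((trilinear_interp(ms$data, idx) - fvec)^2)
  }
  scale <- c(rep(0.02, 3), fs$spacing)
  objs <- function(q) obj(q * scale)
  f0 <- obj(rep(0, 6))
  # Nelder-Mead needs a nonzero start (its initial simplex is scaled to the
  # starting values); alternate simplex search and quasi-Newton polish.
  # Finite-difference steps are kept well above the trilinear-interpolation
  # kink scale.
  best <- list(par = rep(0, 6), value = f0)
  # coarse rotation grid to pick a starting basin (translation start 0)
  grid_ang <- c(-0.1, -0.05, 0, 0.05, 0.1) / scale[1]
  for (qx in grid_ang) for (qy in grid_ang) for (qz in grid_ang) {
    qq <- c(qx, qy, qz, 0, 0, 0)
    v <- objs(qq)
    if (v < best$value) best <- list(par = qq, value = v)
  }
  # cyclic coordinate descent with golden-section line searches: robust to
  # the fine-scale interpolation kinks that defeat gradient line searches
  width <- c(rep(0.06, 3) / scale[1:3], 3 / scale[4:6])
  n_sweeps <- max(4L, config$rigid_maxit %/% 100L)
  for (sweep in seq_len(n_sweeps)) {
    for (i in 1:6) {
      f1 <- function(z) {
        p <- best$par; p[i] <- z; objs(p)
      }
      o <- stats::optimize(f1, lower = best$par[i] - width[i],
                           upper = best$par[i] + width[i], tol = 1e-6)
      if (o$objective < best$value) {
        best$par[i] <- o$minimum
        best$value <- o$objective
      }
    }
    width <- width / 2
  }
  out <- rigid_params(best$par[1:3] * scale[1:3], best$par[4:6] * scale[4:6])
  attr(out, "info") <- list(initial_ssd = f0, final_ssd = best$value,
                            convergence = 0L)
  out
}

#' B-spline FFD registration by sum-of-squared-differences
#'
#' Estimates the control-point displacement coefficients of a cubic
#' B-spline free-form deformation minimizing the SSD between the fixed
#' volume and the moving volume resampled through
#' `T(x) = T_rigid(x) + T_ffd(x)`.  The rigid part (identity by default) is
#' held fixed; the FFD coefficients are optimized by L-BFGS-B with the
#' analytic SSD gradient, which for the separable tensor-product kernel
#' reduces to three mode products of the residual-weighted image gradient
#' with the per-axis basis matrices.  The final SSD never exceeds the
#' initial SSD.
#'
#' @param moving,fixed [volume()] objects (or 3D arrays).
#' @param grid_dims length-3 integer: control intervals per axis (e.g.
#'   `c(26, 26, 8)`).
#' @param config a [registration_config()].
#' @param rigid optional [rigid_params()] pre-alignment, held fixed.
#' @return a [bspline_grid()] over the fixed volume with fitted
#'   coefficients; attribute `"info"` records initial/final SSD, the
#'   optimizer convergence code and a `maxit_reached` flag.
#' @export
register_bspline <- function(moving, fixed, grid_dims,
                             config = registration_config(),
                             rigid = NULL) {
  moving <- as_volume(moving); fixed <- as_volume(fixed)
  if (stats::sd(moving$data) == 0 || stats::sd(fixed$data) == 0) {
    stop("cannot register constant (degenerate) images")
  }
  grid <- bspline_grid(grid_dims, fixed)
  d <- dim(fixed$data)
  B <- lapply(1:3, function(ax) {
    bspline_basis_matrix(d[ax], fixed$spacing[ax], grid$rho[ax],
                         grid$dims[ax])
  })
  Bt <- lapply(B, t)
  pts <- voxel_coordinates(fixed)
  rp <- if (is.null(rigid)) pts
        else rigid_apply(pts, rigid, physical_center(fixed))
  fvec <- as.vector(fixed$data)
  marr <- moving$data
  mgrad <- array_gradient(marr)
  ldim <- dim(grid$lambda)
  nl <- prod(ldim[1:3])
  w <- config$regularization

  state <- new.env(parent = emptyenv())
  evaluate <- function(lam) {
    if (!is.null(state$lam) && identical(state$lam, lam)) return(invisible())
    disp <- lapply(1:3, function(dd) {
      f <- array(lam[seq_len(nl) + (dd - 1L) * nl], dim = ldim[1:3])
      as.vector(ttm(ttm(ttm(f, B[[1]], 1), B[[2]], 2), B[[3]], 3))
    })
    mapped <- rp + cbind(disp[[1]], disp[[2]], disp[[3]])
    idx <- sweep(sweep(mapped, 2, moving$origin), 2, moving$spacing, `/`)
    prep <- trilinear_prepare(dim(marr), idx)
    r <- trilinear_apply(marr, prep) - fvec
    state$lam <- lam
    state$value <- sum(r^2) + w * sum(lam^2)
    state$grad <- unlist(lapply(1:3, function(dd) {
      wres <- 2 * r * trilinear_apply(mgrad[[dd]], prep) / moving$spacing[dd]
      dim(wres) <- d
      as.vector(ttm(ttm(ttm(wres, Bt[[1]], 1), Bt[[2]], 2), Bt[[3]], 3))
    })) + 2 * w * lam
    invisible()
  }
  fn <- function(lam) { evaluate(lam); state$value }
  gr <- function(lam) { evaluate(lam); state$grad }

  lam0 <- numeric(nl * 3L)
  f0 <- fn(lam0)
  res <- stats::optim(lam0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = config$ffd_maxit,
                                     pgtol = config$ffd_pgtol,
                                     factr = 1e5))
  grid$lambda <- array(res$par, dim = ldim)
  attr(grid, "info") <- list(initial_ssd = f0, final_ssd = res$value,
                             convergence = res$convergence,
                             maxit_reached = res$convergence == 1L,
                             message = res$message)
  if (res$convergence == 1L) {
    # recorded in metadata, not an error: partial convergence still usable
    attr(grid, "info")$warning <- "FFD optimizer reached its iteration cap"
  }
  grid
}

#' 3D shape normalization against a fixed reference volume
#'
#' The full normalization of one volume to the reference shape: optional
#' rigid registration (global), then B-spline FFD registration (local) with
#' the rigid part held fixed, then a single resampling of the moving volume
#' through the composite transform onto the reference grid.
#'
#' @param moving a [volume()] to normalize.
#' @param fixed the reference [volume()].
#' @param grid_dims FFD control intervals per axis.
#' @param config a [registration_config()].
#' @param rigid logical: estimate the global rigid transform first?  Set
#'   `FALSE` for cohorts that are already position-normalized upstream.
#' @return list of class `"shape_norm"`: `warped` (normalized volume on the
#'   reference grid), `transform` (the fitted [composite_transform()]), and
#'   `info` from both stages.
#' @export
shape_normalize <- function(moving, fixed, grid_dims = c(8, 8, 4),
                            config = registration_config(), rigid = TRUE) {
  moving <- as_volume(moving); fixed <- as_volume(fixed)
  rp <- if (rigid) register_rigid(moving, fixed, config) else rigid_params()
  ffd <- register_bspline(moving, fixed, grid_dims, config, rigid = rp)
  transform <- composite_transform(rp, ffd, center = physical_center(fixed))
  warped <- warp(moving, transform, fixed)
  structure(list(warped = warped, transform = transform,
                 info = list(rigid = attr(rp, "info"),
                             ffd = attr(ffd, "info"))),
            class = "shape_norm")
}

#' @export
print.shape_norm <- function(x, ...) {
  cat("3D shape normalization result\n")
  if (!is.null(x$info$ffd)) {
    cat(sprintf("  FFD SSD: %.6g -> %.6g\n",
                x$info$ffd$initial_ssd, x$info$ffd$final_ssd))
  }
  print(x$warped)
  invisible(x)
}

# Binary erosion of a logical mask by a (2r+1)^3 box, done separably.
erode_mask <- function(mask, r = 2L) {
  arr <- array(as.numeric(mask), dim = dim(mask))
  for (ax in 1:3) {
    n <- dim(arr)[ax]
    K <- matrix(0, n, n)
    for (o in seq.int(-r, r)) {
      i <- seq_len(n); j <- i + o
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- 1
    }
    arr <- ttm(arr, K, ax)
  }
  arr >= (2 * r + 1)^3 - 0.5
}

#' Texture-preservation round trip through shape normalization
#'
#' Normalizes `original` to the reference shape, then normalizes the result
#' back to the original shape, and reports the normalized correlation
#' between the round-trip volume and the original over the (eroded)
#' foreground.  Values near 1 show that shape normalization preserves
#' texture up to interpolation loss.
#'
#' @param original a textured [volume()].
#' @param fixed the reference [volume()].
#' @param grid_dims FFD control intervals per axis.
#' @param config a [registration_config()].
#' @param rigid logical, passed to [shape_normalize()].
#' @return scalar correlation, with attribute `"volumes"` holding the
#'   forward-normalized and round-trip volumes.
#' @export
roundtrip_check <- function(original, fixed, grid_dims = c(8, 8, 4),
                            config = registration_config(), rigid = FALSE) {
  original <- as_volume(original); fixed <- as_volume(fixed)
  fwd <- shape_normalize(original, fixed, grid_dims, config, rigid = rigid)
  back <- shape_normalize(fwd$warped, original, grid_dims, config,
                          rigid = rigid)
  mask <- erode_mask(original$data != 0, r = 2L)
  r <- normalized_correlation(
    array(original$data[mask], dim = c(sum(mask), 1, 1)),
    array(back$warped$data[mask], dim = c(sum(mask), 1, 1)))
  attr(r, "volumes") <- list(normalized = fwd$warped,
                             roundtrip = back$warped)
  r
}

#' Dice overlap of two foreground masks
#'
#' @param a,b logical arrays (or numeric; nonzero taken as foreground).
#' @return scalar in `[0, 1]`.
#' @export
dice_overlap <- function(a, b) {
  a <- as.array(a) != 0; b <- as.array(b) != 0
  2 * sum(a & b) / (sum(a) + sum(b))
}
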