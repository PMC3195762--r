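#' Specification of a synthetic liver-phantom cohort
#'
#' Describes a seeded cohort of volumetric phantoms emulating a set of
#' segmented, position-normalized organ CT volumes: a shared
#' superellipsoidal "liver" template, per-sample smooth shape deformation
#' (a random B-spline FFD), per-sample texture drawn from a fixed set of
#' shared smooth intensity modes, additive voxel noise, and optional
#' tumor-like lesions in the abnormal samples.
#'
#' @param n_normal,n_abnormal sample counts (the default 19 + 4 mirrors a
#'   typical small clinical cohort).
#' @param shape volume dimensions in voxels (unit spacing).
#' @param n_texture_modes number K of shared smooth texture modes.
#' @param texture_sd per-mode coefficient standard deviation, intensity
#'   units (modes are RMS-normalized over the foreground).
#' @param shape_deform_sd control-point jitter of the random shape
#'   deformation, voxels.
#' @param deform_dims control intervals of the shape-deformation lattice.
#' @param lesion list with `count`, `radius` (range, voxels), `contrast`
#'   (fraction of the foreground mean intensity added inside the lesion).
#' @param noise_sd additive Gaussian noise, intensity units (foreground
#'   only, so the background stays exactly zero).
#' @param seed integer master seed; every sample is reproducible from
#'   `(seed, index, abnormal)`.
#' @return list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_normal = 19L, n_abnormal = 4L,
                        shape = c(64L, 64L, 32L),
                        n_texture_modes = 5L, texture_sd = 0.75,
                        shape_deform_sd = 2.5, deform_dims = c(4L, 4L, 2L),
                        lesion = list(count = 2L, radius = c(5, 8),
                                      contrast = 0.15),
                        noise_sd = 1, seed = 42L) {
  stopifnot(n_normal >= 0, n_abnormal >= 0, all(shape >= 8),
            n_texture_modes >= 1, texture_sd >= 0, shape_deform_sd >= 0,
            noise_sd >= 0)
  structure(list(n_normal = as.integer(n_normal),
                 n_abnormal = as.integer(n_abnormal),
                 shape = as.integer(shape),
                 n_texture_modes = as.integer(n_texture_modes),
                 texture_sd = texture_sd,
                 shape_deform_sd = shape_deform_sd,
                 deform_dims = as.integer(deform_dims),
                 lesion = lesion, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Deterministic per-sample seed below 2^31, exact in double arithmetic.
derive_seed <- function(seed, index, abnormal) {
  h <- abs(seed) %% 2147483647
  h <- (h * 48271 + index * 10007 + as.integer(abnormal) * 7919) %% 2147483647
  as.integer(h)
}

# Normalized [-1, 1] coordinates of each axis.
norm_coords <- function(n) {
  if (n == 1L) return(0)
  (seq_len(n) - 1 - (n - 1) / 2) / ((n - 1) / 2)
}

# Smoothstep: 0 below e0, 1 above e1, C1 cubic in between.
smoothstep <- function(x, e0, e1) {
  t <- pmin(pmax((x - e0) / (e1 - e0), 0), 1)
  t * t * (3 - 2 * t)
}

# Superellipsoid radial measure (1 on the surface) on the voxel grid.
template_radial <- function(shape) {
  a <- c(0.75, 0.65, 0.70); p <- 2.5
  cx <- norm_coords(shape[1]); cy <- norm_coords(shape[2])
  cz <- norm_coords(shape[3])
  q <- outer(outer(abs(cx / a[1])^p, abs(cy / a[2])^p, `+`),
             abs(cz / a[3])^p, `+`)
  q^(1 / p)
}

#' Synthetic liver-like template volume
#'
#' A smooth superellipsoid foreground with a soft (compactly supported)
#' boundary and smoothly varying base intensity around 100 units;
#' background exactly 0.  Deterministic: repeated calls are identical.
#'
#' @param shape volume dimensions in voxels.
#' @return a [volume()] with unit spacing and zero origin.
#' @export
make_template <- function(shape = c(64L, 64L, 32L)) {
  shape <- as.integer(shape)
  rq <- template_radial(shape)
  edge <- 2.5 / (min(shape) / 2)            # soft edge ~2.5 voxels wide
  m <- smoothstep(1 - rq, 0, edge)
  cx <- norm_coords(shape[1]); cy <- norm_coords(shape[2])
  cz <- norm_coords(shape[3])
  base <- 100 +
    15 * outer(outer(sin(1.3 * cx + 0.7), cos(1.1 * cy), `*`),
               rep(1, shape[3]), `*`) +
    10 * outer(outer(rep(1, shape[1]), rep(1, shape[2]), `*`), cz, `*`)
  volume(base * m)
}

# Fixed low-frequency frequency/phase table for the shared texture modes.
texture_mode_table <- function(K) {
  freqs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(1, 0, 1),
                c(0, 1, 1), c(2, 0, 0), c(0, 2, 0), c(1, 1, 1), c(2, 1, 0))
  if (K > length(freqs)) stop("at most ", length(freqs), " texture modes")
  lapply(seq_len(K), function(k) {
    list(f = freqs[[k]], phase = 0.4 * k)
  })
}

#' Shared smooth texture modes of the synthetic cohort
#'
#' The K fixed low-frequency intensity modes that every cohort sample's
#' texture is drawn from, masked to the template foreground and
#' RMS-normalized over it.  Exported so subspace-recovery experiments can
#' compare fitted bases against the generating subspace.
#'
#' @param spec a [cohort_spec()].
#' @return list of K arrays of shape `spec$shape`.
#' @export
cohort_texture_modes <- function(spec) {
  shape <- spec$shape
  tmpl <- make_template(shape)
  m <- tmpl$data > 0
  cx <- norm_coords(shape[1]); cy <- norm_coords(shape[2])
  cz <- norm_coords(shape[3])
  tab <- texture_mode_table(spec$n_texture_modes)
  lapply(tab, function(md) {
    raw <- outer(outer(cos(pi * md$f[1] * cx + md$phase),
                       cos(pi * md$f[2] * cy + 0.5 * md$phase), `*`),
                 cos(pi * md$f[3] * cz + 0.25 * md$phase), `*`)
    raw <- raw * m
    raw / sqrt(mean(raw[m]^2))
  })
}

#' Draw one synthetic cohort sample
#'
#' Builds the sample in the template frame (base intensity + texture from
#' the shared modes + lesions if abnormal), then warps it by a seeded
#' random B-spline shape deformation and adds foreground noise.  Fully
#' reproducible from `(spec$seed, index, abnormal)`.
#'
#' @param spec a [cohort_spec()].
#' @param index sample index (1-based) within its class.
#' @param abnormal logical: insert tumor-like lesions?
#' @return a [volume()]; attribute `"truth"` records the ground-truth
#'   deformation lattice, texture coefficients, lesion parameters and the
#'   derived seed.
#' @export
sample_volume <- function(spec, index, abnormal = FALSE) {
  shape <- spec$shape
  tmpl <- make_template(shape)
  modes <- cohort_texture_modes(spec)
  h <- derive_seed(spec$seed, index, abnormal)
  with_seed(h, function() {
    coefs <- stats::rnorm(spec$n_texture_modes, sd = spec$texture_sd)
    img <- tmpl$data
    fgmask <- img > 0
    for (k in seq_along(modes)) img <- img + coefs[k] * modes[[k]]
    lesions <- NULL
    if (abnormal) {
      rq <- template_radial(shape)
      fg_mean <- mean(tmpl$data[fgmask])
      cand <- which(rq <= 0.6, arr.ind = TRUE)
      if (nrow(cand) == 0L) {
        stop("lesion cannot fit inside the foreground of this template")
      }
      lesions <- vector("list", spec$lesion$count)
      for (l in seq_len(spec$lesion$count)) {
        ctr <- cand[sample.int(nrow(cand), 1L), ]
        rad <- stats::runif(1, spec$lesion$radius[1], spec$lesion$radius[2])
        dist2 <- outer(outer((seq_len(shape[1]) - ctr[1])^2,
                             (seq_len(shape[2]) - ctr[2])^2, `+`),
                       (seq_len(shape[3]) - ctr[3])^2, `+`)
        blob <- smoothstep(rad - sqrt(dist2), 0, 1.5)
        img <- img + spec$lesion$contrast * fg_mean * blob * fgmask
        lesions[[l]] <- list(center = unname(ctr), radius = rad)
      }
    }
    # seeded random smooth shape deformation of the template frame
    grid <- bspline_grid(spec$deform_dims, tmpl)
    grid$lambda <- array(stats::rnorm(length(grid$lambda),
                                      sd = spec$shape_deform_sd),
                         dim = dim(grid$lambda))
    out <- if (spec$shape_deform_sd > 0) {
      warp(volume(img), grid, tmpl)
    } else {
      volume(img)
    }
    if (spec$noise_sd > 0) {
      fg <- out$data != 0
      noise <- array(stats::rnorm(length(out$data), sd = spec$noise_sd),
                     dim = shape)
      out$data <- out$data + noise * fg
    }
    attr(out, "truth") <- list(deform = grid, texture_coefs = coefs,
                               lesions = lesions, seed = h,
                               abnormal = abnormal)
    out
  })
}

#' Generate a full synthetic cohort in memory
#'
#' @param spec a [cohort_spec()].
#' @return list with `volumes` (list of [volume()]s, normals first),
#'   `labels` (character `"normal"`/`"abnormal"`), `template`, `modes`
#'   (the shared texture modes), and `spec`.
#' @export
generate_cohort <- function(spec) {
  vols <- c(
    lapply(seq_len(spec$n_normal), function(i) {
      sample_volume(spec, i, abnormal = FALSE)
    }),
    lapply(seq_len(spec$n_abnormal), function(i) {
      sample_volume(spec, i, abnormal = TRUE)
    })
  )
  labels <- c(rep("normal", spec$n_normal),
              rep("abnormal", spec$n_abnormal))
  list(volumes = vols, labels = labels, template = make_template(spec$shape),
       modes = cohort_texture_modes(spec), spec = spec)
}

#' Write a synthetic cohort to disk
#'
#' Writes every sample as NIfTI plus, per sample, a JSON ground-truth
#' deformation file, and a cohort manifest (filenames, labels, seed).
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if missing).
#' @return the manifest as a data.frame (invisibly also written to
#'   `manifest.json`).
#' @export
write_cohort <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  coh <- generate_cohort(spec)
  n <- length(coh$volumes)
  files <- character(n); truth_files <- character(n)
  for (i in seq_len(n)) {
    files[i] <- sprintf("sample_%02d_%s.nii.gz", i, coh$labels[i])
    write_volume(coh$volumes[[i]], file.path(out_dir, files[i]))
    truth <- attr(coh$volumes[[i]], "truth")
    truth_files[i] <- sprintf("sample_%02d_truth.json", i)
    write_transform(composite_transform(ffd = truth$deform),
                    file.path(out_dir, truth_files[i]))
  }
  write_volume(coh$template, file.path(out_dir, "template.nii.gz"))
  manifest <- data.frame(file = files, label = coh$labels,
                         truth = truth_files, stringsAsFactors = FALSE)
  jsonlite::write_json(list(seed = spec$seed, shape = spec$shape,
                            template = "template.nii.gz",
                            samples = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
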