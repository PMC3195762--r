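#' 3D scalar volume with voxel geometry
#'
#' A minimal container for a 3D image: a numeric array of intensities plus
#' the voxel spacing (physical units, e.g. mm) and the physical coordinates
#' of voxel `(0, 0, 0)` (0-based indexing; voxel `(i, j, k)` sits at
#' `origin + c(i, j, k) * spacing`).
#'
#' @param data numeric 3D array.
#' @param spacing positive length-3 numeric, physical voxel size.
#' @param origin length-3 numeric, physical position of the first voxel.
#' @return object of class `"volume"` with fields `data`, `spacing`,
#'   `origin`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("'data' must be a 3D array")
  }
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be 3 positive finite numbers")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("'origin' must be 3 finite numbers")
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("volume: %s voxels, spacing (%s), origin (%s)\n",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

#' @export
as.array.volume <- function(x, ...) x$data

as_volume <- function(x) {
  if (inherits(x, "volume")) x
  else if (is.array(x) && length(dim(x)) == 3L) volume(x)
  else stop("cannot interpret input as a volume")
}

#' Read / write a 3D volume
#'
#' Supported formats, chosen by extension: NIfTI (`.nii`, `.nii.gz`) through
#' the RNifti library, and MetaImage (`.mha` single-file, or `.mhd` header +
#' `.raw`).  Intensities are stored as 64-bit floats, so a write-then-read
#' round trip reproduces data, spacing and origin exactly.
#'
#' @param path file path; the extension selects the format.
#' @return `read_volume` returns a [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::readNifti(path)
    xf <- RNifti::xform(img)
    volume(array(as.numeric(img), dim = dim(img)),
           spacing = RNifti::pixdim(img)[1:3],
           origin = xf[1:3, 4])
  } else if (grepl("\\.(mha|mhd)$", lp)) {
    read_metaimage(path)
  } else {
    stop("unsupported volume format '", path,
         "'; supported extensions: .nii, .nii.gz, .mha, .mhd")
  }
}

#' @rdname read_volume
#' @param v a [volume()] (or bare 3D array, unit geometry assumed).
#' @export
write_volume <- function(v, path) {
  v <- as_volume(v)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::asNifti(v$data)
    RNifti::pixdim(img) <- v$spacing
    m <- diag(c(v$spacing, 1))
    m[1:3, 4] <- v$origin
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::sform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.(mha|mhd)$", lp)) {
    write_metaimage(v, path)
  } else {
    stop("unsupported volume format '", path,
         "'; supported extensions: .nii, .nii.gz, .mha, .mhd")
  }
  invisible(path)
}

# --- MetaImage (ITK .mha/.mhd): ASCII key = value header + little-endian raw ---

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header in ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1L]])
  if (length(dims) != 3L) stop("only 3D MetaImage volumes are supported")
  spacing <- if (!is.null(hdr$ElementSpacing)) {
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1L]])
  } else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset)) {
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1L]])
  } else c(0, 0, 0)
  type <- hdr$ElementType
  size <- switch(type, MET_DOUBLE = 8L, MET_FLOAT = 4L,
                 MET_SHORT = 2L, MET_USHORT = 2L, MET_UCHAR = 1L,
                 stop("unsupported MetaImage ElementType: ", type))
  what <- if (type %in% c("MET_DOUBLE", "MET_FLOAT")) "double" else "integer"
  signed <- !(type %in% c("MET_USHORT", "MET_UCHAR"))
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path)) stop("MetaImage data file not found: ", raw_path)
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  vals <- readBin(raw_con, what, n = n, size = size, signed = signed,
                  endian = "little")
  if (length(vals) != n) stop("MetaImage data shorter than DimSize implies")
  volume(array(as.numeric(vals), dim = dims), spacing = spacing,
         origin = origin)
}

write_metaimage <- function(v, path) {
  mhd <- grepl("\\.mhd$", tolower(path))
  datafile <- if (mhd) paste0(sub("\\.mhd$", "", basename(path)), ".raw")
              else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(dim(v$data), collapse = " ")),
    paste("ElementSpacing =", paste(format(v$spacing, digits = 17), collapse = " ")),
    paste("Offset =", paste(format(v$origin, digits = 17), collapse = " ")),
    "ElementType = MET_DOUBLE",
    paste("ElementDataFile =", datafile)
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (mhd) {
    raw_con <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(raw_con), add = TRUE)
    writeBin(as.numeric(v$data), raw_con, size = 8, endian = "little")
  } else {
    writeBin(as.numeric(v$data), con, size = 8, endian = "little")
  }
  invisible(path)
}
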