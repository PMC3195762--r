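#' Euclidean distance between core-tensor features
#'
#' The features are flattened to vectors and compared by the Euclidean
#' norm of their difference.
#'
#' @param b,center same-shape numeric arrays (core tensors).
#' @return nonnegative scalar.
#' @export
feature_distance <- function(b, center) {
  if (!identical(dim(b), dim(center))) {
    stop("core tensors must have identical shape")
  }
  sqrt(sum((b - center)^2))
}

#' Largest-distance-of-training (LDT) classifier on core features
#'
#' Fits the discrimination rule used with a texture model trained on normal
#' samples only: the classifier stores the mean training feature
#' (`center`), the Euclidean distance (ED) of every training feature to it,
#' and the largest such distance (LDT).  A test sample is called abnormal
#' iff its ED exceeds the LDT; ties are normal, so every training sample is
#' self-consistent by construction.
#'
#' @param train_features non-empty list of same-shape core tensors (the
#'   training samples' features).
#' @return object of class `"ldt_classifier"`: `center`, `ldt`,
#'   `training_distances`.
#' @seealso [predict.ldt_classifier()], [project()]
#' @export
ldt_classifier <- function(train_features) {
  d <- check_tensor_set(train_features)
  center <- Reduce(`+`, train_features) / length(train_features)
  dim(center) <- d
  dists <- vapply(train_features, feature_distance, numeric(1),
                  center = center)
  structure(list(center = center, ldt = max(dists),
                 training_distances = dists),
            class = "ldt_classifier")
}

#' Predict method for the LDT classifier
#'
#' @param object an [ldt_classifier()].
#' @param newdata a core tensor, or a list of core tensors.
#' @param ... unused.
#' @return data.frame with one row per sample: `label`
#'   (`"normal"`/`"abnormal"`), `ed`, `ldt`, `ed_minus_ldt`.
#' @export
predict.ldt_classifier <- function(object, newdata, ...) {
  if (!is.list(newdata)) newdata <- list(newdata)
  ed <- vapply(newdata, feature_distance, numeric(1), center = object$center)
  data.frame(label = ifelse(ed > object$ldt, "abnormal", "normal"),
             ed = ed, ldt = object$ldt, ed_minus_ldt = ed - object$ldt,
             stringsAsFactors = FALSE)
}

#' @export
print.ldt_classifier <- function(x, ...) {
  cat("LDT distance classifier on core-tensor features\n")
  cat(sprintf("  feature shape : (%s)\n",
              paste(dim(x$center), collapse = " x ")))
  cat(sprintf("  training EDs  : n = %d, range [%.4g, %.4g]\n",
              length(x$training_distances), min(x$training_distances),
              max(x$training_distances)))
  cat(sprintf("  LDT threshold : %.6g\n", x$ldt))
  invisible(x)
}

#' Save / load an LDT classifier as JSON
#'
#' @param object an [ldt_classifier()].
#' @param path JSON file path.
#' @export
write_classifier <- function(object, path) {
  jsonlite::write_json(list(center_dim = dim(object$center),
                            center = as.vector(object$center),
                            ldt = object$ldt,
                            training_distances = object$training_distances),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(center = array(as.numeric(obj$center),
                                dim = as.integer(obj$center_dim)),
                 ldt = as.numeric(obj$ldt),
                 training_distances = as.numeric(obj$training_distances)),
            class = "ldt_classifier")
}
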