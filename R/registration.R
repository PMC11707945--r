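#' Similarity transform between imaging frames
#'
#' A similarity transform maps source-frame points into a target frame by an
#' isotropic scaling, a rotation and a translation:
#' `p' = scale * R(rotation) %*% p + translation`. Reflections are excluded
#' (the linear part has positive determinant), matching how one fundus image
#' maps onto another.
#'
#' @param scale positive isotropic scale factor.
#' @param rotation rotation angle in radians.
#' @param translation length-2 numeric vector, in target-frame units.
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation = 0,
                                 translation = c(0, 0)) {
  if (length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("'scale' must be a single positive number", call. = FALSE)
  if (length(rotation) != 1L || !is.finite(rotation))
    stop("'rotation' must be a single finite number (radians)", call. = FALSE)
  if (length(translation) != 2L || any(!is.finite(translation)))
    stop("'translation' must be a finite length-2 vector", call. = FALSE)
  structure(list(scale = as.numeric(scale),
                 rotation = as.numeric(rotation),
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity transform: scale %.6g, rotation %.6g rad, translation (%.6g, %.6g)\n",
              x$scale, x$rotation, x$translation[1L], x$translation[2L]))
  if (!is.null(x$rmse)) cat(sprintf("  fit RMSE: %.4g\n", x$rmse))
  invisible(x)
}

rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

#' Fiducial correspondence set
#'
#' Paired landmark coordinates picked by one grader: vessel-bifurcation
#' positions in the MP-SLO image (source, pixels) matched to the same
#' bifurcations in the FAF image (target, pixels). At least three
#' non-collinear pairs are required to estimate a similarity transform.
#'
#' @param src,dst n x 2 matrices of source (MP-SLO) and target (FAF) pixel
#'   coordinates, row-matched.
#' @param grader_id,eye_id identifiers.
#' @return An object of class `fiducial_set`.
#' @export
fiducial_set <- function(src, dst, grader_id = NA, eye_id = NA) {
  src <- as_xy(src, "src"); dst <- as_xy(dst, "dst")
  if (nrow(src) != nrow(dst))
    stop("'src' and 'dst' must have the same number of rows", call. = FALSE)
  if (any(!is.finite(src)) || any(!is.finite(dst)))
    stop("fiducial coordinates must be finite", call. = FALSE)
  structure(list(src = src, dst = dst,
                 grader_id = grader_id, eye_id = eye_id),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("fiducial set: %d pairs (grader %s, eye %s)\n",
              nrow(x$src), x$grader_id, x$eye_id))
  invisible(x)
}

# relative smallest-singular-value tolerance below which the centered source
# configuration is treated as collinear
COLLINEARITY_TOL <- 1e-6

#' Fit a similarity transform from fiducial pairs
#'
#' Least-squares estimation of the similarity transform (translation,
#' rotation, isotropic scaling) minimizing the sum of squared target-frame
#' residuals, by the closed-form orthogonal-Procrustes-with-scale solution.
#' Both point sets are centroid-centered before the SVD for numerical
#' stability. Reflections are disallowed: when the data favor a reflection,
#' the best proper-rotation solution is returned and the
#' `reflection_suspected` diagnostic is set. All pairs are weighted equally;
#' no outlier rejection is performed.
#'
#' @param pairs a [fiducial_set], or an n x 2 source matrix when `dst` is
#'   given.
#' @param dst optional n x 2 target matrix (when `pairs` is a matrix).
#' @return A `similarity_transform` carrying fit diagnostics: `residuals`
#'   (n x 2 target-frame residuals), `rmse` (root-mean-square point
#'   distance), `n_pairs`, and `reflection_suspected`.
#' @examples
#' src <- rbind(c(0, 0), c(1, 0), c(0, 1))
#' dst <- src + 5
#' fit_similarity(src, dst)  # pure translation (5, 5)
#' @export
fit_similarity <- function(pairs, dst = NULL) {
  if (inherits(pairs, "fiducial_set")) {
    src <- pairs$src; dst <- pairs$dst
  } else {
    src <- as_xy(pairs, "src"); dst <- as_xy(dst, "dst")
  }
  n <- nrow(src)
  if (n != nrow(dst))
    stop("source and target must have the same number of pairs",
         call. = FALSE)
  if (n < 3L)
    stop("at least 3 fiducial pairs are required", call. = FALSE)
  mx <- colMeans(src); my <- colMeans(dst)
  X <- sweep(src, 2L, mx); Y <- sweep(dst, 2L, my)
  sv_src <- svd(X)$d
  if (sv_src[1L] == 0 || sv_src[2L] < COLLINEARITY_TOL * sv_src[1L])
    stop("degenerate fiducial configuration: source points are collinear ",
         "or coincident", call. = FALSE)
  # cross-covariance between centered target and source
  S <- crossprod(Y, X) / n
  sv <- svd(S)
  det_uv <- det(sv$u %*% t(sv$v))
  reflection <- det_uv < 0
  D <- diag(c(1, sign(det_uv)))
  R <- sv$u %*% D %*% t(sv$v)
  var_x <- sum(X^2) / n
  scale <- sum(diag(D) * sv$d) / var_x
  if (scale <= 0)
    stop("degenerate fiducial configuration: non-positive fitted scale",
         call. = FALSE)
  trans <- as.numeric(my - scale * (R %*% mx))
  tf <- similarity_transform(scale, atan2(R[2L, 1L], R[1L, 1L]), trans)
  fitted <- apply_transform(tf, src)
  res <- dst - fitted
  tf$residuals <- res
  tf$rmse <- sqrt(mean(rowSums(res^2)))
  tf$n_pairs <- n
  tf$reflection_suspected <- reflection
  if (reflection)
    warning("fiducial pairs favor a reflection; returning the best ",
            "proper-rotation similarity transform", call. = FALSE)
  tf
}

#' Apply a similarity transform to points
#'
#' @param transform a [similarity_transform].
#' @param xy n x 2 matrix (or length-2 vector) of source-frame points.
#' @return The transformed n x 2 matrix, row order preserved.
#' @export
apply_transform <- function(transform, xy) {
  stopifnot(inherits(transform, "similarity_transform"))
  xy <- as_xy(xy)
  if (any(!is.finite(xy)))
    stop("points to transform must be finite", call. = FALSE)
  R <- rotation_matrix(transform$rotation)
  out <- transform$scale * (xy %*% t(R))
  out[, 1L] <- out[, 1L] + transform$translation[1L]
  out[, 2L] <- out[, 2L] + transform$translation[2L]
  out
}

#' Invert a similarity transform
#'
#' @param transform a [similarity_transform].
#' @return The inverse `similarity_transform`; composing the two yields the
#'   identity to within floating-point precision.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  s <- 1 / transform$scale
  theta <- -transform$rotation
  trans <- -s * (rotation_matrix(theta) %*% transform$translation)
  similarity_transform(s, theta, as.numeric(trans))
}

compose_transform <- function(outer, inner) {
  # outer(inner(p))
  stopifnot(inherits(outer, "similarity_transform"),
            inherits(inner, "similarity_transform"))
  similarity_transform(
    outer$scale * inner$scale,
    outer$rotation + inner$rotation,
    as.numeric(outer$scale * rotation_matrix(outer$rotation) %*%
                 inner$translation) + outer$translation)
}
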