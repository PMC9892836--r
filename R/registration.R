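#' Rigid (6 degree-of-freedom) transforms
#'
#' A rigid transform is a proper rotation plus a translation: the six
#' degrees of freedom (three translations, three rotations) used to
#' standardize patient image coordinates onto the reference leg.  No scaling
#' or shear is included by default; [fit_rigid_transform()] can optionally
#' estimate a seventh, uniform-scale parameter.
#'
#' @param rotation 3x3 proper orthonormal matrix (det = +1).
#' @param translation length-3 numeric vector (cm).
#' @param scale uniform scale factor, 1 for a rigid transform.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) {
    stop("rotation must be 3x3", call. = FALSE)
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be a proper orthonormal matrix (det = +1)",
         call. = FALSE)
  }
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = as.numeric(scale)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n"); print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  if (!isTRUE(all.equal(x$scale, 1))) cat("scale:", x$scale, "\n")
  if (!is.null(x$rms)) cat("landmark RMS residual:", signif(x$rms, 4), "cm\n")
  invisible(x)
}

#' Apply or invert a rigid transform
#'
#' @param transform a `rigid_transform`.
#' @param points n x 3 matrix of positions (cm).
#' @return `apply_rigid()`: transformed n x 3 matrix.
#'   `invert_rigid()`: the inverse `rigid_transform`.
#' @export
apply_rigid <- function(transform, points) {
  rn <- rownames(points)
  points <- matrix(as.numeric(points), ncol = 3L)
  out <- sweep(transform$scale * points %*% t(transform$rotation), 2L,
               -transform$translation)
  rownames(out) <- rn
  out
}

#' @rdname apply_rigid
#' @export
invert_rigid <- function(transform) {
  Rinv <- t(transform$rotation)
  rigid_transform(Rinv, -Rinv %*% transform$translation / transform$scale,
                  1 / transform$scale)
}

#' Mirror a right-sided patient onto the left-leg frame
#'
#' All analyses run in a left-leg frame: for right-sided patients the
#' medial-lateral coordinate is negated (x to -x) so that the medial side of
#' the right leg maps to the medial side (+x) of the canonical left leg.
#' Left-sided inputs pass through unchanged.  Mirroring twice restores the
#' input (involution).
#'
#' @param lesions lesion data.frame with columns `side` and `x_cm`, `y_cm`,
#'   `z_cm`; all rows must share one side.
#' @param landmarks patient landmark matrix (n x 3, rownames = landmark
#'   names) in the same frame.
#' @return list with elements `lesions`, `landmarks`, and `mirrored`
#'   (logical).
#' @export
mirror_to_left <- function(lesions, landmarks = NULL) {
  sides <- unique(lesions$side)
  if (length(sides) != 1L) {
    stop("all lesions of one patient must share one side; got: ",
         paste(sides, collapse = ", "), call. = FALSE)
  }
  mirrored <- sides == "right"
  if (mirrored) {
    lesions$x_cm <- -lesions$x_cm
    if (!is.null(landmarks)) landmarks[, 1L] <- -landmarks[, 1L]
  }
  list(lesions = lesions, landmarks = landmarks, mirrored = mirrored)
}

#' Least-squares rigid alignment of labeled landmarks
#'
#' Estimates the rigid transform (rotation + translation; optionally a
#' uniform scale) that best aligns a patient's landmark set onto the same
#' labels on the reference, by closed-form orthogonal least squares:
#' centroids are aligned and the rotation is taken from the singular value
#' decomposition of the cross-covariance matrix, with the reflection
#' corrected so the rotation is proper.
#'
#' @param source n x 3 matrix of patient landmark positions, rownames =
#'   landmark names.
#' @param target n x 3 matrix of the same landmarks on the reference.
#' @param allow_scale if `TRUE`, also estimate a uniform scale (7 DOF);
#'   default `FALSE` (the stated 6 DOF exclude scaling).
#' @return a `rigid_transform` with an `rms` element (root-mean-square
#'   landmark residual, cm) and `labels` (the landmark names used).
#' @export
fit_rigid_transform <- function(source, target, allow_scale = FALSE) {
  if (is.null(rownames(source)) || is.null(rownames(target))) {
    stop("source and target landmark matrices need rownames (labels)",
         call. = FALSE)
  }
  labels <- intersect(rownames(source), rownames(target))
  if (length(labels) < 3L) {
    stop("need at least 3 common landmark labels, got ", length(labels),
         call. = FALSE)
  }
  X <- as.matrix(source[labels, , drop = FALSE])
  Y <- as.matrix(target[labels, , drop = FALSE])
  xb <- colMeans(X); yb <- colMeans(Y)
  Xc <- sweep(X, 2L, xb); Yc <- sweep(Y, 2L, yb)
  sv_x <- svd(Xc)$d
  if (sv_x[2L] <= 1e-9 * max(sv_x[1L], 1e-12)) {
    stop("degenerate landmark configuration: points are collinear",
         call. = FALSE)
  }
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (allow_scale) sum(sv$d * diag(D)) / sum(Xc^2) else 1
  t_ <- yb - s * R %*% xb
  res <- sweep(s * X %*% t(R), 2L, -as.numeric(t_)) - Y
  out <- rigid_transform(R, as.numeric(t_), s)
  out$rms <- sqrt(mean(rowSums(res^2)))
  out$labels <- labels
  out
}

#' Transfer lesions onto the reference surface
#'
#' Applies a fitted rigid transform to raw lesion coordinates and snaps
#' each transformed point to its nearest point on the reference surface.
#' The snap distance is reported per lesion; lesions farther than
#' `snap_threshold` from the surface are flagged unmappable (they keep
#' their row but `mappable` is `FALSE` and a warning names them).
#'
#' @param lesions lesion data.frame with `x_cm`, `y_cm`, `z_cm`.
#' @param transform a `rigid_transform` from [fit_rigid_transform()].
#' @param reference the reference `leg_surface`.
#' @param snap_threshold maximal allowed snap distance (cm), default 3.
#' @return the lesion data.frame with added columns `face`, `b1`, `b2`,
#'   `b3`, `x`, `y`, `z` (anchored position), `snap_dist`, `mappable`;
#'   input row order preserved.
#' @export
transfer_lesions <- function(lesions, transform, reference,
                             snap_threshold = 3) {
  pts <- apply_rigid(transform, cbind(lesions$x_cm, lesions$y_cm,
                                      lesions$z_cm))
  snap <- closest_point_on_mesh(reference, pts)
  out <- cbind(lesions, snap)
  out$mappable <- out$snap_dist <= snap_threshold
  if (any(!out$mappable)) {
    warning(sum(!out$mappable), " lesion(s) beyond the ", snap_threshold,
            " cm snap threshold flagged unmappable: ",
            paste(out$lesion_id[!out$mappable], collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Landmark positions of the reference leg
#'
#' @param reference a `leg_surface`.
#' @return matrix of landmark coordinates (rownames = landmark names).
#' @export
reference_landmarks <- function(reference) {
  m <- reference$vertices[reference$landmarks, , drop = FALSE]
  rownames(m) <- names(reference$landmarks)
  m
}
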