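#' Rigid transform from Euler angles and translation
#'
#' A rigid transform acting on points in millimetres as `R %*% p + t`,
#' where `R` is built from intrinsic Z-Y-X Euler angles: with
#' `euler = c(ax, ay, az)`, `R = Rz(az) %*% Ry(ay) %*% Rx(ax)`.
#'
#' @param euler numeric(3), rotation angles in radians (intrinsic Z-Y-X).
#' @param translation numeric(3), translation in mm.
#' @return An object of class `rigid_transform`.
#' @examples
#' t <- rigid_transform(c(0, 0, pi / 2), c(0, 0, 0))
#' apply_rigid(t, matrix(c(1, 0, 0), 1))  # -> (0, 1, 0)
#' @export
rigid_transform <- function(euler = c(0, 0, 0), translation = c(0, 0, 0)) {
  euler <- as.numeric(euler)
  translation <- as.numeric(translation)
  if (length(euler) != 3L || length(translation) != 3L)
    stop("euler and translation must each have length 3")
  if (!all(is.finite(euler)) || !all(is.finite(translation)))
    stop("invalid transform: non-finite angle or translation")
  structure(list(euler = euler, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: euler ZYX (rad) [",
      paste(signif(x$euler, 6), collapse = ", "), "], t (mm) [",
      paste(signif(x$translation, 6), collapse = ", "), "]\n")
  invisible(x)
}

#' @rdname rigid_transform
#' @export
identity_transform <- function() rigid_transform()

#' Rotation matrix for intrinsic Z-Y-X Euler angles
#'
#' @param euler numeric(3) angles in radians.
#' @return 3x3 orthonormal rotation matrix with determinant +1.
#' @export
rotation_zyx <- function(euler) {
  cx <- cos(euler[1]); sx <- sin(euler[1])
  cy <- cos(euler[2]); sy <- sin(euler[2])
  cz <- cos(euler[3]); sz <- sin(euler[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Rz %*% Ry %*% Rx
}

#' Euler angles (intrinsic Z-Y-X) from a rotation matrix
#'
#' Inverse of [rotation_zyx()]. Near gimbal lock (|R[3,1]| -> 1) the
#' z-angle is set to 0 and the remaining rotation folded into x.
#'
#' @param R 3x3 rotation matrix.
#' @return numeric(3) angles in radians.
#' @export
euler_from_rotation <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  if (abs(sy) > 1 - 1e-12) {
    # gimbal lock: only the sum/difference of x and z is determined
    ay <- asin(sy)
    az <- 0
    ax <- atan2(sign(sy) * R[1, 2], R[2, 2]) * sign(sy)
    return(c(ax, ay, az))
  }
  c(atan2(R[3, 2], R[3, 3]), asin(sy), atan2(R[2, 1], R[1, 1]))
}

transform_matrix <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  list(R = rotation_zyx(t$euler), t = t$translation)
}

#' Apply a rigid transform to points
#'
#' @param t a [rigid_transform()].
#' @param pts N x 3 matrix of points (mm), or a `point_cloud`.
#' @return Transformed points, same shape/class as the input.
#' @export
apply_rigid <- function(t, pts) {
  m <- transform_matrix(t)
  cloud <- inherits(pts, "point_cloud")
  p <- if (cloud) pts$points else pts
  p <- as_points(p)
  out <- p %*% t(m$R) + matrix(m$t, nrow(p), 3, byrow = TRUE)
  if (cloud) point_cloud(out, label = pts$label) else out
}

#' Compose and invert rigid transforms
#'
#' `compose_rigid(a, b)` returns the transform whose action equals applying
#' `b` first, then `a`. `invert_rigid(t)` is the group inverse.
#'
#' @param a,b,t rigid transforms.
#' @return A `rigid_transform`.
#' @export
compose_rigid <- function(a, b) {
  ma <- transform_matrix(a); mb <- transform_matrix(b)
  R <- ma$R %*% mb$R
  tt <- as.numeric(ma$R %*% mb$t) + ma$t
  rigid_transform(euler_from_rotation(R), tt)
}

#' @rdname compose_rigid
#' @export
invert_rigid <- function(t) {
  m <- transform_matrix(t)
  Ri <- t(m$R)
  rigid_transform(euler_from_rotation(Ri), as.numeric(-Ri %*% m$t))
}

#' Serialize / deserialize a rigid transform as JSON-ready list
#' @param t a rigid transform; `x` a list with fields `euler_zyx_rad`
#'   and `translation_mm`.
#' @return `transform_to_list`: a named list; `transform_from_list`: a
#'   `rigid_transform`.
#' @export
transform_to_list <- function(t) {
  list(euler_zyx_rad = t$euler, translation_mm = t$translation)
}

#' @rdname transform_to_list
#' @param x list as produced by `transform_to_list`.
#' @export
transform_from_list <- function(x) {
  rigid_transform(as.numeric(x$euler_zyx_rad), as.numeric(x$translation_mm))
}
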