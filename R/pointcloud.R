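#' Point cloud container
#'
#' A labelled set of 3D points in world millimetres.
#'
#' @param points N x 3 numeric matrix, N >= 1, all finite.
#' @param label optional character label.
#' @return An object of class `point_cloud` with fields `points`, `label`.
#' @export
point_cloud <- function(points, label = NULL) {
  points <- as_points(points)
  structure(list(points = points, label = label), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("point_cloud:", nrow(x$points), "points",
      if (!is.null(x$label)) paste0("(", x$label, ")"), "\n")
  invisible(x)
}

# coerce to a validated N x 3 matrix
as_points <- function(p) {
  if (inherits(p, "point_cloud")) p <- p$points
  p <- as.matrix(p)
  if (is.null(dim(p)) || ncol(p) != 3L)
    stop("points must be an N x 3 matrix")
  if (nrow(p) < 1L) stop("point set is empty")
  storage.mode(p) <- "double"
  if (!all(is.finite(p))) stop("points contain non-finite coordinates")
  dimnames(p) <- NULL
  p
}

#' Build a nearest-neighbour index over a fixed point set
#'
#' KD-tree over the rows of `points`; used wherever the closest skeleton
#' point to a candidate bone point is needed.
#'
#' @param points N x 3 matrix or `point_cloud`.
#' @return An object of class `spatial_index`.
#' @export
spatial_index <- function(points) {
  p <- as_points(points)
  structure(list(ptr = cpp_kdtree_build(p), points = p, n = nrow(p)),
            class = "spatial_index")
}

#' @export
print.spatial_index <- function(x, ...) {
  cat("spatial_index over", x$n, "points\n")
  invisible(x)
}

#' Distances from query points to their nearest indexed point
#'
#' @param query M x 3 matrix or `point_cloud`.
#' @param ref a [spatial_index()].
#' @return numeric(M) of nonnegative Euclidean distances in mm.
#' @export
closest_distances <- function(query, ref) {
  stopifnot(inherits(ref, "spatial_index"))
  q <- as_points(query)
  cpp_kdtree_query(ref$ptr, q)$distance
}

# nearest indices as well (internal)
closest_points <- function(query, ref) {
  q <- as_points(query)
  r <- cpp_kdtree_query(ref$ptr, q)
  list(distance = r$distance, index = r$index,
       point = ref$points[r$index, , drop = FALSE])
}

#' Deterministically subsample a point cloud
#'
#' Evenly strided subsample used to cap optimization cost; keeps the
#' full cloud when `n_max` is not exceeded.
#'
#' @param points N x 3 matrix.
#' @param n_max maximum number of points to keep.
#' @return Matrix with at most `n_max` rows.
#' @export
subsample_points <- function(points, n_max) {
  p <- as_points(points)
  n <- nrow(p)
  if (n <= n_max) return(p)
  idx <- unique(round(seq(1L, n, length.out = n_max)))
  p[idx, , drop = FALSE]
}
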