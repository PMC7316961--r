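#' Bone model
#'
#' One bone of the foot in its reference (unloaded, segmented) pose:
#' a point cloud used for registration and optionally a surface mesh.
#'
#' @param bone_id character bone identifier (see [foot_bone_names()]).
#' @param points N x 3 matrix or [point_cloud()] in the reference pose.
#' @param mesh optional [surface_mesh()] in the reference pose.
#' @return An object of class `bone_model`.
#' @export
bone_model <- function(bone_id, points, mesh = NULL) {
  stopifnot(is.character(bone_id), length(bone_id) == 1L)
  p <- as_points(points)
  if (!is.null(mesh)) stopifnot(inherits(mesh, "surface_mesh"))
  structure(list(bone_id = bone_id, points = p, mesh = mesh),
            class = "bone_model")
}

#' Names of the modelled bones
#'
#' The 28 foot bones plus tibia and fibula tracked by the workflow.
#'
#' @return character(30).
#' @export
foot_bone_names <- function() {
  c("tibia", "fibula", "calcaneus", "talus", "navicular", "cuboid",
    "cuneiform_medial", "cuneiform_intermediate", "cuneiform_lateral",
    paste0("metatarsal_", 1:5), "sesamoid_medial", "sesamoid_lateral",
    paste0("proximal_phalanx_", 1:5), paste0("middle_phalanx_", 2:5),
    paste0("distal_phalanx_", 1:5))
}

#' Coarse-to-fine foot segment hierarchy
#'
#' The ordered segment list used to initialize bone registration: the
#' whole foot first, then anatomical sub-segments (ankle, midfoot, rays,
#' metatarsus, phalanx rows), and finally bone-by-bone minimization from
#' the tibia to the distal phalanges. Registering coarse segments first
#' avoids the local minima that trap a cold per-bone start.
#'
#' @return A list of segments, each `list(order, name, bones)`; the last
#'   segment has `bone_by_bone = TRUE` and lists bones proximal to distal.
#' @export
foot_hierarchy <- function() {
  all_foot <- setdiff(foot_bone_names(), c("tibia", "fibula"))
  seg <- function(order, name, bones, bone_by_bone = FALSE)
    list(order = order, name = name, bones = bones,
         bone_by_bone = bone_by_bone)
  list(
    seg(1, "foot", all_foot),
    seg(2, "upper_ankle", c("tibia", "fibula")),
    seg(3, "ankle", c("calcaneus", "talus")),
    seg(4, "midfoot", c("cuneiform_medial", "cuneiform_intermediate",
                        "cuneiform_lateral", "cuboid")),
    seg(5, "line_1", c("metatarsal_1", "sesamoid_medial",
                       "proximal_phalanx_1", "distal_phalanx_1")),
    seg(6, "line_2", c("metatarsal_2", "proximal_phalanx_2",
                       "middle_phalanx_2", "distal_phalanx_2")),
    seg(7, "line_3", c("metatarsal_3", "proximal_phalanx_3",
                       "middle_phalanx_3", "distal_phalanx_3")),
    seg(8, "line_4", c("metatarsal_4", "proximal_phalanx_4",
                       "middle_phalanx_4", "distal_phalanx_4")),
    seg(9, "line_5", c("metatarsal_5", "proximal_phalanx_5",
                       "middle_phalanx_5", "distal_phalanx_5")),
    seg(10, "metatarsus", c(paste0("metatarsal_", 1:5), "sesamoid_medial",
                            "sesamoid_lateral")),
    seg(11, "metatarsus_1_plus", c("metatarsal_1", "sesamoid_medial")),
    seg(12, "proximal_phalanges", paste0("proximal_phalanx_", 1:5)),
    seg(13, "middle_phalanges", paste0("middle_phalanx_", 2:5)),
    seg(14, "distal_phalanges", paste0("distal_phalanx_", 1:5)),
    seg(15, "bone", c("tibia", "fibula", "calcaneus", "talus", "navicular",
                      "cuboid", "cuneiform_medial", "cuneiform_intermediate",
                      "cuneiform_lateral", paste0("metatarsal_", 1:5),
                      "sesamoid_medial", "sesamoid_lateral",
                      paste0("proximal_phalanx_", 1:5),
                      paste0("middle_phalanx_", 2:5),
                      paste0("distal_phalanx_", 1:5)),
        bone_by_bone = TRUE)
  )
}

#' Registration cost: mean squared closest-point distance
#'
#' The objective of the rigid bone-to-skeleton fit: the mean over bone
#' points of the squared distance from the transformed point to its
#' nearest skeleton point. Nearest neighbours are recomputed at every
#' evaluation, since the matched skeleton point depends on the candidate
#' transform. Rotation is taken about `center` (points are centered
#' before rotation, translation added after), which decouples the
#' rotation and translation scales for the optimizer.
#'
#' @param params numeric(6): Euler Z-Y-X angles (rad) then translation
#'   (mm).
#' @param bone_pts N x 3 matrix or [point_cloud()].
#' @param skeleton a [spatial_index()] over the skeleton cloud.
#' @param center numeric(3) rotation center; default the bone centroid.
#' @return Nonnegative scalar (mm^2).
#' @export
registration_cost <- function(params, bone_pts, skeleton, center = NULL) {
  stopifnot(inherits(skeleton, "spatial_index"), length(params) == 6L)
  p <- as_points(bone_pts)
  if (is.null(center)) center <- colMeans(p)
  R <- rotation_zyx(params[1:3])
  x <- sweep(p, 2, center) %*% t(R)
  x <- sweep(x, 2, center + params[4:6], `+`)
  cpp_kdtree_meansq(skeleton$ptr, x)
}

# centered 6-parameter delta -> world-frame rigid transform
params_to_transform <- function(params, center) {
  R <- rotation_zyx(params[1:3])
  rigid_transform(params[1:3],
                  as.numeric(center - R %*% center) + params[4:6])
}

# one Kabsch step on fixed nearest-neighbour correspondences
kabsch_transform <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(euler_from_rotation(R), as.numeric(cq - R %*% cp))
}

#' Rigidly register a bone cloud onto the skeleton
#'
#' Minimizes [registration_cost()] starting from `init` with a
#' quasi-Newton sequential quadratic-programming-style scheme (numerical
#' gradients, restarts until no further decrease), followed by
#' closest-point (Kabsch) polish iterations that are only accepted while
#' the cost keeps decreasing. The returned residual is the mean
#' *non-squared* closest-point distance at the optimum, matching how
#' registration quality is reported; the optimized objective is the mean
#' squared form.
#'
#' @param bone_pts N x 3 matrix or [point_cloud()].
#' @param skeleton a [spatial_index()].
#' @param init initial [rigid_transform()].
#' @param control list of optimizer settings: `maxit` (500), `reltol`
#'   (1e-10), `max_points` subsample cap for the objective (2000),
#'   `restarts` (3), `icp_polish` (TRUE).
#' @return list with `transform`, `residual` (mm), `iterations`,
#'   `converged`, `cost` (mm^2).
#' @export
register_rigid <- function(bone_pts, skeleton, init = identity_transform(),
                           control = list()) {
  ctl <- modifyList(list(maxit = 500, reltol = 1e-9, max_points = 1500,
                         restarts = 3, icp_polish = TRUE,
                         escape_cost = 0.5, escape_step = 0.2), control)
  p_full <- as_points(bone_pts)
  p0_full <- apply_rigid(init, p_full)
  p0 <- subsample_points(p0_full, ctl$max_points)
  center <- colMeans(p0)
  fn <- function(par) registration_cost(par, p0, skeleton, center)
  total_it <- 0L
  converged <- FALSE
  run_bfgs <- function(par, maxit) {
    opt <- optim(par, fn, method = "BFGS",
                 control = list(maxit = maxit, reltol = ctl$reltol,
                                parscale = c(rep(0.02, 3), rep(1, 3))))
    total_it <<- total_it + opt$counts[1]
    if (opt$convergence == 0) converged <<- TRUE
    opt
  }
  descend <- function(par) {
    f_prev <- fn(par)
    for (r in seq_len(ctl$restarts + 1L)) {
      opt <- run_bfgs(par, ctl$maxit)
      par <- opt$par
      if (f_prev - opt$value < 1e-14 * max(1, f_prev)) break
      f_prev <- opt$value
    }
    opt
  }
  opt <- descend(rep(0, 6))
  if (is.finite(ctl$escape_cost) && opt$value > ctl$escape_cost) {
    # shallow rotational wells are common for near-symmetric bones: probe
    # a fixed stencil of angle offsets around the found minimum and keep
    # the best basin (deterministic; no random multi-start)
    best <- opt
    for (d in 1:3) for (s in c(-1, 1)) {
      par2 <- opt$par
      par2[d] <- par2[d] + s * ctl$escape_step
      o2 <- run_bfgs(par2, 80)
      if (o2$value < best$value) best <- o2
    }
    if (best$value < opt$value - 1e-12) opt <- descend(best$par)
  }
  par <- opt$par
  f_prev <- opt$value
  if (!converged)
    warning("registration did not converge within ", ctl$maxit,
            " iterations; returning best-so-far")
  delta <- params_to_transform(par, center)
  if (isTRUE(ctl$icp_polish)) {
    # fixed-correspondence closest-point refinement to machine precision
    cur <- delta
    f_cur <- f_prev
    for (k in 1:50) {
      x <- apply_rigid(cur, p0)
      nn <- closest_points(x, skeleton)
      step <- kabsch_transform(x, nn$point)
      cand <- compose_rigid(step, cur)
      f_cand <- cpp_kdtree_meansq(skeleton$ptr, apply_rigid(cand, p0))
      if (f_cand >= f_cur - 1e-16) break
      cur <- cand; f_cur <- f_cand
      total_it <- total_it + 1L
    }
    if (f_cur <= f_prev) { delta <- cur; f_prev <- f_cur }
  }
  tf <- compose_rigid(delta, init)
  res <- mean(closest_distances(apply_rigid(tf, p_full), skeleton))
  list(transform = tf, residual = res, iterations = as.integer(total_it),
       converged = converged, cost = f_prev)
}

#' Remove skeleton points already explained by a placed bone
#'
#' Returns the skeleton points whose distance to the placed bone cloud
#' exceeds `radius`; used during bone-by-bone minimization so that
#' subsequent (smaller, more distal) bones are fitted on remaining
#' points only.
#'
#' @param skeleton_pts N x 3 matrix or [point_cloud()].
#' @param placed_bone_pts points of the registered bone, world mm.
#' @param radius capture radius in mm (> 0); the default in the pipeline
#'   is one voxel diagonal.
#' @return Matrix of remaining skeleton points.
#' @export
subtract_registered <- function(skeleton_pts, placed_bone_pts, radius) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  sk <- as_points(skeleton_pts)
  idx <- spatial_index(placed_bone_pts)
  keep <- closest_distances(sk, idx) > radius
  if (!any(keep)) stop("skeleton exhausted: all points within radius")
  sk[keep, , drop = FALSE]
}

#' Subvoxel refinement against the skeleton isosurface
#'
#' Polishes a transform by trimmed point-to-surface closest-point
#' iterations of the bone surface onto the thresholded skeleton's
#' isosurface. Working on the two continuous surfaces removes the
#' voxel-lattice quantization that limits cloud-to-cloud registration to
#' roughly half a voxel. Correspondences farther than `trim_factor`
#' times the median distance (joint contact zones, neighbouring bones)
#' are dropped each iteration.
#'
#' @param bone_surface_pts points on the bone surface in the reference
#'   pose (mesh vertices).
#' @param skeleton_index a [mesh_index()] over the skeleton isosurface.
#' @param init starting [rigid_transform()] (from the cloud hierarchy).
#' @param max_iter maximum closest-point iterations.
#' @param trim_factor correspondence trimming threshold.
#' @return list with `transform` and `residual` (mean bone-surface to
#'   skeleton-surface distance, mm).
#' @export
refine_to_surface <- function(bone_surface_pts, skeleton_index,
                              init = identity_transform(), max_iter = 30,
                              trim_factor = 4) {
  stopifnot(inherits(skeleton_index, "mesh_index"))
  x0 <- as_points(bone_surface_pts)
  cur <- init
  f_cur <- Inf
  for (k in seq_len(max_iter)) {
    x <- apply_rigid(cur, x0)
    cl <- closest_on_surface(x, skeleton_index)
    keep <- cl$distance <= trim_factor * max(stats::median(cl$distance),
                                             1e-9)
    f_new <- mean(cl$distance[keep]^2)
    if (f_new >= f_cur - 1e-12) break
    f_cur <- f_new
    step <- kabsch_transform(x[keep, , drop = FALSE],
                             cl$point[keep, , drop = FALSE])
    cur <- compose_rigid(step, cur)
  }
  res <- mean(closest_on_surface(apply_rigid(cur, x0),
                                 skeleton_index)$distance)
  list(transform = cur, residual = res)
}

#' Hierarchical registration of all bones onto a skeleton cloud
#'
#' Segments are processed in [foot_hierarchy()] order. For each segment
#' the member bones' clouds (at their current transforms) are pooled and
#' registered as one rigid body; the found correction composes onto each
#' member's transform and becomes its initial solution at the next level.
#' The final level registers bone by bone from the tibia to the distal
#' phalanges; with `subtract = TRUE`, skeleton points within
#' `subtract_radius` of each already-registered bone are removed before
#' the next bone is fitted.
#'
#' @param bones list of [bone_model()] objects covering the hierarchy.
#' @param hierarchy as returned by [foot_hierarchy()].
#' @param skeleton_pts N x 3 matrix or [point_cloud()] of skeleton
#'   voxel centers.
#' @param subtract logical; subtract placed bones during the final
#'   bone-by-bone pass.
#' @param subtract_radius capture radius in mm; default one voxel
#'   diagonal at CT resolution 0.66 x 0.66 x 1.0 mm.
#' @param init optional named list of initial transforms per bone.
#' @param control optimizer control list, see [register_rigid()].
#' @param skeleton_mesh optional skeleton isosurface ([surface_mesh()] or
#'   [mesh_index()]); when given, each bone's transform is polished with
#'   [refine_to_surface()] (using the bone mesh, or its points) and
#'   `surface_residuals` (mean bone-surface-to-skeleton-surface
#'   distance, the registration quality measure) are reported.
#' @param verbose print per-segment progress.
#' @return An object of class `registration_result`: named `transforms`,
#'   named `residuals` (mean closest-point distance of the bone cloud to
#'   the skeleton cloud, mm), per-segment `segments` data frame,
#'   `converged` flags, and `surface_residuals` when `skeleton_mesh` is
#'   supplied.
#' @export
hierarchical_register <- function(bones, hierarchy = foot_hierarchy(),
                                  skeleton_pts, subtract = FALSE,
                                  subtract_radius = sqrt(0.66^2 + 0.66^2 + 1),
                                  init = NULL, control = list(),
                                  skeleton_mesh = NULL, verbose = FALSE) {
  ids <- vapply(bones, function(b) b$bone_id, "")
  names(bones) <- ids
  hier_bones <- unique(unlist(lapply(hierarchy, `[[`, "bones")))
  missing <- setdiff(hier_bones, ids)
  if (length(missing))
    stop("configuration error: bones in hierarchy but not provided: ",
         paste(missing, collapse = ", "))
  last <- hierarchy[[length(hierarchy)]]
  if (!setequal(last$bones, ids))
    stop("configuration error: final hierarchy level must cover every ",
         "bone exactly once")
  # within the hierarchy the previous level provides a good init, so the
  # local-minimum escape stencil is off and the point budget reduced
  control <- modifyList(list(max_points = 1000, restarts = 1,
                             escape_cost = Inf), control)
  sk_full <- as_points(skeleton_pts)
  index_full <- spatial_index(sk_full)
  tfs <- stats::setNames(lapply(ids, function(i) identity_transform()), ids)
  if (!is.null(init)) for (id in names(init)) tfs[[id]] <- init[[id]]
  conv <- stats::setNames(rep(TRUE, length(ids)), ids)
  seg_log <- list()
  for (seg in hierarchy) {
    if (isTRUE(seg$bone_by_bone)) {
      sk_cur <- sk_full
      idx_cur <- index_full
      for (id in seg$bones) {
        r <- register_rigid(bones[[id]]$points, idx_cur, init = tfs[[id]],
                            control = control)
        tfs[[id]] <- r$transform
        conv[[id]] <- r$converged
        seg_log[[length(seg_log) + 1L]] <-
          data.frame(segment = paste0("bone:", id), iterations = r$iterations,
                     cost = r$cost)
        if (verbose)
          message(sprintf("  bone %-22s iters %4d residual %.3f mm", id,
                          r$iterations, r$residual))
        if (subtract) {
          placed <- apply_rigid(tfs[[id]], bones[[id]]$points)
          sk_cur <- tryCatch(
            subtract_registered(sk_cur, placed, subtract_radius),
            error = function(e) sk_cur)
          idx_cur <- spatial_index(sk_cur)
        }
      }
    } else {
      pooled <- do.call(rbind, lapply(seg$bones, function(id)
        apply_rigid(tfs[[id]], bones[[id]]$points)))
      r <- register_rigid(pooled, index_full, control = control)
      for (id in seg$bones) tfs[[id]] <- compose_rigid(r$transform, tfs[[id]])
      seg_log[[length(seg_log) + 1L]] <-
        data.frame(segment = seg$name, iterations = r$iterations,
                   cost = r$cost)
      if (verbose)
        message(sprintf("segment %-22s iters %4d cost %.4f mm^2", seg$name,
                        r$iterations, r$cost))
    }
  }
  surface_residuals <- NULL
  if (!is.null(skeleton_mesh)) {
    ski <- if (inherits(skeleton_mesh, "mesh_index")) skeleton_mesh else
      mesh_index(skeleton_mesh)
    surface_residuals <- stats::setNames(rep(NA_real_, length(ids)), ids)
    for (id in ids) {
      pts <- if (!is.null(bones[[id]]$mesh)) bones[[id]]$mesh$vertices else
        bones[[id]]$points
      rf <- refine_to_surface(pts, ski, init = tfs[[id]])
      tfs[[id]] <- rf$transform
      surface_residuals[[id]] <- rf$residual
      if (verbose)
        message(sprintf("  refine %-20s surface residual %.3f mm", id,
                        rf$residual))
    }
  }
  residuals <- vapply(ids, function(id)
    mean(closest_distances(apply_rigid(tfs[[id]], bones[[id]]$points),
                           index_full)), 0)
  structure(list(transforms = tfs, residuals = residuals,
                 surface_residuals = surface_residuals,
                 segments = do.call(rbind, seg_log), converged = conv),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("registration_result:", length(x$transforms), "bones, mean residual",
      sprintf("%.3f mm\n", mean(x$residuals)))
  invisible(x)
}
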