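# Synthetic foot phantom: superellipsoid bones laid out as a foot,
# voxelized skeletons with known per-bone transforms, a perturbed
# "generic" source model, and ligament fibers -- everything a pure
# function of (spec, seed) so ground truth is always available.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# subdivided icosahedron on the unit sphere
icosphere <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7),
             c(8, 2, 9), c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9),
             c(4, 9, 10), c(5, 10, 6), c(3, 5, 12), c(7, 3, 11),
             c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edge_id <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_id[[key]]
      if (!is.null(id)) return(id)
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      id <- nrow(verts)
      edge_id[[key]] <- id
      id
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c_ <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                  c(ab, bc, ca))
    }
    v <- verts
    f <- nf
  }
  surface_mesh(v, f)
}

# superellipsoid radius along unit direction u for semi-axes r, exponent p
superellipsoid_scale <- function(u, radii, exponent) {
  (abs(u[, 1] / radii[1])^exponent + abs(u[, 2] / radii[2])^exponent +
     abs(u[, 3] / radii[3])^exponent)^(-1 / exponent)
}

#' Generate one synthetic bone surface
#'
#' A superellipsoid (semi-axes `radii`, shape exponent `exponent`) with a
#' smooth pseudo-random radial perturbation of amplitude `noise_amp`,
#' sampled on a subdivided icosahedron; closed genus-0 and deterministic
#' per seed.
#'
#' @param radii numeric(3) semi-axes in mm.
#' @param exponent superellipsoid exponent (2 = ellipsoid, larger =
#'   boxier).
#' @param noise_amp maximum radial perturbation in mm.
#' @param seed integer seed for the perturbation field.
#' @param subdiv icosphere subdivision level (3 = 642 vertices).
#' @param center numeric(3) center position, mm.
#' @param param_rotation optional 3x3 rotation applied to the sphere
#'   sampling before shaping (yields a different tessellation of the
#'   same surface, used for the generic model remesh).
#' @return A closed [surface_mesh()].
#' @export
generate_bone <- function(radii, exponent = 2.3, noise_amp = 0, seed = 1,
                          subdiv = 3, center = c(0, 0, 0),
                          param_rotation = NULL) {
  stopifnot(all(radii > 0), exponent > 0, noise_amp >= 0)
  ico <- icosphere(subdiv)
  u <- ico$vertices
  if (!is.null(param_rotation)) u <- u %*% t(param_rotation)
  r <- superellipsoid_scale(u, radii, exponent)
  v <- u * r
  if (noise_amp > 0) {
    g <- with_seed(seed, {
      k <- 8
      dirs <- matrix(rnorm(3 * k), k, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      amps <- runif(k, -1, 1)
      sig <- 0.7
      field <- rep(0, nrow(u))
      for (i in seq_len(k)) {
        ang <- acos(pmax(-1, pmin(1, u %*% dirs[i, ])))
        field <- field + amps[i] * exp(-ang^2 / (2 * sig^2))
      }
      field
    })
    g <- g / max(abs(g)) * noise_amp
    v <- v + as.numeric(g) * u
  }
  surface_mesh(sweep(v, 2, center, `+`), ico$faces)
}

# nominal foot layout: name, center (mm), semi-radii (mm)
# x anterior (heel -> toes), y lateral, z superior; all three semi-axes
# are distinct so principal-axis alignment is never roll-degenerate
# (real bones have no revolution symmetry either)
phantom_layout <- function() {
  L <- list(
    tibia = list(c(55, -5, 110), c(18, 16, 40)),
    fibula = list(c(55, 24, 112), c(10, 9, 38)),
    talus = list(c(55, 0, 55), c(24, 16, 13)),
    calcaneus = list(c(35, 2, 22), c(38, 20, 17)),
    navicular = list(c(92, 0, 45), c(10, 14, 11)),
    cuboid = list(c(92, 28, 28), c(12, 11, 10)),
    cuneiform_medial = list(c(115, -20, 40), c(9.3, 8, 8.7)),
    cuneiform_intermediate = list(c(115, -1, 42), c(8.2, 7, 7.6)),
    cuneiform_lateral = list(c(115, 15, 40), c(8.1, 7, 7.4)),
    metatarsal_1 = list(c(157, -28, 36), c(28, 8.3, 7.7)),
    metatarsal_2 = list(c(157, -12, 35), c(27, 6.3, 5.7)),
    metatarsal_3 = list(c(157, 2, 35), c(27, 6.3, 5.7)),
    metatarsal_4 = list(c(157, 16, 35), c(27, 6.3, 5.7)),
    metatarsal_5 = list(c(157, 30, 35), c(27, 6.3, 5.7)),
    sesamoid_medial = list(c(180, -28, 22), c(5, 4.2, 3.8)),
    sesamoid_lateral = list(c(180, -16, 22), c(4, 3.7, 3.3)),
    proximal_phalanx_1 = list(c(202, -28, 36), c(12, 7, 6)),
    proximal_phalanx_2 = list(c(200, -12, 35), c(10, 5.3, 4.7)),
    proximal_phalanx_3 = list(c(200, 2, 35), c(10, 5.3, 4.7)),
    proximal_phalanx_4 = list(c(200, 16, 35), c(10, 5.3, 4.7)),
    proximal_phalanx_5 = list(c(200, 30, 35), c(10, 5.3, 4.7)),
    middle_phalanx_2 = list(c(222, -12, 35), c(6, 4.3, 3.7)),
    middle_phalanx_3 = list(c(222, 2, 35), c(6, 4.3, 3.7)),
    middle_phalanx_4 = list(c(222, 16, 35), c(6, 4.3, 3.7)),
    middle_phalanx_5 = list(c(222, 30, 35), c(6, 4.3, 3.7)),
    distal_phalanx_1 = list(c(224, -28, 36), c(8, 5, 4)),
    distal_phalanx_2 = list(c(238, -12, 35), c(5, 3.8, 3.2)),
    distal_phalanx_3 = list(c(238, 2, 35), c(5, 3.8, 3.2)),
    distal_phalanx_4 = list(c(238, 16, 35), c(5, 3.8, 3.2)),
    distal_phalanx_5 = list(c(238, 30, 35), c(5, 3.8, 3.2)))
  L
}

#' Phantom specification
#'
#' Conditions of the synthetic validation study: the 30-bone layout
#' (28 foot bones plus tibia and fibula), CT voxel spacing
#' 0.66 x 0.66 x 1.0 mm, surface noise, and the seed fixing all
#' randomness.
#'
#' @param spacing numeric(3) voxel spacing in mm.
#' @param noise_amp surface noise amplitude in mm.
#' @param exponent superellipsoid shape exponent.
#' @param subdiv icosphere subdivision per bone.
#' @param seed integer master seed.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(spacing = c(0.66, 0.66, 1.0), noise_amp = 0.4,
                         exponent = 2.3, subdiv = 3, seed = 42) {
  stopifnot(all(spacing > 0), noise_amp >= 0)
  structure(list(spacing = spacing, noise_amp = noise_amp,
                 exponent = exponent, subdiv = subdiv, seed = seed,
                 layout = phantom_layout()), class = "phantom_spec")
}

# smooth invertible deformation used to build the generic source model:
# isotropic scale about the bone center plus a few gaussian bumps
make_generic_warp <- function(center, radii, seed, scale = 1.05,
                              bump_amp = 2, n_bumps = 6) {
  prm <- with_seed(seed, {
    ctrs <- sweep(matrix(rnorm(3 * n_bumps), n_bumps, 3) *
                    rep(radii, each = n_bumps) * 0.7, 2, center, `+`)
    dirs <- matrix(rnorm(3 * n_bumps), n_bumps, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    amps <- runif(n_bumps, 0.5, 1) * bump_amp
    axis_scale <- runif(3, 0.95, 1.05)
    twist <- runif(1, -1, 1) * 6 * pi / 180
    list(ctrs = ctrs, dirs = dirs, amps = amps,
         sigma = pmax(0.3 * mean(radii), 3),
         axis_scale = axis_scale, twist = twist)
  })
  function(x) {
    x <- as_points(x)
    xc <- sweep(x, 2, center)
    # global non-similarity part: anisotropic scale + twist about the
    # longest semi-axis (similarity alignment cannot absorb these)
    out <- xc %*% diag(scale * prm$axis_scale)
    ax <- which.max(radii)
    th <- prm$twist * xc[, ax] / radii[ax]
    oth <- setdiff(1:3, ax)
    u <- out[, oth[1]]; v <- out[, oth[2]]
    out[, oth[1]] <- cos(th) * u - sin(th) * v
    out[, oth[2]] <- sin(th) * u + cos(th) * v
    out <- sweep(out, 2, center, `+`)
    for (i in seq_along(prm$amps)) {
      d2 <- rowSums(sweep(x, 2, prm$ctrs[i, ])^2)
      w <- exp(-d2 / (2 * prm$sigma^2))
      out <- out + outer(w, prm$dirs[i, ]) * prm$amps[i]
    }
    out
  }
}

#' Generate the full synthetic foot phantom
#'
#' Builds the 30 phantom bones in a proximal-to-distal layout with 1-2 mm
#' (or larger) joint gaps, their reference binary masks on a common grid,
#' a ligament set (including a multi-fiber plantar aponeurosis group),
#' and a "generic" source model: each bone retessellated and carried
#' through a known smooth deformation (about 5% scale plus 1-2 mm bumps)
#' with attachment points at known true positions, so morphing accuracy
#' is checkable against ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param masks also voxelize per-bone reference masks (slower).
#' @return list of class `foot_phantom`: `bones` (named [bone_model()]
#'   list), `hierarchy`, `ligaments`, `masks` (per-bone `binary_mask`,
#'   if requested), `generic` (meshes + attachments + true patient
#'   attachment positions), `grid` (origin/spacing/dims), `spec`.
#' @export
generate_foot_phantom <- function(spec = phantom_spec(), masks = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  ids <- foot_bone_names()
  layout <- spec$layout
  stopifnot(setequal(names(layout), ids))
  meshes <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    meshes[[id]] <- generate_bone(layout[[id]][[2]], spec$exponent,
                                  spec$noise_amp, seed = spec$seed + i,
                                  subdiv = spec$subdiv,
                                  center = layout[[id]][[1]])
  }
  grid <- phantom_grid(meshes, spec$spacing)
  bone_masks <- NULL
  bones <- list()
  for (id in ids) {
    if (masks) {
      m <- voxelize_meshes(list(meshes[[id]]), spec$spacing)
      if (is.null(bone_masks)) bone_masks <- list()
      bone_masks[[id]] <- m
      pts <- mask_to_points(m, surface_only = TRUE, label = id)
    } else {
      pts <- point_cloud(meshes[[id]]$vertices, label = id)
    }
    bones[[id]] <- bone_model(id, pts, meshes[[id]])
  }
  ligaments <- phantom_ligaments(meshes)
  # generic source model: retessellated + warped copies, known truth
  gen_meshes <- list()
  gen_attach <- list()
  true_attach <- list()
  rot <- rotation_zyx(c(0.4, 0.25, 0.15))
  for (i in seq_along(ids)) {
    id <- ids[i]
    warp <- make_generic_warp(layout[[id]][[1]], layout[[id]][[2]],
                              seed = spec$seed + 1000 + i)
    remesh <- generate_bone(layout[[id]][[2]], spec$exponent,
                            spec$noise_amp, seed = spec$seed + i,
                            subdiv = spec$subdiv,
                            center = layout[[id]][[1]],
                            param_rotation = rot)
    gen_meshes[[id]] <- surface_mesh(warp(remesh$vertices), remesh$faces)
    att <- attachment_points_for_bone(ligaments, id)
    if (nrow(att$points) > 0) {
      gen_attach[[id]] <- warp(att$points)
      rownames(gen_attach[[id]]) <- att$names
      true_attach[[id]] <- att$points
      rownames(true_attach[[id]]) <- att$names
    }
  }
  structure(list(bones = bones, hierarchy = foot_hierarchy(),
                 ligaments = ligaments, masks = bone_masks,
                 generic = list(meshes = gen_meshes,
                                attachments = gen_attach,
                                true_attachments = true_attach),
                 grid = grid, spec = spec),
            class = "foot_phantom")
}

#' @export
print.foot_phantom <- function(x, ...) {
  cat("foot_phantom:", length(x$bones), "bones,", length(x$ligaments),
      "ligament fibers, spacing (",
      paste(x$spec$spacing, collapse = ", "), ") mm\n")
  invisible(x)
}

phantom_grid <- function(meshes, spacing, pad = 5) {
  allv <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  lo <- apply(allv, 2, min) - pad
  hi <- apply(allv, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  list(origin = lo, spacing = spacing, dims = dims)
}

# fiber table: calcaneus->phalanges (plantar aponeurosis), long plantar,
# deltoid complex, transverse metatarsal, spring/bifurcate
phantom_ligament_pairs <- function() {
  rbind(
    data.frame(name = paste0("plantar_aponeurosis_", 1:5),
               group = "plantar_aponeurosis", origin = "calcaneus",
               insertion = paste0("proximal_phalanx_", 1:5)),
    data.frame(name = paste0("long_plantar_", 2:5), group = "long_plantar",
               origin = "calcaneus", insertion = paste0("metatarsal_", 2:5)),
    data.frame(name = c("tibiocalcaneal", "anterior_tibiotalar",
                        "posterior_tibiotalar", "tibionavicular"),
               group = "deltoid", origin = "tibia",
               insertion = c("calcaneus", "talus", "talus", "navicular")),
    data.frame(name = paste0("deep_transverse_metatarsal_", 1:4),
               group = "deep_transverse_metatarsal",
               origin = paste0("metatarsal_", 1:4),
               insertion = paste0("metatarsal_", 2:5)),
    data.frame(name = c("spring", "calcaneonavicular", "calcaneocuboid"),
               group = c("spring", "bifurcate", "bifurcate"),
               origin = "calcaneus",
               insertion = c("navicular", "navicular", "cuboid")))
}

phantom_ligaments <- function(meshes) {
  pairs <- phantom_ligament_pairs()
  coms <- lapply(meshes, center_of_mass)
  idx <- lapply(meshes, mesh_index)
  ligs <- list()
  for (i in seq_len(nrow(pairs))) {
    ob <- pairs$origin[i]; ib <- pairs$insertion[i]
    # attachment = surface point nearest to the other bone's COM,
    # nudged along the fiber name hash to decorrelate shared origins
    po <- closest_on_surface(matrix(coms[[ib]], 1), idx[[ob]])$point[1, ]
    pi_ <- closest_on_surface(matrix(coms[[ob]], 1), idx[[ib]])$point[1, ]
    ligs[[pairs$name[i]]] <- list(name = pairs$name[i],
                                  group = pairs$group[i],
                                  origin_bone = ob, origin = po,
                                  insertion_bone = ib, insertion = pi_)
  }
  ligs
}

attachment_points_for_bone <- function(ligaments, bone_id) {
  pts <- matrix(0, 0, 3)
  nms <- character(0)
  for (lig in ligaments) {
    if (lig$origin_bone == bone_id) {
      pts <- rbind(pts, lig$origin)
      nms <- c(nms, paste0(lig$name, ":origin"))
    }
    if (lig$insertion_bone == bone_id) {
      pts <- rbind(pts, lig$insertion)
      nms <- c(nms, paste0(lig$name, ":insertion"))
    }
  }
  list(points = pts, names = nms)
}

#' Voxelize closed meshes into a binary mask
#'
#' A voxel is true iff its center lies inside any mesh (z-column parity
#' test). With `origin`/`dims` omitted, a tight grid with `pad` mm
#' margin is used.
#'
#' @param meshes list of closed surface meshes.
#' @param spacing numeric(3) mm.
#' @param origin,dims optional grid; defaults to a tight bounding grid.
#' @param pad margin in mm for the automatic grid.
#' @return A `binary_mask` [voxel_volume()].
#' @export
voxelize_meshes <- function(meshes, spacing, origin = NULL, dims = NULL,
                            pad = 2) {
  if (length(meshes) == 0) stop("empty mesh list")
  for (m in meshes)
    if (!mesh_is_closed(m)) stop("voxelize requires closed meshes")
  if (is.null(origin) || is.null(dims)) {
    g <- phantom_grid(meshes, spacing, pad)
    origin <- g$origin; dims <- g$dims
  }
  arr <- array(FALSE, dims)
  for (m in meshes) {
    # tight aligned subgrid for this mesh
    lo <- apply(m$vertices, 2, min); hi <- apply(m$vertices, 2, max)
    i0 <- pmax(0L, as.integer(floor((lo - origin) / spacing)) - 1L)
    i1 <- pmin(dims - 1L, as.integer(ceiling((hi - origin) / spacing)) + 1L)
    sub_dims <- i1 - i0 + 1L
    sub_origin <- origin + i0 * spacing
    v <- cpp_voxelize_mesh(m$vertices, m$faces, sub_origin, spacing,
                           sub_dims)
    sub <- array(v == 1L, sub_dims)
    rng1 <- (i0[1] + 1):(i1[1] + 1)
    rng2 <- (i0[2] + 1):(i1[2] + 1)
    rng3 <- (i0[3] + 1):(i1[3] + 1)
    arr[rng1, rng2, rng3] <- arr[rng1, rng2, rng3] | sub
  }
  voxel_volume(arr, spacing, origin)
}

#' Rasterize a point cloud onto a grid
#'
#' Inverse of [mask_to_points()] at identical grid metadata: each point
#' sets the voxel whose center is nearest.
#'
#' @param points N x 3 matrix or [point_cloud()].
#' @param spacing,origin,dims grid metadata.
#' @return A `binary_mask`.
#' @export
points_to_mask <- function(points, spacing, origin, dims) {
  p <- as_points(points)
  idx <- round(sweep(sweep(p, 2, origin), 2, spacing, `/`)) + 1
  if (any(idx < 1) || any(sweep(idx, 2, dims, `>`)))
    stop("points fall outside the grid")
  arr <- array(FALSE, dims)
  arr[idx] <- TRUE
  voxel_volume(arr, spacing, origin)
}

#' Random ground-truth load-case transforms
#'
#' A whole-foot rigid motion (rotation about the foot centroid plus a
#' translation) composed with small per-bone perturbations about each
#' bone's centroid; the tibia and fibula receive only the per-bone
#' perturbation (the leg is held by the bench). All rotations are drawn
#' as random axis-angle.
#'
#' @param phantom a [generate_foot_phantom()] result.
#' @param foot_rot_deg,foot_trans_mm whole-foot motion magnitudes. Note
#'   the rotation lever arm: a rotation about the foot centroid displaces
#'   distal bones by roughly 0.02 mm per degree per mm of lever, so the
#'   defaults keep every bone displacement within the load-case
#'   plausibility bounds.
#' @param bone_rot_deg,bone_trans_mm per-bone perturbation caps.
#' @param seed integer seed.
#' @return Named list of [rigid_transform()] per bone.
#' @export
phantom_load_transforms <- function(phantom, foot_rot_deg = 4,
                                    foot_trans_mm = 3, bone_rot_deg = 2,
                                    bone_trans_mm = 1.5, seed = 1) {
  ids <- names(phantom$bones)
  foot_ids <- setdiff(ids, c("tibia", "fibula"))
  ctr <- colMeans(do.call(rbind, lapply(phantom$bones[foot_ids],
                                        function(b) colMeans(b$points))))
  with_seed(seed, {
    foot_tf <- random_rigid_about(ctr, foot_rot_deg, foot_trans_mm)
    tfs <- list()
    for (id in ids) {
      c_b <- colMeans(phantom$bones[[id]]$points)
      local <- random_rigid_about(c_b, bone_rot_deg * runif(1),
                                  bone_trans_mm * runif(1))
      tfs[[id]] <- if (id %in% foot_ids) compose_rigid(foot_tf, local) else
        local
    }
    tfs
  })
}

random_rigid_about <- function(center, rot_deg, trans_mm) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- rot_deg * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  tr <- rnorm(3); tr <- tr / sqrt(sum(tr^2)) * trans_mm
  rigid_transform(euler_from_rotation(R),
                  as.numeric(center - R %*% center) + tr)
}

#' Regenerate one patient (target) bone at a chosen resolution
#'
#' Same continuous surface as the phantom bone, sampled at a different
#' icosphere subdivision; used as a dense morphing target.
#'
#' @param phantom a [generate_foot_phantom()] result.
#' @param bone_id bone name.
#' @param subdiv icosphere subdivision (default: the phantom's).
#' @return A closed [surface_mesh()].
#' @export
phantom_patient_mesh <- function(phantom, bone_id, subdiv = NULL) {
  spec <- phantom$spec
  i <- match(bone_id, foot_bone_names())
  if (is.na(i)) stop("unknown bone: ", bone_id)
  if (is.null(subdiv)) subdiv <- spec$subdiv
  layout <- spec$layout
  generate_bone(layout[[bone_id]][[2]], spec$exponent, spec$noise_amp,
                seed = spec$seed + i, subdiv = subdiv,
                center = layout[[bone_id]][[1]])
}

#' Regenerate one generic source bone at a chosen resolution
#'
#' Rebuilds the generic (warped, retessellated) copy of a phantom bone,
#' optionally at a different icosphere subdivision than the phantom
#' default; the warp is identical to the one used by
#' [generate_foot_phantom()], so attachment ground truth still applies.
#'
#' @param phantom a [generate_foot_phantom()] result.
#' @param bone_id bone name.
#' @param subdiv icosphere subdivision (default: the phantom's).
#' @return A closed [surface_mesh()].
#' @export
phantom_generic_mesh <- function(phantom, bone_id, subdiv = NULL) {
  spec <- phantom$spec
  i <- match(bone_id, foot_bone_names())
  if (is.na(i)) stop("unknown bone: ", bone_id)
  if (is.null(subdiv)) subdiv <- spec$subdiv
  layout <- spec$layout
  warp <- make_generic_warp(layout[[bone_id]][[1]], layout[[bone_id]][[2]],
                            seed = spec$seed + 1000 + i)
  rot <- rotation_zyx(c(0.4, 0.25, 0.15))
  remesh <- generate_bone(layout[[bone_id]][[2]], spec$exponent,
                          spec$noise_amp, seed = spec$seed + i,
                          subdiv = subdiv, center = layout[[bone_id]][[1]],
                          param_rotation = rot)
  surface_mesh(warp(remesh$vertices), remesh$faces)
}

#' Apply a load case: move bones and voxelize the skeleton
#'
#' Moves every bone by its ground-truth transform and voxelizes the
#' union into a single skeleton mask at the phantom spacing, optionally
#' dilating by one voxel to create the joint interconnections that make
#' per-bone connected-component separation fail on real CT. The grid is
#' expanded automatically if bones leave the reference volume.
#'
#' @param phantom a [generate_foot_phantom()] result.
#' @param transforms named list of ground-truth [rigid_transform()].
#' @param dilate logical, one-voxel 6-neighbourhood dilation.
#' @param config_id,orientation,load_bw,footwear configuration metadata.
#' @return list with `state` (the truth [configuration_state()]),
#'   `skeleton` (`binary_mask`), and `skeleton_points` (surface cloud).
#' @export
apply_load_case <- function(phantom, transforms, dilate = FALSE,
                            config_id = "case", orientation = "N",
                            load_bw = 1, footwear = "bare") {
  ids <- names(phantom$bones)
  stopifnot(all(ids %in% names(transforms)))
  moved <- list()
  for (id in ids) {
    tf <- transforms[[id]]
    ang <- acos(max(-1, min(1, (sum(diag(rotation_zyx(tf$euler))) - 1) / 2)))
    com <- colMeans(phantom$bones[[id]]$points)
    disp <- sqrt(sum((apply_rigid(tf, matrix(com, 1)) - com)^2))
    if (ang > 20 * pi / 180 || disp > 15)
      stop("transform for ", id, " outside plausibility bounds ",
           "(<= 20 deg, <= 15 mm)")
    mesh <- phantom$bones[[id]]$mesh
    moved[[id]] <- surface_mesh(apply_rigid(tf, mesh$vertices), mesh$faces)
  }
  mask <- voxelize_meshes(moved, phantom$spec$spacing, pad = 3)
  if (dilate)
    mask <- voxel_volume(array(cpp_dilate6(as.logical(mask$array),
                                           dim(mask$array)),
                               dim(mask$array)),
                         mask$spacing, mask$origin)
  state <- configuration_state(config_id, transforms[ids], orientation,
                               load_bw, footwear)
  list(state = state,
       skeleton = mask,
       skeleton_points = mask_to_points(mask, surface_only = TRUE,
                                        label = "skeleton"))
}
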