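# Synthetic foot phantom: bones, layout, ligaments, generic model,
# voxelization and load cases.

test_that("generate_bone is deterministic with the stated shape", {
  # noise-free exponent-2 superellipsoid is an ellipsoid: analytic volume
  m <- generate_bone(c(12, 8, 6), exponent = 2, noise_amp = 0, subdiv = 4)
  expect_equal(mesh_volume(m), 4 / 3 * pi * 12 * 8 * 6, tolerance = 0.01)
  expect_true(mesh_is_closed(m))
  # same seed -> identical meshes; different seed -> different surface
  a <- generate_bone(c(10, 7, 5), noise_amp = 0.5, seed = 3)
  b <- generate_bone(c(10, 7, 5), noise_amp = 0.5, seed = 3)
  expect_identical(a$vertices, b$vertices)
  c_ <- generate_bone(c(10, 7, 5), noise_amp = 0.5, seed = 4)
  expect_gt(max(abs(a$vertices - c_$vertices)), 1e-3)
  # noise bounded: HRMSd to the unperturbed shape <= amplitude
  base <- generate_bone(c(10, 7, 5), noise_amp = 0, subdiv = 4)
  noisy <- generate_bone(c(10, 7, 5), noise_amp = 0.5, seed = 3,
                         subdiv = 4)
  expect_lte(hrmsd(noisy, base), 0.5 + 1e-9)
})

test_that("the phantom has the full bone set with separated joints", {
  ph <- get_phantom()
  expect_equal(length(ph$bones), 30)
  expect_setequal(names(ph$bones), foot_bone_names())
  expect_equal(ph$hierarchy[[1]]$bones,
               setdiff(foot_bone_names(), c("tibia", "fibula")))
  # ligaments: at least 20 fibers with a multi-fiber plantar group
  expect_gte(length(ph$ligaments), 20)
  groups <- vapply(ph$ligaments, `[[`, "", "group")
  expect_gte(sum(groups == "plantar_aponeurosis"), 3)
  # reference lengths all positive and above the joint gap
  ref <- identity_state(ph)
  lens <- vapply(ph$ligaments, function(f) ligament_length(ref, f), 0)
  expect_true(all(lens > 1))
  # nearby bones never touch: positive surface gap
  meshes <- lapply(ph$bones, `[[`, "mesh")
  idx <- lapply(meshes, mesh_index)
  ids <- names(meshes)
  min_gap <- Inf
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    ci <- colMeans(meshes[[i]]$vertices)
    cj <- colMeans(meshes[[j]]$vertices)
    if (sqrt(sum((ci - cj)^2)) > 90) next
    d <- min(closest_on_surface(meshes[[i]]$vertices, idx[[j]])$distance)
    min_gap <- min(min_gap, d)
  }
  expect_gt(min_gap, 1)
})

test_that("the generic model differs from the patient by the stated amount", {
  ph <- get_phantom()
  for (id in c("calcaneus", "metatarsal_2", "distal_phalanx_3")) {
    h <- hrmsd(ph$generic$meshes[[id]], ph$bones[[id]]$mesh)
    expect_gte(h, 0.5)
    expect_lte(h, 5)
  }
  # attachments carried through the known warp
  att <- ph$generic$attachments$calcaneus
  expect_gt(nrow(att), 3)
  expect_equal(rownames(att),
               rownames(ph$generic$true_attachments$calcaneus))
})

test_that("voxelization matches analytic volume and round-trips", {
  ball <- unit_sphere(4, r = 15)
  mk <- voxelize_meshes(list(ball), c(0.66, 0.66, 1.0))
  n_expected <- 4 / 3 * pi * 15^3 / prod(c(0.66, 0.66, 1.0))
  expect_equal(sum(mk$array), n_expected, tolerance = 0.02)
  # voxelize -> isosurface -> volume consistency
  expect_equal(mesh_volume(mask_to_mesh(mk)), 4 / 3 * pi * 15^3,
               tolerance = 0.03)
  expect_error(voxelize_meshes(list(), c(1, 1, 1)), "empty")
  # open meshes are rejected
  open_mesh <- surface_mesh(ball$vertices, ball$faces[-1, ])
  expect_error(voxelize_meshes(list(open_mesh), c(1, 1, 1)), "closed")
})

test_that("load cases voxelize the union with optional joint dilation", {
  ph <- get_phantom()
  ids <- names(ph$bones)
  idt <- stats::setNames(lapply(ids, function(i) identity_transform()),
                         ids)
  lc <- apply_load_case(ph, idt, dilate = FALSE)
  # identity transforms: skeleton equals the union of reference masks
  union_ref <- voxelize_meshes(lapply(ph$bones, `[[`, "mesh"),
                               ph$spec$spacing, lc$skeleton$origin,
                               dim(lc$skeleton$array))
  expect_identical(lc$skeleton$array, union_ref$array)
  # dilation connects adjacent bones at a joint
  lc_d <- apply_load_case(ph, idt, dilate = TRUE)
  expect_gt(sum(lc_d$skeleton$array), sum(lc$skeleton$array))
  tal <- voxelize_meshes(list(ph$bones$talus$mesh), ph$spec$spacing,
                         lc$skeleton$origin, dim(lc$skeleton$array))
  cal <- voxelize_meshes(list(ph$bones$calcaneus$mesh), ph$spec$spacing,
                         lc$skeleton$origin, dim(lc$skeleton$array))
  gap_before <- min(brute_nn(
    subsample_points(mask_to_points(tal, TRUE)$points, 400),
    subsample_points(mask_to_points(cal, TRUE)$points, 2000)))
  expect_gt(gap_before, 1)  # separated before dilation
  # out-of-bounds transforms are rejected
  bad <- idt
  bad[["talus"]] <- rigid_transform(c(0, 0, 0), c(30, 0, 0))
  expect_error(apply_load_case(ph, bad), "plausibility")
})

test_that("load transforms respect their caps and seed determinism", {
  ph <- get_phantom()
  t1 <- phantom_load_transforms(ph, seed = 5)
  t2 <- phantom_load_transforms(ph, seed = 5)
  expect_identical(lapply(t1, `[[`, "euler"), lapply(t2, `[[`, "euler"))
  t3 <- phantom_load_transforms(ph, seed = 6)
  expect_gt(max(abs(unlist(lapply(t1, `[[`, "translation")) -
                      unlist(lapply(t3, `[[`, "translation")))), 1e-6)
  for (id in names(t1)) {
    R <- rotation_zyx(t1[[id]]$euler)
    ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
    expect_lte(ang, 15)
    com <- colMeans(ph$bones[[id]]$points)
    disp <- sqrt(sum((apply_rigid(t1[[id]], matrix(com, 1)) - com)^2))
    expect_lte(disp, 15)
  }
})
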