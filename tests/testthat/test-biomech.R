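# Relative motion amplitudes, anatomical frame, projected angles,
# ligament strains.

test_that("relative transforms compose like the matrix oracle", {
  set.seed(23)
  for (i in 1:10) {
    bone <- rigid_transform(runif(3, -0.5, 0.5), rnorm(3, sd = 5))
    frame <- rigid_transform(runif(3, -0.5, 0.5), rnorm(3, sd = 5))
    rel <- relative_transform(bone, frame)
    x <- matrix(rnorm(300), 100)
    expect_lt(max(abs(apply_rigid(frame, apply_rigid(rel, x)) -
                        apply_rigid(bone, x))), 1e-9)
  }
  # a bone moving exactly with the frame has the identity relative motion
  t1 <- rigid_transform(c(0.1, 0.2, -0.1), c(1, 2, 3))
  same <- relative_transform(t1, t1)
  expect_lt(sqrt(sum(same$translation^2)) + sqrt(sum(same$euler^2)), 1e-9)
  # identity frame leaves the bone transform unchanged
  rel0 <- relative_transform(t1, identity_transform())
  x <- matrix(rnorm(30), 10)
  expect_lt(max(abs(apply_rigid(rel0, x) - apply_rigid(t1, x))), 1e-9)
})

test_that("amplitudes follow their closed forms", {
  ph <- get_phantom()
  ref <- identity_state(ph)
  ids <- names(ph$bones)
  com <- center_of_mass(ph$bones$talus$mesh)
  # no motion
  expect_equal(translation_amplitude(ref, "talus", "tibia", com), 0)
  expect_equal(rotation_amplitude(ref, "talus", "tibia"), 0)
  # pure relative translation (3, 4, 0) -> 5 mm, 0 deg
  tfs <- ref$transforms
  tfs[["talus"]] <- rigid_transform(c(0, 0, 0), c(3, 4, 0))
  st <- configuration_state("c", tfs, "N", 1, "bare")
  expect_equal(translation_amplitude(st, "talus", "tibia", com), 5)
  expect_equal(rotation_amplitude(st, "talus", "tibia"), 0)
  # 10 deg rotation about an axis 10 mm from the COM: chord 2*10*sin(5)
  ang <- 10 * pi / 180
  axis_pt <- com + c(10, 0, 0)  # lever perpendicular to the y axis
  R <- rotation_zyx(c(0, ang, 0))  # rotation about y through axis_pt
  tfs[["talus"]] <- rigid_transform(euler_from_rotation(R),
                                    as.numeric(axis_pt - R %*% axis_pt))
  st2 <- configuration_state("c2", tfs, "N", 1, "bare")
  expect_equal(rotation_amplitude(st2, "talus", "tibia"), 10,
               tolerance = 1e-6)
  expect_equal(translation_amplitude(st2, "talus", "tibia", com),
               2 * 10 * sin(5 * pi / 180), tolerance = 1e-6)
  expect_error(translation_amplitude(st, "femur", "tibia", com),
               "unknown bone")
})

test_that("the anatomical frame is orthonormal and near grid-aligned", {
  ph <- get_phantom()
  fr <- build_anatomical_frame(ph$bones)
  axes <- rbind(fr$anterior, fr$superior, fr$medial)
  expect_lt(max(abs(axes %*% t(axes) - diag(3))), 1e-9)
  # phantom built with tibia along +z and foot along +x: within 2 deg...
  # of the grid axes (the tibia axis is exact, the foot axis is data-led)
  expect_gt(sum(fr$superior * c(0, 0, 1)), cos(2 * pi / 180))
  expect_gt(sum(fr$anterior * c(1, 0, 0)), cos(8 * pi / 180))
  # left/right flips the medial axis only
  fl <- build_anatomical_frame(ph$bones, side = "left")
  fr2 <- build_anatomical_frame(ph$bones, side = "right")
  expect_equal(fl$anterior, fr2$anterior)
  expect_equal(fl$superior, fr2$superior)
  expect_equal(fl$medial, -fr2$medial)
  expect_error(build_anatomical_frame(ph$bones["tibia"]), "needs bones")
})

test_that("projected angles are signed, bounded and isometry-invariant", {
  f0 <- structure(list(anterior = c(1, 0, 0), superior = c(0, 0, 1),
                       medial = c(0, 1, 0), origin = c(0, 0, 0)),
                  class = "anatomical_frame")
  expect_equal(projected_angle(c(0, 0, 10), c(0, 0, 0), c(10, 0, 0),
                               f0, "sagittal"), 90)
  expect_equal(projected_angle(c(-5, 0, 0), c(0, 0, 0), c(10, 0, 0),
                               f0, "sagittal"), 180)
  # invariance under an in-plane rigid motion of all three points
  rot2d <- function(p, th, dx, dz) {
    c(cos(th) * p[1] - sin(th) * p[3] + dx, p[2],
      sin(th) * p[1] + cos(th) * p[3] + dz)
  }
  a <- c(3, 0, 8); b <- c(1, 0, 1); c_ <- c(7, 0, 2)
  base <- projected_angle(a, b, c_, f0, "sagittal")
  moved <- projected_angle(rot2d(a, 0.7, 5, -3), rot2d(b, 0.7, 5, -3),
                           rot2d(c_, 0.7, 5, -3), f0, "sagittal")
  expect_equal(moved, base, tolerance = 1e-9)
  expect_error(projected_angle(c(0, 5, 0), c(0, 0, 0), c(1, 0, 0),
                               f0, "sagittal"), "coincide")
})

test_that("planned phantom motions reproduce planned angle amplitudes", {
  ph <- get_phantom()
  fr <- build_anatomical_frame(ph$bones)
  ref <- identity_state(ph)
  coms <- lapply(ph$bones, function(b) center_of_mass(b$mesh))
  # reference vs itself: zero amplitude, four rows (2 angles x 2 planes)
  ma0 <- measure_angles(ref, fr, coms, reference = ref)
  expect_equal(nrow(ma0), 4)
  expect_lt(max(abs(ma0$amplitude_deg)), 1e-9)
  # rotate the medial sesamoid 5 deg about the talus COM in the
  # sagittal plane: CalTalSM sagittal amplitude = 5 deg
  ang <- 5 * pi / 180
  K <- outer(fr$medial, fr$medial)
  W <- matrix(c(0, fr$medial[3], -fr$medial[2],
                -fr$medial[3], 0, fr$medial[1],
                fr$medial[2], -fr$medial[1], 0), 3)
  R <- diag(3) + sin(ang) * t(W) + (1 - cos(ang)) * (t(W) %*% t(W))
  ctr <- coms$talus
  tfs <- ref$transforms
  tfs[["sesamoid_medial"]] <- rigid_transform(
    euler_from_rotation(R), as.numeric(ctr - R %*% ctr))
  st <- configuration_state("c", tfs, "N", 1, "bare")
  ma <- measure_angles(st, fr, coms, reference = ref)
  amp <- ma$amplitude_deg[ma$name == "CalTalSM" & ma$plane == "sagittal"]
  expect_equal(abs(amp), 5, tolerance = 0.5)
  # the untouched TibTalCal angles stay put
  expect_lt(max(abs(ma$amplitude_deg[ma$name == "TibTalCal"])), 1e-6)
})

test_that("ligament length and strain follow their definitions", {
  ph <- get_phantom()
  ref <- identity_state(ph)
  fib <- list(origin_bone = "tibia", origin = c(0, 0, 0),
              insertion_bone = "talus", insertion = c(40, 0, 0))
  expect_equal(ligament_length(ref, fib), 40)
  expect_equal(ligament_strain(ref, ref, fib), 0)
  # insertion bone translated 2 mm along the fiber axis: +5%
  tfs <- ref$transforms
  tfs[["talus"]] <- rigid_transform(c(0, 0, 0), c(2, 0, 0))
  st <- configuration_state("c", tfs, "N", 1, "bare")
  expect_equal(ligament_strain(st, ref, fib), 5)
  # L_ref 50 -> L 51 is +2%
  fib2 <- list(origin_bone = "tibia", origin = c(0, 0, 0),
               insertion_bone = "talus", insertion = c(50, 0, 0))
  tfs[["talus"]] <- rigid_transform(c(0, 0, 0), c(1, 0, 0))
  st2 <- configuration_state("c2", tfs, "N", 1, "bare")
  expect_equal(ligament_strain(st2, ref, fib2), 2)
  # degenerate reference fiber
  fib0 <- list(origin_bone = "tibia", origin = c(1, 1, 1),
               insertion_bone = "talus", insertion = c(1, 1, 1))
  expect_error(ligament_strain(st2, ref, fib0), "degenerate")
  expect_error(ligament_length(ref, list(origin_bone = "femur",
                                         origin = c(0, 0, 0),
                                         insertion_bone = "talus",
                                         insertion = c(1, 0, 0))),
               "unregistered")
})

test_that("relative measures are invariant under a global rigid motion", {
  ph <- get_phantom()
  ref <- identity_state(ph)
  set.seed(41)
  tfs <- ref$transforms
  for (id in names(tfs))
    tfs[[id]] <- rigid_transform(runif(3, -0.05, 0.05), rnorm(3))
  st <- configuration_state("c", tfs, "N", 1, "bare")
  g <- rigid_transform(c(0.2, -0.1, 0.3), c(10, -5, 7))
  tfs_g <- lapply(tfs, function(tf) compose_rigid(g, tf))
  st_g <- configuration_state("cg", tfs_g, "N", 1, "bare")
  com <- center_of_mass(ph$bones$navicular$mesh)
  expect_equal(translation_amplitude(st_g, "navicular", "calcaneus", com),
               translation_amplitude(st, "navicular", "calcaneus", com),
               tolerance = 1e-9)
  expect_equal(rotation_amplitude(st_g, "navicular", "calcaneus"),
               rotation_amplitude(st, "navicular", "calcaneus"),
               tolerance = 1e-9)
  # strains are global-rigid invariant too
  fib <- ph$ligaments[["spring"]]
  ref_g <- configuration_state("refg",
                               lapply(ref$transforms, function(tf)
                                 compose_rigid(g, tf)), "N", 0, "bare")
  expect_equal(ligament_strain(st_g, ref_g, fib),
               ligament_strain(st, ref, fib), tolerance = 1e-9)
})

test_that("measure_all produces the long table with all metric types", {
  ph <- get_phantom()
  ref <- identity_state(ph)
  set.seed(51)
  mk_state <- function(cid, fw) {
    tfs <- ref$transforms
    for (id in names(tfs))
      tfs[[id]] <- rigid_transform(runif(3, -0.02, 0.02), rnorm(3, sd = 1))
    configuration_state(cid, tfs, "N", 1, fw)
  }
  states <- list(mk_state("N_1_bare", "bare"), mk_state("N_1_shod", "shod"))
  fr <- build_anatomical_frame(ph$bones)
  m <- measure_all(states, ref, ph$bones, ph$ligaments, fr)
  expect_setequal(unique(m$metric_type),
                  c("translation_mm", "rotation_deg", "angle_deg",
                    "strain_pct"))
  # 2 states x (2 frames x 29 bones x 2 metrics + 4 angles + 20 fibers)
  expect_equal(nrow(m),
               2 * (2 * 29 * 2 + 4 + length(ph$ligaments)))
  expect_true(all(is.finite(m$value)))
})
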