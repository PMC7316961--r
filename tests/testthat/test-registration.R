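# Rigid and hierarchical bone-to-skeleton registration.

test_that("registration cost matches its definition and the brute-force oracle", {
  set.seed(5)
  skel <- matrix(runif(900, 0, 50), 300)
  idx <- spatial_index(skel)
  # subset of the skeleton at identity -> exactly zero
  expect_equal(registration_cost(rep(0, 6), skel[1:50, ], idx), 0)
  # single point at distance 2 -> squared distance 4
  expect_equal(registration_cost(rep(0, 6), matrix(c(0, 0, 0), 1),
                                 spatial_index(matrix(c(2, 0, 0), 1))), 4)
  # random instances equal the exhaustive O(N^2) evaluation
  for (i in 1:5) {
    pts <- matrix(runif(300, 0, 50), 100)
    par <- c(runif(3, -0.3, 0.3), rnorm(3))
    ctr <- colMeans(pts)
    R <- rotation_zyx(par[1:3])
    moved <- sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr + par[4:6], `+`)
    expect_equal(registration_cost(par, pts, idx, ctr),
                 mean(brute_nn(moved, skel)^2), tolerance = 1e-12)
  }
})

test_that("register_rigid recovers a known transform from identity", {
  set.seed(2)
  bone <- ellipsoid_mesh(c(30, 15, 12))$vertices
  truth <- rigid_transform(c(0.17, -0.09, 0.05), c(5, 2, -3))
  skel <- apply_rigid(truth, bone)
  r <- register_rigid(bone, spatial_index(skel))
  err <- max(sqrt(rowSums((apply_rigid(r$transform, bone) - skel)^2)))
  expect_lt(err, 1e-3)  # point action within 0.05 mm easily
  expect_lt(r$residual, 1e-6)
  # recovered rotation within 0.1 degree of truth
  Rr <- rotation_zyx(r$transform$euler)
  Rt <- rotation_zyx(truth$euler)
  ang <- acos(min(1, (sum(diag(t(Rr) %*% Rt)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 0.1)
  # trivial case: skeleton equals the cloud
  r0 <- register_rigid(bone, spatial_index(bone))
  expect_lt(r0$residual, 1e-9)
  expect_lt(max(abs(apply_rigid(r0$transform, bone) - bone)), 1e-6)
})

test_that("cost at the optimum never exceeds cost at the init", {
  set.seed(9)
  bone <- ellipsoid_mesh(c(10, 6, 5))$vertices
  skel <- apply_rigid(rigid_transform(c(0.1, 0.05, -0.08), c(3, -2, 1)),
                      bone)
  idx <- spatial_index(skel)
  init <- rigid_transform(c(0.02, 0, 0), c(1, 1, 0))
  r <- register_rigid(bone, idx, init = init)
  cost_init <- mean(closest_distances(apply_rigid(init, bone), idx)^2)
  expect_lte(r$cost, cost_init + 1e-12)
})

test_that("subtract_registered removes covered points only", {
  set.seed(4)
  skel <- matrix(runif(3000, 0, 100), 1000)
  # construct 400 skeleton points within radius of the placed cloud
  placed <- skel[1:400, ] + matrix(runif(1200, -0.4, 0.4), 400)
  remaining <- subtract_registered(skel, placed, radius = 1)
  covered <- brute_nn(skel, placed) <= 1
  expect_equal(nrow(remaining), sum(!covered))
  # disjoint clouds with tiny radius -> unchanged
  expect_equal(nrow(subtract_registered(skel, skel + 50, 1e-6)), 1000)
  # full coverage -> error
  expect_error(subtract_registered(skel, skel, 1), "exhausted")
  expect_error(subtract_registered(skel, placed, -1), "radius")
})

test_that("hierarchy covers all bones and rejects missing ones", {
  h <- foot_hierarchy()
  expect_equal(h[[1]]$bones,
               setdiff(foot_bone_names(), c("tibia", "fibula")))
  expect_setequal(h[[length(h)]]$bones, foot_bone_names())
  bones <- lapply(c("tibia", "fibula"), function(id)
    bone_model(id, matrix(rnorm(30), 10)))
  expect_error(hierarchical_register(bones, h, matrix(rnorm(30), 10)),
               "configuration error")
})

test_that("hierarchical registration escapes the adjacent-bone trap", {
  # two similar small bones displaced by about their spacing: fitting
  # bone by bone from identity locks the larger bone onto the smaller
  # bone's target, while the pooled-first hierarchy recovers the truth
  a <- unit_sphere(2, r = 4, center = c(0, 0, 0))
  b <- unit_sphere(2, r = 2.5, center = c(9, 0, 0))
  shift <- rigid_transform(c(0, 0, 0), c(-9, 0, 0))
  skel <- rbind(apply_rigid(shift, a$vertices),
                apply_rigid(shift, b$vertices))
  idx <- spatial_index(skel)
  # bone-by-bone from identity: bone a is trapped on b's target
  ra <- register_rigid(a$vertices, idx, control = list(escape_cost = Inf))
  expect_gt(ra$residual, 1)
  # hierarchical: pooled segment first, then per bone
  hier <- list(list(order = 1, name = "pair", bones = c("a", "b"),
                    bone_by_bone = FALSE),
               list(order = 2, name = "bone", bones = c("a", "b"),
                    bone_by_bone = TRUE))
  rr <- hierarchical_register(list(bone_model("a", a$vertices),
                                   bone_model("b", b$vertices)),
                              hier, skel)
  expect_lt(rr$residuals[["a"]], 0.05)
  expect_lt(rr$residuals[["b"]], 0.05)
  expect_lt(max(abs(apply_rigid(rr$transforms[["a"]], a$vertices) -
                      apply_rigid(shift, a$vertices))), 0.1)
})

test_that("whole-segment motion plus per-bone perturbation is recovered on exact clouds", {
  # noiseless two-bone analogue of the full hierarchy: pooled motion
  # 10 deg / 8 mm, per-bone perturbations <= 3 deg / 2 mm
  set.seed(31)
  a <- ellipsoid_mesh(c(20, 10, 8), center = c(0, 0, 0))
  b <- ellipsoid_mesh(c(12, 7, 6), center = c(40, 5, -2))
  ctr <- c(20, 2, -1)
  ang <- 10 * pi / 180
  Rg <- rotation_zyx(c(0, 0, ang))
  global <- rigid_transform(euler_from_rotation(Rg),
                            as.numeric(ctr - Rg %*% ctr) + c(5, 5, 4))
  perturb <- function(center, rot_deg, tr) {
    R <- rotation_zyx(c(rot_deg * pi / 180, 0, 0))
    rigid_transform(euler_from_rotation(R),
                    as.numeric(center - R %*% center) + tr)
  }
  ta <- compose_rigid(global, perturb(c(0, 0, 0), 2.5, c(1, -0.5, 0.7)))
  tb <- compose_rigid(global, perturb(c(40, 5, -2), -2, c(-0.8, 1.2, 0.4)))
  skel <- rbind(apply_rigid(ta, a$vertices), apply_rigid(tb, b$vertices))
  hier <- list(list(order = 1, name = "pair", bones = c("a", "b"),
                    bone_by_bone = FALSE),
               list(order = 2, name = "bone", bones = c("a", "b"),
                    bone_by_bone = TRUE))
  rr <- hierarchical_register(list(bone_model("a", a$vertices),
                                   bone_model("b", b$vertices)),
                              hier, skel)
  erra <- max(sqrt(rowSums((apply_rigid(rr$transforms[["a"]], a$vertices) -
                              apply_rigid(ta, a$vertices))^2)))
  errb <- max(sqrt(rowSums((apply_rigid(rr$transforms[["b"]], b$vertices) -
                              apply_rigid(tb, b$vertices))^2)))
  expect_lt(erra, 1e-3)  # noiseless clouds: sub-micron point action
  expect_lt(errb, 1e-3)
  expect_lt(rr$residuals[["a"]], 1e-6)
})

test_that("registration is deterministic", {
  set.seed(13)
  bone <- ellipsoid_mesh(c(15, 9, 7))$vertices
  skel <- apply_rigid(rigid_transform(c(0.1, -0.04, 0.07), c(4, 1, -2)),
                      bone)
  r1 <- register_rigid(bone, spatial_index(skel))
  r2 <- register_rigid(bone, spatial_index(skel))
  expect_identical(r1$transform$euler, r2$transform$euler)
  expect_identical(r1$residual, r2$residual)
})
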