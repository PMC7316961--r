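# Alignment, normal projection, RBF kernels/solves and the full morph.

test_that("projection weight follows the capped linear schedule", {
  sched <- projection_schedule(a = 0.025, w1 = 1)
  expect_equal(projection_weight(0, sched), 0.025)
  expect_equal(projection_weight(39, sched), 1.0)   # 0.025 * 40, at cap
  expect_equal(projection_weight(1000, sched), 1.0)
  expect_equal(projection_weight(10, projection_schedule(a = 0.01,
                                                         w1 = 0.5)), 0.11)
})

test_that("align_and_scale recovers a constructed similarity", {
  m <- ellipsoid_mesh(c(20, 12, 8), center = c(3, -4, 6))
  tgt <- surface_mesh(sweep(sweep(m$vertices, 2, c(3, -4, 6)) * 1.3, 2,
                            c(3, -4, 6), `+`), m$faces)
  al <- align_and_scale(m, tgt)
  expect_equal(al$similarity$scale, 1.3, tolerance = 1e-6)
  expect_lt(hrmsd(al$mesh, tgt), 1e-6)
  # source onto itself: identity similarity
  al0 <- align_and_scale(m, m)
  expect_equal(al0$similarity$scale, 1, tolerance = 1e-9)
  expect_lt(max(abs(al0$similarity$R - diag(3))), 1e-6)
  # alignment strictly improves a displaced/rotated/scaled bone pair
  ph <- get_phantom()
  src <- ph$generic$meshes$calcaneus
  tgt2 <- ph$bones$calcaneus$mesh
  expect_lt(hrmsd(align_and_scale(src, tgt2)$mesh, tgt2),
            hrmsd(src, tgt2))
  # near-spherical source falls back with a warning
  expect_warning(align_and_scale(unit_sphere(3, 5),
                                 unit_sphere(3, 6)), "near-spherical")
})

test_that("normal projection moves concentric spheres radially", {
  src <- unit_sphere(3, r = 10)
  tgt <- unit_sphere(4, r = 12)
  ti <- mesh_index(tgt)
  # full step without smoothing: all radii reach ~12
  s1 <- normal_projection_step(src, ti, w = 1, smooth_iterations = 0)
  expect_equal(mean(sqrt(rowSums(s1$vertices^2))), 12, tolerance = 0.01)
  # half step: ~11
  s2 <- normal_projection_step(src, ti, w = 0.5, smooth_iterations = 0)
  expect_equal(mean(sqrt(rowSums(s2$vertices^2))), 11, tolerance = 0.01)
  # fixed point: source on target is unchanged (up to smoothing)
  s3 <- normal_projection_step(tgt, ti, w = 1, smooth_iterations = 0)
  expect_lt(max(abs(s3$vertices - tgt$vertices)), 1e-9)
})

test_that("iterative projection records a decreasing finite trace", {
  src <- unit_sphere(3, r = 10)
  tgt <- unit_sphere(4, r = 11)
  np <- normal_projection(src, tgt, projection_schedule(stop_hrmsd = 0.05))
  expect_true(all(is.finite(np$trace)))
  expect_lte(np$trace[length(np$trace)], np$trace[1])
  expect_true(np$converged)
  # already-converged input terminates immediately
  np0 <- normal_projection(tgt, tgt, projection_schedule())
  expect_equal(np0$iterations, 0L)
})

test_that("windowed-sinc smoothing preserves volume and damps spikes", {
  s <- unit_sphere(4, r = 10)
  sm <- smooth_windowed_sinc(s, passband = 0.1, iterations = 20)
  expect_equal(mesh_volume(sm), mesh_volume(s), tolerance = 0.01)
  expect_identical(smooth_windowed_sinc(s, iterations = 0), s)
  # spiked vertex amplitude reduced by at least half
  v <- s$vertices
  v[1, ] <- v[1, ] * 1.5  # 5 mm radial spike
  spiked <- surface_mesh(v, s$faces)
  sm2 <- smooth_windowed_sinc(spiked, passband = 0.1, iterations = 20)
  spike_before <- sqrt(sum(v[1, ]^2)) - 10
  spike_after <- sqrt(sum(sm2$vertices[1, ]^2)) - 10
  expect_lt(abs(spike_after), 0.5 * spike_before)
})

test_that("inverse multiquadric kernel matches hand evaluations", {
  prm <- rbf_params(b = 10, k1 = 0.1, kernel = "inverse_multiquadric")
  expect_equal(rbf_kernel(0, 0.5, prm), 1)
  expect_equal(rbf_kernel(1, 0.5, prm), 1.5^(-0.1), tolerance = 1e-6)
  expect_equal(rbf_kernel(1, 0.5, prm), 0.96026, tolerance = 1e-5)
  expect_equal(rbf_kernel(0.005, 0.01, prm), 7.5e-5^(-0.05),
               tolerance = 1e-6)
  expect_equal(rbf_kernel(0.005, 0.01, prm), 1.6079, tolerance = 1e-4)
  expect_error(rbf_kernel(1, -1, prm), "c must be")
  # Wendland: bounded by 1, compact support, k(0) = 1
  expect_equal(wendland_kernel(0, 2), 1)
  expect_equal(wendland_kernel(2, 2), 0)
  expect_true(all(diff(wendland_kernel(seq(0, 2, 0.1), 2)) <= 0))
})

test_that("landmark selection ranks by magnitude with correct geometry", {
  src <- unit_sphere(3, r = 10)
  tgt <- unit_sphere(3, r = 11)
  lm <- select_landmarks(src, tgt, 1.0)
  # radial construction: all displacements ~1 mm
  expect_equal(mean(lm$magnitude), 1, tolerance = 0.05)
  expect_true(all(abs(lm$magnitude - 1) < 0.15))
  # identical surfaces: displacements ~0
  lm0 <- select_landmarks(src, src, 1.0)
  expect_lt(max(lm0$magnitude), 1e-9)
  # smaller fraction keeps a magnitude-top subset of the full ranking
  ph <- get_phantom()
  s2 <- align_and_scale(ph$generic$meshes$talus, ph$bones$talus$mesh)$mesh
  lm_small <- select_landmarks(s2, ph$bones$talus$mesh, 0.1)
  lm_full <- select_landmarks(s2, ph$bones$talus$mesh, 1.0)
  expect_gte(min(lm_small$magnitude),
             sort(lm_full$magnitude, decreasing = TRUE)[
               length(lm_small$magnitude)] - 1e-9)
})

test_that("RBF weight solve interpolates landmark displacements exactly", {
  set.seed(17)
  for (kern in c("wendland", "inverse_multiquadric")) {
    P <- matrix(runif(30, 0, 20), 10)
    lm <- structure(list(source = P,
                         target = P + matrix(rnorm(30, sd = 0.5), 10),
                         magnitude = rep(1, 10)), class = "landmark_set")
    prm <- rbf_params(kernel = kern)
    W <- solve_rbf_weights(lm, c = 0.5, prm)
    expect_lt(attr(W, "residual"), 1e-6)
  }
  # zero displacements give zero weights
  P <- matrix(runif(18, 0, 10), 6)
  lm0 <- structure(list(source = P, target = P, magnitude = rep(0, 6)),
                   class = "landmark_set")
  expect_lt(max(abs(solve_rbf_weights(lm0, 0.5, rbf_params()))), 1e-12)
  expect_error(solve_rbf_weights(structure(list(source = P[1:3, ],
                                                target = P[1:3, ]),
                                           class = "landmark_set"),
                                 0.5, rbf_params()), "4 landmarks")
})

test_that("rbf_morph_step reproduces a densely sampled translation field", {
  src <- unit_sphere(3, r = 10)
  lm <- structure(list(source = src$vertices,
                       target = sweep(src$vertices, 2, c(1, 0, 0), `+`),
                       magnitude = rep(1, nrow(src$vertices))),
                  class = "landmark_set")
  out <- rbf_morph_step(src, lm, c = 0.5, rbf_params(),
                        smooth_iterations = 0)
  # every vertex is a landmark: exact displacement by (1, 0, 0)
  disp <- out$vertices - src$vertices
  expect_lt(max(abs(sweep(disp, 2, c(1, 0, 0)))), 1e-4)
  # zero-displacement landmarks: mesh unchanged
  lm0 <- structure(list(source = src$vertices, target = src$vertices,
                        magnitude = rep(0, nrow(src$vertices))),
                   class = "landmark_set")
  out0 <- rbf_morph_step(src, lm0, c = 0.5, rbf_params(),
                         smooth_iterations = 0)
  expect_lt(max(abs(out0$vertices - src$vertices)), 1e-10)
})

test_that("full morph drives phantom pairs to sub-voxel agreement", {
  ph <- get_phantom()
  src <- phantom_generic_mesh(ph, "talus", subdiv = 4)
  tgt <- phantom_patient_mesh(ph, "talus", subdiv = 4)
  mr <- morph(src, tgt)
  expect_lt(mr$trace[length(mr$trace)], 0.06)
  # topology preserved, coordinates finite
  expect_equal(dim(mr$mesh$vertices), dim(src$vertices))
  expect_identical(mr$mesh$faces, src$faces)
  expect_true(all(is.finite(mr$mesh$vertices)))
  # displacement bookkeeping
  expect_equal(mr$displacement,
               mr$mesh$vertices - mr$aligned$vertices)
  # trace: aligned >= projected >= final
  expect_lte(mr$trace[["projected"]], mr$trace[["aligned"]] + 1e-9)
  expect_lte(mr$trace[length(mr$trace)], mr$trace[["projected"]])
  # source equal to target: every stage is a near no-op (the slight
  # post-RBF smoothing leaves a few microns of drift)
  mr0 <- morph(tgt, tgt)
  expect_lt(mr0$trace[length(mr0$trace)], 0.02)
})

test_that("attachment transfer is exact for constructed fields", {
  sph <- unit_sphere(3, r = 10)
  # constructed morph realizing a known affine map
  A <- diag(c(1.3, 0.9, 1.1)); b <- c(2, -1, 0.5)
  morphed_v <- sph$vertices %*% t(A) + rep(b, each = nrow(sph$vertices))
  mres <- structure(list(
    mesh = surface_mesh(morphed_v, sph$faces),
    displacement = morphed_v - sph$vertices,
    aligned = sph,
    similarity = structure(list(scale = 1, R = diag(3),
                                center_src = c(0, 0, 0),
                                center_tgt = c(0, 0, 0)),
                           class = "similarity_transform"),
    trace = c(aligned = 1), converged = TRUE), class = "morph_result")
  q <- rbind(c(10, 0, 0), c(0, 10, 0), c(10, 10, 0) / sqrt(2))
  out <- transfer_attachments(mres, q)
  expected <- q %*% t(A) + rep(b, each = 3)
  rel <- sqrt(rowSums((out - expected)^2)) / sqrt(rowSums(expected^2))
  expect_lt(max(rel), 0.02)
  # translation field: recovered exactly (constant barycentric field)
  mres$displacement <- matrix(rep(c(1, 0, 0), each = nrow(sph$vertices)),
                              ncol = 3)
  mres$mesh <- surface_mesh(sph$vertices + mres$displacement, sph$faces)
  out_t <- transfer_attachments(mres, q)
  expect_lt(max(abs(out_t - sweep(q, 2, c(1, 0, 0), `+`))), 1e-9)
  # attachment at a vertex moves exactly by that vertex's displacement
  qv <- sph$vertices[5, , drop = FALSE]
  expect_lt(max(abs(transfer_attachments(mres, qv) -
                      (qv + c(1, 0, 0)))), 1e-9)
  # distant attachments error with identification
  far <- matrix(c(100, 100, 100), 1, dimnames = list("far_fiber", NULL))
  expect_error(transfer_attachments(mres, far), "far_fiber")
})

test_that("phantom attachment positions are recovered up to tangential ambiguity", {
  # the morph matches surfaces, not material points; tangential sliding
  # bounds attachment recovery by the warp magnitude, not the HRMSd
  ph <- get_phantom()
  id <- "metatarsal_1"
  mr <- morph(phantom_generic_mesh(ph, id, subdiv = 4),
              phantom_patient_mesh(ph, id, subdiv = 4))
  out <- transfer_attachments(mr, ph$generic$attachments[[id]])
  err <- sqrt(rowSums((out - ph$generic$true_attachments[[id]])^2))
  expect_lt(max(err), 5)  # bounded by the warp's tangential component
  # transferred points land on the patient bone surface
  d_surf <- closest_on_surface(out,
                               mesh_index(ph$bones[[id]]$mesh))$distance
  expect_lt(max(d_surf), 1)
})
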