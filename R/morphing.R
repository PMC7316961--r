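#' Normal-projection weight schedule
#'
#' During normal projection the per-vertex step is `w(t) * d_i`; the
#' weight rises linearly with the iteration index and is capped:
#' `w(t) = min(a * (1 + t), w1)`. Small early steps keep the projection
#' stable while the source is still far from the target.
#'
#' @param a dimensionless slope (> 0), default 0.025.
#' @param w1 dimensionless cap in (0, 1], default 1.
#' @param stop_hrmsd stop threshold on the source-target HRMSd, mm.
#' @param max_iters maximum projection iterations.
#' @return list of class `projection_schedule`.
#' @export
projection_schedule <- function(a = 0.025, w1 = 1, stop_hrmsd = 0.3,
                                max_iters = 500) {
  stopifnot(a > 0, w1 > 0, w1 <= 1, stop_hrmsd > 0, max_iters >= 1)
  structure(list(a = a, w1 = w1, stop_hrmsd = stop_hrmsd,
                 max_iters = max_iters), class = "projection_schedule")
}

#' @rdname projection_schedule
#' @param t iteration index (integer >= 0).
#' @param sched a `projection_schedule`.
#' @return `projection_weight`: scalar weight in (0, w1].
#' @export
projection_weight <- function(t, sched = projection_schedule()) {
  stopifnot(t >= 0)
  min(sched$a * (1 + t), sched$w1)
}

#' Radial-basis-function morphing parameters
#'
#' Two kernel families are available. `kernel = "wendland"` (default) is
#' the compactly supported Wendland C2 function
#' `k(d) = (1 - d/s)^4 (4 d/s + 1)` for `d < s`, with support `s` set to
#' `support_factor` times the median nearest-landmark spacing: positive
#' definite, local, and sparse, so exact interpolation of thousands of
#' landmarks stays well conditioned. `kernel = "inverse_multiquadric"`
#' is the capped-exponent inverse multiquadric
#' `k(d) = (d^2 + d * c)^(-beta)` with `beta = min(b * d, k1)` and
#' `k(0) = 1` by continuity (`c` is a length scale: the minimum distance
#' between the deformed source and the target, floored at 1e-6 mm); with
#' `b = 10`, `k1 = 0.1` this kernel is nearly flat at bone scale, which
#' makes dense exact interpolation ill-conditioned -- it is retained for
#' comparison and small landmark sets. The alternative typographic
#' reading of its base, `d^2 + d^c`, is selectable via
#' `c_mode = "power"`.
#'
#' @param b dimensionless slope of beta, default 10.
#' @param k1 cap of beta, default 0.1.
#' @param n_iterations number of RBF morphing iterations, default 5.
#' @param landmark_fractions nondecreasing fractions in (0, 1] of the
#'   deduplicated landmark ranking used at each iteration.
#' @param min_sep_factor landmark spatial deduplication: minimum pair
#'   separation as a multiple of the source mean edge length. One edge
#'   length gives landmark coverage at the mesh resolution, which the
#'   final morphing accuracy requires.
#' @param c_mode `"product"` (default) or `"power"` reading of the
#'   inverse multiquadric base.
#' @param kernel `"wendland"` or `"inverse_multiquadric"`.
#' @param support_factor Wendland support as a multiple of the median
#'   nearest-landmark spacing.
#' @return list of class `rbf_params`.
#' @export
rbf_params <- function(b = 10, k1 = 0.1, n_iterations = 5,
                       landmark_fractions = c(0.10, 0.25, 0.45, 0.70, 1.00),
                       min_sep_factor = 1, c_mode = c("product", "power"),
                       kernel = c("wendland", "inverse_multiquadric"),
                       support_factor = 3) {
  c_mode <- match.arg(c_mode)
  kernel <- match.arg(kernel)
  stopifnot(b > 0, k1 > 0, n_iterations >= 1,
            length(landmark_fractions) == n_iterations,
            all(diff(landmark_fractions) >= 0),
            all(landmark_fractions > 0), all(landmark_fractions <= 1),
            min_sep_factor > 0, support_factor > 1)
  structure(list(b = b, k1 = k1, n_iterations = n_iterations,
                 landmark_fractions = landmark_fractions,
                 min_sep_factor = min_sep_factor, c_mode = c_mode,
                 kernel = kernel, support_factor = support_factor),
            class = "rbf_params")
}

#' Wendland C2 compactly supported kernel
#' @param d nonnegative distance(s), mm.
#' @param s support radius, mm (> 0).
#' @return Kernel values in [0, 1]; zero for `d >= s`.
#' @export
wendland_kernel <- function(d, s) {
  if (!is.numeric(s) || s <= 0) stop("support s must be > 0")
  u <- pmin(d / s, 1)
  (1 - u)^4 * (4 * u + 1)
}

#' Inverse multiquadric RBF kernel with capped exponent
#'
#' @param d nonnegative distance(s), mm.
#' @param c kernel length scale, mm (> 0).
#' @param params an [rbf_params()].
#' @return Kernel value(s); `k(0) = 1`.
#' @export
rbf_kernel <- function(d, c, params = rbf_params()) {
  if (!is.numeric(c) || c <= 0) stop("kernel scale c must be > 0")
  if (any(d < 0)) stop("distances must be nonnegative")
  beta <- pmin(params$b * d, params$k1)
  base <- if (params$c_mode == "product") d^2 + d * c else d^2 + d^c
  k <- base^(-beta)
  k[d == 0] <- 1
  k
}

# -------------------------------------------------------------- alignment

#' Similarity alignment of the generic source onto the target bone
#'
#' Maps the source centroid onto the target centroid, aligns principal
#' axes (sign-disambiguated to the right-handed combination with the
#' smallest rotation), and applies the isotropic scale given by the ratio
#' of mean centroid-to-vertex distances. Near-spherical sources with
#' degenerate principal axes fall back to centroid + scale only.
#'
#' @param source,target surface meshes.
#' @return list with `mesh` (aligned source) and `similarity` (a
#'   `similarity_transform`: `scale`, `R`, `center_src`, `center_tgt`
#'   mapping original source points into the aligned frame).
#' @export
align_and_scale <- function(source, target) {
  vs <- source$vertices; vt <- target$vertices
  cs <- colMeans(vs); ct <- colMeans(vt)
  ds <- sweep(vs, 2, cs); dt <- sweep(vt, 2, ct)
  scale <- mean(sqrt(rowSums(dt^2))) / mean(sqrt(rowSums(ds^2)))
  es <- eigen(crossprod(ds) / nrow(ds), symmetric = TRUE)
  et <- eigen(crossprod(dt) / nrow(dt), symmetric = TRUE)
  rel_gap <- (es$values[1] - es$values[2]) / max(es$values[1], 1e-300)
  if (rel_gap < 1e-3) {
    warning("near-spherical source: degenerate principal axes, ",
            "using centroid and scale only")
    R <- diag(3)
  } else {
    Us <- es$vectors; Ut <- et$vectors
    if (det(Us) < 0) Us[, 3] <- -Us[, 3]
    if (det(Ut) < 0) Ut[, 3] <- -Ut[, 3]
    flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
    best <- NULL; best_tr <- -Inf
    for (s in flips) {
      Rc <- Ut %*% diag(s) %*% t(Us)
      if (sum(diag(Rc)) > best_tr) { best_tr <- sum(diag(Rc)); best <- Rc }
    }
    R <- best
  }
  sim <- structure(list(scale = scale, R = R, center_src = cs,
                        center_tgt = ct), class = "similarity_transform")
  surface_mesh(apply_similarity(sim, vs), source$faces) -> aligned
  list(mesh = aligned, similarity = sim)
}

#' Apply a similarity transform from [align_and_scale()]
#' @param sim a `similarity_transform`.
#' @param pts N x 3 matrix.
#' @return Transformed N x 3 matrix.
#' @export
apply_similarity <- function(sim, pts) {
  p <- as_points(pts)
  sweep(sim$scale * sweep(p, 2, sim$center_src) %*% t(sim$R), 2,
        sim$center_tgt, `+`)
}

# ------------------------------------------------------- normal projection

#' One normal-projection step
#'
#' Displaces each source vertex along its unit normal — flipped per
#' vertex to point toward the nearest target surface point — by
#' `w * d_i`, where `d_i` is the nearest distance to the target, then
#' applies windowed-sinc smoothing.
#'
#' @param src source [surface_mesh()].
#' @param target a [mesh_index()] over the target surface.
#' @param w step weight in (0, 1].
#' @param smooth_iterations,passband smoothing settings (0 iterations
#'   skips smoothing).
#' @param adjacency optional precomputed neighbour operator (internal
#'   reuse across iterations).
#' @return Displaced (and smoothed) `surface_mesh`.
#' @export
normal_projection_step <- function(src, target, w, smooth_iterations = 20,
                                   passband = 0.1, adjacency = NULL) {
  stopifnot(inherits(target, "mesh_index"), w > 0, w <= 1)
  n <- mesh_vertex_normals(src)
  cl <- closest_on_surface(src$vertices, target)
  toward <- cl$point - src$vertices
  flip <- rowSums(n * toward) < 0
  n[flip, ] <- -n[flip, ]
  x <- src$vertices + (w * cl$distance) * n
  if (smooth_iterations > 0) {
    if (is.null(adjacency)) adjacency <- mesh_adjacency(src)
    x <- taubin_iterate(x, adjacency, passband, smooth_iterations)
  }
  surface_mesh(x, src$faces)
}

#' Iterative normal projection of the source onto the target
#'
#' Repeats [normal_projection_step()] with the scheduled weight until the
#' source-target HRMSd falls below `sched$stop_hrmsd` or `max_iters` is
#' reached.
#'
#' @param src aligned source [surface_mesh()].
#' @param target target `surface_mesh` or [mesh_index()].
#' @param sched a [projection_schedule()].
#' @param smooth_iterations,passband smoothing applied after every step.
#' @return list with `mesh`, `trace` (HRMSd per iteration, starting at
#'   the input mesh), `converged`, `iterations`.
#' @export
normal_projection <- function(src, target, sched = projection_schedule(),
                              smooth_iterations = 20, passband = 0.1) {
  ti <- if (inherits(target, "mesh_index")) target else mesh_index(target)
  adjacency <- mesh_adjacency(src)
  cur <- src
  trace <- hrmsd(mesh_index(cur), ti)
  converged <- trace[1] < sched$stop_hrmsd
  t <- 0L
  while (!converged && t < sched$max_iters) {
    w <- projection_weight(t, sched)
    cur <- normal_projection_step(cur, ti, w, smooth_iterations, passband,
                                  adjacency)
    h <- hrmsd(mesh_index(cur), ti)
    trace <- c(trace, h)
    t <- t + 1L
    if (h < sched$stop_hrmsd) converged <- TRUE
  }
  if (!converged)
    warning("normal projection did not reach stop_hrmsd within ",
            sched$max_iters, " iterations")
  list(mesh = cur, trace = trace, converged = converged, iterations = t)
}

# ------------------------------------------------------------- landmarks

#' Normal-distance landmark correspondence
#'
#' For each target vertex, the line along its normal is cast onto the
#' source surface; the intersection is the initial landmark position
#' `p_j` on the source and the target vertex the final position `p_j*`.
#' Target vertices whose normal line misses the source within 5x the
#' source mean edge length fall back to the closest point on the source.
#' Pairs are ranked by displacement magnitude (descending),
#' spatially deduplicated at a minimum separation of `min_sep_factor`
#' source mean edge lengths (ties broken by vertex index), and the top
#' `fraction` kept.
#'
#' @param src source [surface_mesh()] (after normal projection).
#' @param target target [surface_mesh()].
#' @param fraction fraction in (0, 1] of the deduplicated ranking kept.
#' @param src_index optional precomputed [mesh_index()] over `src`.
#' @param min_sep_factor minimum landmark separation in source mean edge
#'   lengths.
#' @return An object of class `landmark_set`: matrices `source`
#'   (`p_j`), `target` (`p_j*`), and `magnitude`.
#' @export
select_landmarks <- function(src, target, fraction, src_index = NULL,
                             min_sep_factor = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  if (is.null(src_index)) src_index <- mesh_index(src)
  tv <- target$vertices
  tn <- mesh_vertex_normals(target)
  hit <- cpp_bvh_linecast(src_index$ptr, tv, tn)
  max_t <- 5 * mean_edge_length(src)
  ok <- !is.na(hit$t) & abs(hit$t) <= max_t
  pj <- tv + hit$t * tn
  if (any(!ok)) {
    cl <- closest_on_surface(tv[!ok, , drop = FALSE], src_index)
    pj[!ok, ] <- cl$point
  }
  disp <- tv - pj
  mag <- sqrt(rowSums(disp^2))
  ord <- order(mag, seq_along(mag), decreasing = c(TRUE, FALSE),
               method = "radix")
  min_sep <- min_sep_factor * mean_edge_length(src)
  kept <- integer(0)
  kp <- matrix(0, 0, 3)
  for (i in ord) {
    if (nrow(kp) > 0) {
      d2 <- (kp[, 1] - pj[i, 1])^2 + (kp[, 2] - pj[i, 2])^2 +
        (kp[, 3] - pj[i, 3])^2
      if (min(d2) < min_sep^2) next
    }
    kept <- c(kept, i)
    kp <- rbind(kp, pj[i, ])
  }
  n_keep <- max(1L, ceiling(fraction * length(kept)))
  kept <- kept[seq_len(n_keep)]
  if (length(kept) < 4L)
    stop("fewer than 4 landmarks survive deduplication")
  structure(list(source = pj[kept, , drop = FALSE],
                 target = tv[kept, , drop = FALSE],
                 magnitude = mag[kept]), class = "landmark_set")
}

#' Solve the landmark RBF weight matrix
#'
#' Solves `K_land W = D_land` where `K_land[j, l] = k(p_j, p_l)` and
#' `D_land = p* - p`; the solution interpolates the landmark
#' displacements exactly. With the Wendland kernel the system is sparse
#' and solved by Cholesky factorization; the support radius is recorded
#' as attribute `"support"`. With the inverse multiquadric the dense
#' solve gets iterative refinement and, if near-singular, a 1e-9 ridge.
#'
#' @param lm a [select_landmarks()] result.
#' @param c kernel length scale, mm (inverse multiquadric only).
#' @param params an [rbf_params()].
#' @return N_j x 3 weight matrix with attribute `"residual"` (max abs
#'   entry of `K W - D`) and, for Wendland, `"support"`.
#' @export
solve_rbf_weights <- function(lm, c, params = rbf_params()) {
  P <- lm$source
  n <- nrow(P)
  if (n < 4L) stop("at least 4 landmarks required")
  Dmat <- lm$target - lm$source
  if (params$kernel == "wendland") {
    s <- landmark_support(P, params$support_factor)
    tree <- spatial_index(P)
    pr <- cpp_kdtree_pairs(tree$ptr, P, s)
    K <- Matrix::sparseMatrix(i = pr$i, j = pr$j,
                              x = wendland_kernel(pr$d, s),
                              dims = c(n, n))
    W <- tryCatch(as.matrix(Matrix::solve(K, Dmat)), error = function(e) {
      K2 <- K + Matrix::Diagonal(n, 1e-9)
      tryCatch(as.matrix(Matrix::solve(K2, Dmat)),
               error = function(e2) stop("landmark RBF system is singular"))
    })
    attr(W, "residual") <- max(abs(as.matrix(K %*% W) - Dmat))
    attr(W, "support") <- s
    return(W)
  }
  K <- rbf_kernel(pairwise_dist(P, P), c, params)
  W <- tryCatch(solve(K, Dmat), error = function(e) {
    K2 <- K + diag(1e-9, n)
    tryCatch(solve(K2, Dmat),
             error = function(e2) stop("landmark RBF system is singular"))
  })
  for (it in 1:3) {  # iterative refinement
    r <- Dmat - K %*% W
    if (max(abs(r)) < 1e-10) break
    dW <- tryCatch(solve(K, r), error = function(e)
      solve(K + diag(1e-9, n), r))
    W <- W + dW
  }
  attr(W, "residual") <- max(abs(Dmat - K %*% W))
  W
}

# Wendland support radius: support_factor x median nearest-landmark
# spacing (floored to avoid zero support for coincident landmarks)
landmark_support <- function(P, support_factor) {
  n <- nrow(P)
  S <- subsample_points(P, 1000L)
  if (n <= 2000L) {
    d <- pairwise_dist(S, P)
    d[d == 0] <- Inf
    d1 <- apply(d, 1, min)
  } else {
    tree <- spatial_index(P)
    ext <- apply(P, 2, function(x) diff(range(x)))
    r0 <- 10 * (prod(pmax(ext, 1e-6)) / n)^(1 / 3)
    pr <- cpp_kdtree_pairs(tree$ptr, S, r0)
    ok <- pr$d > 0
    d1 <- tapply(pr$d[ok], pr$i[ok], min)
  }
  d1 <- d1[is.finite(d1)]
  if (length(d1) == 0) return(1e-3)
  max(support_factor * stats::median(d1), 1e-3)
}

pairwise_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' One RBF morphing step
#'
#' Displaces every source vertex by the kernel interpolation of the
#' landmark displacements, `D = K W`; landmark source points map onto
#' their targets exactly (before smoothing).
#'
#' @param src source [surface_mesh()].
#' @param lm a `landmark_set`.
#' @param c kernel length scale, mm.
#' @param params an [rbf_params()].
#' @param smooth_iterations,passband gentle smoothing after the step
#'   (0 iterations skips it).
#' @return Morphed `surface_mesh`.
#' @export
rbf_morph_step <- function(src, lm, c, params = rbf_params(),
                           smooth_iterations = 20, passband = 0.1) {
  W <- solve_rbf_weights(lm, c, params)
  if (params$kernel == "wendland") {
    s <- attr(W, "support")
    tree <- spatial_index(lm$source)
    pr <- cpp_kdtree_pairs(tree$ptr, src$vertices, s)
    K <- Matrix::sparseMatrix(i = pr$i, j = pr$j,
                              x = wendland_kernel(pr$d, s),
                              dims = c(nrow(src$vertices), nrow(lm$source)))
    x <- src$vertices + as.matrix(K %*% W)
  } else {
    K <- rbf_kernel(pairwise_dist(src$vertices, lm$source), c, params)
    x <- src$vertices + K %*% W
  }
  if (smooth_iterations > 0)
    x <- taubin_iterate(x, mesh_adjacency(src), passband, smooth_iterations)
  surface_mesh(x, src$faces)
}

#' Full generic-to-patient morphing protocol
#'
#' Alignment and scaling, iterative normal projection, then
#' `params$n_iterations` RBF morphing passes with an increasing landmark
#' fraction. The kernel scale `c` is recomputed before each RBF pass as
#' the minimum distance between the deformed source and the target
#' (floored at 1e-6 mm). The per-stage HRMSd is recorded.
#'
#' @param source generic source [surface_mesh()].
#' @param target patient target [surface_mesh()].
#' @param sched a [projection_schedule()].
#' @param params an [rbf_params()].
#' @param smooth_iterations,passband windowed-sinc smoothing after every
#'   projection step.
#' @param rbf_smooth_iterations slight smoothing after each RBF step
#'   (heavier smoothing would undo the exact landmark interpolation).
#' @param verbose print stage HRMSd.
#' @return An object of class `morph_result`: `mesh` (morphed source),
#'   `displacement` (per-vertex total displacement from the aligned
#'   source), `trace` (named HRMSd per stage), `similarity`, `aligned`,
#'   `converged`.
#' @export
morph <- function(source, target, sched = projection_schedule(),
                  params = rbf_params(), smooth_iterations = 20,
                  passband = 0.1, rbf_smooth_iterations = 5,
                  verbose = FALSE) {
  ti <- mesh_index(target)
  al <- align_and_scale(source, target)
  trace <- c(aligned = hrmsd(mesh_index(al$mesh), ti))
  np <- normal_projection(al$mesh, ti, sched, smooth_iterations, passband)
  trace <- c(trace, projected = trace_last(np$trace))
  cur <- np$mesh
  if (verbose)
    message(sprintf("aligned %.4f mm -> projected %.4f mm", trace[1],
                    trace[2]))
  for (it in seq_len(params$n_iterations)) {
    ci <- mesh_index(cur)
    cmin <- max(min(closest_on_surface(cur$vertices, ti)$distance), 1e-6)
    lm <- select_landmarks(cur, target, params$landmark_fractions[it],
                           src_index = ci,
                           min_sep_factor = params$min_sep_factor)
    cur <- rbf_morph_step(cur, lm, cmin, params, rbf_smooth_iterations,
                          passband)
    h <- hrmsd(mesh_index(cur), ti)
    trace <- c(trace, stats::setNames(h, paste0("rbf_", it)))
    if (verbose)
      message(sprintf("rbf %d (%d landmarks, c = %.2g) %.5f mm", it,
                      nrow(lm$source), cmin, h))
  }
  structure(list(mesh = cur,
                 displacement = cur$vertices - al$mesh$vertices,
                 trace = trace, similarity = al$similarity,
                 aligned = al$mesh, converged = np$converged),
            class = "morph_result")
}

trace_last <- function(x) x[length(x)]

#' @export
print.morph_result <- function(x, ...) {
  cat("morph_result: HRMSd", paste(sprintf("%s %.4g", names(x$trace),
                                           x$trace), collapse = " -> "),
      "mm\n")
  invisible(x)
}

#' Transfer ligament attachment points through a morph
#'
#' Each attachment point (source space) is carried through the alignment
#' similarity transform, then displaced by barycentric interpolation of
#' the per-vertex displacement field on its closest aligned-source
#' triangle.
#'
#' @param morphed a [morph()] result.
#' @param attachments N x 3 matrix of points in original source space;
#'   row names identify the ligament in error messages.
#' @param max_distance attachments farther than this from the aligned
#'   source surface are an error (default 5 mm).
#' @return N x 3 matrix of points in patient space.
#' @export
transfer_attachments <- function(morphed, attachments, max_distance = 5) {
  stopifnot(inherits(morphed, "morph_result"))
  q <- as.matrix(attachments)
  nm <- rownames(q)
  qa <- apply_similarity(morphed$similarity, q)
  ai <- mesh_index(morphed$aligned)
  cl <- closest_on_surface(qa, ai)
  too_far <- cl$distance > max_distance
  if (any(too_far)) {
    lab <- if (!is.null(nm)) paste(nm[too_far], collapse = ", ") else
      paste(which(too_far), collapse = ", ")
    stop("attachment(s) farther than ", max_distance,
         " mm from the source surface: ", lab)
  }
  f <- ai$mesh$faces[cl$triangle, , drop = FALSE]
  disp <- cl$bary[, 1] * morphed$displacement[f[, 1], , drop = FALSE] +
    cl$bary[, 2] * morphed$displacement[f[, 2], , drop = FALSE] +
    cl$bary[, 3] * morphed$displacement[f[, 3], , drop = FALSE]
  out <- qa + disp
  rownames(out) <- nm
  out
}
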