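# Shared fixtures (lazily built and cached across test files) and
# independent oracles used to freeze expected values.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# default phantom under the study conditions (seed 42)
get_phantom <- function() {
  cached("phantom", function() generate_foot_phantom(phantom_spec(seed = 42)))
}

# icosphere-based test meshes
unit_sphere <- function(subdiv = 3, r = 1, center = c(0, 0, 0)) {
  s <- footmech:::icosphere(subdiv)
  surface_mesh(s$vertices * r + rep(center, each = nrow(s$vertices)),
               s$faces)
}

ellipsoid_mesh <- function(radii, subdiv = 3, center = c(0, 0, 0)) {
  s <- footmech:::icosphere(subdiv)
  surface_mesh(s$vertices %*% diag(radii) +
                 rep(center, each = nrow(s$vertices)), s$faces)
}

# O(N^2) brute-force nearest-neighbour distances (oracle)
brute_nn <- function(query, ref) {
  apply(query, 1, function(q) sqrt(min(colSums((t(ref) - q)^2))))
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(Vs - mu) >= abs(V - mu) - 1e-9)
}

# the full voxel-resolution registration study: phantom + known
# transforms + hierarchical registration with surface refinement;
# expensive, shared between the registration-quality and
# transform-recovery acceptance checks
acceptance_registration <- function() {
  cached("acc_reg", function() {
    ph <- get_phantom()
    truth <- phantom_load_transforms(ph, seed = 43)
    lc <- apply_load_case(ph, truth, dilate = FALSE)
    bones <- list()
    for (id in names(ph$bones)) {
      m <- voxelize_meshes(list(ph$bones[[id]]$mesh), ph$spec$spacing)
      bones[[id]] <- bone_model(id, mask_to_points(m, TRUE, id),
                                mask_to_mesh(m))
    }
    rr <- hierarchical_register(bones, ph$hierarchy, lc$skeleton_points,
                                subtract = TRUE,
                                skeleton_mesh = mask_to_mesh(lc$skeleton))
    list(phantom = ph, truth = truth, bones = bones, result = rr)
  })
}

# identity transforms for every phantom bone
identity_state <- function(ph, config_id = "ref", footwear = "bare",
                           load_bw = 0) {
  ids <- names(ph$bones)
  configuration_state(config_id,
                      stats::setNames(lapply(ids, function(i)
                        identity_transform()), ids),
                      "N", load_bw, footwear)
}
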