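#' Configuration state: per-bone transforms for one load case
#'
#' @param config_id character id (e.g. `"N_1.0_bare"`).
#' @param transforms named list of [rigid_transform()] (one per bone),
#'   mapping the reference pose into this configuration.
#' @param orientation one of `"N"`, `"PF"`, `"DF"`, `"EV"`, `"IV"`.
#' @param load_bw load ratio in body weights (>= 0).
#' @param footwear `"bare"` or `"shod"`.
#' @return list of class `configuration_state`.
#' @export
configuration_state <- function(config_id, transforms, orientation = "N",
                                load_bw = 0, footwear = "bare") {
  stopifnot(is.list(transforms), !is.null(names(transforms)),
            load_bw >= 0,
            orientation %in% c("N", "PF", "DF", "EV", "IV"),
            footwear %in% c("bare", "shod"))
  structure(list(config_id = config_id, transforms = transforms,
                 orientation = orientation, load_bw = load_bw,
                 footwear = footwear), class = "configuration_state")
}

#' Motion of a bone relative to a frame bone
#'
#' Returns `invert(frame_tf) o bone_tf`: the identity when the bone moves
#' exactly with the frame bone. Expressing motion relative to the tibia
#' keeps whole-leg placement; relative to the calcaneus it removes the
#' rigid motion of the foot segment.
#'
#' @param bone_tf,frame_tf rigid transforms from the reference pose.
#' @return A [rigid_transform()].
#' @export
relative_transform <- function(bone_tf, frame_tf) {
  compose_rigid(invert_rigid(frame_tf), bone_tf)
}

#' Bone motion amplitudes relative to a frame bone
#'
#' Translation amplitude is the displacement norm of the bone's
#' reference-pose center of mass under the relative transform (mm);
#' rotation amplitude is the geodesic angle of the relative rotation,
#' `acos((trace(R) - 1) / 2)`, in degrees.
#'
#' @param state a [configuration_state()].
#' @param bone_id,frame_bone_id bone identifiers present in `state`.
#' @param com reference-pose center of mass of `bone_id` (numeric(3)).
#' @return `translation_amplitude`: mm; `rotation_amplitude`: degrees.
#' @export
translation_amplitude <- function(state, bone_id, frame_bone_id, com) {
  rel <- state_relative(state, bone_id, frame_bone_id)
  sqrt(sum((apply_rigid(rel, matrix(com, 1)) - com)^2))
}

#' @rdname translation_amplitude
#' @export
rotation_amplitude <- function(state, bone_id, frame_bone_id) {
  rel <- state_relative(state, bone_id, frame_bone_id)
  R <- rotation_zyx(rel$euler)
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

state_relative <- function(state, bone_id, frame_bone_id) {
  tfs <- state$transforms
  if (!bone_id %in% names(tfs)) stop("unknown bone: ", bone_id)
  if (!frame_bone_id %in% names(tfs))
    stop("unknown frame bone: ", frame_bone_id)
  relative_transform(tfs[[bone_id]], tfs[[frame_bone_id]])
}

#' Anatomical reference frame from the reference pose
#'
#' The three anatomical planes need an explicit axis construction:
#' the superior axis is the tibia's long principal axis oriented from
#' the talus toward the tibial plateau; the anterior axis is the
#' direction from the calcaneus center of mass to the 2nd metatarsal
#' center of mass, orthogonalized against superior; the medial axis
#' completes the frame with a side-dependent sign (`medial =
#' superior x anterior` for a left foot, negated for a right foot).
#'
#' @param bones named list of [bone_model()] with meshes, containing at
#'   least `tibia`, `calcaneus`, `metatarsal_2` (and `talus` if present,
#'   used to orient the superior axis).
#' @param side `"left"` or `"right"`.
#' @return list of class `anatomical_frame` with unit axes `anterior`,
#'   `superior`, `medial` and `origin` (calcaneus center of mass).
#' @export
build_anatomical_frame <- function(bones, side = c("left", "right")) {
  side <- match.arg(side)
  need <- c("tibia", "calcaneus", "metatarsal_2")
  if (!all(need %in% names(bones)))
    stop("anatomical frame needs bones: ", paste(need, collapse = ", "))
  com <- function(id) {
    b <- bones[[id]]
    if (!is.null(b$mesh)) center_of_mass(b$mesh) else colMeans(b$points)
  }
  tib <- bones[["tibia"]]
  tp <- if (!is.null(tib$mesh)) tib$mesh$vertices else tib$points
  ev <- eigen(stats::cov(tp), symmetric = TRUE)
  sup <- ev$vectors[, 1]
  up_ref <- com("tibia") - if ("talus" %in% names(bones)) com("talus") else
    com("calcaneus")
  if (sum(sup * up_ref) < 0) sup <- -sup
  ant_raw <- com("metatarsal_2") - com("calcaneus")
  ant <- ant_raw - sum(ant_raw * sup) * sup
  if (sqrt(sum(ant^2)) < 1e-9)
    stop("degenerate geometry: foot axis collinear with tibia axis")
  ant <- ant / sqrt(sum(ant^2))
  med <- c(sup[2] * ant[3] - sup[3] * ant[2],
           sup[3] * ant[1] - sup[1] * ant[3],
           sup[1] * ant[2] - sup[2] * ant[1])
  if (side == "right") med <- -med
  structure(list(anterior = ant, superior = sup, medial = med,
                 origin = com("calcaneus"), side = side),
            class = "anatomical_frame")
}

frame_plane_axes <- function(frame, plane) {
  switch(plane,
         sagittal = list(u = frame$anterior, v = frame$superior),
         coronal = list(u = frame$medial, v = frame$superior),
         transverse = list(u = frame$anterior, v = frame$medial),
         stop("unknown plane: ", plane))
}

#' Signed projected angle at a vertex bone
#'
#' The three centers of mass are projected onto the named anatomical
#' plane (sagittal: anterior/superior; coronal: medial/superior;
#' transverse: anterior/medial) and the signed angle at vertex `comB`
#' between the rays to `comA` and `comC` is returned via the two-argument
#' arctangent, in (-180, 180] degrees.
#'
#' @param comA,comB,comC centers of mass (numeric(3), mm).
#' @param frame an [build_anatomical_frame()] result.
#' @param plane `"sagittal"`, `"coronal"` or `"transverse"`.
#' @return Angle in degrees.
#' @export
projected_angle <- function(comA, comB, comC, frame, plane) {
  ax <- frame_plane_axes(frame, plane)
  pr <- function(p) c(sum(p * ax$u), sum(p * ax$v))
  a <- pr(comA) - pr(comB)
  c_ <- pr(comC) - pr(comB)
  if (sqrt(sum(a^2)) < 1e-9 || sqrt(sum(c_^2)) < 1e-9)
    stop("projected points coincide at the vertex bone")
  # counterclockwise-positive angle from ray B->C to ray B->A
  ang <- atan2(a[2], a[1]) - atan2(c_[2], c_[1])
  ang <- ang * 180 / pi
  if (ang <= -180) ang <- ang + 360
  if (ang > 180) ang <- ang - 360
  ang
}

#' Joint angle definitions tracked by the workflow
#'
#' Two center-of-mass angles: TibTalCal (tibia-talus-calcaneus; sagittal
#' plane = plantar-dorsal flexion, coronal = varus-valgus) and CalTalSM
#' (calcaneus-talus-medial sesamoid; sagittal = arch sagging, transverse
#' = abduction-adduction).
#'
#' @return data.frame with columns `name`, `boneA`, `boneB`, `boneC`,
#'   `plane`, `measure`.
#' @export
angle_definitions <- function() {
  data.frame(
    name = c("TibTalCal", "TibTalCal", "CalTalSM", "CalTalSM"),
    boneA = c("tibia", "tibia", "calcaneus", "calcaneus"),
    boneB = c("talus", "talus", "talus", "talus"),
    boneC = c("calcaneus", "calcaneus", "sesamoid_medial",
              "sesamoid_medial"),
    plane = c("sagittal", "coronal", "sagittal", "transverse"),
    measure = c("plantar_dorsal_flexion", "varus_valgus", "arch_sagging",
                "abduction_adduction"))
}

#' Measure projected joint angles for a configuration
#'
#' Centers of mass move rigidly with their bones; each definition row
#' yields the projected angle in this configuration and, when a
#' `reference` state is given, the amplitude (angle minus reference
#' angle).
#'
#' @param state a [configuration_state()].
#' @param frame an anatomical frame built from the reference pose.
#' @param coms named list/matrix of reference-pose centers of mass per
#'   bone.
#' @param definitions as [angle_definitions()].
#' @param reference optional reference [configuration_state()] for
#'   amplitudes.
#' @return data.frame: `config_id`, `name`, `plane`, `measure`,
#'   `angle_deg` and (with reference) `amplitude_deg`.
#' @export
measure_angles <- function(state, frame, coms,
                           definitions = angle_definitions(),
                           reference = NULL) {
  com_in <- function(st, id) {
    if (!id %in% names(st$transforms)) stop("unknown bone: ", id)
    as.numeric(apply_rigid(st$transforms[[id]], matrix(coms[[id]], 1)))
  }
  one <- function(st, d) {
    projected_angle(com_in(st, d$boneA), com_in(st, d$boneB),
                    com_in(st, d$boneC), frame, d$plane)
  }
  rows <- lapply(seq_len(nrow(definitions)), function(i) {
    d <- definitions[i, ]
    ang <- one(state, d)
    out <- data.frame(config_id = state$config_id, name = d$name,
                      plane = d$plane, measure = d$measure,
                      angle_deg = ang)
    if (!is.null(reference))
      out$amplitude_deg <- ang - one(reference, d)
    out
  })
  do.call(rbind, rows)
}

#' Ligament fiber length and engineering strain
#'
#' A fiber is a straight line between two attachment points, each fixed
#' in its bone's local (reference-pose) frame and carried into world
#' space by the bone's transform. Strain is `100 * (L - L_ref) / L_ref`
#' (percent), with `L_ref` from the reference configuration.
#'
#' @param state a [configuration_state()].
#' @param fiber list with `origin_bone`, `origin` (numeric(3), bone-local
#'   mm), `insertion_bone`, `insertion`.
#' @param reference reference [configuration_state()] for `L_ref`.
#' @return `ligament_length`: mm; `ligament_strain`: percent.
#' @export
ligament_length <- function(state, fiber) {
  tfs <- state$transforms
  for (b in c(fiber$origin_bone, fiber$insertion_bone))
    if (!b %in% names(tfs)) stop("fiber references unregistered bone: ", b)
  p1 <- apply_rigid(tfs[[fiber$origin_bone]], matrix(fiber$origin, 1))
  p2 <- apply_rigid(tfs[[fiber$insertion_bone]], matrix(fiber$insertion, 1))
  sqrt(sum((p1 - p2)^2))
}

#' @rdname ligament_length
#' @export
ligament_strain <- function(state, reference, fiber) {
  L <- ligament_length(state, fiber)
  L0 <- ligament_length(reference, fiber)
  if (L0 < 1e-6) stop("reference fiber length is degenerate (< 1e-6 mm)")
  100 * (L - L0) / L0
}

#' Tabulate all biomechanical measures for a set of configurations
#'
#' One long table over configurations: per-bone translation and rotation
#' amplitudes relative to `frame_bones`, projected joint angles, and
#' per-fiber ligament strains.
#'
#' @param states list of [configuration_state()].
#' @param reference reference [configuration_state()] (bare, unloaded).
#' @param bones named list of [bone_model()] with meshes.
#' @param ligaments list of fibers (see [ligament_length()]), each with a
#'   `name` and optional `group`.
#' @param frame an [build_anatomical_frame()] result.
#' @param frame_bones bones relative to which amplitudes are expressed.
#' @return data.frame with columns `config_id`, `orientation`, `load_bw`,
#'   `footwear`, `metric_type`, `entity`, `frame_bone`, `value`.
#' @export
measure_all <- function(states, reference, bones, ligaments, frame,
                        frame_bones = c("tibia", "calcaneus")) {
  coms <- lapply(bones, function(b)
    if (!is.null(b$mesh)) center_of_mass(b$mesh) else colMeans(b$points))
  names(coms) <- vapply(bones, `[[`, "", "bone_id")
  rows <- list()
  add <- function(st, metric, entity, frame_bone, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      config_id = st$config_id, orientation = st$orientation,
      load_bw = st$load_bw, footwear = st$footwear, metric_type = metric,
      entity = entity, frame_bone = frame_bone, value = value)
  }
  for (st in states) {
    for (fb in frame_bones) {
      for (id in names(st$transforms)) {
        if (id == fb) next
        add(st, "translation_mm", id, fb,
            translation_amplitude(st, id, fb, coms[[id]]))
        add(st, "rotation_deg", id, fb, rotation_amplitude(st, id, fb))
      }
    }
    ang <- measure_angles(st, frame, coms, reference = reference)
    for (i in seq_len(nrow(ang)))
      add(st, "angle_deg", paste(ang$name[i], ang$plane[i], sep = "_"),
          "anatomical", ang$amplitude_deg[i])
    for (lig in ligaments)
      add(st, "strain_pct", lig$name, "", ligament_strain(st, reference, lig))
  }
  do.call(rbind, rows)
}
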