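#' Drainage zone of surface-anchored lesions
#'
#' Looks up the drainage-zone label of the face on which each lesion is
#' anchored.  The assignment is a total function on the surface: every
#' anchored lesion receives exactly one zone.
#'
#' @param mesh a `leg_surface` with zones assigned.
#' @param anchored anchored-point data.frame (column `face`), e.g. from
#'   [closest_point_on_mesh()] or [transfer_lesions()].
#' @return character vector of zone ids.
#' @export
assign_zone_3d <- function(mesh, anchored) {
  if (is.null(mesh$zone_of_face)) {
    stop("mesh has no zones assigned; run segment_zones() first",
         call. = FALSE)
  }
  face <- if (is.data.frame(anchored)) anchored$face else anchored
  if (is.null(face) || any(is.na(face))) {
    stop("lesions are not anchored on the surface", call. = FALSE)
  }
  mesh$zone_of_face[as.integer(face)]
}

# first view (fixed order) in which a face is front-facing
face_view <- function(mesh) {
  nrm <- face_normals(mesh)
  dirs <- cbind(anterior = c(0, 1, 0), medial = c(1, 0, 0),
                lateral = c(-1, 0, 0), dorsal = c(0, -1, 0))
  d <- nrm %*% dirs > 1e-12
  vw <- rep(NA_integer_, nrow(d))
  for (k in rev(seq_len(ncol(d)))) vw[d[, k]] <- k
  colnames(dirs)[vw]
}

view_uv <- function(view, p) {
  p <- matrix(p, ncol = 3L)
  switch(view,
         lateral = cbind(-p[, 2L], p[, 3L]),
         medial = cbind(p[, 2L], p[, 3L]),
         anterior = cbind(p[, 1L], p[, 3L]),
         dorsal = cbind(-p[, 1L], p[, 3L]),
         stop("unknown view: ", view, call. = FALSE))
}

#' Map one patient's lesions onto the reference leg
#'
#' Runs the per-patient standardization chain: mirror right-sided
#' coordinates into the left-leg frame, fit the landmark-based rigid
#' transform onto the reference, transfer and snap the lesions onto the
#' reference surface, assign each lesion its drainage zone, and project it
#' into the 2D template view facing its anchoring face.
#'
#' A patient is evaluable only with exactly one primary melanoma and at
#' least one mappable in-transit metastasis; otherwise the patient is
#' flagged unevaluable with a reason and no lesion table is produced.
#'
#' @param lesions one patient's lesion rows (columns `patient_id`,
#'   `lesion_id`, `role`, `side`, `site`, `x_cm`, `y_cm`, `z_cm`).
#' @param landmarks the patient's landmark matrix (n x 3, rownames =
#'   landmark names) in the same coordinate frame.
#' @param reference the reference `leg_surface`.
#' @param snap_threshold maximal snap distance (cm) before a lesion is
#'   flagged unmappable.
#' @return list with `evaluable` (logical), `reason` (`NA` if evaluable),
#'   `lesions` (annotated table with `zone`, `view`, `u_cm`, `v_cm`,
#'   `snap_dist`, `mappable`), `transform` (the fitted `rigid_transform`),
#'   `mirrored`.
#' @export
map_patient <- function(lesions, landmarks, reference, snap_threshold = 3) {
  n_primary <- sum(lesions$role == "primary")
  if (n_primary != 1L) {
    return(list(evaluable = FALSE,
                reason = sprintf("%d primary melanomas (need exactly 1)",
                                 n_primary),
                lesions = NULL, transform = NULL, mirrored = NA))
  }
  mir <- mirror_to_left(lesions, landmarks)
  tf <- fit_rigid_transform(mir$landmarks, reference_landmarks(reference))
  mapped <- transfer_lesions(mir$lesions, tf, reference,
                             snap_threshold = snap_threshold)
  mapped$zone <- assign_zone_3d(reference, mapped)
  vw <- face_view(reference)[mapped$face]
  uv <- matrix(NA_real_, nrow(mapped), 2L)
  pts3 <- cbind(mapped$x, mapped$y, mapped$z)
  for (v in unique(vw)) {
    rows <- which(vw == v)
    uv[rows, ] <- view_uv(v, pts3[rows, , drop = FALSE])
  }
  mapped$view <- vw
  mapped$u_cm <- uv[, 1L]
  mapped$v_cm <- uv[, 2L]
  n_itm_ok <- sum(mapped$role == "itm" & mapped$mappable)
  if (n_itm_ok < 1L) {
    return(list(evaluable = FALSE, reason = "no mappable in-transit metastasis",
                lesions = mapped, transform = tf, mirrored = mir$mirrored))
  }
  if (!mapped$mappable[mapped$role == "primary"]) {
    return(list(evaluable = FALSE, reason = "primary melanoma unmappable",
                lesions = mapped, transform = tf, mirrored = mir$mirrored))
  }
  list(evaluable = TRUE, reason = NA_character_, lesions = mapped,
       transform = tf, mirrored = mir$mirrored)
}

#' Score a mapped patient's drainage concordance
#'
#' @param mapped result of [map_patient()] for an evaluable patient.
#' @return one-row [score_concordance()] result.
#' @export
score_patient <- function(mapped) {
  if (!isTRUE(mapped$evaluable)) {
    stop("patient is not evaluable: ", mapped$reason, call. = FALSE)
  }
  les <- mapped$lesions[mapped$lesions$mappable, , drop = FALSE]
  prim <- les[les$role == "primary", , drop = FALSE]
  itm <- les[les$role == "itm", , drop = FALSE]
  score_concordance(prim$zone[1L], itm$zone,
                    patient_id = prim$patient_id[1L], site = prim$site[1L])
}
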