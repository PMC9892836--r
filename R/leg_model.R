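#' Build the canonical reference leg surface
#'
#' Constructs a parametric triangle mesh of a left lower limb in the
#' canonical frame (+z proximal, +y anterior, +x medial; units cm), used as
#' the common target onto which patient lesions are registered.  The limb is
#' a generalized cylinder: elliptical cross-section rings are swept from the
#' toes along the foot, through a quarter-circle bend at the ankle, then up
#' the lower leg and thigh, with apex caps at the toe tip and thigh top.
#'
#' Named bone landmarks (patella, medial/lateral malleolus, first and fifth
#' toe tips) are placed analytically on key rings whose positions depend
#' only on the shape parameters, not on the mesh resolution, so landmark
#' coordinates are invariant to refinement.
#'
#' @param foot_length heel-to-toe extent of the foot (cm).
#' @param foot_half_width,foot_half_height cross-section semi-axes of the
#'   midfoot (cm).
#' @param ankle_rx,ankle_ry cross-section semi-axes at the malleolus ring (cm).
#' @param lower_leg_length malleolus-to-knee length (cm).
#' @param calf_rx,calf_ry semi-axes at the widest calf ring (cm).
#' @param knee_rx,knee_ry semi-axes at the patella ring (cm).
#' @param thigh_length knee-to-groin length (cm).
#' @param thigh_rx,thigh_ry semi-axes at the top ring (cm).
#' @param toe_length axial extent of the toe region (cm); faces in this
#'   region are always assigned to the anteromedial drainage sector.
#' @param n_circ number of circumferential segments (>= 8, multiple of 4 so
#'   that the pure medial/anterior/lateral/posterior meridians fall on
#'   vertices).
#' @param n_axial number of interior rings inserted between consecutive key
#'   rings (>= 1).
#' @param boundaries drainage-sector boundary meridians passed on to
#'   [segment_zones()]; use `NULL` to leave zones unassigned.
#' @param plantar_zone drainage zone assigned to the plantar (sole) faces of
#'   the foot, or `NULL` to use the meridian sectors there as well.  The
#'   plantar drainage pathway is anatomically unresolved; the default sends
#'   it, like the toes, to the anteromedial bundle.
#' @return a `leg_surface` object: a [surface_mesh()] with additional
#'   elements `landmarks` (named vertex indices), `vertex_angle` (meridian
#'   angle in degrees per vertex, NA at cap apexes), `vertex_region`
#'   (`"toe"`, `"foot"` or `"leg"`), `zone_of_face`, and `params`.
#' @examples
#' leg <- build_reference_leg(n_circ = 16, n_axial = 1)
#' leg$landmarks
#' table(leg$zone_of_face)
#' @export
build_reference_leg <- function(foot_length = 25,
                                foot_half_width = 4.5,
                                foot_half_height = 2.6,
                                ankle_rx = 4.0, ankle_ry = 4.5,
                                lower_leg_length = 39,
                                calf_rx = 5.5, calf_ry = 6.0,
                                knee_rx = 5.0, knee_ry = 5.5,
                                thigh_length = 40,
                                thigh_rx = 8.0, thigh_ry = 8.5,
                                toe_length = 4,
                                n_circ = 32, n_axial = 3,
                                boundaries = default_zone_boundaries(),
                                plantar_zone = "anteromedial") {
  dims <- c(foot_length, foot_half_width, foot_half_height, ankle_rx,
            ankle_ry, lower_leg_length, calf_rx, calf_ry, knee_rx, knee_ry,
            thigh_length, thigh_rx, thigh_ry, toe_length)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("all shape parameters must be positive finite numbers", call. = FALSE)
  }
  n_circ <- as.integer(n_circ)
  n_axial <- as.integer(n_axial)
  if (n_circ < 8L || n_circ %% 4L != 0L) {
    stop("n_circ must be >= 8 and a multiple of 4", call. = FALSE)
  }
  if (n_axial < 1L) stop("n_axial must be >= 1", call. = FALSE)

  z_fc <- foot_half_height                 # foot tube centre height
  r_bend <- max(ankle_ry, 1.5 * foot_half_height)
  z_ankle <- z_fc + r_bend                 # malleolus ring height
  y_toe <- foot_length - r_bend            # toe ring plane
  if (y_toe <= toe_length) {
    stop("foot_length too small for the requested toe_length", call. = FALSE)
  }
  z_knee <- z_ankle + lower_leg_length
  z_top <- z_knee + thigh_length
  z_calf <- z_ankle + 0.35 * lower_leg_length
  z_thigh_max <- z_knee + 0.6 * thigh_length

  # --- key stations along the sweep (toe -> top) --------------------------
  # each: centre, cross axes U (always +x) and V (dorsal/anterior), radii
  station <- function(center, V, rx, rv) {
    list(center = center, V = V, rx = rx, rv = rv)
  }
  Vfoot <- c(0, 0, 1)                      # dorsal on the foot
  Vleg <- c(0, 1, 0)                       # anterior on the leg
  key <- list(
    toe = station(c(0, y_toe, z_fc), Vfoot, 0.85 * foot_half_width,
                  0.75 * foot_half_height),
    midfoot = station(c(0, 0.55 * y_toe + 0.45 * r_bend, z_fc), Vfoot,
                      foot_half_width, foot_half_height),
    bend_start = station(c(0, r_bend, z_fc), Vfoot, 0.95 * foot_half_width,
                         1.1 * foot_half_height),
    ankle = station(c(0, 0, z_ankle), Vleg, ankle_rx, ankle_ry),
    calf = station(c(0, 0, z_calf), Vleg, calf_rx, calf_ry),
    knee = station(c(0, 0, z_knee), Vleg, knee_rx, knee_ry),
    thigh_max = station(c(0, 0, z_thigh_max), Vleg, thigh_rx, thigh_ry),
    top = station(c(0, 0, z_top), Vleg, 0.95 * thigh_rx, 0.95 * thigh_ry)
  )

  # interpolated stations: n_axial interior rings between key rings; the
  # bend segment sweeps a quarter circle with V rotating from +z to +y
  lerp_station <- function(s1, s2, t) {
    station(s1$center + t * (s2$center - s1$center),
            s1$V + t * (s2$V - s1$V),       # only used within straight parts
            s1$rx + t * (s2$rx - s1$rx),
            s1$rv + t * (s2$rv - s1$rv))
  }
  bend_station <- function(s1, s2, t) {
    alpha <- t * pi / 2                    # 0 = horizontal, pi/2 = vertical
    center <- c(0, r_bend * (1 - sin(alpha)) + 0,  # y: r_bend -> 0
                z_fc + r_bend * (1 - cos(alpha)))  # z: z_fc -> z_ankle
    station(center, c(0, sin(alpha), cos(alpha)),
            s1$rx + t * (s2$rx - s1$rx), s1$rv + t * (s2$rv - s1$rv))
  }
  seg_names <- names(key)
  stations <- list(key[[1L]])
  for (s in seq_len(length(key) - 1L)) {
    s1 <- key[[s]]; s2 <- key[[s + 1L]]
    interp <- if (seg_names[s] == "bend_start") bend_station else lerp_station
    for (j in seq_len(n_axial)) {
      stations[[length(stations) + 1L]] <- interp(s1, s2, j / (n_axial + 1))
    }
    stations[[length(stations) + 1L]] <- s2
  }
  key_ring <- cumsum(c(1L, rep(n_axial + 1L, length(key) - 1L)))
  names(key_ring) <- seg_names

  # --- vertices -----------------------------------------------------------
  phi <- (seq_len(n_circ) - 1L) * 360 / n_circ
  phi_rad <- phi * pi / 180
  U <- c(1, 0, 0)
  n_rings <- length(stations)
  verts <- matrix(0, n_rings * n_circ + 2L, 3L)
  v_angle <- rep(NA_real_, nrow(verts))
  for (i in seq_len(n_rings)) {
    st <- stations[[i]]
    rows <- (i - 1L) * n_circ + seq_len(n_circ)
    verts[rows, ] <- matrix(st$center, n_circ, 3L, byrow = TRUE) +
      outer(st$rx * cos(phi_rad), U) + outer(st$rv * sin(phi_rad), st$V)
    v_angle[rows] <- phi
  }
  apex_toe <- n_rings * n_circ + 1L
  apex_top <- n_rings * n_circ + 2L
  verts[apex_toe, ] <- key$toe$center + c(0, 0.6 * key$toe$rv, 0)
  verts[apex_top, ] <- key$top$center + c(0, 0, 0.4 * key$top$rv)

  # regions: toe (forced anteromedial), foot (below malleoli), leg
  v_region <- rep("leg", nrow(verts))
  ring_of_vertex <- rep(seq_len(n_rings), each = n_circ)
  ring_y <- vapply(stations, function(s) s$center[2L], 0)
  ring_z <- vapply(stations, function(s) s$center[3L], 0)
  foot_rings <- which(ring_z < z_ankle - 1e-9)
  toe_rings <- which(ring_y >= y_toe - toe_length - 1e-9 &
                       ring_z < z_ankle - 1e-9)
  v_region[seq_len(n_rings * n_circ)] <- "leg"
  v_region[ring_of_vertex %in% foot_rings] <- "foot"
  v_region[ring_of_vertex %in% toe_rings] <- "toe"
  v_region[apex_toe] <- "toe"
  v_region[apex_top] <- "leg"

  # --- faces (outward winding) -------------------------------------------
  nxt <- c(seq_len(n_circ)[-1L], 1L)
  faces <- vector("list", n_rings + 1L)
  for (i in seq_len(n_rings - 1L)) {
    lo <- (i - 1L) * n_circ
    hi <- i * n_circ
    a <- lo + seq_len(n_circ); b <- lo + nxt
    c_ <- hi + seq_len(n_circ); d <- hi + nxt
    faces[[i]] <- rbind(cbind(a, b, c_), cbind(b, d, c_))
  }
  r0 <- seq_len(n_circ)
  faces[[n_rings]] <- cbind(apex_toe, r0[nxt], r0)          # toe cap
  rl <- (n_rings - 1L) * n_circ + seq_len(n_circ)
  faces[[n_rings + 1L]] <- cbind(apex_top, rl, rl[nxt])     # top cap
  faces <- do.call(rbind, faces)

  mesh <- surface_mesh(verts, faces)
  # ensure outward orientation: flip all faces if signed volume is negative
  if (signed_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  }

  landmarks <- c(
    toe_tip_1 = (key_ring[["toe"]] - 1L) * n_circ + 1L,
    toe_tip_5 = (key_ring[["toe"]] - 1L) * n_circ + n_circ %/% 2L + 1L,
    medial_malleolus = (key_ring[["ankle"]] - 1L) * n_circ + 1L,
    lateral_malleolus = (key_ring[["ankle"]] - 1L) * n_circ +
      n_circ %/% 2L + 1L,
    patella = (key_ring[["knee"]] - 1L) * n_circ + n_circ %/% 4L + 1L
  )

  mesh$landmarks <- landmarks
  mesh$vertex_angle <- v_angle
  mesh$vertex_region <- v_region
  mesh$params <- list(z_ankle = z_ankle, z_knee = z_knee, z_top = z_top,
                      z_foot_center = z_fc, y_toe = y_toe,
                      toe_length = toe_length, n_circ = n_circ,
                      n_axial = n_axial)
  class(mesh) <- c("leg_surface", class(mesh))
  mesh <- cache_mesh_geometry(mesh)
  if (!is.null(boundaries)) {
    mesh <- segment_zones(mesh, boundaries, plantar_zone = plantar_zone)
  }
  mesh
}

signed_volume <- function(mesh) {
  fc <- face_corners(mesh)
  a <- fc$a; b <- fc$b; c <- fc$c
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
        a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
        a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

# circular mean of meridian angles (degrees), NAs dropped
circ_mean_deg <- function(theta) {
  th <- theta[!is.na(theta)] * pi / 180
  (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi) %% 360
}

#' Meridian angle of each face
#'
#' The meridian angle of a face is the circular mean of the meridian angles
#' of its vertices (cap apexes, which have no angle, are ignored).  Angles
#' are degrees counter-clockwise from medial (0) through anterior (90),
#' viewed from proximal.
#'
#' @param mesh a `leg_surface`.
#' @return numeric vector, one angle in [0, 360) per face.
#' @export
face_angles <- function(mesh) {
  if (!is.null(mesh$face_angle)) return(mesh$face_angle)
  if (is.null(mesh$vertex_angle)) {
    stop("mesh carries no vertex meridian angles; build it with ",
         "build_reference_leg()", call. = FALSE)
  }
  th <- matrix(mesh$vertex_angle[mesh$faces], ncol = 3L) * pi / 180
  s <- rowMeans(sin(th), na.rm = TRUE)
  c_ <- rowMeans(cos(th), na.rm = TRUE)
  (atan2(s, c_) * 180 / pi) %% 360
}

# face region by vertex majority; ties resolved toward the more distal
# region (toe > foot > leg) so cap and transition faces inherit the toe rule
face_regions <- function(mesh) {
  if (!is.null(mesh$face_region)) return(mesh$face_region)
  r <- matrix(mesh$vertex_region[mesh$faces], ncol = 3L)
  n_toe <- rowSums(r == "toe")
  n_foot <- rowSums(r == "foot")
  n_leg <- rowSums(r == "leg")
  ifelse(n_toe >= pmax(n_foot, n_leg), "toe",
         ifelse(n_foot >= n_leg, "foot", "leg"))
}

#' Assign drainage zones to every face of the leg surface
#'
#' Partitions the surface into the four lymphatic drainage sectors by
#' meridian angle: each face belongs to the sector whose angular interval
#' (counter-clockwise from its boundary meridian to the next) contains the
#' face's meridian angle.  A face lying exactly on a boundary meridian goes
#' to the sector counter-clockwise of that boundary (the sector that starts
#' there).  Two anatomical overrides apply: all toe-region faces are forced
#' to the anteromedial sector, and plantar faces of the foot are assigned to
#' `plantar_zone` (default anteromedial) unless `plantar_zone` is `NULL`.
#'
#' @param mesh a `leg_surface` built by [build_reference_leg()].
#' @param boundaries named numeric vector of four distinct boundary
#'   meridians in degrees, see [default_zone_boundaries()].
#' @param plantar_zone zone for the sole of the foot, or `NULL`.
#' @return the mesh with `zone_of_face` filled (character, one zone per face).
#' @export
segment_zones <- function(mesh, boundaries = default_zone_boundaries(),
                          plantar_zone = "anteromedial") {
  check_zone_boundaries(boundaries)
  ang <- face_angles(mesh)
  reg <- face_regions(mesh)
  zone <- zone_of_angle(ang, boundaries)
  if (!is.null(plantar_zone)) {
    plantar <- reg == "foot" & ang > 180 & ang < 360
    zone[plantar] <- as_zone_id(plantar_zone)
  }
  zone[reg == "toe"] <- "anteromedial"
  mesh$face_angle <- ang
  mesh$face_region <- reg
  mesh$zone_of_face <- zone
  mesh$zone_boundaries <- boundaries
  mesh
}

# faces available for lesion placement at a given anatomic site
site_faces <- function(mesh, site) {
  reg <- face_regions(mesh)
  cz <- face_centroids(mesh)[, 3L]
  p <- mesh$params
  switch(site,
         foot = which(reg %in% c("toe", "foot")),
         lower_leg = which(reg == "leg" & cz <= p$z_knee),
         thigh = which(reg == "leg" & cz > p$z_knee),
         stop("unknown site: ", site, call. = FALSE))
}
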