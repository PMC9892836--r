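#' Project the leg surface into the four 2D reference views
#'
#' Builds the 2D reference template: orthographic projections of the
#' zone-labeled surface along the four horizontal view directions
#' (lateral, medial, anterior, dorsal).  Only front-facing faces (outward
#' normal toward the camera) contribute to a view, so each view shows the
#' visible half of the limb as a set of zone-labeled 2D triangles; the
#' vertical template coordinate v equals the canonical z, so axial
#' distances are preserved exactly.  Landmarks are projected into every
#' view and flagged visible where they belong to at least one front-facing
#' face.
#'
#' View conventions (left leg, +x medial, +y anterior):
#' lateral camera at -x (u = -y), medial at +x (u = y), anterior at +y
#' (u = x), dorsal at -y (u = -x); v = z in all views.
#'
#' @param mesh a `leg_surface` with zones assigned.
#' @return object of class `zone_template`: list of `views`, each holding
#'   `triangles` (data.frame: `zone`, `face`, `u1`,`v1`,`u2`,`v2`,`u3`,`v3`,
#'   cm) and `landmarks_2d` (data.frame: `name`, `u`, `v`, `visible`).
#' @export
project_views <- function(mesh) {
  if (is.null(mesh$zone_of_face)) {
    stop("mesh has no zones assigned; run segment_zones() first",
         call. = FALSE)
  }
  dirs <- list(lateral = c(-1, 0, 0), medial = c(1, 0, 0),
               anterior = c(0, 1, 0), dorsal = c(0, -1, 0))
  uv <- list(
    lateral = function(p) cbind(u = -p[, 2L], v = p[, 3L]),
    medial = function(p) cbind(u = p[, 2L], v = p[, 3L]),
    anterior = function(p) cbind(u = p[, 1L], v = p[, 3L]),
    dorsal = function(p) cbind(u = -p[, 1L], v = p[, 3L])
  )
  nrm <- face_normals(mesh)
  fc <- face_corners(mesh)
  lm_xyz <- reference_landmarks(mesh)
  views <- list()
  for (vw in names(dirs)) {
    front <- which(nrm %*% dirs[[vw]] > 1e-12)
    p1 <- uv[[vw]](fc$a[front, , drop = FALSE])
    p2 <- uv[[vw]](fc$b[front, , drop = FALSE])
    p3 <- uv[[vw]](fc$c[front, , drop = FALSE])
    tri <- data.frame(zone = mesh$zone_of_face[front], face = front,
                      u1 = p1[, 1L], v1 = p1[, 2L],
                      u2 = p2[, 1L], v2 = p2[, 2L],
                      u3 = p3[, 1L], v3 = p3[, 2L],
                      stringsAsFactors = FALSE)
    lm_uv <- uv[[vw]](lm_xyz)
    vis <- vapply(mesh$landmarks, function(vi)
      any(front %in% which(mesh$faces[, 1L] == vi | mesh$faces[, 2L] == vi |
                             mesh$faces[, 3L] == vi)), TRUE)
    views[[vw]] <- list(
      triangles = tri,
      landmarks_2d = data.frame(name = rownames(lm_xyz), u = lm_uv[, 1L],
                                v = lm_uv[, 2L], visible = unname(vis),
                                stringsAsFactors = FALSE))
  }
  structure(list(views = views, units = "cm"), class = "zone_template")
}

#' @export
print.zone_template <- function(x, ...) {
  cat("<zone_template> views:", paste(names(x$views), collapse = ", "), "\n")
  for (vw in names(x$views)) {
    cat(sprintf("  %-9s %4d visible faces\n", vw,
                nrow(x$views[[vw]]$triangles)))
  }
  invisible(x)
}

# signed-area-free barycentric point-in-triangle, tolerance on edges
points_in_triangles <- function(u, v, tri, eps = 1e-9) {
  d <- (tri$v2 - tri$v3) * (tri$u1 - tri$u3) +
    (tri$u3 - tri$u2) * (tri$v1 - tri$v3)
  w1 <- ((tri$v2 - tri$v3) * (u - tri$u3) + (tri$u3 - tri$u2) * (v - tri$v3)) / d
  w2 <- ((tri$v3 - tri$v1) * (u - tri$u3) + (tri$u1 - tri$u3) * (v - tri$v3)) / d
  w3 <- 1 - w1 - w2
  abs(d) > eps & w1 >= -eps & w2 >= -eps & w3 >= -eps
}

#' Assign a drainage zone on the 2D template
#'
#' Looks up the zone of the template polygon containing a 2D point in the
#' given view.  A point lying on an edge shared by polygons of different
#' zones is resolved deterministically to the zone that comes first in the
#' [zone_ids()] enumeration order.
#'
#' @param point numeric length-2 vector `c(u, v)` in template cm.
#' @param view one of `"lateral"`, `"medial"`, `"anterior"`, `"dorsal"`.
#' @param template a `zone_template` from [project_views()].
#' @return the zone id (character scalar).
#' @export
assign_zone_2d <- function(point, view, template) {
  if (!view %in% names(template$views)) {
    stop("unknown view: ", view, call. = FALSE)
  }
  tri <- template$views[[view]]$triangles
  hit <- points_in_triangles(point[1L], point[2L], tri)
  if (!any(hit)) {
    stop("point (", point[1L], ", ", point[2L], ") lies outside the ",
         view, " view silhouette", call. = FALSE)
  }
  zones <- tri$zone[hit]
  zone_ids()[min(match(zones, zone_ids()))]
}

#' Render a template view with mapped lesions
#'
#' Draws one view of the zone template with its conventional zone colours
#' and overlays mapped lesions: primary melanoma in black, in-transit
#' metastases in red.
#'
#' @param template a `zone_template`.
#' @param view the view to draw.
#' @param lesions optional mapped lesion table with columns `view`, `u_cm`,
#'   `v_cm`, `role`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plot_template_view <- function(template, view = "anterior", lesions = NULL,
                               ...) {
  tri <- template$views[[view]]$triangles
  cols <- zone_colors()
  u <- c(tri$u1, tri$u2, tri$u3)
  v <- c(tri$v1, tri$v2, tri$v3)
  graphics::plot(NA, xlim = range(u), ylim = range(v), asp = 1,
                 xlab = "u (cm)", ylab = "v (cm)",
                 main = paste(view, "view"), ...)
  for (i in seq_len(nrow(tri))) {
    graphics::polygon(c(tri$u1[i], tri$u2[i], tri$u3[i]),
                      c(tri$v1[i], tri$v2[i], tri$v3[i]),
                      col = grDevices::adjustcolor(cols[[tri$zone[i]]], 0.6),
                      border = NA)
  }
  if (!is.null(lesions)) {
    sel <- lesions$view == view & !is.na(lesions$u_cm)
    pts <- lesions[sel, , drop = FALSE]
    graphics::points(pts$u_cm, pts$v_cm, pch = 21,
                     bg = ifelse(pts$role == "primary", "black", "red"),
                     col = "white", cex = ifelse(pts$role == "primary",
                                                 1.4, 1))
  }
  invisible(NULL)
}

#' Serialize a zone template to JSON
#'
#' @param template a `zone_template`.
#' @param path output JSON path.
#' @return `read_zone_template()`: a `zone_template`.
#' @export
write_zone_template <- function(template, path) {
  jsonlite::write_json(unclass(template), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_zone_template
#' @export
read_zone_template <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(views = lapply(x$views, function(vw)
    list(triangles = as.data.frame(vw$triangles),
         landmarks_2d = as.data.frame(vw$landmarks_2d))),
    units = x$units), class = "zone_template")
}
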