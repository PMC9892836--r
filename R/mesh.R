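#' Triangle surface mesh
#'
#' Minimal container for a triangle mesh in the canonical limb frame
#' (units cm; +z proximal, +y anterior, +x medial for a left leg).  The
#' reference leg built by [build_reference_leg()] is a `leg_surface`, which
#' extends `surface_mesh` with landmarks, per-vertex meridian angles and
#' anatomical regions, and a drainage-zone label per face.
#'
#' @param vertices numeric matrix, one row per vertex, columns x, y, z (cm).
#' @param faces integer matrix, one row per triangle, vertex indices (1-based).
#' @return an object of class `surface_mesh` with elements `vertices` and
#'   `faces`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must have 3 columns", call. = FALSE)
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<%s> %d vertices, %d faces\n",
              class(x)[1L], nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$landmarks)) {
    cat("landmarks:", paste(names(x$landmarks), collapse = ", "), "\n")
  }
  if (!is.null(x$zone_of_face)) {
    cat("zones:\n")
    print(table(x$zone_of_face))
  }
  invisible(x)
}

# corner coordinate arrays: list of three n_face x 3 matrices
face_corners <- function(mesh) {
  if (!is.null(mesh$geom_cache)) return(mesh$geom_cache$corners)
  v <- mesh$vertices
  f <- mesh$faces
  list(a = v[f[, 1L], , drop = FALSE],
       b = v[f[, 2L], , drop = FALSE],
       c = v[f[, 3L], , drop = FALSE])
}

#' Precompute and attach face geometry
#'
#' Caches the per-face corner matrices, centroids, unit normals and areas
#' on the mesh object, so the snap/sampling/zone hot paths avoid
#' recomputing them.  All geometry accessors use the cache when present.
#'
#' @param mesh a `surface_mesh`.
#' @return the mesh with a `geom_cache` element.
#' @export
cache_mesh_geometry <- function(mesh) {
  mesh$geom_cache <- NULL
  fc <- face_corners(mesh)
  cen <- (fc$a + fc$b + fc$c) / 3
  r2 <- pmax(rowSums((fc$a - cen)^2), rowSums((fc$b - cen)^2),
             rowSums((fc$c - cen)^2))
  mesh$geom_cache <- list(corners = fc, centroids = cen,
                          normals = face_normals(mesh),
                          areas = face_areas(mesh),
                          rmax = sqrt(max(r2)))
  mesh
}

#' Face geometry helpers
#'
#' @param mesh a `surface_mesh`.
#' @return `face_centroids()`: n_face x 3 matrix; `face_normals()`:
#'   n_face x 3 matrix of unit outward normals (right-hand rule on the
#'   stored vertex order); `face_areas()`: numeric vector (cm^2).
#' @export
face_centroids <- function(mesh) {
  if (!is.null(mesh$geom_cache)) return(mesh$geom_cache$centroids)
  fc <- face_corners(mesh)
  (fc$a + fc$b + fc$c) / 3
}

#' @rdname face_centroids
#' @export
face_normals <- function(mesh) {
  if (!is.null(mesh$geom_cache)) return(mesh$geom_cache$normals)
  fc <- face_corners(mesh)
  e1 <- fc$b - fc$a
  e2 <- fc$c - fc$a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' @rdname face_centroids
#' @export
face_areas <- function(mesh) {
  if (!is.null(mesh$geom_cache)) return(mesh$geom_cache$areas)
  fc <- face_corners(mesh)
  e1 <- fc$b - fc$a
  e2 <- fc$c - fc$a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sqrt(rowSums(n^2)) / 2
}

# unique undirected edges; returns matrix with columns v1 < v2
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

# is the mesh edge-connected (every face reachable over shared vertices)?
mesh_is_connected <- function(mesh) {
  e <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$vertices) - igraph::vcount(g)))
  igraph::components(g)$no == 1L
}

#' Anchor points on a mesh surface
#'
#' A surface-anchored point is stored as a face index plus barycentric
#' coordinates within that face.  `anchored_points()` validates the
#' anchoring and returns a data frame that also carries the resolved 3D
#' position.
#'
#' @param mesh a `surface_mesh`.
#' @param face integer vector of face indices.
#' @param bary numeric matrix with 3 columns of barycentric coordinates
#'   (rows sum to 1, entries non-negative).
#' @return data.frame with columns `face`, `b1`, `b2`, `b3`, `x`, `y`, `z`.
#' @export
anchored_points <- function(mesh, face, bary) {
  face <- as.integer(face)
  bary <- matrix(as.numeric(bary), ncol = 3L)
  if (length(face) != nrow(bary)) stop("face/bary length mismatch", call. = FALSE)
  if (any(face < 1L | face > nrow(mesh$faces))) {
    stop("face index out of range", call. = FALSE)
  }
  if (any(bary < -1e-9) || any(abs(rowSums(bary) - 1) > 1e-9)) {
    stop("barycentric coordinates must be non-negative and sum to 1",
         call. = FALSE)
  }
  bary[bary < 0] <- 0
  p <- barycentric_to_xyz(mesh, face, bary)
  data.frame(face = face, b1 = bary[, 1L], b2 = bary[, 2L], b3 = bary[, 3L],
             x = p[, 1L], y = p[, 2L], z = p[, 3L])
}

barycentric_to_xyz <- function(mesh, face, bary) {
  v <- mesh$vertices
  f <- mesh$faces[face, , drop = FALSE]
  bary[, 1L] * v[f[, 1L], , drop = FALSE] +
    bary[, 2L] * v[f[, 2L], , drop = FALSE] +
    bary[, 3L] * v[f[, 3L], , drop = FALSE]
}

#' Sample points uniformly on a mesh surface
#'
#' Faces are chosen with probability proportional to area (optionally
#' restricted to a subset) and a point is drawn uniformly within the chosen
#' triangle.
#'
#' @param mesh a `surface_mesh`.
#' @param n number of points.
#' @param faces optional integer vector restricting the candidate faces.
#' @return anchored-point data frame (see [anchored_points()]).
#' @export
sample_surface_points <- function(mesh, n, faces = NULL) {
  areas <- face_areas(mesh)
  cand <- if (is.null(faces)) seq_along(areas) else as.integer(faces)
  if (length(cand) == 0L) stop("no candidate faces to sample from", call. = FALSE)
  f <- cand[sample.int(length(cand), n, replace = TRUE, prob = areas[cand])]
  # uniform barycentric via square-root trick
  r1 <- sqrt(stats::runif(n))
  r2 <- stats::runif(n)
  bary <- cbind(1 - r1, r1 * (1 - r2), r1 * r2)
  anchored_points(mesh, f, bary)
}

# Closest point on a single set of triangles to one query point.
# Vectorised over triangles (Ericson's region test).  Returns list with
# per-triangle closest points (n x 3), squared distances, barycentrics.
closest_point_triangles <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a
  ap <- sweep(-a, 2, -p)        # p - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(-b, 2, -p)
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- sweep(-c, 2, -p)
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)

  n <- nrow(a)
  u <- numeric(n); v <- numeric(n)  # coords along ab (v) and ac (w): point = a + v*ab + w*ac
  vv <- numeric(n); ww <- numeric(n)
  done <- logical(n)

  # vertex a region
  m <- d1 <= 0 & d2 <= 0
  done[m] <- TRUE                       # vv=ww=0
  # vertex b region
  m <- !done & d3 >= 0 & d4 <= d3
  vv[m] <- 1; done[m] <- TRUE
  # edge ab region
  vc <- d1 * d4 - d3 * d2
  m <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  denom <- d1 - d3
  vv[m] <- ifelse(denom[m] != 0, d1[m] / denom[m], 0)
  done[m] <- TRUE
  # vertex c region
  m <- !done & d6 >= 0 & d5 <= d6
  ww[m] <- 1; done[m] <- TRUE
  # edge ac region
  vb <- d5 * d2 - d1 * d6
  m <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  denom <- d2 - d6
  ww[m] <- ifelse(denom[m] != 0, d2[m] / denom[m], 0)
  done[m] <- TRUE
  # edge bc region
  va <- d3 * d6 - d5 * d4
  m <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  denom <- (d4 - d3) + (d5 - d6)
  t_ <- ifelse(denom != 0, (d4 - d3) / denom, 0)
  vv[m] <- 1 - t_[m]; ww[m] <- t_[m]
  done[m] <- TRUE
  # interior
  m <- !done
  denom <- va + vb + vc
  safe <- ifelse(denom != 0, denom, 1)
  vv[m] <- (vb / safe)[m]
  ww[m] <- (vc / safe)[m]

  pt <- a + vv * ab + ww * ac
  d2q <- rowSums(sweep(pt, 2, p)^2)
  list(point = pt, dist2 = d2q, bary = cbind(1 - vv - ww, vv, ww))
}

#' Closest point on a mesh surface
#'
#' Finds, for each query point, the nearest point on the mesh (over all
#' faces), returned as an anchored point together with the snap distance.
#' A centroid-based prefilter keeps only faces that can possibly contain
#' the nearest point; set `prefilter = FALSE` to scan every face.
#'
#' @param mesh a `surface_mesh`.
#' @param points numeric matrix (n x 3) of query positions (cm).
#' @param prefilter logical; use the centroid distance bound to restrict the
#'   candidate faces (exact, faster on large meshes).
#' @return anchored-point data frame with an extra column `snap_dist` (cm).
#' @export
closest_point_on_mesh <- function(mesh, points, prefilter = TRUE) {
  points <- matrix(as.numeric(points), ncol = 3L)
  fc <- face_corners(mesh)
  cen <- face_centroids(mesh)
  if (!is.null(mesh$geom_cache)) {
    rmax <- mesh$geom_cache$rmax
  } else {
    r2 <- pmax(rowSums((fc$a - cen)^2),
               rowSums((fc$b - cen)^2),
               rowSums((fc$c - cen)^2))
    rmax <- sqrt(max(r2))
  }
  out <- vector("list", nrow(points))
  if (prefilter) {
    # squared centroid-to-query distances for all faces x points at once
    cen2 <- rowSums(cen^2)
    d2 <- outer(cen2, rowSums(points^2), "+") - 2 * cen %*% t(points)
    dmin <- sqrt(pmax(apply(d2, 2L, min), 0))
  }
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    if (prefilter) {
      # nearest surface point is within (min centroid dist + rmax); any face
      # whose whole triangle lies farther cannot win
      keep <- which(d2[, i] <= (dmin[i] + 2 * rmax)^2 + 1e-9)
    } else {
      keep <- seq_len(nrow(mesh$faces))
    }
    cp <- closest_point_triangles(p, fc$a[keep, , drop = FALSE],
                                  fc$b[keep, , drop = FALSE],
                                  fc$c[keep, , drop = FALSE])
    j <- which.min(cp$dist2)
    out[[i]] <- c(face = keep[j], cp$bary[j, ], sqrt(cp$dist2[j]))
  }
  m <- do.call(rbind, out)
  res <- anchored_points(mesh, m[, 1L], m[, 2:4])
  res$snap_dist <- m[, 5L]
  res
}
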