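#' Read and write triangle meshes (ASCII OBJ / PLY)
#'
#' `write_mesh()` writes a [surface_mesh()] as Wavefront OBJ or ASCII PLY,
#' chosen from the file extension.  `read_mesh()` reads either format back;
#' polygonal faces with more than three vertices are fan-triangulated.
#' Landmarks, zone labels and the other leg annotations are not part of
#' either format and travel in a JSON sidecar, see [write_leg_surface()].
#'
#' @param mesh a `surface_mesh`.
#' @param path file path ending in `.obj` or `.ply`.
#' @return `read_mesh()`: a `surface_mesh`. `write_mesh()`: `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  if (ext == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else {
    stop("unsupported mesh format: .", ext, " (use .obj or .ply)", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    lines <- readLines(path)
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
      as.numeric(x[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
      idx <- as.integer(sub("/.*", "", x[-1L]))
      if (length(idx) < 3L) stop("OBJ face with fewer than 3 vertices",
                                 call. = FALSE)
      cbind(idx[1L], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
    }))
    surface_mesh(v, f)
  } else if (ext == "ply") {
    lines <- readLines(path)
    hdr_end <- match("end_header", trimws(lines))
    if (is.na(hdr_end)) stop("not an ASCII PLY file", call. = FALSE)
    hdr <- lines[seq_len(hdr_end)]
    if (!any(grepl("^format ascii", hdr))) {
      stop("only ASCII PLY is supported", call. = FALSE)
    }
    nv <- as.integer(sub("element vertex\\s+", "",
                         grep("^element vertex", hdr, value = TRUE)))
    nf <- as.integer(sub("element face\\s+", "",
                         grep("^element face", hdr, value = TRUE)))
    body <- lines[(hdr_end + 1L):length(lines)]
    v <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                               function(x) as.numeric(x[1:3])))
    f <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                               function(x) {
      idx <- as.integer(x[-1L]) + 1L
      cbind(idx[1L], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
    }))
    surface_mesh(v, f)
  } else {
    stop("unsupported mesh format: .", ext, " (use .obj or .ply)", call. = FALSE)
  }
}

#' Persist a leg surface with its annotations
#'
#' Writes the mesh to OBJ or PLY plus a JSON sidecar holding the landmark
#' vertex indices, per-face zone labels, per-vertex meridian angles and
#' regions, and the construction parameters.  `read_leg_surface()` restores
#' the full `leg_surface` from the pair.
#'
#' @param mesh a `leg_surface`.
#' @param path mesh file path (`.obj`/`.ply`); the sidecar is written next
#'   to it as `<path>.json`.
#' @return `read_leg_surface()`: a `leg_surface`; the writer returns `path`
#'   invisibly.
#' @export
write_leg_surface <- function(mesh, path) {
  write_mesh(mesh, path)
  side <- list(landmarks = as.list(mesh$landmarks),
               zone_of_face = mesh$zone_of_face,
               zone_boundaries = as.list(mesh$zone_boundaries),
               vertex_angle = mesh$vertex_angle,
               vertex_region = mesh$vertex_region,
               params = mesh$params)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_leg_surface
#' @export
read_leg_surface <- function(path) {
  mesh <- read_mesh(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mesh$landmarks <- unlist(side$landmarks)
  mesh$zone_of_face <- side$zone_of_face
  mesh$zone_boundaries <- unlist(side$zone_boundaries)
  mesh$vertex_angle <- as.numeric(side$vertex_angle)
  mesh$vertex_region <- side$vertex_region
  mesh$params <- side$params
  class(mesh) <- c("leg_surface", class(mesh))
  cache_mesh_geometry(mesh)
}

#' Read and write lesion tables
#'
#' Lesion tables are delimited text with one row per lesion and columns
#' `patient_id`, `lesion_id`, `role` (`primary`/`itm`), `side`
#' (`left`/`right`), `site` (`foot`/`lower_leg`/`thigh`), and either raw 3D
#' coordinates `x_cm`, `y_cm`, `z_cm` or surface anchoring `face`, `b0`,
#' `b1`, `b2`.  Validation failures report the offending row numbers.
#'
#' @param path CSV/TSV file path (separator inferred from extension).
#' @param lesions data.frame in the same layout, for writing.
#' @return `read_lesion_table()`: validated data.frame.
#' @export
read_lesion_table <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_lesion_table(df)
}

#' @rdname read_lesion_table
#' @export
write_lesion_table <- function(lesions, path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  utils::write.table(lesions, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

validate_lesion_table <- function(df) {
  need <- c("patient_id", "lesion_id", "role", "side", "site")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("lesion table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  has_xyz <- all(c("x_cm", "y_cm", "z_cm") %in% names(df))
  has_bary <- all(c("face", "b0", "b1", "b2") %in% names(df))
  if (!has_xyz && !has_bary) {
    stop("lesion table needs either x_cm/y_cm/z_cm or face/b0/b1/b2 columns",
         call. = FALSE)
  }
  bad <- which(!df$role %in% c("primary", "itm"))
  if (length(bad)) {
    stop("invalid role at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$side %in% c("left", "right"))
  if (length(bad)) {
    stop("invalid side at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$site %in% c("foot", "lower_leg", "thigh"))
  if (length(bad)) {
    stop("invalid site at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (has_bary) {
    s <- df$b0 + df$b1 + df$b2
    bad <- which(abs(s - 1) > 1e-9 | df$b0 < -1e-9 | df$b1 < -1e-9 |
                   df$b2 < -1e-9)
    if (length(bad)) {
      stop("invalid barycentric coordinates at row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' Read and write patient landmark tables
#'
#' One row per named landmark per patient: columns `patient_id`, `landmark`,
#' `x_cm`, `y_cm`, `z_cm`.
#'
#' @param path CSV/TSV file path.
#' @param landmarks data.frame in the same layout.
#' @return `read_landmark_table()`: validated data.frame.
#' @export
read_landmark_table <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("patient_id", "landmark", "x_cm", "y_cm", "z_cm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("landmark table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_landmark_table
#' @export
write_landmark_table <- function(landmarks, path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  utils::write.table(landmarks, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
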