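#' Lymphatic drainage zones of the distal lower extremity
#'
#' The distal lower limb drains along four anatomically defined lymphatic
#' vessel bundles, each serving a longitudinal sector of the skin surface:
#' posterolateral, posteromedial, anterolateral, and anteromedial (the
#' anteromedial sector includes the toes).  `zone_ids()` returns the four
#' sector names in their canonical enumeration order; `zone_colors()` returns
#' the conventional display colour of each sector.
#'
#' The enumeration order is also the documented tie-break order: a 2D template
#' point lying exactly on a shared polygon edge is assigned to the zone that
#' comes first in this order.
#'
#' @return `zone_ids()`: character vector of the four zone names.
#'   `zone_colors()`: named character vector mapping zone name to colour.
#' @examples
#' zone_ids()
#' zone_colors()["anteromedial"]
#' @export
zone_ids <- function() {
  c("posterolateral", "posteromedial", "anterolateral", "anteromedial")
}

#' @rdname zone_ids
#' @export
zone_colors <- function() {
  c(posterolateral = "red", posteromedial = "yellow",
    anterolateral = "green", anteromedial = "blue")
}

#' Check and normalise a zone identifier
#' @param zone character scalar or vector of zone names.
#' @return the input, validated.
#' @keywords internal
as_zone_id <- function(zone) {
  bad <- !(zone %in% zone_ids())
  if (any(bad)) {
    stop("unknown zone id(s): ", paste(unique(zone[bad]), collapse = ", "),
         call. = FALSE)
  }
  zone
}

# Sector lookup by meridian angle.  Angles are in degrees, measured in the
# cross-sectional plane of the limb, counter-clockwise when viewed from
# proximal (+z), with 0 deg = medial (+x for a left leg) and 90 deg =
# anterior (+y).  `boundaries` are the four sector start angles, in
# counter-clockwise order, for (anteromedial, anterolateral, posterolateral,
# posteromedial).  A point exactly on a boundary meridian belongs to the
# sector that starts there (the counter-clockwise side).
zone_of_angle <- function(theta_deg, boundaries = default_zone_boundaries()) {
  check_zone_boundaries(boundaries)
  theta <- theta_deg %% 360
  zones <- names(boundaries)
  # rotate so boundaries are increasing starting from the first
  b0 <- boundaries[1L]
  rel <- (boundaries - b0) %% 360
  th <- (theta - b0) %% 360
  idx <- findInterval(th, sort(rel))
  ord <- order(rel)
  zones[ord][idx]
}

#' Default drainage-sector boundary meridians
#'
#' Sector boundaries are meridian curves at fixed angular positions around
#' the limb axis.  The default places the four boundaries on the pure
#' medial (0), anterior (90), lateral (180) and posterior (270) directions,
#' which makes each sector a 90-degree wedge centred on one of the four
#' oblique anatomical directions (anteromedial, anterolateral,
#' posterolateral, posteromedial).
#'
#' @return named numeric vector of four sector start angles in degrees,
#'   named by the sector that begins (counter-clockwise) at each boundary.
#' @export
default_zone_boundaries <- function() {
  c(anteromedial = 0, anterolateral = 90,
    posterolateral = 180, posteromedial = 270)
}

check_zone_boundaries <- function(boundaries) {
  if (length(boundaries) != 4L || is.null(names(boundaries)) ||
      !setequal(names(boundaries), zone_ids())) {
    stop("boundaries must be a named numeric vector with one start angle ",
         "per zone (", paste(zone_ids(), collapse = ", "), ")", call. = FALSE)
  }
  b <- boundaries %% 360
  if (anyDuplicated(b)) {
    stop("zone boundary meridians must be four distinct angles in [0, 360)",
         call. = FALSE)
  }
  # boundaries must run counter-clockwise in the listed zone order
  rel <- (b - b[1L]) %% 360
  if (is.unsorted(rel, strictly = TRUE)) {
    stop("zone boundaries must be in counter-clockwise order ",
         "(anteromedial, anterolateral, posterolateral, posteromedial)",
         call. = FALSE)
  }
  invisible(b)
}
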