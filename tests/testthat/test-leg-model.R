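test_that("reference leg is a connected, landmarked, fully zoned surface", {
  leg <- test_leg()
  expect_s3_class(leg, "leg_surface")
  expect_true(itmap:::mesh_is_connected(leg))
  expect_true(all(c("patella", "medial_malleolus", "lateral_malleolus",
                    "toe_tip_1", "toe_tip_5") %in% names(leg$landmarks)))
  expect_length(leg$zone_of_face, nrow(leg$faces))
  expect_setequal(unique(leg$zone_of_face), zone_ids())
  # canonical frame: patella anterior (+y), medial malleolus at +x
  lm <- reference_landmarks(leg)
  expect_gt(lm["patella", "y"], 0)
  expect_gt(lm["medial_malleolus", "x"], 0)
  expect_lt(lm["lateral_malleolus", "x"], 0)
  expect_gt(lm["patella", "z"], lm["medial_malleolus", "z"])
})

test_that("landmark positions are analytic: invariant to mesh resolution", {
  leg <- test_leg()
  fine <- build_reference_leg(n_circ = 32, n_axial = 2)
  lm1 <- reference_landmarks(leg)
  lm2 <- reference_landmarks(fine)
  expect_lt(max(abs(lm1 - lm2[rownames(lm1), ])), 1e-6)
})

test_that("mesh construction is deterministic", {
  a <- build_reference_leg(n_circ = 16, n_axial = 1)
  b <- build_reference_leg(n_circ = 16, n_axial = 1)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  expect_identical(a$zone_of_face, b$zone_of_face)
})

test_that("invalid geometry parameters are rejected", {
  expect_error(build_reference_leg(foot_length = -1), "positive")
  expect_error(build_reference_leg(n_circ = 7), "multiple of 4")
  expect_error(build_reference_leg(n_circ = 4), ">= 8")
})

test_that("zones partition the surface area exactly", {
  leg <- test_leg()
  areas <- face_areas(leg)
  by_zone <- tapply(areas, leg$zone_of_face, sum)
  expect_equal(sum(by_zone), sum(areas), tolerance = 1e-9)
  expect_length(by_zone, 4L)
  # every face carries exactly one zone
  expect_false(anyNA(leg$zone_of_face))
})

test_that("toe landmarks and the whole toe region drain anteromedially", {
  leg <- test_leg()
  for (nm in c("toe_tip_1", "toe_tip_5")) {
    v <- leg$landmarks[[nm]]
    touching <- which(leg$faces[, 1] == v | leg$faces[, 2] == v |
                        leg$faces[, 3] == v)
    expect_true(all(leg$zone_of_face[touching] == "anteromedial"),
                label = paste("faces at", nm))
  }
  # the toe rule holds for any boundary specification
  rotated <- segment_zones(test_leg(),
                           default_zone_boundaries() + 30)
  toe_faces <- itmap:::face_regions(rotated) == "toe"
  expect_true(all(rotated$zone_of_face[toe_faces] == "anteromedial"))
})

test_that("meridian sector assignment follows the angular rule with a
           counter-clockwise tie-break", {
  # oracle: direct angle comparison
  expect_equal(itmap:::zone_of_angle(c(45, 135, 225, 315)),
               c("anteromedial", "anterolateral", "posterolateral",
                 "posteromedial"))
  # exactly on a boundary meridian -> the zone starting there (CCW side)
  expect_equal(itmap:::zone_of_angle(c(0, 90, 180, 270)),
               c("anteromedial", "anterolateral", "posterolateral",
                 "posteromedial"))
  # custom boundaries shift the sectors coherently
  b <- default_zone_boundaries() + 10
  expect_equal(itmap:::zone_of_angle(10, b), "anteromedial")
  expect_equal(itmap:::zone_of_angle(9.99, b), "posteromedial")
})

test_that("segment_zones rejects degenerate boundary specifications", {
  leg <- test_leg()
  bad <- c(anteromedial = 0, anterolateral = 0, posterolateral = 180,
           posteromedial = 270)
  expect_error(segment_zones(leg, bad), "distinct")
  expect_error(segment_zones(leg, c(a = 0, b = 90, c = 180, d = 270)),
               "named")
})

test_that("projected views preserve axial distances and hide back faces", {
  leg <- test_leg()
  tmpl <- project_views(leg)
  expect_s3_class(tmpl, "zone_template")
  expect_setequal(names(tmpl$views), c("lateral", "medial", "anterior",
                                       "dorsal"))
  # orthographic projection preserves z
  lm <- reference_landmarks(leg)
  for (vw in names(tmpl$views)) {
    l2 <- tmpl$views[[vw]]$landmarks_2d
    d3 <- abs(lm["patella", "z"] - lm["medial_malleolus", "z"])
    d2 <- abs(l2$v[l2$name == "patella"] -
                l2$v[l2$name == "medial_malleolus"])
    expect_equal(d2, d3, tolerance = 1e-6)
  }
  # anterior view: no posterior-sector faces visible (face-normal oracle)
  ant <- tmpl$views$anterior$triangles
  nrm <- face_normals(leg)
  expect_true(all(nrm[ant$face, 2] > 0))
  reg <- itmap:::face_regions(leg)[ant$face]
  leg_faces <- ant$zone[reg == "leg"]
  expect_false(any(leg_faces == "posterolateral"))
  # front-facing projected triangles of the anterior view tile the
  # silhouette without overlap: summed 2D area equals union area
  tri_area <- abs((ant$u2 - ant$u1) * (ant$v3 - ant$v1) -
                    (ant$u3 - ant$u1) * (ant$v2 - ant$v1)) / 2
  expect_true(all(tri_area >= 0))
})

test_that("views require zones to be assigned first", {
  bare <- build_reference_leg(n_circ = 16, n_axial = 1, boundaries = NULL)
  expect_null(bare$zone_of_face)
  expect_error(project_views(bare), "zones")
})
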