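test_that("3D zone assignment equals the face-label lookup and the
           angular-sector oracle", {
  leg <- test_leg()
  set.seed(21)
  pts <- sample_surface_points(leg, 500)
  zones <- assign_zone_3d(leg, pts)
  expect_false(anyNA(zones))            # total function on the surface
  # brute-force oracle: classify the containing face by the angle of its
  # centroid around the limb axis (geometric atan2 on the straight leg,
  # the swept meridian definition on the bent foot), with the toe and
  # plantar overrides, independently of the stored per-face labels
  ang_v <- leg$vertex_angle
  reg_f <- itmap:::face_regions(leg)
  cen <- face_centroids(leg)
  ok <- 0; n_checked <- 0
  for (i in seq_len(nrow(pts))) {
    f <- pts$face[i]
    if (reg_f[f] == "leg") {
      ang <- (atan2(cen[f, 2], cen[f, 1]) * 180 / pi) %% 360
    } else {
      th <- ang_v[leg$faces[f, ]] * pi / 180
      th <- th[!is.na(th)]
      ang <- (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi) %% 360
    }
    # off-boundary only: skip faces near a sector meridian
    if (min(abs((ang - c(0, 90, 180, 270) + 180) %% 360 - 180)) < 3) next
    expected <- if (reg_f[f] == "toe") "anteromedial"
    else if (reg_f[f] == "foot" && ang > 180 && ang < 360) "anteromedial"
    else itmap:::zone_of_angle(ang)
    n_checked <- n_checked + 1
    ok <- ok + (zones[i] == expected)
  }
  expect_gt(n_checked, 300)
  expect_equal(ok, n_checked)
})

test_that("unanchored lesions and unzoned meshes are state errors", {
  leg <- test_leg()
  expect_error(assign_zone_3d(leg, data.frame(face = NA)), "not anchored")
  bare <- build_reference_leg(n_circ = 16, n_axial = 1, boundaries = NULL)
  expect_error(assign_zone_3d(bare, data.frame(face = 1L)), "no zones")
})

test_that("2D template assignment matches an independent point-in-polygon
           oracle", {
  skip_if_not_installed("mgcv")
  leg <- test_leg()
  tmpl <- project_views(leg)
  tri <- tmpl$views$anterior$triangles
  set.seed(22)
  n_hit <- 0
  for (rep in 1:300) {
    i <- sample(nrow(tri), 1)
    w <- stats::runif(3); w <- w / sum(w)
    u <- w[1] * tri$u1[i] + w[2] * tri$u2[i] + w[3] * tri$u3[i]
    v <- w[1] * tri$v1[i] + w[2] * tri$v2[i] + w[3] * tri$v3[i]
    z2d <- assign_zone_2d(c(u, v), "anterior", tmpl)
    # oracle: mgcv ray-crossing test against every triangle, tie-broken by
    # enumeration order
    inside <- vapply(seq_len(nrow(tri)), function(j) {
      mgcv::in.out(rbind(cbind(c(tri$u1[j], tri$u2[j], tri$u3[j]),
                               c(tri$v1[j], tri$v2[j], tri$v3[j])),
                         c(tri$u1[j], tri$v1[j])), c(u, v))
    }, TRUE)
    if (!any(inside)) next  # oracle calls boundary points outside
    expected <- zone_ids()[min(match(tri$zone[inside], zone_ids()))]
    n_hit <- n_hit + 1
    expect_identical(z2d, expected)
  }
  expect_gt(n_hit, 250)
})

test_that("2D assignment resolves shared edges by enumeration order and
           rejects outside points", {
  leg <- test_leg()
  tmpl <- project_views(leg)
  tri <- tmpl$views$anterior$triangles
  # a point on the shared edge of two triangles of different zones
  pair <- NULL
  for (i in seq_len(nrow(tri) - 1)) {
    for (j in seq(i + 1, nrow(tri))) {
      shared <- intersect(
        c(paste(tri$u1[i], tri$v1[i]), paste(tri$u2[i], tri$v2[i]),
          paste(tri$u3[i], tri$v3[i])),
        c(paste(tri$u1[j], tri$v1[j]), paste(tri$u2[j], tri$v2[j]),
          paste(tri$u3[j], tri$v3[j])))
      if (length(shared) == 2 && tri$zone[i] != tri$zone[j]) {
        pair <- c(i, j); break
      }
    }
    if (!is.null(pair)) break
  }
  expect_false(is.null(pair))
  xy <- do.call(rbind, lapply(strsplit(shared, " "), as.numeric))
  mid <- colMeans(xy)
  z <- assign_zone_2d(mid, "anterior", tmpl)
  lower <- zone_ids()[min(match(tri$zone[pair], zone_ids()))]
  expect_identical(z, lower)
  expect_error(assign_zone_2d(c(1e3, 1e3), "anterior", tmpl), "outside")
  expect_error(assign_zone_2d(c(0, 0), "sagittal", tmpl), "unknown view")
})

test_that("map_patient recovers generated zones through mirroring and a
           random rigid motion", {
  leg <- test_leg()
  cfg <- simulation_config(seed = 31)
  for (side in c("left", "right")) {
    pat <- data.frame(patient_id = "T001", site = "lower_leg", side = side,
                      has_itm = TRUE, n_itm = 6)
    les <- simulate_lesions(cfg, pat, leg, patient_index = 1L)
    obs <- simulate_patient_observation(cfg, les, leg, patient_index = 1L)
    mp <- map_patient(obs$lesions, obs$landmarks, leg)
    expect_true(mp$evaluable)
    expect_identical(mp$mirrored, side == "right")
    expect_lt(mp$transform$rms, 1e-9)
    # registration undoes the motion exactly: zones equal generation
    ref_zones <- assign_zone_3d(leg, les)
    expect_identical(mp$lesions$zone, ref_zones)
    expect_lt(max(mp$lesions$snap_dist), 1e-6)
  }
})

test_that("3D and 2D zone assignment agree for front-facing lesions", {
  leg <- test_leg()
  tmpl <- project_views(leg)
  cfg <- simulation_config(seed = 33)
  pat <- data.frame(patient_id = "T002", site = "lower_leg", side = "left",
                    has_itm = TRUE, n_itm = 10)
  les <- simulate_lesions(cfg, pat, leg, patient_index = 2L)
  obs <- simulate_patient_observation(cfg, les, leg, patient_index = 2L)
  mp <- map_patient(obs$lesions, obs$landmarks, leg)
  for (i in seq_len(nrow(mp$lesions))) {
    row <- mp$lesions[i, ]
    z2 <- assign_zone_2d(c(row$u_cm, row$v_cm), row$view, tmpl)
    expect_identical(z2, row$zone)
  }
})

test_that("patients without exactly one primary are unevaluable", {
  leg <- test_leg()
  p <- anchored_points(leg, c(5L, 6L), rbind(c(1, 0, 0), c(0, 1, 0)))
  les <- data.frame(patient_id = "P", lesion_id = c("a", "b"),
                    role = c("itm", "itm"), side = "left", site = "foot",
                    x_cm = p$x, y_cm = p$y, z_cm = p$z)
  lm <- reference_landmarks(leg)
  mp <- map_patient(les, lm, leg)
  expect_false(mp$evaluable)
  expect_match(mp$reason, "0 primary")
  les$role <- c("primary", "primary")
  mp <- map_patient(les, lm, leg)
  expect_false(mp$evaluable)
  expect_match(mp$reason, "2 primary")
  expect_error(score_patient(mp), "not evaluable")
})
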