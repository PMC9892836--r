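test_that("simulation configs are validated", {
  expect_error(simulation_config(site_mix = c(foot = 0.5, lower_leg = 0.6,
                                              thigh = 0.2)), "sum to 1")
  expect_error(simulation_config(phi_leg = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(jitter_sd = -1), ">= 0")
  expect_s3_class(simulation_config(), "simulation_config")
})

test_that("cohorts are reproducible and patient streams are stable under
           cohort-size changes", {
  cfg <- simulation_config(seed = 71, n_patients = 60)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  bigger <- simulate_cohort(simulation_config(seed = 71, n_patients = 80))
  expect_identical(a, bigger[seq_len(60), ])
  empty <- simulate_cohort(simulation_config(seed = 71, n_patients = 0))
  expect_equal(nrow(empty), 0)
})

test_that("beta = 0 cohorts have the intercept-implied ITM prevalence", {
  beta0 <- c(intercept = -1.2, age_ge55 = 0, subtype_NM = 0,
             subtype_ALM = 0, subtype_NOS = 0, thickness_ge1 = 0,
             ulceration_present = 0, site_lower_leg = 0, site_thigh = 0)
  cfg <- simulation_config(seed = 72, n_patients = 5000, beta = beta0)
  coh <- simulate_cohort(cfg)
  p_hat <- mean(coh$has_itm)
  p_true <- stats::plogis(-1.2)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 5000))
})

test_that("cohort structure matches the configured marginals", {
  cfg <- simulation_config(seed = 73, n_patients = 2000)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$age >= 16 & coh$age <= 97))
  expect_true(all(coh$thickness > 0, na.rm = TRUE))
  # MUP only among ITM patients, with masked covariates
  mup <- coh[coh$subtype == "MUP", ]
  expect_true(all(mup$has_itm))
  expect_true(all(is.na(mup$thickness)) && all(is.na(mup$ulceration)))
  # ITM count categories close to the configured distribution
  itm <- coh[coh$has_itm, ]
  cuts <- cut(itm$n_itm, c(0, 5, 10, 20, 30))
  gof <- chi_square_test(cbind(as.vector(table(cuts)),
                               round(cfg$itm_count_probs * nrow(itm))))
  expect_gt(gof$p, 0.001)
})

test_that("lesion sets anchor on the surface with valid barycentrics", {
  leg <- test_leg()
  cfg <- simulation_config(seed = 74)
  pat <- data.frame(patient_id = "S001", site = "lower_leg", side = "left",
                    has_itm = TRUE, n_itm = 12)
  les <- simulate_lesions(cfg, pat, leg, patient_index = 1L)
  expect_equal(nrow(les), 13)
  expect_true(all(les$face >= 1 & les$face <= nrow(leg$faces)))
  bsum <- les$b1 + les$b2 + les$b3
  expect_true(all(abs(bsum - 1) < 1e-9))
  expect_true(all(les$b1 > -1e-9 & les$b2 > -1e-9 & les$b3 > -1e-9))
  # anchored coordinates agree with barycentric interpolation
  xyz <- itmap:::barycentric_to_xyz(leg, les$face,
                                    cbind(les$b1, les$b2, les$b3))
  expect_equal(unname(cbind(les$x_cm, les$y_cm, les$z_cm)), unname(xyz),
               tolerance = 1e-9)
  # determinism
  les2 <- simulate_lesions(cfg, pat, leg, patient_index = 1L)
  expect_identical(les, les2)
})

test_that("unsupported sites and ITM-free patients are rejected", {
  leg <- test_leg()
  cfg <- simulation_config(seed = 75)
  thigh <- data.frame(patient_id = "S", site = "thigh", side = "left",
                      has_itm = TRUE, n_itm = 3)
  expect_error(simulate_lesions(cfg, thigh, leg), "thigh")
  noitm <- data.frame(patient_id = "S", site = "foot", side = "left",
                      has_itm = FALSE, n_itm = NA)
  expect_error(simulate_lesions(cfg, noitm, leg), "no in-transit")
})

test_that("zone fidelity one places every ITM in the primary's sector", {
  leg <- test_leg()
  cfg <- simulation_config(seed = 76, phi_leg = 1, phi_foot = 1,
                           jitter_sd = 0)
  for (i in 1:6) {
    site <- if (i %% 2) "lower_leg" else "foot"
    pat <- data.frame(patient_id = sprintf("S%03d", i), site = site,
                      side = "left", has_itm = TRUE, n_itm = 8)
    les <- simulate_lesions(cfg, pat, leg, patient_index = i)
    z <- assign_zone_3d(leg, les)
    expect_true(all(z == z[les$role == "primary"]))
    sc <- score_concordance(z[les$role == "primary"],
                            z[les$role == "itm"])
    expect_identical(sc$category, "full")
  }
})

test_that("zone fidelity zero avoids the primary's sector (before jitter)", {
  leg <- test_leg()
  cfg <- simulation_config(seed = 77, phi_leg = 0, phi_foot = 0,
                           jitter_sd = 0)
  n_in <- 0; n_tot <- 0
  for (i in 1:8) {
    pat <- data.frame(patient_id = sprintf("S%03d", i), site = "lower_leg",
                      side = "left", has_itm = TRUE, n_itm = 10)
    les <- simulate_lesions(cfg, pat, leg, patient_index = i)
    z <- assign_zone_3d(leg, les)
    n_in <- n_in + sum(z[les$role == "itm"] == z[les$role == "primary"])
    n_tot <- n_tot + sum(les$role == "itm")
  }
  expect_equal(n_in, 0)
  expect_equal(n_tot, 80)
})

test_that("proximal bias places ITM above the primary", {
  leg <- test_leg()
  cfg <- simulation_config(seed = 78, proximal_bias = 1)
  for (i in 1:5) {
    pat <- data.frame(patient_id = sprintf("S%03d", i), site = "foot",
                      side = "left", has_itm = TRUE, n_itm = 8)
    les <- simulate_lesions(cfg, pat, leg, patient_index = i)
    zp <- les$z_cm[les$role == "primary"]
    # jitter can move a lesion slightly; allow its scale
    expect_true(all(les$z_cm[les$role == "itm"] >
                      zp - 4 * cfg$jitter_sd))
  }
})

test_that("simulated observations exercise mirroring and are undone by
           registration", {
  leg <- test_leg()
  cfg <- simulation_config(seed = 79)
  pat <- data.frame(patient_id = "S001", site = "lower_leg", side = "right",
                    has_itm = TRUE, n_itm = 5)
  les <- simulate_lesions(cfg, pat, leg, patient_index = 1L)
  obs <- simulate_patient_observation(cfg, les, leg, patient_index = 1L)
  # observation is genuinely moved
  expect_gt(max(abs(obs$lesions$x_cm - les$x_cm)), 0.1)
  mp <- map_patient(obs$lesions, obs$landmarks, leg)
  expect_true(mp$evaluable)
  expect_true(mp$mirrored)
  expect_equal(mp$lesions$x, les$x_cm, tolerance = 1e-6)
})

test_that("generated primary-ITM distances fall in the published range
           envelope", {
  leg <- test_leg()
  cfg <- simulation_config(seed = 80)
  gg <- geodesic_graph(leg, refinement = 1)
  dists <- c()
  for (i in 1:6) {
    site <- if (i %% 2) "lower_leg" else "foot"
    pat <- data.frame(patient_id = sprintf("S%03d", i), site = site,
                      side = "left", has_itm = TRUE, n_itm = 4)
    les <- simulate_lesions(cfg, pat, leg, patient_index = i)
    les$mappable <- TRUE
    dd <- lesion_distances(gg, les)
    dists <- c(dists, dd$distance_cm)
  }
  # realism anchor: the published per-lesion ranges span roughly 2-71 cm;
  # the canonical surface allows up to ~ toe-to-groin (~110 cm), and the
  # bulk of generated distances must sit in the published scale
  expect_true(all(dists >= 0 & dists <= 110))
  expect_gt(max(dists), 5)
  expect_true(stats::median(dists) > 5 && stats::median(dists) < 60)
})
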