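#' Simulation configuration for synthetic cohorts and lesion patterns
#'
#' Bundles every tunable of the synthetic-data generator.  Defaults emulate
#' the covariate structure of a retrospective lower-extremity melanoma
#' cohort (382 patients, about a quarter of whom develop in-transit
#' metastases) and the spatial ITM patterns seen on the mapped
#' photographic subset (31 lower-leg and 15 foot patients).
#'
#' The single biological knob for spatial patterns is the zone fidelity
#' phi: the probability that an individual ITM arises within the drainage
#' sector of the primary melanoma (otherwise it falls uniformly over the
#' other three sectors).  The defaults `phi_leg = 0.968` and
#' `phi_foot = 0.735` are calibrated on the full generative pipeline
#' (per-patient ITM count distribution, uniform in-sector placement,
#' localization jitter, default reference mesh) so that the expected
#' full-match rate (>= 90% of a patient's ITM in the primary's sector) is
#' 71% on the lower leg and 20% on the foot.
#'
#' @param seed integer master seed; every patient derives an independent
#'   substream from `(seed, patient index)`, so regenerating a single
#'   patient is stable under cohort-size changes.
#' @param n_patients cohort size.
#' @param site_mix probabilities of primary site (foot, lower_leg, thigh).
#' @param gender_female probability of female gender.
#' @param age_mean,age_sd,age_range normal age model (years), truncated.
#' @param subtype_probs marginal probabilities of SSM/NM/ALM/NOS.
#' @param mup_rate fraction of ITM patients relabeled melanoma of unknown
#'   primary (covariates of the unknown primary set missing).
#' @param thickness_meanlog,thickness_sdlog log-normal Breslow thickness
#'   (mm).
#' @param ulceration_intercept,ulceration_slope logistic model of
#'   ulceration probability on log-thickness.
#' @param missing_thickness,missing_ulceration covariate missingness rates.
#' @param beta named logistic coefficients for ITM risk on the coded
#'   covariates (intercept, age_ge55, subtype_NM/ALM/NOS, thickness_ge1,
#'   ulceration_present, site_lower_leg, site_thigh), log odds-ratio scale.
#' @param itm_count_probs probabilities of the ITM count categories 1-5,
#'   6-10, 11-20, >20.
#' @param phi_leg,phi_foot zone fidelity by primary site.
#' @param proximal_bias probability that a patient's ITM are restricted to
#'   proximal of the primary (larger z).
#' @param jitter_sd localization jitter along the surface (cm), emulating
#'   lesions localized in the middle of an excision scar.
#' @param n_leg_mapped,n_foot_mapped size of the mapped (photographed)
#'   subset used by [end_to_end_recovery()].
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_patients = 382L,
                              site_mix = c(foot = 75, lower_leg = 159,
                                           thigh = 145) / 379,
                              gender_female = 263 / 382,
                              age_mean = 56, age_sd = 16,
                              age_range = c(16, 97),
                              subtype_probs = c(SSM = 226, NM = 62,
                                                ALM = 43, NOS = 35) / 366,
                              mup_rate = 0.032,
                              thickness_meanlog = log(1.1),
                              thickness_sdlog = 1.0,
                              ulceration_intercept = -2.3,
                              ulceration_slope = 1.2,
                              missing_thickness = 0.02,
                              missing_ulceration = 0.03,
                              beta = c(intercept = -2.75,
                                       age_ge55 = 0.41,
                                       subtype_NM = 0.96,
                                       subtype_ALM = 0.99,
                                       subtype_NOS = 0.53,
                                       thickness_ge1 = 1.74,
                                       ulceration_present = 0.74,
                                       site_lower_leg = 0.59,
                                       site_thigh = -0.51),
                              itm_count_probs = c(34, 18, 14, 15) / 81,
                              phi_leg = 0.968,
                              phi_foot = 0.735,
                              proximal_bias = 0.80,
                              jitter_sd = 0.5,
                              n_leg_mapped = 31L,
                              n_foot_mapped = 15L) {
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              site_mix = site_mix, gender_female = gender_female,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              subtype_probs = subtype_probs, mup_rate = mup_rate,
              thickness_meanlog = thickness_meanlog,
              thickness_sdlog = thickness_sdlog,
              ulceration_intercept = ulceration_intercept,
              ulceration_slope = ulceration_slope,
              missing_thickness = missing_thickness,
              missing_ulceration = missing_ulceration,
              beta = beta, itm_count_probs = itm_count_probs,
              phi_leg = phi_leg, phi_foot = phi_foot,
              proximal_bias = proximal_bias, jitter_sd = jitter_sd,
              n_leg_mapped = as.integer(n_leg_mapped),
              n_foot_mapped = as.integer(n_foot_mapped))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (abs(sum(cfg$site_mix) - 1) > 1e-6 ||
      abs(sum(cfg$subtype_probs) - 1) > 1e-6 ||
      abs(sum(cfg$itm_count_probs) - 1) > 1e-6) {
    stop("site_mix, subtype_probs and itm_count_probs must each sum to 1",
         call. = FALSE)
  }
  probs <- c(cfg$gender_female, cfg$mup_rate, cfg$phi_leg, cfg$phi_foot,
             cfg$proximal_bias, cfg$missing_thickness, cfg$missing_ulceration)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_patients < 0L) stop("n_patients must be >= 0", call. = FALSE)
  if (cfg$jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  invisible(cfg)
}

# deterministic per-patient substream seed (kept below 2^31)
stream_seed <- function(seed, index, salt = 0L) {
  as.integer((as.double(seed) * 69821 + as.double(index) * 7919 +
                as.double(salt) * 104729) %% 2147483629) + 1L
}

itm_count_ranges <- function() list(1:5, 6:10, 11:20, 21:30)

# coded design row -> linear predictor under cfg$beta
risk_linpred <- function(cfg, age, subtype, thickness, ulceration, site) {
  b <- cfg$beta
  b[["intercept"]] +
    b[["age_ge55"]] * (age >= 55) +
    b[["subtype_NM"]] * (subtype == "NM") +
    b[["subtype_ALM"]] * (subtype == "ALM") +
    b[["subtype_NOS"]] * (subtype == "NOS") +
    b[["thickness_ge1"]] * (thickness >= 1.0) +
    b[["ulceration_present"]] * (ulceration == "present") +
    b[["site_lower_leg"]] * (site == "lower_leg") +
    b[["site_thigh"]] * (site == "thigh")
}

#' Simulate a clinical cohort
#'
#' Draws per-patient covariates from the configured marginals and the ITM
#' outcome from the logistic risk model with coefficients `beta`.  ITM
#' patients additionally receive an ITM count (drawn from the count
#' category distribution), a time to first ITM, and a body side; a small
#' fraction are relabeled melanoma of unknown primary (MUP) with the
#' covariates of the unknown primary set to missing.  Output is
#' byte-identical for a fixed seed.
#'
#' @param config a [simulation_config()].
#' @return data.frame with one row per patient: `patient_id`, `gender`,
#'   `age`, `subtype`, `thickness`, `ulceration`, `site`, `side`,
#'   `has_itm`, `n_itm`, `months_to_itm`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_patients
  rows <- vector("list", n)
  ranges <- itm_count_ranges()
  for (i in seq_len(n)) {
    set.seed(stream_seed(config$seed, i, salt = 1L))
    gender <- if (stats::runif(1) < config$gender_female) "female" else "male"
    age <- 0
    repeat {
      age <- stats::rnorm(1, config$age_mean, config$age_sd)
      if (age >= config$age_range[1L] && age <= config$age_range[2L]) break
    }
    age <- round(age)
    subtype <- sample(names(config$subtype_probs), 1L,
                      prob = config$subtype_probs)
    thickness <- round(pmin(pmax(stats::rlnorm(1, config$thickness_meanlog,
                                               config$thickness_sdlog),
                                 0.1), 35), 1)
    p_ulc <- stats::plogis(config$ulceration_intercept +
                             config$ulceration_slope * log(thickness))
    ulceration <- if (stats::runif(1) < p_ulc) "present" else "absent"
    site <- sample(names(config$site_mix), 1L, prob = config$site_mix)
    lp <- risk_linpred(config, age, subtype, thickness, ulceration, site)
    has_itm <- stats::runif(1) < stats::plogis(lp)
    side <- if (stats::runif(1) < 0.5) "left" else "right"
    n_itm <- NA_integer_
    months <- NA_real_
    if (has_itm) {
      cat_i <- sample.int(4L, 1L, prob = config$itm_count_probs)
      n_itm <- sample(ranges[[cat_i]], 1L)
      months <- round(pmin(stats::rlnorm(1, log(19), 1.1), 244))
      if (stats::runif(1) < config$mup_rate) {
        subtype <- "MUP"
        thickness <- NA_real_
        ulceration <- NA_character_
      }
    }
    if (subtype != "MUP" || is.na(subtype)) {
      if (stats::runif(1) < config$missing_thickness) thickness <- NA_real_
      if (stats::runif(1) < config$missing_ulceration) {
        ulceration <- NA_character_
      }
    }
    rows[[i]] <- data.frame(
      patient_id = sprintf("P%04d", i), gender = gender, age = age,
      subtype = subtype, thickness = thickness, ulceration = ulceration,
      site = site, side = side, has_itm = has_itm, n_itm = n_itm,
      months_to_itm = months, stringsAsFactors = FALSE)
  }
  if (n == 0L) {
    return(data.frame(patient_id = character(), gender = character(),
                      age = numeric(), subtype = character(),
                      thickness = numeric(), ulceration = character(),
                      site = character(), side = character(),
                      has_itm = logical(), n_itm = integer(),
                      months_to_itm = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Simulate on-surface lesions for one ITM patient
#'
#' Places the primary melanoma uniformly within the patient's site region
#' of the reference surface, then places each in-transit metastasis in the
#' primary's drainage sector with probability phi (site-specific) and
#' uniformly over the other three sectors otherwise.  With probability
#' `proximal_bias` the patient's ITM are restricted to proximal of the
#' primary (larger z, toward the inguinal basin).  Every lesion position
#' is then jittered tangentially by an isotropic Gaussian of sd
#' `jitter_sd` and re-snapped to the surface, emulating localization from
#' the middle of an excision scar.  All lesions are returned anchored on
#' the mesh.
#'
#' @param config a [simulation_config()].
#' @param patient one row of [simulate_cohort()] with `has_itm = TRUE` and
#'   site foot or lower_leg.
#' @param reference the reference `leg_surface`.
#' @param patient_index integer used (with the master seed) to derive the
#'   patient's private random substream; defaults to the numeric part of
#'   `patient_id`.
#' @return lesion data.frame (one primary + `n_itm` ITM rows): columns
#'   `patient_id`, `lesion_id`, `role`, `side`, `site`, `face`, `b1`,
#'   `b2`, `b3`, `x_cm`, `y_cm`, `z_cm`, and `gen_zone` (the sector the
#'   lesion was generated in, before jitter).
#' @export
simulate_lesions <- function(config, patient, reference,
                             patient_index = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!isTRUE(patient$has_itm)) {
    stop("patient has no in-transit metastases to simulate", call. = FALSE)
  }
  if (patient$site == "thigh") {
    stop("unsupported site 'thigh': drainage sectors are defined only for ",
         "the distal lower extremity", call. = FALSE)
  }
  if (is.null(patient_index)) {
    patient_index <- as.integer(sub("\\D+", "", patient$patient_id))
  }
  set.seed(stream_seed(config$seed, patient_index, salt = 2L))
  zones <- reference$zone_of_face
  areas <- face_areas(reference)
  cz <- face_centroids(reference)[, 3L]
  phi <- if (patient$site == "foot") config$phi_foot else config$phi_leg
  sfaces <- site_faces(reference, patient$site)

  draw_on <- function(faces, n) {
    fi <- faces[sample.int(length(faces), n, replace = TRUE,
                           prob = areas[faces])]
    r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
    list(face = fi, bary = cbind(1 - r1, r1 * (1 - r2), r1 * r2))
  }
  jitter_points <- function(face, bary) {
    p <- barycentric_to_xyz(reference, face, bary)
    if (config$jitter_sd > 0) {
      nrm <- face_normals(reference)[face, , drop = FALSE]
      t1 <- cbind(nrm[, 2L], -nrm[, 1L], 0)
      bad <- rowSums(t1^2) < 1e-12
      t1[bad, ] <- rep(c(1, 0, 0), each = sum(bad))
      t1 <- t1 / sqrt(rowSums(t1^2))
      t2 <- cbind(nrm[, 2L] * t1[, 3L] - nrm[, 3L] * t1[, 2L],
                  nrm[, 3L] * t1[, 1L] - nrm[, 1L] * t1[, 3L],
                  nrm[, 1L] * t1[, 2L] - nrm[, 2L] * t1[, 1L])
      n <- nrow(p)
      p <- p + stats::rnorm(n, 0, config$jitter_sd) * t1 +
        stats::rnorm(n, 0, config$jitter_sd) * t2
    }
    closest_point_on_mesh(reference, p)
  }
  prim <- draw_on(sfaces, 1L)
  prim_zone <- zones[prim$face]
  prim_snap <- jitter_points(prim$face, prim$bary)
  only_proximal <- stats::runif(1) < config$proximal_bias
  z_prim <- prim_snap$z

  in_faces <- which(zones == prim_zone)
  out_faces <- which(zones != prim_zone)
  if (only_proximal) {
    in_prox <- in_faces[cz[in_faces] > z_prim]
    out_prox <- out_faces[cz[out_faces] > z_prim]
    if (length(in_prox)) in_faces <- in_prox
    if (length(out_prox)) out_faces <- out_prox
  }
  n_itm <- patient$n_itm
  in_zone <- stats::runif(n_itm) < phi
  faces <- integer(n_itm)
  bary <- matrix(0, n_itm, 3L)
  if (any(in_zone)) {
    d <- draw_on(in_faces, sum(in_zone))
    faces[in_zone] <- d$face; bary[in_zone, ] <- d$bary
  }
  if (any(!in_zone)) {
    d <- draw_on(out_faces, sum(!in_zone))
    faces[!in_zone] <- d$face; bary[!in_zone, ] <- d$bary
  }
  itm_snap <- jitter_points(faces, bary)
  snap <- rbind(prim_snap, itm_snap)
  data.frame(
    patient_id = patient$patient_id,
    lesion_id = c(paste0(patient$patient_id, "_primary"),
                  sprintf("%s_itm%02d", patient$patient_id,
                          seq_len(n_itm))),
    role = rep(c("primary", "itm"), c(1L, n_itm)),
    side = patient$side, site = patient$site,
    face = snap$face, b1 = snap$b1, b2 = snap$b2, b3 = snap$b3,
    x_cm = snap$x, y_cm = snap$y, z_cm = snap$z,
    gen_zone = c(prim_zone, zones[faces]),
    stringsAsFactors = FALSE)
}

#' Simulate the observed coordinates of one mapped patient
#'
#' Emulates a patient's photographic coordinate frame: the reference-frame
#' lesions and landmarks are moved by a random rigid motion and, for
#' right-sided patients, mirrored (x negated).  Running the pipeline's
#' [map_patient()] on this observation must undo both and recover the
#' generated zones exactly in the noise-free case.
#'
#' @param config a [simulation_config()].
#' @param lesions output of [simulate_lesions()].
#' @param reference the reference `leg_surface`.
#' @param patient_index patient substream index (see [simulate_lesions()]).
#' @param landmark_noise_sd isotropic Gaussian noise added to the observed
#'   landmark positions (cm).
#' @return list `lesions` (raw-coordinate lesion table), `landmarks`
#'   (matrix with rownames).
#' @export
simulate_patient_observation <- function(config, lesions, reference,
                                         patient_index = NULL,
                                         landmark_noise_sd = 0) {
  if (is.null(patient_index)) {
    patient_index <- as.integer(sub("\\D+", "", lesions$patient_id[1L]))
  }
  set.seed(stream_seed(config$seed, patient_index, salt = 3L))
  tf <- random_rigid_transform()
  lm <- reference_landmarks(reference)
  if (landmark_noise_sd > 0) {
    lm <- lm + matrix(stats::rnorm(length(lm), 0, landmark_noise_sd),
                      nrow(lm))
  }
  pts <- apply_rigid(tf, cbind(lesions$x_cm, lesions$y_cm, lesions$z_cm))
  lmo <- apply_rigid(tf, lm)
  if (lesions$side[1L] == "right") {
    pts[, 1L] <- -pts[, 1L]
    lmo[, 1L] <- -lmo[, 1L]
  }
  obs <- lesions[c("patient_id", "lesion_id", "role", "side", "site")]
  obs$x_cm <- pts[, 1L]; obs$y_cm <- pts[, 2L]; obs$z_cm <- pts[, 3L]
  rownames(lmo) <- rownames(lm)
  list(lesions = obs, landmarks = lmo)
}

#' Draw a uniformly random rigid transform
#'
#' Rotation uniform over SO(3) (QR of a Gaussian matrix, sign-corrected),
#' translation uniform in a cube.
#'
#' @param max_translation half-width of the translation cube (cm).
#' @return a `rigid_transform`.
#' @export
random_rigid_transform <- function(max_translation = 20) {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  rigid_transform(Q, stats::runif(3L, -max_translation, max_translation))
}

#' End-to-end recovery experiment
#'
#' Runs the whole chain on synthetic data: simulate a mapped subset
#' (`n_leg_mapped` lower-leg and `n_foot_mapped` foot ITM patients), move
#' each into a random patient frame, map every patient back onto the
#' reference with [map_patient()], score concordance, tabulate the match
#' patterns by site and compare the sites.  Optionally repeats over
#' several replicates (each with a shifted master seed) and summarizes the
#' distribution of the per-site category percentages and of the
#' site-comparison p-value.
#'
#' @param config a [simulation_config()].
#' @param reference the reference `leg_surface`.
#' @param replicates number of replicates.
#' @param apply_motion move patients into random frames (exercises the
#'   registration); disable for a fast zones-only run.
#' @return list with `per_replicate` (data.frame: replicate, full/partial/
#'   none percentages per site, p) and `tables` (the last replicate's
#'   `pattern_table`).
#' @export
end_to_end_recovery <- function(config, reference, replicates = 1L,
                                apply_motion = TRUE) {
  per <- vector("list", replicates)
  last_tab <- NULL
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- stream_seed(config$seed, r, salt = 9L)
    res <- run_mapped_subset(cfg, reference, apply_motion = apply_motion)
    tab <- res$pattern_table
    cmp <- compare_sites(tab)
    last_tab <- tab
    per[[r]] <- data.frame(
      replicate = r,
      full_foot = tab$percentages["full", "foot"],
      partial_foot = tab$percentages["partial", "foot"],
      none_foot = tab$percentages["none", "foot"],
      full_leg = tab$percentages["full", "lower_leg"],
      partial_leg = tab$percentages["partial", "lower_leg"],
      none_leg = tab$percentages["none", "lower_leg"],
      p = cmp$p)
  }
  list(per_replicate = do.call(rbind, per), tables = last_tab)
}

# simulate + map + score the photographed subset for one replicate
run_mapped_subset <- function(config, reference, apply_motion = TRUE) {
  sites <- c(rep("lower_leg", config$n_leg_mapped),
             rep("foot", config$n_foot_mapped))
  ranges <- itm_count_ranges()
  results <- vector("list", length(sites))
  mapped_all <- vector("list", length(sites))
  for (i in seq_along(sites)) {
    set.seed(stream_seed(config$seed, i, salt = 4L))
    patient <- data.frame(
      patient_id = sprintf("M%03d", i), site = sites[i],
      side = if (stats::runif(1) < 0.5) "left" else "right",
      has_itm = TRUE,
      n_itm = {
        cat_i <- sample.int(4L, 1L, prob = config$itm_count_probs)
        sample(ranges[[cat_i]], 1L)
      }, stringsAsFactors = FALSE)
    les <- simulate_lesions(config, patient, reference, patient_index = i)
    if (apply_motion) {
      obs <- simulate_patient_observation(config, les, reference,
                                          patient_index = i)
      mp <- map_patient(obs$lesions, obs$landmarks, reference)
    } else {
      anchored <- les
      anchored$zone <- assign_zone_3d(reference, anchored)
      anchored$mappable <- TRUE
      mp <- list(evaluable = TRUE, reason = NA_character_,
                 lesions = anchored, transform = NULL, mirrored = FALSE)
    }
    if (!mp$evaluable) next
    results[[i]] <- score_patient(mp)
    mapped_all[[i]] <- mp$lesions
  }
  results <- do.call(rbind, results[!vapply(results, is.null, TRUE)])
  list(scores = results, pattern_table = tabulate_patterns(results),
       mapped = do.call(rbind,
                        mapped_all[!vapply(mapped_all, is.null, TRUE)]))
}
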