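#' Run the full mapping-and-statistics pipeline
#'
#' Orchestrates every stage on file-based or in-memory inputs: validate
#' and cross-reference the tables, map each patient's lesions onto the
#' reference leg (mirror, register, snap), score per-patient drainage
#' concordance, tabulate match patterns by site and compare sites,
#' measure primary-to-ITM skin-surface distances, and run the cohort
#' risk-factor statistics.  All result tables are written as CSV under
#' `outdir` together with a self-describing JSON run report (package
#' version, seed, configuration hash, evaluability funnel, and every
#' summary statistic).
#'
#' @param lesions lesion table (data.frame or CSV/TSV path; see
#'   [read_lesion_table()]).
#' @param landmarks patient landmark table (data.frame or path; see
#'   [read_landmark_table()]).
#' @param cohort optional cohort table (data.frame or path) for the
#'   risk-factor statistics; every lesion's patient must appear in it.
#' @param reference a `leg_surface` (default: [build_reference_leg()]).
#' @param outdir output directory, created if missing; `NULL` writes no
#'   files.
#' @param seed integer recorded in the report (the pipeline itself is
#'   deterministic).
#' @param refinement geodesic graph refinement level.
#' @param snap_threshold lesion snap threshold (cm).
#' @param compute_distances set `FALSE` to skip the geodesic stage.
#' @return list of class `itmap_report`: `patients` (evaluability),
#'   `mapped` (annotated lesion table), `scores`, `pattern_table`,
#'   `site_comparison`, `distances`, `distance_summary`, `risk_univariate`,
#'   `risk_multivariate`, `report` (the JSON-ready summary list).
#' @export
run_pipeline <- function(lesions, landmarks, cohort = NULL,
                         reference = build_reference_leg(),
                         outdir = NULL, seed = 1L, refinement = 3L,
                         snap_threshold = 3, compute_distances = TRUE) {
  if (is.character(lesions)) lesions <- read_lesion_table(lesions)
  else lesions <- validate_lesion_table(lesions)
  if (is.character(landmarks)) landmarks <- read_landmark_table(landmarks)
  if (is.character(cohort)) {
    cohort <- utils::read.csv(cohort, stringsAsFactors = FALSE)
  }
  if (!is.null(cohort)) {
    unknown <- which(!lesions$patient_id %in% cohort$patient_id)
    if (length(unknown)) {
      stop("lesion row(s) reference unknown patient(s): row ",
           paste(unknown, collapse = ", "), " (patient ",
           paste(unique(lesions$patient_id[unknown]), collapse = ", "), ")",
           call. = FALSE)
    }
  }

  patient_ids <- unique(lesions$patient_id)
  funnel <- list()
  mapped_all <- list()
  scores <- list()
  for (pid in patient_ids) {
    les <- lesions[lesions$patient_id == pid, , drop = FALSE]
    lm_rows <- landmarks[landmarks$patient_id == pid, , drop = FALSE]
    if (nrow(lm_rows) < 3L) {
      funnel[[pid]] <- list(evaluable = FALSE,
                            reason = "fewer than 3 landmarks")
      next
    }
    lm <- as.matrix(lm_rows[, c("x_cm", "y_cm", "z_cm")])
    rownames(lm) <- lm_rows$landmark
    mp <- map_patient(les, lm, reference, snap_threshold = snap_threshold)
    funnel[[pid]] <- list(evaluable = mp$evaluable, reason = mp$reason)
    if (!mp$evaluable) next
    mapped_all[[pid]] <- mp$lesions
    scores[[pid]] <- score_patient(mp)
  }
  mapped <- do.call(rbind, mapped_all)
  score_df <- do.call(rbind, scores)
  in_scope <- !is.null(score_df) &&
    any(score_df$site %in% c("foot", "lower_leg"))
  tab <- cmp <- NULL
  if (in_scope) {
    score_tab <- score_df[score_df$site %in% c("foot", "lower_leg"), ,
                          drop = FALSE]
    tab <- tabulate_patterns(score_tab)
    if (all(tab$n > 0L)) cmp <- compare_sites(tab)
  }

  dists <- dsum <- NULL
  if (compute_distances && !is.null(mapped) && nrow(mapped)) {
    gg <- geodesic_graph(reference, refinement = refinement)
    dists <- lesion_distances(gg, mapped[mapped$mappable, , drop = FALSE])
    if (nrow(dists) && all(c("foot", "lower_leg") %in% dists$site)) {
      dsum <- distance_summary(dists)
    }
  }

  uni <- multi <- NULL
  if (!is.null(cohort) && nrow(cohort) > 0L) {
    uni <- logistic_risk_model(cohort, mode = "univariate")
    multi <- logistic_risk_model(cohort, mode = "multivariate")
  }

  report <- list(
    package = "itmap",
    version = as.character(utils::packageVersion("itmap")),
    seed = seed,
    n_patients_input = length(patient_ids),
    n_evaluable = sum(vapply(funnel, function(x) isTRUE(x$evaluable), TRUE)),
    unevaluable = lapply(funnel[!vapply(funnel, function(x)
      isTRUE(x$evaluable), TRUE)], function(x) x$reason),
    pattern_counts = if (!is.null(tab)) tab$counts,
    pattern_percentages = if (!is.null(tab)) tab$percentages,
    site_comparison = if (!is.null(cmp))
      list(U = cmp$U, z = cmp$z, p = cmp$p),
    distance_summary = if (!is.null(dsum)) dsum$summary,
    distance_comparison_p = if (!is.null(dsum) && !is.null(dsum$comparison))
      dsum$comparison$p
  )

  out <- list(patients = funnel, mapped = mapped, scores = score_df,
              pattern_table = tab, site_comparison = cmp,
              distances = dists, distance_summary = dsum,
              risk_univariate = uni, risk_multivariate = multi,
              report = report)
  class(out) <- "itmap_report"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(mapped)) {
      utils::write.csv(mapped, file.path(outdir, "mapped_lesions.csv"),
                       row.names = FALSE)
    }
    if (!is.null(score_df)) {
      utils::write.csv(score_df, file.path(outdir, "concordance.csv"),
                       row.names = FALSE)
    }
    if (!is.null(tab)) {
      pt <- data.frame(category = rownames(tab$counts), tab$counts,
                       foot_pct = tab$percentages[, "foot"],
                       lower_leg_pct = tab$percentages[, "lower_leg"])
      utils::write.csv(pt, file.path(outdir, "pattern_table.csv"),
                       row.names = FALSE)
    }
    if (!is.null(dists)) {
      utils::write.csv(dists, file.path(outdir, "distances.csv"),
                       row.names = FALSE)
    }
    if (!is.null(uni)) {
      utils::write.csv(rbind(uni, multi),
                       file.path(outdir, "risk_factors.csv"),
                       row.names = FALSE)
    }
    report$config_hash <- report_hash(report)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         null = "null", force = TRUE)
    out$report <- report
  }
  out
}

# md5 of the canonical JSON serialization (written to a temp file because
# base R hashes files, not strings)
report_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null", force = TRUE)
  unname(tools::md5sum(tf))
}

#' @export
print.itmap_report <- function(x, ...) {
  cat("<itmap_report>\n")
  cat(sprintf("patients: %d input, %d evaluable\n",
              x$report$n_patients_input, x$report$n_evaluable))
  if (!is.null(x$pattern_table)) print(x$pattern_table)
  if (!is.null(x$site_comparison)) {
    cat(sprintf("site comparison: z = %.3f, p = %.3f\n",
                x$site_comparison$z, x$site_comparison$p))
  }
  if (!is.null(x$distance_summary)) print(x$distance_summary$summary)
  invisible(x)
}

#' Write a complete demo dataset
#'
#' Generates a small self-contained fixture: the reference mesh (OBJ +
#' JSON sidecar), a simulated mapped subset with per-patient observed
#' lesion and landmark tables, and a simulated clinical cohort CSV.
#'
#' @param dir output directory.
#' @param config a [simulation_config()]; the default uses a compact
#'   cohort so the fixture stays small.
#' @param reference optional prebuilt `leg_surface`.
#' @return invisibly, a list of the written file paths.
#' @export
write_demo_fixture <- function(dir,
                               config = simulation_config(
                                 seed = 20L, n_patients = 120L,
                                 n_leg_mapped = 8L, n_foot_mapped = 4L),
                               reference = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(reference)) reference <- build_reference_leg()
  mesh_path <- file.path(dir, "reference_leg.obj")
  write_leg_surface(reference, mesh_path)
  cohort <- simulate_cohort(config)

  sites <- c(rep("lower_leg", config$n_leg_mapped),
             rep("foot", config$n_foot_mapped))
  les_all <- lm_all <- list()
  ranges <- itm_count_ranges()
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
    obs <- simulate_patient_observation(config, les, reference,
                                        patient_index = i)
    les_all[[i]] <- obs$lesions
    lm_all[[i]] <- data.frame(patient_id = patient$patient_id,
                              landmark = rownames(obs$landmarks),
                              x_cm = obs$landmarks[, 1L],
                              y_cm = obs$landmarks[, 2L],
                              z_cm = obs$landmarks[, 3L],
                              stringsAsFactors = FALSE)
  }
  lesions <- do.call(rbind, les_all)
  landmarks <- do.call(rbind, lm_all)
  # the mapped patients also get cohort rows (cross-reference requirement)
  mapped_ids <- unique(lesions$patient_id)
  extra <- cohort[seq_along(mapped_ids), , drop = FALSE]
  extra$patient_id <- mapped_ids
  extra$site <- sites[seq_along(mapped_ids)]
  extra$has_itm <- TRUE
  cohort <- rbind(cohort, extra)
  utils::write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  write_lesion_table(lesions, file.path(dir, "lesions.csv"))
  write_landmark_table(landmarks, file.path(dir, "landmarks.csv"))
  invisible(list(mesh = mesh_path,
                 sidecar = paste0(mesh_path, ".json"),
                 cohort = file.path(dir, "cohort.csv"),
                 lesions = file.path(dir, "lesions.csv"),
                 landmarks = file.path(dir, "landmarks.csv")))
}
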