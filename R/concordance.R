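#' Round half away from zero
#'
#' Percentages in the concordance tables use commercial ("half-up")
#' rounding: 0.5 always rounds away from zero, unlike R's banker's
#' rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(c(56.5, 57.5)) # 57, 58
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Score drainage concordance for one patient
#'
#' Computes the fraction of a patient's in-transit metastases that fall in
#' the drainage zone of the primary melanoma, and classifies the pattern:
#' full match (fraction >= 90%), partial match (>= 50% and < 90%), or no
#' match (< 50%).
#'
#' @param primary_zone the primary melanoma's drainage zone.
#' @param itm_zones character vector of the zones of each ITM (>= 1).
#' @param patient_id,site optional identifiers carried into the result.
#' @return a one-row data.frame of class `concordance_result` with columns
#'   `patient_id`, `site`, `primary_zone`, `n_itm`, `n_in_zone`, `fraction`,
#'   `percentage` (half-up rounded), `category` (`"full"`, `"partial"`,
#'   `"none"`).
#' @examples
#' score_concordance("anteromedial", rep("anteromedial", 8))$category  # full
#' @export
score_concordance <- function(primary_zone, itm_zones, patient_id = NA,
                              site = NA) {
  as_zone_id(primary_zone)
  as_zone_id(itm_zones)
  if (length(itm_zones) < 1L) {
    stop("concordance is undefined without at least one ITM; ",
         "patient must be excluded", call. = FALSE)
  }
  n <- length(itm_zones)
  k <- sum(itm_zones == primary_zone)
  frac <- k / n
  category <- if (frac >= 0.90) "full" else if (frac >= 0.50) "partial" else "none"
  structure(data.frame(patient_id = patient_id, site = site,
                       primary_zone = primary_zone, n_itm = n,
                       n_in_zone = k, fraction = frac,
                       percentage = round_half_up(100 * frac),
                       category = category, stringsAsFactors = FALSE),
            class = c("concordance_result", "data.frame"))
}

#' Tabulate concordance categories by site
#'
#' Builds the 3 x 2 table of match categories (full / partial / none) by
#' primary-melanoma site (foot / lower leg), with per-site percentages
#' under half-up rounding.
#'
#' @param results data.frame of per-patient concordance results (rows from
#'   [score_concordance()], or any data.frame with `category` and `site`).
#' @return object of class `pattern_table`: list with `counts` and
#'   `percentages` (3 x 2 matrices, rows full/partial/none, columns
#'   foot/lower_leg) and `n` (patients per site).
#' @export
tabulate_patterns <- function(results) {
  cats <- c("full", "partial", "none")
  sites <- c("foot", "lower_leg")
  if (nrow(results)) {
    bad <- !results$site %in% sites
    if (any(bad)) {
      stop("results contain unsupported site(s): ",
           paste(unique(results$site[bad]), collapse = ", "), call. = FALSE)
    }
  }
  counts <- table(factor(results$category, levels = cats),
                  factor(results$site, levels = sites))
  counts <- matrix(as.integer(counts), 3L, 2L,
                   dimnames = list(cats, sites))
  n <- colSums(counts)
  pct <- counts
  for (j in seq_along(sites)) {
    pct[, j] <- if (n[j] > 0) round_half_up(100 * counts[, j] / n[j]) else 0
  }
  structure(list(counts = counts, percentages = pct, n = n),
            class = "pattern_table")
}

#' @export
print.pattern_table <- function(x, ...) {
  cat("In-transit metastatic pattern by primary site\n")
  m <- matrix(sprintf("%d (%d%%)", x$counts, x$percentages), 3L, 2L,
              dimnames = dimnames(x$counts))
  print(as.data.frame(m))
  invisible(x)
}

#' Compare match-pattern distributions between foot and lower leg
#'
#' Treats the match category as an ordinal variable (none < partial < full)
#' and compares the two primary sites with the Mann-Whitney U test
#' (tie-corrected asymptotic by default; exact permutation available for
#' small groups).
#'
#' @param table a `pattern_table` from [tabulate_patterns()].
#' @param method passed to [mw_test()].
#' @return the [mw_test()] result list, with `p` additionally rounded to 3
#'   decimals in `p_rounded`.
#' @export
compare_sites <- function(table, method = c("asymptotic", "exact")) {
  if (!inherits(table, "pattern_table")) {
    stop("table must be a pattern_table", call. = FALSE)
  }
  if (any(table$n == 0L)) {
    stop("both sites must have at least one patient", call. = FALSE)
  }
  code <- c(none = 0, partial = 1, full = 2)
  expand <- function(col) rep(code[rownames(table$counts)], table$counts[, col])
  res <- mw_test(expand("foot"), expand("lower_leg"), method = method)
  res$p_rounded <- round_half_up(res$p, 3)
  res
}
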