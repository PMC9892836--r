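#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction, for mutually
#' exclusive categorical risk factors (e.g. ulceration present/absent by
#' ITM status).  Degrees of freedom are (r - 1)(c - 1).
#'
#' @param table r x c matrix of non-negative counts (>= 2 rows and columns).
#' @return list with `statistic`, `df`, `p`, `expected`.
#' @examples
#' chi_square_test(matrix(c(44, 37, 244, 44), 2))$p  # << 0.001
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("table must have at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: a row or column marginal is zero", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), expected = ct$expected)
}

#' Mann-Whitney U test for a continuous covariate
#'
#' Compares a continuous covariate (age, tumor thickness, time to first
#' ITM) between two independent patient groups; same engine as
#' [compare_sites()].  If every value in both groups is identical the
#' result is degenerate (p = 1) and flagged.
#'
#' @param group_a,group_b numeric vectors; `NA`s are dropped.
#' @param method passed to [mw_test()].
#' @return the [mw_test()] result list.
#' @export
mann_whitney_continuous <- function(group_a, group_b,
                                    method = c("asymptotic", "exact")) {
  mw_test(group_a[!is.na(group_a)], group_b[!is.na(group_b)],
          method = method)
}

# Table-2-style covariate coding.  Returns a data.frame of factors aligned
# with `cohort`, plus the outcome; MUP records carry NA subtype so they are
# dropped (complete-case) from any model that includes subtype.
code_cohort <- function(cohort) {
  subtype <- ifelse(cohort$subtype == "MUP", NA, cohort$subtype)
  data.frame(
    has_itm = as.integer(cohort$has_itm),
    age_group = factor(ifelse(cohort$age >= 55, ">=55", "<55"),
                       levels = c("<55", ">=55")),
    subtype = factor(subtype, levels = c("SSM", "NM", "ALM", "NOS")),
    thickness_group = factor(ifelse(cohort$thickness >= 1.0, ">=1.0", "<1.0"),
                             levels = c("<1.0", ">=1.0")),
    ulceration = factor(cohort$ulceration, levels = c("absent", "present")),
    site = factor(cohort$site, levels = c("foot", "lower_leg", "thigh")),
    stringsAsFactors = FALSE
  )
}

#' Logistic regression of ITM risk factors
#'
#' Fits maximum-likelihood logistic regressions of ITM occurrence on the
#' standard covariates, coded as in the clinical risk tables: age (< 55 vs
#' >= 55 years), histologic subtype (reference SSM; melanoma of unknown
#' primary is excluded from subtype models), Breslow thickness (< 1.0 vs
#' >= 1.0 mm), ulceration (reference absent), and primary site (reference
#' foot).  `mode = "univariate"` fits one model per covariate;
#' `mode = "multivariate"` fits them jointly on the complete-case subset.
#' Effects are reported as odds ratios with 95% Wald confidence intervals
#' and Wald p-values; each reference level is listed with OR fixed at 1 and
#' no interval.
#'
#' Records missing a covariate are dropped from models containing it.
#' Complete or quasi-complete separation is detected from exploding
#' standard errors and flagged in the `converged` column.
#'
#' @param cohort cohort data.frame with columns `has_itm`, `age`, `subtype`,
#'   `thickness`, `ulceration`, `site` (see [simulate_cohort()]).
#' @param mode `"univariate"` or `"multivariate"`.
#' @param covariates subset of covariates to include.
#' @return data.frame with columns `covariate`, `level`, `or`, `ci_low`,
#'   `ci_high`, `p`, `n`, `model`, `converged`.
#' @export
logistic_risk_model <- function(cohort,
                                mode = c("univariate", "multivariate"),
                                covariates = c("age_group", "subtype",
                                               "thickness_group",
                                               "ulceration", "site")) {
  mode <- match.arg(mode)
  coded <- code_cohort(cohort)
  covariates <- match.arg(covariates, several.ok = TRUE)
  # drop covariates with a single observed level
  usable <- covariates[vapply(covariates, function(v)
    length(unique(stats::na.omit(coded[[v]]))) > 1L, TRUE)]
  dropped <- setdiff(covariates, usable)
  if (length(dropped)) {
    warning("covariate(s) with a single observed level dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit_one <- function(vars, label) {
    dat <- coded[c("has_itm", vars)]
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    fml <- stats::as.formula(paste("has_itm ~", paste(vars, collapse = " + ")))
    fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                       data = dat))
    sm <- summary(fit)$coefficients
    zc <- stats::qnorm(0.975)
    out <- list()
    for (v in vars) {
      levs <- levels(dat[[v]])
      levs <- levs[levs %in% unique(as.character(dat[[v]]))]
      ref <- levs[1L]
      out[[length(out) + 1L]] <- data.frame(
        covariate = v, level = ref, or = 1, ci_low = NA_real_,
        ci_high = NA_real_, p = NA_real_, n = nrow(dat), model = label,
        converged = TRUE, stringsAsFactors = FALSE)
      for (lv in levs[-1L]) {
        cn <- paste0(v, lv)
        if (!cn %in% rownames(sm)) next
        est <- sm[cn, "Estimate"]; se <- sm[cn, "Std. Error"]
        ok <- fit$converged && se < 100
        out[[length(out) + 1L]] <- data.frame(
          covariate = v, level = lv, or = exp(est),
          ci_low = exp(est - zc * se), ci_high = exp(est + zc * se),
          p = sm[cn, "Pr(>|z|)"], n = nrow(dat), model = label,
          converged = ok, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }
  if (mode == "univariate") {
    do.call(rbind, lapply(usable, function(v) fit_one(v, "univariate")))
  } else {
    fit_one(usable, "multivariate")
  }
}
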