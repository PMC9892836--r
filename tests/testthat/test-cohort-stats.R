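test_that("chi-square reproduces the ulceration association", {
  ct <- chi_square_test(matrix(c(44, 37, 244, 44), 2))
  # oracle: direct sum of (O - E)^2 / E
  obs <- matrix(c(44, 37, 244, 44), 2)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  expect_equal(ct$statistic, sum((obs - expd)^2 / expd), tolerance = 1e-9)
  expect_equal(ct$statistic, 34.1, tolerance = 0.01)
  expect_lt(ct$p, 0.001)
  expect_equal(ct$df, 1)
})

test_that("chi-square handles identical proportions and degenerate tables", {
  flat <- chi_square_test(matrix(c(10, 20, 30, 60), 2))
  expect_equal(flat$statistic, 0, tolerance = 1e-12)
  expect_equal(flat$p, 1)
  expect_error(chi_square_test(matrix(c(1, 2), 1)), "at least 2")
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
  expect_error(chi_square_test(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("chi-square on a 2x2 equals the squared score z", {
  m <- matrix(c(12, 30, 44, 19), 2)
  ct <- chi_square_test(m)
  # score z for the difference of two proportions (pooled)
  n1 <- sum(m[1, ]); n2 <- sum(m[2, ])
  p1 <- m[1, 1] / n1; p2 <- m[2, 1] / n2
  pp <- sum(m[, 1]) / sum(m)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  expect_equal(ct$statistic, z^2, tolerance = 1e-9)
})

test_that("continuous Mann-Whitney: ties, separation, degeneracy", {
  same <- mann_whitney_continuous(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  sep <- mann_whitney_continuous(c(1, 2), c(10, 20))
  expect_equal(sep$U, 0)
  deg <- mann_whitney_continuous(c(5, 5, 5), c(5, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  expect_error(mann_whitney_continuous(numeric(0), 1:3), "non-empty")
  # NAs are dropped before testing
  expect_equal(mann_whitney_continuous(c(1, 2, NA), c(1, 2))$n1, 2)
})

test_that("univariate logistic OR on a 2x2 equals the cross-product ratio", {
  # exposed cases a=20, exposed controls b=10, unexposed cases c=10,
  # unexposed controls d=20 -> OR = ad/bc = 4
  coh <- data.frame(
    patient_id = 1:60,
    age = rep(c(60, 40), c(30, 30)),
    subtype = "SSM", thickness = 2, ulceration = "absent", site = "foot",
    has_itm = c(rep(c(TRUE, FALSE), c(20, 10)),
                rep(c(TRUE, FALSE), c(10, 20))))
  fit <- logistic_risk_model(coh, "univariate", covariates = "age_group")
  eff <- fit[fit$level == ">=55", ]
  expect_equal(eff$or, 4, tolerance = 1e-6)
  expect_true(eff$ci_low < 4 && 4 < eff$ci_high)
  ref <- fit[fit$level == "<55", ]
  expect_equal(ref$or, 1)
  expect_true(is.na(ref$ci_low) && is.na(ref$p))
})

test_that("a covariate independent of the outcome estimates OR near 1", {
  set.seed(61)
  n <- 10000
  coh <- data.frame(
    patient_id = seq_len(n),
    age = sample(c(40, 70), n, replace = TRUE),
    subtype = "SSM", thickness = 2, ulceration = "absent", site = "foot",
    has_itm = runif(n) < 0.25)
  fit <- logistic_risk_model(coh, "univariate", covariates = "age_group")
  expect_gt(fit$or[fit$level == ">=55"], 0.9)
  expect_lt(fit$or[fit$level == ">=55"], 1.1)
})

test_that("multivariate model codes covariates as in the risk tables and
           drops incomplete records", {
  cfg <- simulation_config(seed = 62, n_patients = 400)
  coh <- simulate_cohort(cfg)
  fit <- logistic_risk_model(coh, "multivariate")
  expect_setequal(unique(fit$covariate),
                  c("age_group", "subtype", "thickness_group", "ulceration",
                    "site"))
  # reference levels: OR 1, no CI
  refs <- fit[fit$or == 1 & is.na(fit$p), ]
  expect_setequal(refs$level, c("<55", "SSM", "<1.0", "absent", "foot"))
  # complete cases only: n below the cohort size (missing + MUP dropped)
  n_complete <- sum(stats::complete.cases(
    coh[c("age", "thickness", "ulceration")]) & coh$subtype != "MUP")
  expect_true(all(fit$n == n_complete))
  # CI bracket the estimate
  est <- fit[!is.na(fit$p), ]
  expect_true(all(est$ci_low <= est$or & est$or <= est$ci_high))
})

test_that("logistic parameter recovery: known coefficients are estimated
           consistently with near-nominal CI coverage", {
  cfg <- simulation_config(seed = 63, n_patients = 2000,
                           missing_thickness = 0, missing_ulceration = 0,
                           mup_rate = 0)
  truth <- cfg$beta
  reps <- 40
  est <- matrix(NA_real_, reps, 3,
                dimnames = list(NULL, c("thickness_ge1",
                                        "ulceration_present",
                                        "age_ge55")))
  cover <- est
  for (r in seq_len(reps)) {
    cfg_r <- cfg; cfg_r$seed <- 63000 + r
    coh <- simulate_cohort(cfg_r)
    fit <- logistic_risk_model(coh, "multivariate")
    pick <- function(cov, lev) fit[fit$covariate == cov & fit$level == lev, ]
    rows <- list(pick("thickness_group", ">=1.0"),
                 pick("ulceration", "present"),
                 pick("age_group", ">=55"))
    for (j in 1:3) {
      est[r, j] <- log(rows[[j]]$or)
      b <- truth[[colnames(est)[j]]]
      cover[r, j] <- rows[[j]]$ci_low <= exp(b) & exp(b) <= rows[[j]]$ci_high
    }
  }
  for (j in 1:3) {
    b <- truth[[colnames(est)[j]]]
    mc_se <- stats::sd(est[, j]) / sqrt(reps)
    expect_lt(abs(mean(est[, j]) - b), 3 * mc_se + 0.05)
  }
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 1.0)
})
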