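test_that("concordance scoring reproduces the worked match examples", {
  full <- score_concordance("anteromedial", rep("anteromedial", 8))
  expect_equal(full$fraction, 1)
  expect_equal(full$percentage, 100)
  expect_identical(full$category, "full")

  part <- score_concordance("anteromedial",
                            rep(c("anteromedial", "posterolateral"),
                                c(8, 6)))
  expect_equal(part$n_itm, 14L)
  expect_equal(part$percentage, 57)
  expect_identical(part$category, "partial")

  none <- score_concordance("anteromedial",
                            rep(c("anteromedial", "posteromedial"),
                                c(2, 8)))
  expect_equal(none$percentage, 20)
  expect_identical(none$category, "none")
})

test_that("category thresholds are closed at 90% and 50%", {
  z <- function(k, n) score_concordance(
    "anterolateral", rep(c("anterolateral", "posteromedial"), c(k, n - k)))
  expect_identical(z(9, 10)$category, "full")      # exactly 90%
  expect_identical(z(5, 10)$category, "partial")   # exactly 50%
  expect_identical(z(89, 100)$category, "partial") # just below 90%
  expect_identical(z(49, 100)$category, "none")
  expect_error(score_concordance("anteromedial", character(0)), "excluded")
  expect_error(score_concordance("shin", "anteromedial"), "unknown zone")
})

test_that("category is monotone non-decreasing in the in-zone fraction", {
  ord <- c(none = 0, partial = 1, full = 2)
  prev <- -1
  for (k in 0:20) {
    cat_k <- score_concordance(
      "anteromedial",
      rep(c("anteromedial", "posterolateral"), c(k, 20 - k)))$category
    expect_gte(ord[[cat_k]], prev)
    prev <- ord[[cat_k]]
  }
})

test_that("half-up rounding rounds .5 away from zero", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
  expect_equal(round_half_up(56.45, 1), 56.5)
  # the documented checks from the clinical tables
  expect_equal(round_half_up(100 * 34 / 94), 36)
  expect_equal(round_half_up(100 * 7 / 31), 23)
})

test_that("pattern tabulation reproduces the published percentages", {
  tab <- tabulate_patterns(make_scores(c(22, 2, 7), c(3, 6, 6)))
  expect_equal(unname(tab$counts[, "lower_leg"]), c(22, 2, 7))
  expect_equal(unname(tab$percentages[, "lower_leg"]), c(71, 6, 23))
  expect_equal(unname(tab$percentages[, "foot"]), c(20, 40, 40))
  expect_equal(unname(tab$n), c(15, 31))
  # counts per site sum to the site's patient count
  expect_equal(colSums(tab$counts), tab$n)
})

test_that("tabulation round-trips categories and handles edge cases", {
  single <- tabulate_patterns(data.frame(category = "full", site = "foot"))
  expect_equal(unname(single$percentages[, "foot"]), c(100, 0, 0))
  empty <- tabulate_patterns(data.frame(category = character(),
                                        site = character()))
  expect_true(all(empty$counts == 0))
  expect_error(tabulate_patterns(data.frame(category = "full",
                                            site = "thigh")),
               "unsupported site")
  # re-deriving counts from expanded categories is the identity
  scores <- make_scores(c(5, 3, 2), c(1, 4, 0))
  tab <- tabulate_patterns(scores)
  expect_equal(unname(tab$counts[, "lower_leg"]), c(5, 3, 2))
  expect_equal(unname(tab$counts[, "foot"]), c(1, 4, 0))
})

test_that("site comparison reproduces the published p = 0.007", {
  tab <- tabulate_patterns(make_scores(c(22, 2, 7), c(3, 6, 6)))
  cmp <- compare_sites(tab)
  expect_equal(cmp$z, -2.6914, tolerance = 1e-4)
  expect_equal(cmp$p_rounded, 0.007)
  # cross-check against the standard library implementation
  foot <- rep(c(2, 1, 0), c(3, 6, 6))
  leg <- rep(c(2, 1, 0), c(22, 2, 7))
  wt <- stats::wilcox.test(foot, leg, exact = FALSE, correct = FALSE)
  expect_equal(cmp$p, wt$p.value, tolerance = 1e-9)
})

test_that("identical category distributions give z = 0, p = 1", {
  tab <- tabulate_patterns(make_scores(c(4, 3, 2), c(4, 3, 2)))
  cmp <- compare_sites(tab)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p, 1)
})

test_that("site comparison is anti-symmetric under site swap and needs
           both sites", {
  tab <- tabulate_patterns(make_scores(c(6, 1, 1), c(1, 2, 5)))
  swapped <- tabulate_patterns(make_scores(c(1, 2, 5), c(6, 1, 1)))
  expect_equal(compare_sites(tab)$z, -compare_sites(swapped)$z,
               tolerance = 1e-12)
  expect_equal(compare_sites(tab)$p, compare_sites(swapped)$p)
  empty_site <- tabulate_patterns(make_scores(c(2, 1, 0), c(0, 0, 0)))
  expect_error(compare_sites(empty_site), "at least one patient")
})

test_that("exact-mode site comparison equals the enumeration oracle", {
  oracle_p <- function(a, b) {
    x <- c(a, b)
    n1 <- length(a); N <- length(x)
    r <- rank(x)
    mu <- n1 * (N - n1) / 2
    us <- apply(utils::combn(N, n1), 2,
                function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
    obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
  }
  set.seed(51)
  for (rep in 1:12) {
    fc <- as.vector(stats::rmultinom(1, 4, c(1, 1, 1)))
    lc <- as.vector(stats::rmultinom(1, 4, c(1, 1, 1)))
    tab <- tabulate_patterns(make_scores(lc, fc))
    cmp <- compare_sites(tab, method = "exact")
    a <- rep(c(2, 1, 0), fc)
    b <- rep(c(2, 1, 0), lc)
    expect_equal(cmp$p, oracle_p(a, b), tolerance = 1e-12)
  }
})
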