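test_that("method mix reproduces the published counts and percentages", {
  counts <- readr::read_csv(extdata("rdhs2015_method_mix.csv"),
                            show_col_types = FALSE)
  d <- tibble::tibble(method_type = rep(counts$method, counts$n))
  mix <- prevalence_by_method(d)
  expect_equal(mix$n, c(3237, 402, 3208))
  expect_equal(mix$pct, c(47.3, 5.9, 46.9))
  expect_equal(sum(mix$pct[mix$method != "none"]), 52.8)  # 5.9 + 46.9 as printed rows
  # any-method prevalence from the raw counts
  expect_equal(round_half_up(100 * (402 + 3208) / 6847, 1), 52.7)

  single <- prevalence_by_method(tibble::tibble(method_type = rep("modern", 10)))
  expect_equal(single$pct, c(0, 0, 100))

  set.seed(1)
  rand <- tibble::tibble(method_type = sample(c("none", "modern", "traditional"),
                                              997, replace = TRUE))
  expect_lt(abs(sum(prevalence_by_method(rand)$pct) - 100), 0.11)
  expect_error(prevalence_by_method(tibble::tibble(method_type = "pill")),
               "unknown method")
})

test_that("crosstab reproduces the published working-status row", {
  counts <- readr::read_csv(extdata("rdhs2015_crosstab_counts.csv"),
                            show_col_types = FALSE)
  wk <- counts[counts$covariate == "working", ]
  d <- survey_from_counts(wk, "working")
  ct <- crosstab(d, "working")
  expect_equal(unname(ct$pct_user[ct$level == "yes"]), 53.6)
  # Pearson chi-square on the printed counts gives p = 1.9e-4
  expect_lt(attr(ct, "p_value"), 0.001)
  expect_true(attr(ct, "significant"))
})

test_that("chi-square statistic matches hand and brute-force computation", {
  d <- tibble::tibble(
    outcome = rep(c(0, 1, 0, 1), c(10, 20, 20, 10)),
    g = rep(c("a", "b"), c(30, 30))
  )
  ct <- crosstab(d, "g")
  expect_equal(attr(ct, "statistic"), 20 / 3, tolerance = 1e-9)  # 6.667
  expect_equal(attr(ct, "df"), 1L)

  # homogeneous table: statistic 0, p 1
  dh <- tibble::tibble(outcome = rep(c(0, 1), 20), g = rep(c("a", "b"), each = 20))
  cth <- crosstab(dh, "g")
  expect_equal(attr(cth, "statistic"), 0)
  expect_equal(attr(cth, "p_value"), 1)

  # brute-force oracle on random multi-level tables
  set.seed(6)
  for (i in 1:10) {
    dr <- tibble::tibble(outcome = rbinom(300, 1, 0.5),
                         g = sample(letters[1:4], 300, replace = TRUE))
    ctr <- crosstab(dr, "g")
    tab <- table(dr$g, dr$outcome)
    expect_equal(attr(ctr, "statistic"), chisq_brute(tab), tolerance = 1e-10)
    expect_equal(attr(ctr, "df"), (nrow(tab) - 1L) * (ncol(tab) - 1L))
    expect_true(all(abs(rowSums(cbind(ctr$pct_nonuser, ctr$pct_user)) - 100) <= 0.1))
  }

  expect_error(crosstab(tibble::tibble(outcome = c(0, 1), g = "a"), "g"),
               "single level")
})

test_that("screening keeps strong covariates and respects alpha", {
  set.seed(8)
  n <- 10000
  x_strong <- sample(c("u", "v"), n, replace = TRUE)
  eta <- ifelse(x_strong == "v", 1, -1)
  d <- tibble::tibble(outcome = rbinom(n, 1, plogis(eta)),
                      strong = x_strong,
                      null = sample(c("p", "q"), n, replace = TRUE))
  sc <- screen_covariates(d, c("strong", "null"))
  expect_equal(sc$covariate, c("strong", "null"))  # input order preserved
  expect_true(sc$significant[sc$covariate == "strong"])

  # alpha = 1 boundary: everything passes
  sc1 <- screen_covariates(d, c("strong", "null"), alpha = 1)
  expect_true(all(sc1$significant))
})

test_that("zero-count levels are dropped with a warning", {
  d <- tibble::tibble(outcome = rbinom(40, 1, 0.5),
                      g = factor(sample(c("a", "b"), 40, replace = TRUE),
                                 levels = c("a", "b", "ghost")))
  expect_warning(ct <- crosstab(d, "g"), "ghost")
  expect_equal(nrow(ct), 2L)
})
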