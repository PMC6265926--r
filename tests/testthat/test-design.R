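test_that("treatment coding produces one dummy per non-reference level", {
  d <- tibble::tibble(education = c("no_education", "primary", "secondary",
                                    "tertiary", "primary"))
  fd <- encode_fixed(d, c(education = "no_education"))
  expect_equal(fd$column_labels,
               c("(Intercept)", "education:primary", "education:secondary",
                 "education:tertiary"))
  # all-reference record encodes as (1, 0, ..., 0)
  expect_equal(unname(fd$matrix[1, ]), c(1, 0, 0, 0))
  # each row: intercept plus at most one dummy per covariate
  expect_true(all(fd$matrix[, -1] %in% c(0, 1)))
  expect_true(all(rowSums(fd$matrix[, -1, drop = FALSE]) <= 1))
})

test_that("the full reference covariate set yields 27 dummies plus intercept", {
  d <- simulate_survey(simulation_spec(n_women = 4000, seed = 2))
  fd <- encode_fixed(d, default_references())
  # per-covariate non-reference level counts: 3+4+1+1+1+1+1+1+4+3+4+3 = 27
  expect_equal(ncol(fd$matrix), 28L)
  # round trip: decoding the dummy rows recovers the original levels
  dec <- decode_fixed(fd)
  for (cov in names(default_references())) {
    expect_equal(dec[[cov]], as.character(d[[cov]]), label = cov)
  }
})

test_that("unseen levels at prediction time are rejected by name", {
  d <- tibble::tibble(wealth = c("poorest", "middle"))
  fd <- encode_fixed(d, c(wealth = "poorest"))
  newd <- tibble::tibble(wealth = c("poorest", "imperial"))
  expect_error(fixed_design_rows(fd, newd), "imperial")
  expect_error(encode_fixed(d, c(wealth = "gold")), "reference level")
})

test_that("RW2 penalty matches the hand-multiplied D2'D2 and its null space", {
  expect_equal(rw2_penalty(1:3),
               rbind(c(1, -2, 1), c(-2, 4, -2), c(1, -2, 1)))
  for (m in c(3, 7, 10)) {
    k <- rw2_penalty(seq_len(m))
    expect_equal(k, t(k))
    expect_equal(drop(k %*% rep(1, m)), rep(0, m))
    expect_equal(drop(k %*% seq_len(m)), rep(0, m))
    ev <- eigen(k, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(ev > 1e-9), m - 2L)
    expect_true(all(ev > -1e-10))  # PSD
  }
  expect_error(rw2_penalty(1:2), "at least 3")
  expect_error(rw2_penalty(c(1, 1, 2)), "strictly increasing")
})

test_that("RW2 quadratic form equals the sum of squared second differences", {
  set.seed(12)
  for (m in c(5, 12, 34)) {
    k <- rw2_penalty(seq_len(m))
    f <- rnorm(m)
    expect_equal(drop(t(f) %*% k %*% f), sum(diff(f, differences = 2)^2),
                 tolerance = 1e-10)
  }
})

test_that("smooth design grids, incidence and counts are consistent", {
  d <- tibble::tibble(current_age = rep(16:49, length.out = 500))
  st <- smooth_design(d, "current_age", max_grid = 50)
  expect_equal(length(st$grid), 34L)
  expect_equal(dim(st$incidence), c(500L, 34L))
  expect_equal(unname(Matrix::rowSums(st$incidence)), rep(1, 500))
  # column sums recover the raw frequency table
  counts <- as.numeric(table(factor(d$current_age, levels = st$grid)))
  expect_equal(unname(Matrix::colSums(st$incidence)), counts)

  # more distinct values than max_grid: equal-width bin midpoints
  set.seed(3)
  dc <- tibble::tibble(x = runif(300))
  stb <- smooth_design(dc, "x", max_grid = 20)
  expect_equal(length(stb$grid), 20L)
  expect_equal(unname(Matrix::rowSums(stb$incidence)), rep(1, 300))

  # truncation clamps before gridding
  dt <- tibble::tibble(x = c(9, 10:49, 95))
  stt <- smooth_design(dt, "x", truncate = c(10, 49))
  expect_equal(range(stt$grid), c(10, 49))

  expect_error(smooth_design(tibble::tibble(x = rep(1, 5)), "x"), "constant")
  expect_error(smooth_design(tibble::tibble(x = letters[1:5]), "x"), "numeric")
})
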