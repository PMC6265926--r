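test_that("intercept-only posterior matches 1-D grid quadrature", {
  d <- tibble::tibble(outcome = c(rep(1, 35), rep(0, 65)))
  spec <- model_spec(1, fixed = character(0), continuous = character(0))
  fit <- fit_model(d, spec = spec, mcmc = mcmc_settings(6000, 1000, 2, seed = 42))
  b <- fit$theta_draws[, 1]

  grid <- seq(-3, 2, length.out = 4001)
  lp <- 35 * grid - 100 * log1p(exp(grid))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  mean_quad <- sum(grid * w)
  sd_quad <- sqrt(sum(grid^2 * w) - mean_quad^2)

  expect_lt(abs(mean(b) - mean_quad), 0.02)
  expect_lt(abs(mean(b) - qlogis(0.35)), 0.02)
  expect_lt(abs(sd(b) - sd_quad), 3 * bm_se(b) + 0.01)
})

test_that("intercept + one dummy matches 2-D grid quadrature", {
  d <- tibble::tibble(
    outcome = c(rep(1, 30), rep(0, 70), rep(1, 50), rep(0, 30)),
    group = rep(c("a", "b"), c(100, 80))
  )
  spec <- model_spec(1, fixed = "group", references = c(group = "a"),
                     continuous = character(0))
  fit <- fit_model(d, spec = spec, mcmc = mcmc_settings(8000, 1000, 2, seed = 7))

  g0 <- seq(-2.5, 1, length.out = 351)
  g1 <- seq(-1.5, 3, length.out = 351)
  lp <- outer(g0, g1, function(b0, b1) {
    30 * b0 - 100 * log1p(exp(b0)) + 50 * (b0 + b1) - 80 * log1p(exp(b0 + b1))
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  mean0 <- sum(rowSums(w) * g0)
  mean1 <- sum(colSums(w) * g1)

  b <- fit$theta_draws
  expect_lt(abs(mean(b[, 1]) - mean0), 3 * bm_se(b[, 1]) + 0.01)
  expect_lt(abs(mean(b[, 2]) - mean1), 3 * bm_se(b[, 2]) + 0.01)
})

test_that("perfectly balanced data keeps non-intercept effects at zero", {
  lev <- rep(c("a", "b", "c"), each = 200)
  d <- tibble::tibble(outcome = rep(c(1, 0), 300), group = lev)
  spec <- model_spec(1, fixed = "group", references = c(group = "a"),
                     continuous = character(0))
  fit <- fit_model(d, spec = spec, mcmc = mcmc_settings(3000, 500, 2, seed = 9))
  td <- tidy(fit)
  nonint <- td[td$term != "(Intercept)", ]
  expect_true(all(abs(nonint$estimate) < 3 * nonint$std.error))
})

test_that("Model 1 recovers known coefficients within 3 posterior SDs", {
  gen <- recovery_spec(5000, seed = 101, spatial_tau = NULL, smooth = NULL)
  d <- simulate_survey(gen)
  spec <- recovery_model_spec(1)
  spec$continuous <- character(0)
  fit <- fit_model(d, spec = spec, mcmc = mcmc_settings(2500, 500, 2, seed = 11))
  td <- tidy(fit)
  truth <- true_fixed_vector(gen, fit)
  expect_true(all(abs(td$estimate - truth[td$term]) < 3 * td$std.error),
              label = paste("max |z| =",
                            round(max(abs(td$estimate - truth[td$term]) /
                                      td$std.error), 2)))
})

test_that("fits are deterministic given a seed and constraints hold at 1e-8", {
  gen <- recovery_spec(1200, seed = 33)
  d <- simulate_survey(gen)
  spec <- recovery_model_spec(4)
  mc <- mcmc_settings(400, 100, 2, seed = 77)
  fit1 <- fit_model(d, graph = gen$graph, spec = spec, mcmc = mc)
  fit2 <- fit_model(d, graph = gen$graph, spec = spec, mcmc = mc)
  expect_identical(fit1$theta_draws, fit2$theta_draws)
  expect_identical(fit1$deviance_draws, fit2$deviance_draws)

  for (bl in fit1$blocks) {
    if (bl$type %in% c("smooth", "spatial")) {
      sums <- rowSums(fit1$theta_draws[, bl$cols, drop = FALSE])
      expect_lt(max(abs(sums)), 1e-8)
    }
  }
  expect_true(all(is.finite(fit1$theta_draws)))
  # precisions are positive and finite
  expect_true(all(fit1$tau_draws > 0 & is.finite(fit1$tau_draws)))
})

test_that("posterior summaries transform draws correctly", {
  # hand-built fit: two coefficients, known draws
  set.seed(5)
  draws <- cbind(`(Intercept)` = rnorm(400, -0.5, 0.1),
                 `x:yes` = rep(0, 400))
  fake <- structure(list(
    theta_draws = draws,
    blocks = list(fixed = list(name = "fixed", type = "fixed", cols = 1:2,
                               labels = colnames(draws)))
  ), class = "geoadd_fit")
  td <- tidy(fake)
  expect_equal(td$odds.ratio[2], 1)
  expect_equal(td$conf.low[2], 1)
  expect_equal(td$conf.high[2], 1)
  expect_equal(td$odds.ratio[1], exp(mean(draws[, 1])))
  # order-statistics bracket for the interval endpoints
  srt <- sort(draws[, 1])
  expect_gte(td$conf.low[1], exp(srt[floor(0.025 * 400)]))
  expect_lte(td$conf.low[1], exp(srt[ceiling(0.025 * 400) + 1]))
  expect_gte(td$conf.high[1], exp(srt[floor(0.975 * 400)]))
  expect_lte(td$conf.high[1], exp(srt[ceiling(0.975 * 400) + 1]))
})

test_that("fit validation rejects inconsistent inputs", {
  d <- tibble::tibble(outcome = c(0, 1), district_id = c(1, 99))
  spec <- model_spec(3, fixed = character(0), continuous = character(0))
  expect_error(fit_model(d, graph = NULL, spec = spec,
                         mcmc = mcmc_settings(10, 0, 1, seed = 1)),
               "requires an adjacency graph")
  g <- path_graph(3)
  expect_error(fit_model(d, graph = g, spec = spec,
                         mcmc = mcmc_settings(10, 0, 1, seed = 1)),
               "absent from graph: 99")
  d2 <- tibble::tibble(outcome = c(0, 2))
  expect_error(fit_model(d2, spec = model_spec(1, fixed = character(0),
                                               continuous = character(0)),
                         mcmc = mcmc_settings(10, 0, 1, seed = 1)),
               "0/1")
  expect_error(mcmc_settings(100, 200, 1, seed = 1), "exceed")
  expect_error(mcmc_settings(100, 10, 1), "seed")
  expect_error(model_spec(5), "model_id")
})
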