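#' Tidy the fixed effects of a fitted geo-additive model
#'
#' One row per fixed coefficient: posterior mean, posterior SD, the odds
#' ratio `exp(posterior mean)`, and the 95% credible interval of the odds
#' ratio obtained as the exponential of the equal-tailed 2.5%/97.5%
#' coefficient quantiles (the monotone transform makes the two orderings of
#' "quantile" and "exp" identical).
#'
#' @param x a `geoadd_fit`.
#' @param level credible level (default 0.95).
#' @param ... unused.
#' @return tibble with columns `term`, `estimate`, `std.error`,
#'   `odds.ratio`, `conf.low`, `conf.high` (the last two on the odds-ratio
#'   scale).
#' @method tidy geoadd_fit
#' @export
tidy.geoadd_fit <- function(x, level = 0.95, ...) {
  draws <- fit_block(x, "fixed")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- t(apply(draws, 2, stats::quantile, probs = probs, names = FALSE))
  tibble::tibble(
    term = colnames(draws),
    estimate = unname(colMeans(draws)),
    std.error = unname(apply(draws, 2, stats::sd)),
    odds.ratio = exp(unname(colMeans(draws))),
    conf.low = unname(exp(qs[, 1])),
    conf.high = unname(exp(qs[, 2]))
  )
}

#' One-line model summary
#'
#' @param x a `geoadd_fit`.
#' @param ... unused.
#' @return tibble with `model_id`, `n`, `n_draws`, `D_bar`, `p_D`, `DIC`.
#' @method glance geoadd_fit
#' @export
glance.geoadd_fit <- function(x, ...) {
  d <- dic(x)
  tibble::tibble(model_id = x$spec$model_id, n = x$n,
                 n_draws = nrow(x$theta_draws),
                 D_bar = d$D_bar, p_D = d$p_D, DIC = d$DIC)
}

#' Posterior summary of the smooth effects
#'
#' @param fit a `geoadd_fit` with smooth terms.
#' @param level credible level for the pointwise band.
#' @return tibble with `covariate`, `value` (grid point), `mean`, `lower`,
#'   `upper`.
#' @export
smooth_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "geoadd_fit"))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- list()
  for (bl in fit$blocks) {
    if (bl$type != "smooth") next
    draws <- fit$theta_draws[, bl$cols, drop = FALSE]
    qs <- t(apply(draws, 2, stats::quantile, probs = probs, names = FALSE))
    out[[bl$covariate]] <- tibble::tibble(
      covariate = bl$covariate, value = bl$grid,
      mean = colMeans(draws), lower = qs[, 1], upper = qs[, 2]
    )
  }
  if (!length(out)) stop("fit has no smooth terms", call. = FALSE)
  dplyr::bind_rows(out)
}

#' Posterior summary of the district spatial effects
#'
#' @param fit a `geoadd_fit` with a spatial term.
#' @param level credible level.
#' @return tibble with `region_id`, `label` (if the graph carries labels),
#'   `mean`, `lower`, `upper`.
#' @export
spatial_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "geoadd_fit"))
  bl <- fit$blocks[["spatial"]]
  if (is.null(bl)) stop("fit has no spatial term", call. = FALSE)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  draws <- fit$theta_draws[, bl$cols, drop = FALSE]
  qs <- t(apply(draws, 2, stats::quantile, probs = probs, names = FALSE))
  out <- tibble::tibble(
    region_id = bl$region_ids,
    mean = colMeans(draws), lower = qs[, 1], upper = qs[, 2]
  )
  if (!is.null(fit$graph$labels)) {
    out <- dplyr::mutate(out, label = fit$graph$labels[
      match(.data$region_id, fit$graph$region_ids)], .after = "region_id")
  }
  out
}

#' Full posterior summary of a fit
#'
#' Bundles the fixed-effect table ([tidy.geoadd_fit()]), the smooth and
#' spatial summaries where present, the precision summaries and the DIC
#' block.
#'
#' @param object a `geoadd_fit`.
#' @param level credible level.
#' @param ... unused.
#' @return an object of class `geoadd_summary` (a list of tibbles).
#' @export
summary.geoadd_fit <- function(object, level = 0.95, ...) {
  out <- list(
    fixed = tidy.geoadd_fit(object, level = level),
    smooth = if (length(object$spec$smooth)) smooth_summary(object, level),
    spatial = if (object$spec$spatial) spatial_summary(object, level),
    precisions = tibble::tibble(
      component = colnames(object$tau_draws),
      mean = colMeans(object$tau_draws),
      sd = apply(object$tau_draws, 2, stats::sd)
    ),
    dic = dic(object),
    model_id = object$spec$model_id
  )
  class(out) <- "geoadd_summary"
  out
}

#' @export
print.geoadd_summary <- function(x, ...) {
  cat(sprintf("Geo-additive Bernoulli-logit fit (Model %d)\n\nFixed effects:\n",
              x$model_id))
  print(x$fixed, n = Inf)
  if (!is.null(x$smooth)) {
    cat(sprintf("\nSmooth terms: %s (see smooth_summary()/plot_smooth_effects())\n",
                paste(unique(x$smooth$covariate), collapse = ", ")))
  }
  if (!is.null(x$spatial)) {
    cat(sprintf("\nSpatial effects over %d districts (see spatial_summary()/plot_spatial_effects())\n",
                nrow(x$spatial)))
  }
  cat(sprintf("\nDIC: %.2f  (D_bar %.2f, p_D %.2f)\n", x$dic$DIC, x$dic$D_bar,
              x$dic$p_D))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
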