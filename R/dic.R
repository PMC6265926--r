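#' Deviance information criterion of a fit
#'
#' Computes the Spiegelhalter DIC from the retained posterior draws:
#' `D_bar` is the posterior mean of the per-draw Bernoulli deviance,
#' the effective number of parameters is `p_D = D_bar - D(theta_bar)` where
#' `theta_bar` plugs the posterior means of all linear-predictor components
#' (fixed coefficients, smooth grid values, spatial effects) into the linear
#' predictor and then the deviance, and `DIC = D_bar + p_D` by construction.
#'
#' @param fit a `geoadd_fit` with at least 2 retained draws.
#' @return tibble with columns `D_bar`, `p_D`, `DIC`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "geoadd_fit"))
  if (nrow(fit$theta_draws) < 2) stop("need at least 2 retained draws", call. = FALSE)
  theta_bar <- colMeans(fit$theta_draws)
  eta_bar <- as.numeric(fit$z %*% theta_bar)
  d_plug <- deviance_bernoulli(fit$y, stats::plogis(eta_bar))
  dic_components(fit$deviance_draws, d_plug)
}

#' @rdname dic
#' @description `dic_components()` is the bare arithmetic: given the vector
#'   of per-draw deviances and the plug-in deviance at the posterior mean,
#'   it returns the (D_bar, p_D, DIC) triple.
#' @param deviances numeric vector of per-draw deviances (length >= 2).
#' @param deviance_at_mean plug-in deviance at the posterior-mean parameters.
#' @export
dic_components <- function(deviances, deviance_at_mean) {
  if (length(deviances) < 2) stop("need at least 2 deviance draws", call. = FALSE)
  d_bar <- mean(deviances)
  p_d <- d_bar - deviance_at_mean
  tibble::tibble(D_bar = d_bar, p_D = p_d, DIC = d_bar + p_d)
}

#' Monte-Carlo standard error of the DIC estimate
#'
#' Batch-means estimate of the simulation error in `D_bar` (the dominant
#' Monte-Carlo term of the DIC), giving model comparisons a principled
#' noise scale.
#'
#' @param fit a `geoadd_fit`.
#' @param batches number of equal batches (default 20).
#' @return scalar standard error.
#' @export
dic_mcse <- function(fit, batches = 20) {
  dev <- fit$deviance_draws
  s <- length(dev)
  batches <- max(2L, min(batches, s %/% 2L))
  size <- s %/% batches
  means <- vapply(seq_len(batches), function(b) {
    mean(dev[((b - 1L) * size + 1L):(b * size)])
  }, numeric(1))
  stats::sd(means) / sqrt(batches)
}

#' Fit and rank the four model structures by DIC
#'
#' Fits each supplied [model_spec()] with a common seed policy (the same
#' `mcmc` settings, hence the same seed, for every model) and reports the
#' (D_bar, p_D, DIC) triple per model with the DIC-ascending ranking —
#' lower DIC is the better-supported structure.
#'
#' @param data record-level data frame.
#' @param graph adjacency graph (needed by the spatial specs; may be `NULL`
#'   if none is spatial).
#' @param specs list of [model_spec()] objects.
#' @param mcmc an [mcmc_settings()].
#' @param keep_fits also return the fitted objects (attribute `fits`).
#' @param ... passed to [fit_model()].
#' @return a `dic_report`: tibble with `model_id`, `D_bar`, `p_D`, `DIC`,
#'   `rank`, ordered as supplied.
#' @export
compare_models <- function(data, graph = NULL, specs, mcmc, keep_fits = FALSE,
                           ...) {
  if (!length(specs)) stop("`specs` must be a nonempty list", call. = FALSE)
  fits <- vector("list", length(specs))
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    fit <- tryCatch(
      fit_model(data, graph = graph, spec = sp, mcmc = mcmc, ...),
      error = function(e) {
        stop(sprintf("model %d failed: %s", sp$model_id, conditionMessage(e)),
             call. = FALSE)
      }
    )
    rows[[i]] <- dplyr::mutate(dic(fit), model_id = sp$model_id,
                               .before = "D_bar")
    if (keep_fits) fits[[i]] <- fit
  }
  out <- dplyr::bind_rows(rows)
  out$rank <- rank(out$DIC, ties.method = "first")
  class(out) <- c("dic_report", class(out))
  if (keep_fits) attr(out, "fits") <- fits
  out
}
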