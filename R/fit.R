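#' Specify one of the four geo-additive model structures
#'
#' The four nested structures compared by DIC are:
#' \describe{
#'   \item{Model 1}{fixed effects only (classical logistic regression; any
#'     continuous covariates entered linearly via `linear`).}
#'   \item{Model 2}{fixed effects + RW2 smooth effects of the continuous
#'     covariates (additive logistic regression).}
#'   \item{Model 3}{fixed effects (+ linear continuous terms) + ICAR spatial
#'     district effects.}
#'   \item{Model 4}{fixed effects + smooths + spatial effects (structured
#'     additive regression).}
#' }
#'
#' @param model_id 1, 2, 3 or 4.
#' @param fixed character vector of categorical covariate names.
#' @param references named character vector of reference levels; covariates
#'   without an entry use their alphabetically first level.
#' @param continuous character vector of continuous covariate names; entered
#'   as RW2 smooths in Models 2/4 and as linear fixed columns in Models 1/3.
#' @param max_grid maximum smooth grid size.
#' @param smooth_truncate named list of `c(lo, hi)` clamping ranges applied
#'   before gridding (default pulls ages at first cohabitation into the
#'   eligible 10-49 range).
#' @param hyperprior Gamma (shape, rate) hyperprior on every variance
#'   component's precision; the weakly-informative Gamma(1, 0.0005) default
#'   is the convention of structured-additive-regression software.
#' @param beta_precision prior precision of each fixed coefficient: fixed
#'   effects get the effectively diffuse proper prior N(0, 1/beta_precision)
#'   (default variance 1e6, numerically a flat prior at survey data scales).
#' @param iid_district additionally include an unstructured iid district
#'   effect (off by default: the four reference structures contain none).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(model_id,
                       fixed = names(default_references()),
                       references = default_references(),
                       continuous = c("current_age", "age_first_cohabitation"),
                       max_grid = 50,
                       smooth_truncate = list(age_first_cohabitation = c(10, 49)),
                       hyperprior = c(shape = 1, rate = 5e-4),
                       beta_precision = 1e-6,
                       iid_district = FALSE) {
  if (!model_id %in% 1:4) stop("`model_id` must be 1, 2, 3 or 4", call. = FALSE)
  references <- unlist(references)
  references <- references[names(references) %in% fixed]
  structure(
    list(model_id = as.integer(model_id),
         fixed = fixed,
         references = references,
         continuous = continuous,
         smooth = if (model_id %in% c(2L, 4L)) continuous else character(0),
         spatial = model_id %in% c(3L, 4L),
         max_grid = max_grid,
         smooth_truncate = smooth_truncate,
         hyperprior = hyperprior,
         beta_precision = beta_precision,
         iid_district = isTRUE(iid_district)),
    class = "model_spec"
  )
}

#' MCMC settings for the Gibbs sampler
#'
#' @param iterations total Gibbs iterations (must exceed `burn_in`).
#' @param burn_in discarded initial iterations (>= 0).
#' @param thinning keep every `thinning`-th post-burn-in draw (>= 1).
#' @param seed integer seed; mandatory, so every fit is reproducible.
#' @return an object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(iterations = 12000, burn_in = 2000, thinning = 5,
                          seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  iterations <- assert_count(iterations, "iterations")
  burn_in <- assert_count(burn_in, "burn_in", min = 0L)
  thinning <- assert_count(thinning, "thinning")
  if (iterations <= burn_in) stop("`iterations` must exceed `burn_in`", call. = FALSE)
  structure(list(iterations = iterations, burn_in = burn_in,
                 thinning = thinning, seed = as.integer(seed)),
            class = "mcmc_settings")
}

resolve_references <- function(data, fixed, references) {
  out <- character(0)
  for (cov in fixed) {
    if (!cov %in% names(data)) {
      stop("fixed covariate `", cov, "` not in data", call. = FALSE)
    }
    out[[cov]] <- if (cov %in% names(references)) references[[cov]] else
      sort(unique(as.character(data[[cov]])))[1]
  }
  out
}

#' Fit a geo-additive Bernoulli-logit model by Polya-Gamma Gibbs sampling
#'
#' Samples the joint posterior of the model declared by `spec` on
#' record-level survey data.  Each Gibbs cycle draws (a) one Polya-Gamma
#' latent variable per record given the current linear predictor, (b) all
#' linear-predictor coefficients (fixed, smooth, spatial and optional iid
#' blocks) jointly from the resulting multivariate normal full conditional —
#' solving the complete augmented precision system at once — and (c) each
#' smoothing/spatial precision from its Gamma full conditional.
#' Sum-to-zero identifiability constraints (one per smooth term, one per
#' spatial connected component) are imposed on every draw by
#' conditioning-by-kriging, i.e. the exact correction
#' `theta - P^-1 A' (A P^-1 A')^-1 A theta` of the unconstrained Gaussian
#' draw, which leaves the intercept to carry the overall level.  The
#' Bernoulli deviance is recorded for every retained draw.
#'
#' @param data record-level data frame with a 0/1 `outcome` column, the
#'   model's covariates, and (for spatial models) `district_id`.
#' @param graph an [adjacency_graph()]; required iff `spec$spatial` or
#'   `spec$iid_district`.
#' @param spec a [model_spec()].
#' @param mcmc an [mcmc_settings()].
#' @param outcome name of the outcome column.
#' @param verbose log progress to stderr every 1,000 iterations.
#' @return an object of class `geoadd_fit`; see [tidy.geoadd_fit()],
#'   [summary.geoadd_fit()], [dic()], [smooth_summary()],
#'   [spatial_summary()].
#' @export
fit_model <- function(data, graph = NULL, spec, mcmc, outcome = "outcome",
                      verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"), inherits(mcmc, "mcmc_settings"))
  if (!outcome %in% names(data)) stop("no `", outcome, "` column", call. = FALSE)
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1", call. = FALSE)
  n <- length(y)

  needs_graph <- spec$spatial || spec$iid_district
  if (needs_graph) {
    if (is.null(graph)) stop("spatial model requires an adjacency graph", call. = FALSE)
    stopifnot(inherits(graph, "adjacency_graph"))
    if (!"district_id" %in% names(data)) stop("no `district_id` column", call. = FALSE)
    missing_d <- setdiff(unique(data$district_id), graph$region_ids)
    if (length(missing_d)) {
      stop("district(s) absent from graph: ", paste(missing_d, collapse = ", "),
           call. = FALSE)
    }
  }

  # ---- assemble design: Z = [fixed | linear | smooths | spatial | iid] ----
  refs <- resolve_references(data, spec$fixed, spec$references)
  fd <- if (length(spec$fixed)) encode_fixed(data, refs) else NULL
  x_fixed <- if (is.null(fd)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")) else
    fd$matrix

  linear_cov <- if (spec$model_id %in% c(1L, 3L)) spec$continuous else character(0)
  for (cov in linear_cov) {
    if (!cov %in% names(data)) stop("covariate `", cov, "` not in data", call. = FALSE)
    v <- as.numeric(data[[cov]])
    x_fixed <- cbind(x_fixed, v - mean(v))  # centred linear column
    colnames(x_fixed)[ncol(x_fixed)] <- cov
  }

  smooth_terms <- list()
  for (cov in spec$smooth) {
    smooth_terms[[cov]] <- smooth_design(
      data, cov, max_grid = spec$max_grid,
      truncate = spec$smooth_truncate[[cov]],
      tau_prior = spec$hyperprior
    )
  }

  blocks <- list()
  zparts <- list(Matrix::Matrix(x_fixed, sparse = TRUE))
  p_off <- ncol(x_fixed)
  blocks[["fixed"]] <- list(name = "fixed", type = "fixed",
                            cols = seq_len(ncol(x_fixed)),
                            labels = colnames(x_fixed))
  for (cov in names(smooth_terms)) {
    st <- smooth_terms[[cov]]
    m <- length(st$grid)
    blocks[[paste0("smooth_", cov)]] <- list(
      name = paste0("smooth_", cov), type = "smooth", covariate = cov,
      cols = p_off + seq_len(m), labels = paste0("f(", cov, ")[", st$grid, "]"),
      grid = st$grid, penalty = st$penalty, rank = m - 2L,
      tau_prior = st$tau_prior
    )
    zparts <- c(zparts, list(st$incidence))
    p_off <- p_off + m
  }
  components <- NULL
  if (spec$spatial || spec$iid_district) {
    ids <- graph$region_ids
    d <- length(ids)
    didx <- match(data$district_id, ids)
    b_spat <- Matrix::sparseMatrix(i = seq_len(n), j = didx, x = 1,
                                   dims = c(n, d))
    components <- connected_components(graph)
    if (spec$spatial) {
      q <- icar_precision(graph)
      blocks[["spatial"]] <- list(
        name = "spatial", type = "spatial",
        cols = p_off + seq_len(d), labels = paste0("spat[", ids, "]"),
        region_ids = ids, penalty = q,
        rank = d - length(unique(components)),
        tau_prior = spec$hyperprior
      )
      zparts <- c(zparts, list(b_spat))
      p_off <- p_off + d
    }
    if (spec$iid_district) {
      blocks[["iid"]] <- list(
        name = "iid", type = "iid",
        cols = p_off + seq_len(d), labels = paste0("iid[", ids, "]"),
        region_ids = ids, penalty = diag(d), rank = d,
        tau_prior = spec$hyperprior
      )
      zparts <- c(zparts, list(b_spat))
      p_off <- p_off + d
    }
  }
  z <- do.call(cbind, zparts)
  p <- ncol(z)

  # sum-to-zero constraint rows (conditioning-by-kriging)
  cons <- list()
  for (bl in blocks) {
    if (bl$type == "smooth") {
      a <- numeric(p); a[bl$cols] <- 1
      cons[[length(cons) + 1L]] <- a
    } else if (bl$type == "spatial") {
      for (cc in unique(components)) {
        a <- numeric(p)
        a[bl$cols[components == cc]] <- 1
        cons[[length(cons) + 1L]] <- a
      }
    }
  }
  amat <- if (length(cons)) do.call(rbind, cons) else NULL

  # variance components (everything but the fixed block)
  vc <- blocks[vapply(blocks, function(b) b$type != "fixed", logical(1))]

  prior_precision <- function(taus) {
    p0 <- matrix(0, p, p)
    fb <- blocks[["fixed"]]
    p0[cbind(fb$cols, fb$cols)] <- spec$beta_precision
    for (bl in vc) {
      p0[bl$cols, bl$cols] <- taus[[bl$name]] * bl$penalty
    }
    p0
  }

  # ---- Gibbs ----
  set.seed(mcmc$seed)
  n_keep <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thinning
  theta_draws <- matrix(NA_real_, n_keep, p,
                        dimnames = list(NULL, unlist(lapply(blocks, `[[`, "labels"))))
  tau_draws <- matrix(NA_real_, n_keep, length(vc),
                      dimnames = list(NULL, vapply(vc, `[[`, "", "name")))
  dev_draws <- numeric(n_keep)

  theta <- numeric(p)
  taus <- stats::setNames(as.list(rep(100, length(vc))),
                          vapply(vc, `[[`, "", "name"))
  kappa <- y - 0.5
  ztk <- as.numeric(Matrix::crossprod(z, kappa))
  eta <- numeric(n)
  keep <- 0L

  for (it in seq_len(mcmc$iterations)) {
    omega <- rpg_devroye(eta)
    prec <- as.matrix(Matrix::crossprod(z, Matrix::Diagonal(x = omega) %*% z)) +
      prior_precision(taus)
    ch <- tryCatch(chol(prec), error = function(e) chol(prec + diag(1e-8, p)))
    mu <- backsolve(ch, forwardsolve(t(ch), ztk))
    theta <- mu + backsolve(ch, stats::rnorm(p))
    if (!is.null(amat)) {
      va <- backsolve(ch, forwardsolve(t(ch), t(amat)))   # P^-1 A'
      w <- amat %*% va                                    # A P^-1 A'
      theta <- as.numeric(theta - va %*% solve(w, amat %*% theta))
      # sweep the O(1e-6) floating-point residue of the correction into the
      # intercept so each constrained block sums to zero exactly
      for (ci in seq_len(nrow(amat))) {
        idx <- which(amat[ci, ] == 1)
        resid <- mean(theta[idx])
        theta[idx] <- theta[idx] - resid
        theta[1L] <- theta[1L] + resid
      }
    }
    if (any(!is.finite(theta))) {
      stop("sampler diverged (non-finite state) at iteration ", it, call. = FALSE)
    }
    eta <- as.numeric(z %*% theta)
    for (bl in vc) {
      f <- theta[bl$cols]
      quad <- drop(crossprod(f, bl$penalty %*% f))
      taus[[bl$name]] <- stats::rgamma(1, shape = bl$tau_prior[["shape"]] + bl$rank / 2,
                                       rate = bl$tau_prior[["rate"]] + quad / 2)
    }
    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thinning == 0 &&
        keep < n_keep) {
      keep <- keep + 1L
      theta_draws[keep, ] <- theta
      tau_draws[keep, ] <- unlist(taus)
      pr <- stats::plogis(eta)
      dev_draws[keep] <- deviance_bernoulli(y, pr)
    }
    if (verbose && it %% 1000 == 0) {
      message(sprintf("iteration %d / %d", it, mcmc$iterations))
    }
  }

  structure(
    list(theta_draws = theta_draws, tau_draws = tau_draws,
         deviance_draws = dev_draws, blocks = blocks, z = z, y = y,
         spec = spec, mcmc = mcmc, graph = if (needs_graph) graph else NULL,
         components = components, n = n,
         fixed_design = fd, smooth_terms = smooth_terms),
    class = "geoadd_fit"
  )
}

#' @export
print.geoadd_fit <- function(x, ...) {
  cat(sprintf("<geoadd_fit> Model %d: %d records, %d coefficients, %d retained draws\n",
              x$spec$model_id, x$n, ncol(x$theta_draws), nrow(x$theta_draws)))
  invisible(x)
}

fit_block <- function(fit, name) {
  bl <- fit$blocks[[name]]
  if (is.null(bl)) stop("no block `", name, "` in this fit", call. = FALSE)
  fit$theta_draws[, bl$cols, drop = FALSE]
}
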