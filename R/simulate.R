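#' Default covariate marginals, effects and references for the synthetic survey
#'
#' The generator's defaults emulate a national Demographic and Health Survey
#' extract of married women of childbearing age: twelve categorical
#' covariates with marginal frequencies close to the published descriptive
#' table of such a survey, two continuous age variables (current age 16-49,
#' mean ~32.8; age at first cohabitation 10-49, mean ~21), ~6,847 women in
#' 492 clusters nested in 30 districts, and an overall outcome prevalence
#' near 0.53.
#'
#' @return `default_covariate_marginals()`: named list of named probability
#'   vectors, one per covariate.  `default_fixed_effects()`: named list of
#'   named log-odds-ratio vectors for the non-reference levels.
#'   `default_references()`: named character vector mapping each covariate to
#'   its reference level.  `default_smooth_functions()`: named list of two
#'   functions (a monotone-decreasing effect of current age and an
#'   inverted-U effect of age at first cohabitation peaking near 25).
#' @export
default_covariate_marginals <- function() {
  list(
    education = c(no_education = .165, primary = .705, secondary = .103, tertiary = .027),
    wealth = c(poorest = .188, poorer = .212, middle = .209, richer = .199, richest = .192),
    working = c(no = .132, yes = .868),
    radio = c(no = .45, yes = .55),
    newspapers = c(no = .939, yes = .061),
    fp_worker_visit = c(no = .708, yes = .292),
    health_facility_visit = c(no = .282, yes = .718),
    residing_with_husband = c(living = .88, elsewhere = .12),
    living_children = c(`0` = .052, `1` = .179, `2` = .252, `3` = .174, `4plus` = .343),
    religion = c(catholic = .382, protestant = .456, adventist = .128, other = .034),
    province = c(west = .22, kigali = .12, south = .24, north = .17, east = .25),
    husband_desires = c(same = .121, more = .606, fewer = .179, do_not_know = .094)
  )
}

#' @rdname default_covariate_marginals
#' @export
default_fixed_effects <- function() {
  list(
    education = c(primary = .16, secondary = .32, tertiary = .58),
    wealth = c(poorer = .07, middle = .22, richer = .30, richest = .36),
    working = c(yes = .24),
    radio = c(yes = .11),
    newspapers = c(yes = .29),
    fp_worker_visit = c(yes = .20),
    health_facility_visit = c(yes = .20),
    residing_with_husband = c(elsewhere = -.58),
    living_children = c(`0` = -1.2, `1` = -.81, `2` = -.31, `3` = -.12),
    religion = c(catholic = -.35, protestant = .13, adventist = .02),
    province = c(kigali = .05, south = -.12, north = .36, east = .17),
    husband_desires = c(more = .26, fewer = -.05, do_not_know = .21)
  )
}

#' @rdname default_covariate_marginals
#' @export
default_references <- function() {
  c(education = "no_education", wealth = "poorest", working = "no",
    radio = "no", newspapers = "no", fp_worker_visit = "no",
    health_facility_visit = "no", residing_with_husband = "living",
    living_children = "4plus", religion = "other", province = "west",
    husband_desires = "same")
}

#' @rdname default_covariate_marginals
#' @export
default_smooth_functions <- function() {
  list(
    current_age = function(a) -1.1 * stats::plogis((a - 32) / 5),
    age_first_cohabitation = function(x) -0.0035 * (x - 25)^2
  )
}

# discretised truncated-normal pmf over integer support
age_pmf <- function(support, mean, sd) {
  w <- stats::dnorm(support, mean, sd)
  stats::setNames(w / sum(w), support)
}

#' Specify a synthetic survey simulation
#'
#' Collects everything the generator needs: sample sizes, the district
#' adjacency graph, the true effect structure (intercept, categorical fixed
#' effects, smooth functions of the two age variables, ICAR spatial
#' precision) and the covariate marginals.  Defaults reproduce the package's
#' reference conditions (see [default_covariate_marginals()]).
#'
#' When `intercept` is `NULL` it is set to
#' `qlogis(target_prevalence) - E[fixed-effect contribution]` computed
#' analytically from the marginals; the smooth functions are centred against
#' the age distributions and the spatial field sums to zero, so the overall
#' outcome prevalence lands near `target_prevalence` without any tuning.
#'
#' @param n_women number of records to simulate.
#' @param graph an [adjacency_graph()] of districts; default 5 x 6 lattice
#'   (30 regions).
#' @param n_clusters number of survey clusters (primary sampling units).
#' @param intercept log-odds intercept, or `NULL` to derive it from
#'   `target_prevalence`.
#' @param target_prevalence overall outcome prevalence aimed for when
#'   `intercept` is `NULL`.
#' @param fixed_effects named list (by covariate) of named coefficient
#'   vectors for non-reference levels; may be `NULL` for no fixed effects.
#' @param references named character vector of reference levels.
#' @param covariate_marginals named list of category probability vectors;
#'   probabilities are validated to sum to 1 (within 1e-6) per covariate.
#' @param smooth_functions named list of functions of `current_age` and/or
#'   `age_first_cohabitation`; `NULL` for no smooth effects.
#' @param spatial_tau ICAR precision of the true district field, or `NULL`
#'   for no spatial effect.
#' @param cluster_sd standard deviation of an optional iid cluster effect
#'   (default 0: none, matching the fitted model structures).
#' @param modern_share probability that a simulated contraceptive user uses a
#'   modern rather than traditional method (drives the method-mix table).
#' @param age_range,cohabitation_range integer ranges of the two age
#'   variables.
#' @param age_mean,age_sd,cohabitation_mean,cohabitation_sd parameters of the
#'   discretised truncated-normal age distributions.
#' @param seed integer seed used by [simulate_survey()].
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_women = 6847,
                            graph = make_lattice_adjacency(5, 6),
                            n_clusters = 492,
                            intercept = NULL,
                            target_prevalence = 0.53,
                            fixed_effects = default_fixed_effects(),
                            references = default_references(),
                            covariate_marginals = default_covariate_marginals(),
                            smooth_functions = default_smooth_functions(),
                            spatial_tau = 4,
                            cluster_sd = 0,
                            modern_share = 3208 / 3610,
                            age_range = c(16L, 49L),
                            age_mean = 32.8, age_sd = 8.2,
                            cohabitation_range = c(10L, 49L),
                            cohabitation_mean = 21.1, cohabitation_sd = 4.2,
                            seed = NULL) {
  stopifnot(inherits(graph, "adjacency_graph"))
  n_women <- assert_count(n_women, "n_women")
  n_clusters <- assert_count(n_clusters, "n_clusters")
  if (n_women < n_regions(graph)) {
    stop("`n_women` must be at least the number of districts", call. = FALSE)
  }
  if (!is.null(spatial_tau)) spatial_tau <- assert_scalar_pos(spatial_tau, "spatial_tau")

  for (cov in names(covariate_marginals)) {
    p <- covariate_marginals[[cov]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop("marginal probabilities for `", cov, "` must be nonnegative and sum to 1",
           call. = FALSE)
    }
    covariate_marginals[[cov]] <- p / sum(p)
  }
  fixed_effects <- fixed_effects %||% list()
  for (cov in names(fixed_effects)) {
    if (!cov %in% names(covariate_marginals)) {
      stop("fixed effect declared for unknown covariate `", cov, "`", call. = FALSE)
    }
    bad <- setdiff(names(fixed_effects[[cov]]), names(covariate_marginals[[cov]]))
    if (length(bad)) {
      stop("fixed-effect level(s) absent from marginals of `", cov, "`: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  smooth_functions <- smooth_functions %||% list()
  bad_sm <- setdiff(names(smooth_functions), c("current_age", "age_first_cohabitation"))
  if (length(bad_sm)) {
    stop("smooth functions must be of current_age / age_first_cohabitation",
         call. = FALSE)
  }

  pmfs <- list(
    current_age = age_pmf(seq(age_range[1], age_range[2]), age_mean, age_sd),
    age_first_cohabitation = age_pmf(seq(cohabitation_range[1], cohabitation_range[2]),
                                     cohabitation_mean, cohabitation_sd)
  )

  # expected fixed-effect contribution under the marginals (independent draws)
  e_fixed <- 0
  for (cov in names(fixed_effects)) {
    b <- fixed_effects[[cov]]
    p <- covariate_marginals[[cov]]
    e_fixed <- e_fixed + sum(p[names(b)] * b)
  }
  if (is.null(intercept)) intercept <- stats::qlogis(target_prevalence) - e_fixed

  structure(
    list(n_women = n_women, graph = graph, n_clusters = n_clusters,
         intercept = intercept, fixed_effects = fixed_effects,
         references = references, covariate_marginals = covariate_marginals,
         smooth_functions = smooth_functions, spatial_tau = spatial_tau,
         cluster_sd = cluster_sd, modern_share = modern_share,
         age_pmfs = pmfs, seed = seed),
    class = "simulation_spec"
  )
}

#' Simulate a DHS-like survey dataset
#'
#' Draws a record-level survey table under the geo-additive generating model:
#' each woman's success probability is the inverse logit of
#' intercept + categorical fixed effects + centred smooth functions of the
#' two age variables + her district's ICAR spatial effect (+ an optional iid
#' cluster effect).  Clusters are assigned to districts uniformly (each
#' district receives at least one cluster) and women to clusters uniformly.
#'
#' The returned tibble carries a `truth` attribute with the per-record linear
#' predictor and its components, the true spatial field, and the centred
#' smooth functions tabulated over their grids — retrieve it with
#' [survey_truth()].  Identical spec + seed gives byte-identical data.
#'
#' @param spec a [simulation_spec()].
#' @param seed integer seed; defaults to `spec$seed`, and one of the two must
#'   be supplied.
#' @return a tibble with columns `woman_id`, `cluster_id`, `district_id`,
#'   `outcome` (0/1), `method_type` (none/traditional/modern),
#'   `current_age`, `age_first_cohabitation`, and one column per categorical
#'   covariate.
#' @examples
#' spec <- simulation_spec(n_women = 500, n_clusters = 40, seed = 1)
#' d <- simulate_survey(spec)
#' mean(d$outcome)
#' @export
simulate_survey <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  seed <- seed %||% spec$seed
  if (is.null(seed)) stop("a seed is required to simulate", call. = FALSE)
  set.seed(seed)

  n <- spec$n_women
  graph <- spec$graph
  ids <- graph$region_ids
  d <- length(ids)

  # true spatial field
  f_spat <- if (is.null(spec$spatial_tau)) {
    stats::setNames(rep(0, d), ids)
  } else {
    draw_icar_effects(graph, spec$spatial_tau)
  }

  # clusters: one per district first, remainder uniform
  n_cl <- spec$n_clusters
  cl_district <- c(ids[seq_len(min(d, n_cl))],
                   if (n_cl > d) sample(ids, n_cl - d, replace = TRUE))
  cluster_id <- sample.int(n_cl, n, replace = TRUE)
  district_id <- cl_district[cluster_id]

  cols <- list(woman_id = seq_len(n), cluster_id = cluster_id,
               district_id = district_id)

  # categorical covariates
  for (cov in names(spec$covariate_marginals)) {
    p <- spec$covariate_marginals[[cov]]
    cols[[cov]] <- sample(names(p), n, replace = TRUE, prob = p)
  }

  # continuous age covariates
  for (cov in names(spec$age_pmfs)) {
    pmf <- spec$age_pmfs[[cov]]
    cols[[cov]] <- as.integer(sample(names(pmf), n, replace = TRUE, prob = pmf))
  }

  # linear-predictor components
  fixed_part <- rep(0, n)
  for (cov in names(spec$fixed_effects)) {
    b <- spec$fixed_effects[[cov]]
    fixed_part <- fixed_part + unname(ifelse(cols[[cov]] %in% names(b),
                                             b[cols[[cov]]], 0))
  }

  smooth_parts <- list()
  smooth_grids <- list()
  for (cov in names(spec$smooth_functions)) {
    fn <- spec$smooth_functions[[cov]]
    pmf <- spec$age_pmfs[[cov]]
    support <- as.numeric(names(pmf))
    centre <- sum(pmf * fn(support))
    smooth_parts[[cov]] <- fn(cols[[cov]]) - centre
    smooth_grids[[cov]] <- tibble::tibble(value = support, effect = fn(support) - centre)
  }

  spatial_part <- unname(f_spat[as.character(district_id)])
  cluster_part <- if (spec$cluster_sd > 0) {
    u <- stats::rnorm(n_cl, 0, spec$cluster_sd)
    u[cluster_id]
  } else rep(0, n)

  eta <- spec$intercept + fixed_part + spatial_part + cluster_part
  for (s in smooth_parts) eta <- eta + s
  p <- stats::plogis(eta)
  outcome <- stats::rbinom(n, 1L, p)
  method_type <- ifelse(outcome == 0L, "none",
                        ifelse(stats::runif(n) < spec$modern_share,
                               "modern", "traditional"))

  out <- tibble::as_tibble(c(cols[c("woman_id", "cluster_id", "district_id")],
                             list(outcome = outcome, method_type = method_type),
                             cols[setdiff(names(cols),
                                          c("woman_id", "cluster_id", "district_id"))]))

  record_truth <- tibble::tibble(
    eta = eta,
    intercept = spec$intercept,
    fixed_part = fixed_part,
    spatial_part = spatial_part,
    cluster_part = cluster_part
  )
  for (cov in names(smooth_parts)) {
    record_truth[[paste0("f_", cov)]] <- smooth_parts[[cov]]
  }

  attr(out, "truth") <- list(
    record = record_truth,
    spatial_effects = f_spat,
    smooth_grids = smooth_grids,
    intercept = spec$intercept,
    fixed_effects = spec$fixed_effects,
    seed = seed
  )
  out
}

#' Retrieve the truth block of a simulated survey
#'
#' @param data a tibble produced by [simulate_survey()] (the truth block is
#'   carried only by simulated data).
#' @return list with `record` (per-record linear predictor and components),
#'   `spatial_effects`, `smooth_grids`, `intercept` and `fixed_effects`.
#' @export
survey_truth <- function(data) {
  tr <- attr(data, "truth", exact = TRUE)
  if (is.null(tr)) stop("no truth block attached to this dataset", call. = FALSE)
  tr
}
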