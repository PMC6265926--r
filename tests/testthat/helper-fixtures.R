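# shared fixtures: small graphs, reduced simulation specs, oracles

path_graph <- function(k = 3) {
  nb <- lapply(seq_len(k), function(i) {
    c(if (i > 1) i - 1L, if (i < k) i + 1L)
  })
  names(nb) <- seq_len(k)
  adjacency_graph(nb)
}

# reduced-covariate generating spec used by the recovery experiments:
# a parsimonious sub-model (education, wealth, working, radio) of the full
# default set, keeping every cell well-populated at moderate n
recovery_spec <- function(n_women, seed, spatial_tau = 4,
                          smooth = default_smooth_functions()) {
  marg <- default_covariate_marginals()[c("education", "wealth", "working", "radio")]
  eff <- default_fixed_effects()[c("education", "wealth", "working", "radio")]
  simulation_spec(
    n_women = n_women,
    n_clusters = 120,
    covariate_marginals = marg,
    fixed_effects = eff,
    references = default_references()[c("education", "wealth", "working", "radio")],
    smooth_functions = smooth,
    spatial_tau = spatial_tau,
    seed = seed
  )
}

recovery_model_spec <- function(model_id) {
  model_spec(model_id, fixed = c("education", "wealth", "working", "radio"),
             references = default_references()[c("education", "wealth",
                                                 "working", "radio")])
}

# generating truth for the DIC-discrimination experiment: unambiguously
# nonlinear smooths (quadratic age effect, sinusoidal inverted-U in
# cohabitation age) so the four model structures are separable at moderate n
dic_experiment_smooths <- function() {
  list(
    current_age = function(a) -0.0045 * (a - 30)^2,
    age_first_cohabitation = function(x) 0.9 * sin(pi * (x - 10) / 39)
  )
}

# independent chi-square oracle: brute-force sum((O-E)^2/E)
chisq_brute <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# true coefficient vector in the order of the fitted fixed block
true_fixed_vector <- function(spec, fit) {
  labels <- fit$blocks[["fixed"]]$labels
  truth <- numeric(length(labels))
  names(truth) <- labels
  truth["(Intercept)"] <- spec$intercept
  for (cov in names(spec$fixed_effects)) {
    b <- spec$fixed_effects[[cov]]
    truth[paste0(cov, ":", names(b))] <- b
  }
  truth
}

# batch-means Monte-Carlo SE of a draw vector's mean
bm_se <- function(x, batches = 20) {
  size <- length(x) %/% batches
  means <- vapply(seq_len(batches), function(b) {
    mean(x[((b - 1) * size + 1):(b * size)])
  }, numeric(1))
  sd(means) / sqrt(batches)
}

extdata <- function(file) {
  system.file("extdata", file, package = "geoadditive", mustWork = TRUE)
}
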