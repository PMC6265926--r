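#' Draw a spatial field from the ICAR prior
#'
#' Samples one realisation of the intrinsic conditional autoregressive
#' (ICAR) field over the regions of `graph` at precision `tau`.  Because the
#' intrinsic prior is improper (constant fields carry no penalty), the draw
#' is taken by the spectral method on the sum-to-zero subspace: the precision
#' Q is eigendecomposed, independent normals are drawn along the eigenvectors
#' with nonzero eigenvalue (variance `1/(tau * lambda)`), and the null
#' eigenvector (the constant) is excluded, so the returned field sums to
#' zero exactly.
#'
#' @param graph a connected [adjacency_graph()].
#' @param tau positive precision of the field.
#' @param seed optional integer; when supplied the draw is deterministic
#'   (`set.seed(seed)` is called first), otherwise the current RNG stream is
#'   used.
#' @return numeric vector of length D, named by region id, summing to zero.
#' @examples
#' g <- make_lattice_adjacency(3, 3)
#' f <- draw_icar_effects(g, tau = 1, seed = 7)
#' sum(f)  # 0 up to rounding
#' @export
draw_icar_effects <- function(graph, tau, seed = NULL) {
  stopifnot(inherits(graph, "adjacency_graph"))
  tau <- assert_scalar_pos(tau, "tau")
  comp <- connected_components(graph)
  if (length(unique(comp)) > 1L) {
    parts <- split(names(comp), comp)
    stop("graph is disconnected; components: ",
         paste(vapply(parts, function(p) paste0("{", paste(p, collapse = ","), "}"),
                      character(1)),
               collapse = " "),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  q <- icar_precision(graph)
  eg <- eigen(q, symmetric = TRUE)
  d <- nrow(q)
  tol <- max(eg$values) * d * .Machine$double.eps
  keep <- eg$values > tol
  z <- stats::rnorm(sum(keep)) / sqrt(tau * eg$values[keep])
  f <- drop(eg$vectors[, keep, drop = FALSE] %*% z)
  f <- f - mean(f)  # exact sum-to-zero (removes numerical residue)
  stats::setNames(f, graph$region_ids)
}
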