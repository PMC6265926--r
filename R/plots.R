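#' Plot posterior smooth effects
#'
#' Pointwise posterior mean with the 95% credible band for each RW2 smooth
#' term, the standard display for nonlinear covariate effects on the
#' log-odds scale.
#'
#' @param x a `geoadd_fit` or the tibble from [smooth_summary()].
#' @param ... passed to [smooth_summary()] when `x` is a fit.
#' @return a ggplot object.
#' @export
plot_smooth_effects <- function(x, ...) {
  sm <- if (inherits(x, "geoadd_fit")) smooth_summary(x, ...) else x
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~covariate, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "effect on log-odds") +
    ggplot2::theme_minimal()
}

#' Choropleth-style map of posterior spatial effects
#'
#' Renders the posterior mean district effects on a diverging colour scale
#' centred at zero, labelled with the district codes.  If GeoJSON polygons
#' are supplied they are drawn as a true choropleth; otherwise, when the
#' graph is a lattice, a heat-grid analogue is drawn so a map-style figure
#' exists for synthetic runs; failing both, districts are shown as a labelled
#' strip.
#'
#' @param fit a `geoadd_fit` with a spatial term, or a tibble from
#'   [spatial_summary()] (then `graph` should be given).
#' @param geo optional GeoJSON path or tibble from
#'   [read_geojson_polygons()].
#' @param graph adjacency graph (taken from the fit when omitted).
#' @return a ggplot object.
#' @export
plot_spatial_effects <- function(fit, geo = NULL, graph = NULL) {
  if (inherits(fit, "geoadd_fit")) {
    sp <- spatial_summary(fit)
    graph <- graph %||% fit$graph
  } else {
    sp <- fit
  }
  if (is.character(geo)) geo <- read_geojson_polygons(geo)
  base_scale <- ggplot2::scale_fill_gradient2(
    low = "#67a9cf", mid = "#f7f7f7", high = "#08519c", midpoint = 0,
    name = "spatial effect"
  )
  if (!is.null(geo)) {
    dat <- dplyr::left_join(geo, sp, by = "region_id")
    centers <- dplyr::summarise(dplyr::group_by(dat, .data$region_id),
                                x = mean(.data$x), y = mean(.data$y))
    return(
      ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
        ggplot2::geom_polygon(ggplot2::aes(group = .data$ring,
                                           fill = .data$mean),
                              colour = "grey30", linewidth = 0.2) +
        ggplot2::geom_text(data = centers,
                           ggplot2::aes(label = .data$region_id), size = 3) +
        base_scale + ggplot2::coord_equal() + ggplot2::theme_void()
    )
  }
  dim <- attr(graph, "lattice_dim")
  if (!is.null(dim)) {
    sp <- dplyr::mutate(sp,
      row = (match(.data$region_id, graph$region_ids) - 1L) %/% dim[["cols"]] + 1L,
      col = (match(.data$region_id, graph$region_ids) - 1L) %% dim[["cols"]] + 1L)
  } else {
    sp <- dplyr::mutate(sp, row = 1L, col = dplyr::row_number())
  }
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$mean), colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$region_id), size = 3) +
    base_scale + ggplot2::coord_equal() + ggplot2::theme_void()
}

#' Autoplot a fitted geo-additive model
#'
#' @param object a `geoadd_fit`.
#' @param type `"smooth"` (default when the model has smooth terms) or
#'   `"spatial"`.
#' @param ... passed on to the underlying plot function.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot geoadd_fit
#' @export
autoplot.geoadd_fit <- function(object, type = NULL, ...) {
  type <- type %||% if (length(object$spec$smooth)) "smooth" else "spatial"
  switch(type,
    smooth = plot_smooth_effects(object, ...),
    spatial = plot_spatial_effects(object, ...),
    stop("`type` must be \"smooth\" or \"spatial\"", call. = FALSE)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
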