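#' Read and write record-level survey tables
#'
#' Surveys are stored as comma-separated tables with a header row and one
#' record per line.  For simulated data the truth block travels in sibling
#' files next to the table: `<stem>_truth.csv` (per-record linear predictor
#' and components) and `<stem>_truth.json` (true spatial field, smooth
#' grids, intercept); `read_survey()` reattaches them when present.
#'
#' @param data survey tibble (see [simulate_survey()] for the schema).
#' @param path CSV file path.
#' @return `write_survey()` returns `path` invisibly; `read_survey()`
#'   returns the survey tibble.
#' @export
write_survey <- function(data, path) {
  readr::write_csv(data, path)
  tr <- attr(data, "truth", exact = TRUE)
  if (!is.null(tr)) {
    stem <- sub("\\.[^.]*$", "", path)
    readr::write_csv(tr$record, paste0(stem, "_truth.csv"))
    jsonlite::write_json(
      list(spatial_effects = as.list(tr$spatial_effects),
           smooth_grids = tr$smooth_grids,
           intercept = tr$intercept,
           fixed_effects = lapply(tr$fixed_effects, as.list),
           seed = tr$seed),
      paste0(stem, "_truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stem <- sub("\\.[^.]*$", "", path)
  tcsv <- paste0(stem, "_truth.csv")
  tjson <- paste0(stem, "_truth.json")
  if (file.exists(tcsv)) {
    truth <- list(record = readr::read_csv(tcsv, show_col_types = FALSE,
                                           progress = FALSE))
    if (file.exists(tjson)) {
      js <- jsonlite::read_json(tjson, simplifyVector = TRUE)
      truth$spatial_effects <- unlist(js$spatial_effects)
      truth$smooth_grids <- lapply(js$smooth_grids, tibble::as_tibble)
      truth$intercept <- js$intercept
      truth$fixed_effects <- lapply(js$fixed_effects, unlist)
      truth$seed <- js$seed
    }
    attr(out, "truth") <- truth
  }
  out
}

#' Read a JSON run configuration
#'
#' The configuration declares the model terms and sampler settings for the
#' command-line workflow: `fixed` (covariate names), `references`
#' (covariate -> reference level), `continuous`, `max_grid`, `hyperprior`
#' (`shape`, `rate`), and `mcmc` (`iterations`, `burn_in`, `thinning`).
#' All fields are optional; package defaults fill the gaps.
#'
#' @param path JSON file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

config_model_spec <- function(config, model_id) {
  args <- list(model_id = model_id)
  if (!is.null(config$fixed)) args$fixed <- config$fixed
  if (!is.null(config$references)) args$references <- unlist(config$references)
  if (!is.null(config$continuous)) args$continuous <- config$continuous
  if (!is.null(config$max_grid)) args$max_grid <- config$max_grid
  if (!is.null(config$hyperprior)) {
    args$hyperprior <- c(shape = config$hyperprior$shape,
                         rate = config$hyperprior$rate)
  }
  if (!is.null(config$iid_district)) args$iid_district <- config$iid_district
  do.call(model_spec, args)
}

config_mcmc <- function(config, seed) {
  m <- config$mcmc %||% list()
  mcmc_settings(iterations = m$iterations %||% 12000,
                burn_in = m$burn_in %||% 2000,
                thinning = m$thinning %||% 5,
                seed = seed)
}

write_manifest <- function(dir, config, seed) {
  jsonlite::write_json(
    list(config = config, seed = seed,
         package = "geoadditive",
         version = as.character(utils::packageVersion("geoadditive"))),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
}

#' Read polygons from a GeoJSON file (map rendering only)
#'
#' Minimal GeoJSON reader for choropleth rendering: extracts Polygon /
#' MultiPolygon features and the region id property.  This is never used to
#' derive adjacency by default — see [adjacency_from_geojson()] for the
#' explicit opt-in builder.
#'
#' @param path GeoJSON file.
#' @param id_property name of the feature property holding the region id.
#' @return tibble with columns `region_id`, `ring`, `x`, `y` (one row per
#'   vertex, rings in drawing order).
#' @export
read_geojson_polygons <- function(path, id_property = "id") {
  js <- jsonlite::read_json(path)
  if (is.null(js$features)) stop("not a GeoJSON FeatureCollection", call. = FALSE)
  rows <- list()
  ring_n <- 0L
  for (ft in js$features) {
    rid <- ft$properties[[id_property]]
    if (is.null(rid)) stop("feature missing property `", id_property, "`",
                           call. = FALSE)
    geom <- ft$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    )
    for (poly in polys) {
      for (ring in poly) {
        ring_n <- ring_n + 1L
        xy <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
        rows[[ring_n]] <- tibble::tibble(
          region_id = as.integer(rid), ring = ring_n,
          x = xy[, 1], y = xy[, 2]
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Derive adjacency from GeoJSON polygons (explicit opt-in)
#'
#' Builds an [adjacency_graph()] by declaring two regions neighbours when
#' their polygons share at least one vertex (coordinates rounded to
#' `digits`).  Vertex-sharing is a crude topology test; prefer a curated
#' neighbour-list file ([read_graph_file()]) whenever one exists, which is
#' why this builder sits behind its own function and is never called by the
#' default map path.
#'
#' @param path GeoJSON file.
#' @param id_property feature property holding the region id.
#' @param digits coordinate rounding used to match shared vertices.
#' @return an `adjacency_graph`.
#' @export
adjacency_from_geojson <- function(path, id_property = "id", digits = 6) {
  pol <- read_geojson_polygons(path, id_property)
  pol$key <- paste(round(pol$x, digits), round(pol$y, digits))
  ids <- sort(unique(pol$region_id))
  nb <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) nb[[i]] <- integer(0)
  by_key <- split(pol$region_id, pol$key)
  for (regions in by_key) {
    u <- unique(regions)
    if (length(u) < 2) next
    for (a in u) {
      others <- setdiff(u, a)
      k <- match(a, ids)
      nb[[k]] <- union(nb[[k]], others)
    }
  }
  adjacency_graph(nb)
}
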