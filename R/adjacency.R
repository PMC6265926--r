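#' District adjacency graphs
#'
#' An `adjacency_graph` holds the neighbourhood structure of a set of
#' administrative areas (districts): the ordered region ids, optional display
#' labels, and one neighbour set per region.  It is the spatial backbone of
#' the intrinsic conditional autoregressive (ICAR) prior: two districts are
#' conditionally dependent iff they are neighbours.
#'
#' @param neighbors named list; one integer vector of neighbouring region ids
#'   per region.  Names are the region ids.
#' @param labels optional character vector of display names, same length and
#'   order as the regions.  Labels are display metadata only, never identity
#'   (duplicate labels are allowed).
#' @return an object of class `adjacency_graph` with fields `region_ids`,
#'   `labels` and `neighbors`.
#' @examples
#' g <- adjacency_graph(list(`1` = 2L, `2` = c(1L, 3L), `3` = 2L))
#' n_regions(g)
#' @export
adjacency_graph <- function(neighbors, labels = NULL) {
  if (!is.list(neighbors) || is.null(names(neighbors))) {
    stop("`neighbors` must be a named list (names are region ids)", call. = FALSE)
  }
  ids <- suppressWarnings(as.integer(names(neighbors)))
  if (anyNA(ids)) stop("region ids must be integers", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate region id: ", paste(ids[duplicated(ids)], collapse = ", "),
         call. = FALSE)
  }
  nb <- lapply(neighbors, function(v) sort(unique(as.integer(v))))
  names(nb) <- ids
  g <- structure(
    list(region_ids = ids, labels = labels, neighbors = nb),
    class = "adjacency_graph"
  )
  validate_graph(g)
  g
}

validate_graph <- function(g) {
  ids <- g$region_ids
  if (!is.null(g$labels) && length(g$labels) != length(ids)) {
    stop("`labels` must have one entry per region", call. = FALSE)
  }
  for (i in seq_along(ids)) {
    nb <- g$neighbors[[i]]
    if (any(nb == ids[i])) {
      stop("self-loop at region ", ids[i], call. = FALSE)
    }
    unknown <- setdiff(nb, ids)
    if (length(unknown)) {
      stop("region ", ids[i], " lists unknown neighbor(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (k in nb) {
      back <- g$neighbors[[match(k, ids)]]
      if (!(ids[i] %in% back)) {
        stop(sprintf("asymmetric adjacency: %d lists %d but %d does not list %d",
                     ids[i], k, k, ids[i]), call. = FALSE)
      }
    }
  }
  invisible(g)
}

#' @rdname adjacency_graph
#' @param g an `adjacency_graph`.
#' @export
n_regions <- function(g) length(g$region_ids)

#' @export
print.adjacency_graph <- function(x, ...) {
  ncomp <- length(unique(connected_components(x)))
  nedge <- sum(lengths(x$neighbors)) / 2
  cat(sprintf("<adjacency_graph> %d regions, %d edges, %d component%s\n",
              n_regions(x), nedge, ncomp, if (ncomp == 1) "" else "s"))
  invisible(x)
}

#' Rook-neighbour lattice adjacency
#'
#' Builds a rows x cols rectangular lattice in which regions sharing an edge
#' are neighbours.  The 5 x 6 lattice (30 regions) is the package's default
#' stand-in for a 30-district national map when no real adjacency file is
#' supplied.
#'
#' @param rows,cols lattice dimensions, both >= 1.
#' @return an `adjacency_graph` with `rows * cols` regions numbered row-wise
#'   from 1, carrying a `lattice_dim` attribute used by the map plot.
#' @examples
#' make_lattice_adjacency(5, 6)
#' @export
make_lattice_adjacency <- function(rows, cols) {
  rows <- assert_count(rows, "rows")
  cols <- assert_count(cols, "cols")
  idx <- function(r, c) (r - 1L) * cols + c
  nb <- vector("list", rows * cols)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      v <- integer(0)
      if (r > 1L)    v <- c(v, idx(r - 1L, c))
      if (r < rows)  v <- c(v, idx(r + 1L, c))
      if (c > 1L)    v <- c(v, idx(r, c - 1L))
      if (c < cols)  v <- c(v, idx(r, c + 1L))
      nb[[idx(r, c)]] <- v
    }
  }
  names(nb) <- seq_len(rows * cols)
  g <- adjacency_graph(nb)
  attr(g, "lattice_dim") <- c(rows = rows, cols = cols)
  g
}

#' Read / write a plain-text neighbour-list graph file
#'
#' The file dialect is the classic disease-mapping one: the first line holds
#' the number of regions D; then, for each region, three lines follow — the
#' region id, its neighbour count, and the space-separated neighbour region
#' ids (an empty third line for isolated regions).  Adjacency must be
#' symmetric; an asymmetric file fails to load, naming the offending pair.
#'
#' @param path file path.
#' @return `read_graph_file()` returns an `adjacency_graph`;
#'   `write_graph_file()` returns `path` invisibly.
#' @export
read_graph_file <- function(path) {
  if (!file.exists(path)) stop("graph file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  d <- suppressWarnings(as.integer(lines[[1]]))
  if (is.na(d) || d < 1L) stop("first line must be the region count", call. = FALSE)
  if (length(lines) < 1L + 3L * d) {
    stop("graph file truncated: expected ", 1L + 3L * d, " lines", call. = FALSE)
  }
  nb <- vector("list", d)
  ids <- integer(d)
  for (j in seq_len(d)) {
    base <- 1L + 3L * (j - 1L)
    ids[j] <- as.integer(lines[[base + 1L]])
    cnt <- as.integer(lines[[base + 2L]])
    vals <- scan(text = lines[[base + 3L]], what = integer(), quiet = TRUE)
    if (length(vals) != cnt) {
      stop(sprintf("region %d declares %d neighbors but lists %d",
                   ids[j], cnt, length(vals)), call. = FALSE)
    }
    nb[[j]] <- vals
  }
  if (anyDuplicated(ids)) {
    stop("duplicate region id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  names(nb) <- ids
  adjacency_graph(nb)
}

#' @rdname read_graph_file
#' @param g an `adjacency_graph`.
#' @export
write_graph_file <- function(g, path) {
  stopifnot(inherits(g, "adjacency_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n_regions(g)), con)
  for (j in seq_along(g$region_ids)) {
    writeLines(as.character(g$region_ids[j]), con)
    writeLines(as.character(length(g$neighbors[[j]])), con)
    writeLines(paste(g$neighbors[[j]], collapse = " "), con)
  }
  invisible(path)
}

#' Connected components of an adjacency graph
#'
#' @param g an `adjacency_graph`.
#' @return integer vector of component labels (1, 2, ...), named by region id;
#'   two regions share a label iff a path of neighbour steps connects them.
#' @export
connected_components <- function(g) {
  stopifnot(inherits(g, "adjacency_graph"))
  ids <- g$region_ids
  d <- length(ids)
  comp <- rep(NA_integer_, d)
  label <- 0L
  for (start in seq_len(d)) {
    if (!is.na(comp[start])) next
    label <- label + 1L
    queue <- start
    comp[start] <- label
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (k in match(g$neighbors[[v]], ids)) {
        if (is.na(comp[k])) {
          comp[k] <- label
          queue <- c(queue, k)
        }
      }
    }
  }
  stats::setNames(comp, ids)
}

#' ICAR precision matrix of an adjacency graph
#'
#' Builds the intrinsic conditional autoregressive structure matrix
#' Q = diag(n_j) - A, where n_j is the neighbour count of region j and A the
#' 0/1 adjacency matrix.  Q is symmetric positive semidefinite with every row
#' summing to zero and rank D - (number of connected components); the ICAR
#' prior on a spatial field f is the improper Gaussian density
#' proportional to exp(-tau/2 * t(f) Q f).
#'
#' @param g an `adjacency_graph`.
#' @return a D x D base matrix with dimnames the region ids.
#' @export
icar_precision <- function(g) {
  stopifnot(inherits(g, "adjacency_graph"))
  ids <- g$region_ids
  d <- length(ids)
  q <- matrix(0, d, d, dimnames = list(ids, ids))
  for (j in seq_len(d)) {
    nb <- match(g$neighbors[[j]], ids)
    q[j, nb] <- -1
    q[j, j] <- length(nb)
  }
  q
}
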