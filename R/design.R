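#' Dummy-code categorical covariates against stated reference levels
#'
#' Builds the fixed-effect design matrix W: an intercept column of ones plus
#' one 0/1 treatment-coded dummy column per non-reference level of each
#' covariate, so each coefficient exponentiates to an odds ratio against the
#' named reference.
#'
#' @param data a data frame with one row per record.
#' @param references named character vector or list mapping each covariate to
#'   its reference level; every named covariate must be a column of `data`
#'   and every reference level must occur in it.
#' @return an object of class `fixed_design`: list with `matrix`
#'   (n x (1 + P) base matrix), `column_labels`, `reference_levels`, and
#'   `levels` (the full level sets, reference first, used to validate new
#'   data).
#' @examples
#' d <- data.frame(education = c("none", "primary", "primary", "tertiary"))
#' fd <- encode_fixed(d, c(education = "none"))
#' fd$column_labels
#' @export
encode_fixed <- function(data, references) {
  references <- unlist(references)
  missing_cov <- setdiff(names(references), names(data))
  if (length(missing_cov)) {
    stop("covariate(s) not in data: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  level_sets <- list()
  for (cov in names(references)) {
    vals <- as.character(data[[cov]])
    ref <- references[[cov]]
    if (!ref %in% vals) {
      stop("reference level `", ref, "` does not occur in `", cov, "`",
           call. = FALSE)
    }
    level_sets[[cov]] <- c(ref, sort(setdiff(unique(vals), ref)))
  }
  design <- structure(
    list(column_labels = NULL, reference_levels = references,
         levels = level_sets),
    class = "fixed_design"
  )
  design$matrix <- fixed_design_rows(design, data)
  design$column_labels <- colnames(design$matrix)
  design
}

#' @rdname encode_fixed
#' @description `fixed_design_rows()` re-applies an existing coding to new
#'   records (for prediction), erroring on any level unseen at encoding time.
#' @param design a `fixed_design`.
#' @export
fixed_design_rows <- function(design, data) {
  stopifnot(inherits(design, "fixed_design"))
  n <- nrow(data)
  blocks <- list(`(Intercept)` = rep(1, n))
  for (cov in names(design$levels)) {
    levs <- design$levels[[cov]]
    idx <- match(as.character(data[[cov]]), levs)
    if (anyNA(idx)) {
      bad <- unique(as.character(data[[cov]])[is.na(idx)])
      stop("unseen level(s) in `", cov, "`: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (l in seq_along(levs)[-1]) {
      blocks[[paste0(cov, ":", levs[l])]] <- as.numeric(idx == l)
    }
  }
  m <- do.call(cbind, blocks)
  rownames(m) <- NULL
  m
}

#' Decode a fixed design matrix back to covariate levels
#'
#' Inverse of [encode_fixed()]: reconstructs the categorical columns from the
#' dummy columns (a row with all dummies of a covariate zero is at the
#' reference level).
#'
#' @param design a `fixed_design`.
#' @param matrix optionally, a matrix of rows produced by
#'   [fixed_design_rows()]; defaults to the training matrix.
#' @return tibble of the reconstructed categorical covariates.
#' @export
decode_fixed <- function(design, matrix = design$matrix) {
  out <- list()
  for (cov in names(design$levels)) {
    levs <- design$levels[[cov]]
    cols <- paste0(cov, ":", levs[-1])
    sub <- matrix[, cols, drop = FALSE]
    which_lev <- apply(sub, 1, function(r) {
      j <- which(r == 1)
      if (length(j) == 0) 1L else j + 1L
    })
    out[[cov]] <- levs[which_lev]
  }
  tibble::as_tibble(out)
}

#' Second-order random-walk (RW2) penalty matrix
#'
#' Returns K = t(D2) %*% D2 with D2 the (m-2) x m second-difference operator,
#' the precision structure of the RW2 smoothness prior: the prior density of
#' a function f over the grid is proportional to exp(-tau/2 * t(f) K f),
#' penalising squared second differences.  K is symmetric positive
#' semidefinite of rank m - 2; its null space is spanned by the constant and
#' the linear vector, so level and trend are left to the likelihood (and to
#' the identifiability constraints).  Grid points are assumed equally spaced
#' (both age covariates are recorded in whole years).
#'
#' @param grid strictly increasing numeric vector of m >= 3 grid points.
#' @return m x m base matrix.
#' @examples
#' rw2_penalty(1:3)
#' @export
rw2_penalty <- function(grid) {
  m <- length(grid)
  if (m < 3) stop("RW2 penalty needs at least 3 grid points", call. = FALSE)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  d2 <- matrix(0, m - 2, m)
  for (i in seq_len(m - 2)) d2[i, i:(i + 2)] <- c(1, -2, 1)
  crossprod(d2)
}

#' Build the structure of one smooth model term
#'
#' Maps each record to a point of a finite evaluation grid of the covariate
#' and attaches the RW2 penalty over that grid.  If the covariate has at most
#' `max_grid` distinct values the grid is those values; otherwise it is the
#' midpoints of `max_grid` equal-width bins.
#'
#' @param data a data frame.
#' @param covariate name of a numeric column.
#' @param max_grid maximum grid size (>= 3).
#' @param truncate optional `c(lo, hi)`: values are clamped into this range
#'   before gridding (used e.g. to pull implausible ages at first
#'   cohabitation above the eligible range back to its boundary, so they do
#'   not create an isolated grid tail).
#' @param tau_prior Gamma hyperprior (shape, rate) on the smoothing precision.
#' @return an object of class `smooth_term`: list with `covariate`, `grid`,
#'   `incidence` (sparse n x m 0/1 matrix, one 1 per row), `penalty`
#'   (m x m RW2 matrix) and `tau_prior`.
#' @export
smooth_design <- function(data, covariate, max_grid = 50, truncate = NULL,
                          tau_prior = c(shape = 1, rate = 5e-4)) {
  if (!covariate %in% names(data)) {
    stop("covariate `", covariate, "` not in data", call. = FALSE)
  }
  x <- data[[covariate]]
  if (!is.numeric(x)) stop("covariate `", covariate, "` must be numeric", call. = FALSE)
  if (anyNA(x)) stop("covariate `", covariate, "` has missing values", call. = FALSE)
  max_grid <- assert_count(max_grid, "max_grid", min = 3L)
  if (!is.null(truncate)) x <- pmin(pmax(x, truncate[1]), truncate[2])
  ux <- sort(unique(x))
  if (length(ux) < 2) {
    stop("covariate `", covariate, "` is constant; no smooth possible", call. = FALSE)
  }
  if (length(ux) <= max_grid) {
    grid <- ux
    idx <- match(x, grid)
  } else {
    breaks <- seq(min(x), max(x), length.out = max_grid + 1)
    grid <- (breaks[-1] + breaks[-length(breaks)]) / 2
    idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  }
  m <- length(grid)
  if (m < 3) stop("fewer than 3 grid points for `", covariate, "`", call. = FALSE)
  incidence <- Matrix::sparseMatrix(i = seq_along(x), j = idx, x = 1,
                                    dims = c(length(x), m))
  structure(
    list(covariate = covariate, grid = grid, incidence = incidence,
         penalty = rw2_penalty(grid), tau_prior = tau_prior),
    class = "smooth_term"
  )
}
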