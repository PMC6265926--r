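#' Prevalence of contraceptive use by method type
#'
#' Tabulates the three-way method mix (none / traditional / modern) with
#' counts and percentages of the total, percentages rounded half-up to one
#' decimal in the print convention of survey reports.
#'
#' @param data data frame with a method-type column.
#' @param method_col name of the column; values must be among
#'   "none", "traditional", "modern".
#' @return tibble with rows none/traditional/modern and columns `method`,
#'   `n`, `pct`.
#' @export
prevalence_by_method <- function(data, method_col = "method_type") {
  if (!method_col %in% names(data)) {
    stop("no `", method_col, "` column", call. = FALSE)
  }
  v <- as.character(data[[method_col]])
  known <- c("none", "traditional", "modern")
  bad <- setdiff(unique(v), known)
  if (length(bad)) {
    stop("unknown method label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- vapply(known, function(k) sum(v == k), numeric(1))
  tibble::tibble(method = known, n = unname(n),
                 pct = round_half_up(100 * unname(n) / length(v), 1))
}

#' Cross-tabulate a covariate against the binary outcome
#'
#' Builds the level x (non-user / user) contingency table with row
#' percentages and tests independence with the Pearson chi-square statistic
#' (no continuity correction by default, matching plain chi-square reporting
#' for tables that include multi-level covariates).  Levels with zero
#' marginal total are dropped from the test with a warning rather than
#' erroring.
#'
#' @param data data frame.
#' @param covariate name of a categorical column.
#' @param outcome name of the 0/1 outcome column.
#' @param alpha significance level for the `significant` flag.
#' @param correct apply the Yates continuity correction (2x2 tables only).
#' @return a tibble of class `crosstab` with columns `level`, `n_nonuser`,
#'   `pct_nonuser`, `n_user`, `pct_user`, and attributes `statistic`, `df`,
#'   `p_value`, `significant`.
#' @export
crosstab <- function(data, covariate, outcome = "outcome", alpha = 0.05,
                     correct = FALSE) {
  if (!covariate %in% names(data)) stop("no `", covariate, "` column", call. = FALSE)
  if (!outcome %in% names(data)) stop("no `", outcome, "` column", call. = FALSE)
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1", call. = FALSE)
  lev <- data[[covariate]]
  if (!is.factor(lev)) lev <- factor(as.character(lev))
  tab <- table(lev, factor(y, levels = c(0, 1)))
  zero <- rowSums(tab) == 0
  if (any(zero)) {
    warning("dropping zero-count level(s): ",
            paste(rownames(tab)[zero], collapse = ", "))
    tab <- tab[!zero, , drop = FALSE]
  }
  if (nrow(tab) < 2) {
    stop("covariate `", covariate, "` has a single level; test undefined",
         call. = FALSE)
  }
  test <- stats::chisq.test(tab, correct = correct)
  out <- tibble::tibble(
    level = rownames(tab),
    n_nonuser = as.integer(tab[, 1]),
    pct_nonuser = round_half_up(100 * tab[, 1] / rowSums(tab), 1),
    n_user = as.integer(tab[, 2]),
    pct_user = round_half_up(100 * tab[, 2] / rowSums(tab), 1)
  )
  attr(out, "statistic") <- unname(test$statistic)
  attr(out, "df") <- unname(test$parameter)
  attr(out, "p_value") <- unname(test$p.value)
  attr(out, "significant") <- unname(test$p.value < alpha)
  class(out) <- c("crosstab", class(out))
  out
}

#' @export
print.crosstab <- function(x, ...) {
  NextMethod()
  cat(sprintf("chi-square = %.4f, df = %d, p = %.4g%s\n",
              attr(x, "statistic"), attr(x, "df"), attr(x, "p_value"),
              if (attr(x, "significant")) " (significant at 5%)" else ""))
  invisible(x)
}

#' Screen covariates by chi-square association with the outcome
#'
#' The univariate gate that precedes the multivariate model: each covariate
#' is cross-tabulated against the outcome and flagged for inclusion when its
#' chi-square p-value is below `alpha` (5% by default).  Input order is
#' preserved.
#'
#' @param data data frame.
#' @param covariates character vector of categorical covariate names.
#' @param alpha significance level.
#' @param outcome name of the 0/1 outcome column.
#' @return tibble with columns `covariate`, `statistic`, `df`, `p_value`,
#'   `significant`; the selected set is `covariate[significant]`.
#' @export
screen_covariates <- function(data, covariates, alpha = 0.05,
                              outcome = "outcome") {
  rows <- lapply(covariates, function(cov) {
    ct <- crosstab(data, cov, outcome = outcome, alpha = alpha)
    tibble::tibble(covariate = cov,
                   statistic = attr(ct, "statistic"),
                   df = attr(ct, "df"),
                   p_value = attr(ct, "p_value"),
                   significant = attr(ct, "p_value") < alpha)
  })
  dplyr::bind_rows(rows)
}

#' Expand printed contingency counts to record-level data
#'
#' Reconstructs a record-level tibble from a published counts table (one row
#' per covariate level with non-user and user counts), so the package's
#' descriptive functions can be run on printed tables exactly as on raw
#' extracts.
#'
#' @param counts data frame with columns `level`, `n_nonuser`, `n_user`.
#' @param covariate name to give the covariate column.
#' @return tibble with columns `outcome` (0/1) and `<covariate>`.
#' @export
survey_from_counts <- function(counts, covariate = "covariate") {
  stopifnot(all(c("level", "n_nonuser", "n_user") %in% names(counts)))
  out <- tibble::tibble(
    outcome = unlist(lapply(seq_len(nrow(counts)), function(i) {
      rep(c(0L, 1L), c(counts$n_nonuser[i], counts$n_user[i]))
    })),
    lev = unlist(lapply(seq_len(nrow(counts)), function(i) {
      rep(counts$level[i], counts$n_nonuser[i] + counts$n_user[i])
    }))
  )
  names(out)[2] <- covariate
  out
}
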