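# Power-law normalization of CTSS tag counts onto a referent distribution.
#
# CAGE libraries follow an approximate power law in their reverse-cumulative
# count distribution: N(>= x), the number of CTSSs with at least x tags, is
# close to linear in log-log space. Mapping each library onto a shared
# referent power law (slope alpha_ref, total 1e6 tags) makes expression
# values comparable across libraries of different depth and slope.

#' Fit the reverse-cumulative power law of a tag-count library
#'
#' For each distinct count value x inside `fit_range`, computes
#' N(>= x) = number of CTSSs with count >= x, and fits ordinary least
#' squares on (log10 x, log10 N(>= x)). The fitted slope's magnitude is
#' `alpha`. Fitting on distinct values (not per-CTSS replicated points)
#' avoids overweighting the singleton count mass.
#'
#' @param table a [ctss_table()], or a numeric vector of counts.
#' @param fit_range length-2 numeric, count bounds used in the fit
#'   (default `c(10, 1000)`).
#' @return An object of class `power_law_fit` with elements `alpha`,
#'   `fit_range`, `intercept` (log10 scale), `n_points`.
#' @export
fit_power_law <- function(table, fit_range = c(10, 1000)) {
  counts <- if (is.data.frame(table)) {
    assert_ctss(table)
    table$count
  } else as.numeric(table)
  stopifnot(length(fit_range) == 2L, fit_range[1] < fit_range[2])
  if (any(counts <= 0)) stop("non-positive counts")
  x <- sort(unique(counts))
  x <- x[x >= fit_range[1] & x <= fit_range[2]]
  if (length(x) < 2L) {
    stop("degenerate input: fewer than 2 distinct count values in fit range; ",
         "consider the simple-TPM fallback (normalize_tpm)")
  }
  n_ge <- vapply(x, function(v) sum(counts >= v), numeric(1))
  fit <- stats::lm.fit(cbind(1, log10(x)), log10(n_ge))
  out <- list(alpha = -unname(fit$coefficients[2]),
              intercept = unname(fit$coefficients[1]),
              fit_range = fit_range, n_points = length(x))
  class(out) <- "power_law_fit"
  out
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: alpha = %.4f over counts [%g, %g] (%d points)\n",
              x$alpha, x$fit_range[1], x$fit_range[2], x$n_points))
  invisible(x)
}

#' Normalize a library onto a referent power law
#'
#' Maps raw counts onto the referent distribution with slope `alpha_ref`
#' via `tpm_i = scale * count_i^(alpha/alpha_ref)`, with `scale` chosen so
#' that the normalized totals sum to `total` (1e6 by default, i.e. tags per
#' million). The map is strictly increasing, so count ranks are preserved
#' exactly. When `alpha == alpha_ref` this reduces to simple per-million
#' scaling.
#'
#' @param table a [ctss_table()] with raw counts.
#' @param fit a [fit_power_law()] result; fitted from `table` when `NULL`.
#' @param alpha_ref slope of the referent distribution (default 1.25).
#' @param total normalized library total (default 1e6).
#' @param fit_range passed to [fit_power_law()] when `fit` is `NULL`.
#' @return The table with a `tpm` column; the fit and scale are attached as
#'   attributes `power_law_fit` and `scale`.
#' @seealso [normalize_tpm()] for the depth-only fallback.
#' @export
normalize_power_law <- function(table, fit = NULL, alpha_ref = 1.25,
                                total = 1e6, fit_range = c(10, 1000)) {
  assert_ctss(table)
  if (any(table$count <= 0)) stop("non-positive counts")
  stopifnot(alpha_ref > 0, total > 0)
  if (is.null(fit)) fit <- fit_power_law(table, fit_range)
  stopifnot(inherits(fit, "power_law_fit"))
  raw <- table$count ^ (fit$alpha / alpha_ref)
  scale <- total / sum(raw)
  table$tpm <- scale * raw
  attr(table, "power_law_fit") <- fit
  attr(table, "scale") <- scale
  attr(table, "alpha_ref") <- alpha_ref
  table
}

#' Simple tags-per-million normalization
#'
#' Depth-only fallback for libraries whose count distribution is too
#' degenerate to fit a power law: `tpm_i = count_i * total / sum(count)`.
#'
#' @inheritParams normalize_power_law
#' @return The table with a `tpm` column.
#' @export
normalize_tpm <- function(table, total = 1e6) {
  assert_ctss(table)
  if (any(table$count <= 0)) stop("non-positive counts")
  table$tpm <- table$count * total / sum(table$count)
  table
}
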