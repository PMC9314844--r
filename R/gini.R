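# Spatial heterogeneity of habitat quality: weighted Gini coefficient of
# patch mean breeding success and its association with population mean
# success.

#' Weighted Gini coefficient
#'
#' Dispersion of patch-level values weighted by patch size:
#' `G = sum_ij w_i w_j |v_i - v_j| / (2 (sum w)^2 vbar)` with `vbar` the
#' weighted mean. `G` is 0 under perfect equality and approaches 1 when the
#' total is concentrated in a vanishing weight share. No small-sample
#' correction factor is applied.
#'
#' @param values non-negative values (e.g. mean fledglings per nest per patch).
#' @param weights positive weights (e.g. occupied nests per patch).
#' @return The Gini coefficient in `[0, 1)`, or `NA` when the weighted mean is
#'   zero (dispersion undefined).
#' @export
#' @examples
#' weighted_gini(c(0, 1), c(1, 1))   # 0.5, any two-point (0, x) split
#' weighted_gini(c(3, 3, 3), 1:3)    # 0, perfect equality
weighted_gini <- function(values, weights = rep(1, length(values))) {
  check_nonneg(values, "values")
  if (length(values) != length(weights)) {
    bp_stop("'values' and 'weights' must have equal length")
  }
  if (!is.numeric(weights) || anyNA(weights) || any(weights <= 0)) {
    bp_stop("'weights' must be positive")
  }
  if (length(values) < 2L) bp_stop("need at least 2 values")
  w <- weights / sum(weights)
  vbar <- sum(w * values)
  if (vbar == 0) return(NA_real_)
  # sorted closed form: sum_ij w_i w_j |v_i - v_j| = 2 sum_i v_(i) w_(i) F_(i-1) ...
  # kept as the O(n^2) double sum; patch counts are small
  mad <- sum(outer(w, w) * abs(outer(values, values, "-")))
  mad / (2 * vbar)
}

#' Heterogeneity prerequisite check
#'
#' For each year with at least two occupied patches, computes the nest-weighted
#' mean breeding success (fledglings per nest) and the weighted Gini
#' coefficient of patch mean success, then the product-moment correlation
#' between the two annual series. A strongly negative correlation indicates
#' that good years are years when quality is high across many patches
#' (low spatial heterogeneity), the prerequisite for reading population
#' breeding success as availability of high-quality sites.
#'
#' @param table data.frame with columns `year`, `patch`, `n_nests`,
#'   `n_fledglings`; patches with zero nests are excluded from that year.
#' @return list of class `prerequisite_check`: `per_year` (year, mean success,
#'   Gini, patches), `correlation`, `fit` (linear model of Gini on mean
#'   success, for plotting with a confidence band), `n_years`.
#' @export
prerequisite_check <- function(table) {
  need <- c("year", "patch", "n_nests", "n_fledglings")
  if (!all(need %in% names(table))) {
    bp_stop(sprintf("patch table must have columns %s", paste(need, collapse = ", ")))
  }
  check_nonneg(table$n_nests, "n_nests")
  check_nonneg(table$n_fledglings, "n_fledglings")
  years <- sort(unique(table$year))
  rows <- lapply(years, function(y) {
    d <- table[table$year == y & table$n_nests > 0, , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    v <- d$n_fledglings / d$n_nests
    w <- d$n_nests
    data.frame(year = y,
               mean_success = sum(d$n_fledglings) / sum(d$n_nests),
               gini = weighted_gini(v, w),
               n_patches = nrow(d))
  })
  per_year <- do.call(rbind, rows)
  if (is.null(per_year) || nrow(per_year) < 3L) {
    bp_stop("need at least 3 years with >= 2 occupied patches")
  }
  ok <- complete.cases(per_year)
  per_year_ok <- per_year[ok, , drop = FALSE]
  if (nrow(per_year_ok) < 3L || sd(per_year_ok$gini) == 0 ||
      sd(per_year_ok$mean_success) == 0) {
    warning("Gini or mean success has no variation; correlation undefined")
    corr <- NA_real_
    fit <- NULL
  } else {
    corr <- cor(per_year_ok$mean_success, per_year_ok$gini)
    fit <- lm(gini ~ mean_success, data = per_year_ok)
  }
  structure(list(per_year = per_year, correlation = corr, fit = fit,
                 n_years = nrow(per_year)),
            class = "prerequisite_check")
}

#' @export
print.prerequisite_check <- function(x, ...) {
  cat(sprintf("Spatial-heterogeneity prerequisite: %d years\n", x$n_years))
  cat(sprintf("  mean success %.3f .. %.3f; Gini %.3f .. %.3f\n",
              min(x$per_year$mean_success), max(x$per_year$mean_success),
              min(x$per_year$gini, na.rm = TRUE),
              max(x$per_year$gini, na.rm = TRUE)))
  cat(sprintf("  Pearson r(mean success, Gini) = %s\n",
              ifelse(is.na(x$correlation), "NA",
                     sprintf("%.3f", x$correlation))))
  invisible(x)
}
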