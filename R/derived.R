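# Derived posterior quantities and the partial-correlation analyses.
# Everything is computed per posterior draw, never on posterior means.

#' Breeding population growth rate
#'
#' `lambda[t] = B[t] / B[t-1]` for `t = 2..T`. The product of the series
#' telescopes to `B[T] / B[1]`.
#'
#' @param B breeder totals (> 0).
#' @return Numeric vector of length `length(B) - 1`.
#' @export
growth_rate <- function(B) {
  B <- as.numeric(B)
  if (length(B) < 2L) bp_stop("need at least 2 years")
  if (any(B == 0)) bp_stop("zero breeder total: growth rate undefined")
  B[-1L] / B[-length(B)]
}

#' Integrative recruitment rate
#'
#' Age-pooled breeding propensity of pre-breeders: the proportion of
#' first-time breeders among the local individuals of recruitable age alive
#' in the current year, i.e. local recruits divided by local recruits plus
#' surviving never-bred pre-breeders of ages 3--6. Immigrants are excluded
#' from numerator and denominator.
#'
#' @param recruits local recruits entering the breeder class each year.
#' @param available surviving non-recruited pre-breeders of ages 3--6 in the
#'   same years.
#' @return Proportions; `NA` where no individual was available.
#' @export
integrative_recruitment <- function(recruits, available) {
  den <- recruits + available
  ifelse(den > 0, recruits / den, NA_real_)
}

#' Immigration rate
#'
#' Proportion of immigrants among breeders, `I[t] / B[t]`, using the raw
#' (possibly negative) immigrant number so that evidence against immigration
#' is preserved.
#'
#' @param I immigrant numbers.
#' @param B breeder totals (> 0).
#' @return Numeric vector (may be negative).
#' @export
immigration_rate <- function(I, B) {
  if (any(B == 0)) bp_stop("zero breeder total: immigration rate undefined")
  I / B
}

#' Present non-breeders
#'
#' Number of non-breeders attending the colonies: pre-breeders of ages 2--6
#' discounted by their resighting probability plus skippers discounted by the
#' recruited-bird resighting probability (yearlings, essentially absent from
#' the colonies, are not included).
#'
#' @param P_total pre-breeders of ages 2--6 (sum over classes).
#' @param S skipper numbers.
#' @param p_p pre-breeder resighting probability (recycled).
#' @param p_r breeder/skipper resighting probability.
#' @return Expected numbers present.
#' @export
present_nonbreeders <- function(P_total, S, p_p, p_r) {
  check_prob(p_p, "p_p"); check_prob(p_r, "p_r")
  P_total * p_p + S * p_r
}

#' Among-breeder composition
#'
#' Proportions of the four origins among current breeders: former breeders
#' (bred in the previous year), former skippers, local first-time breeders
#' and immigrants. Computed from the latent transition counts, so the four
#' proportions sum to one exactly.
#'
#' @param former_b,former_s,local_first,immigrants origin counts per year.
#' @return Matrix with one row per year and four proportion columns.
#' @export
breeder_composition <- function(former_b, former_s, local_first, immigrants) {
  B <- former_b + former_s + local_first + immigrants
  if (any(B == 0)) bp_stop("zero breeder total: composition undefined")
  cbind(former_breeder = former_b / B,
        former_skipper = former_s / B,
        local_first_time = local_first / B,
        immigrant = immigrants / B)
}

#' Partial correlation
#'
#' Correlation between `y` and `x` after removing the linear effect of the
#' control series from both (residuals of least-squares projections on
#' `[1, controls]`). Without controls this is the plain product-moment
#' correlation.
#'
#' @param y,x numeric series.
#' @param controls optional numeric matrix (columns = control series) or
#'   vector.
#' @return The partial correlation, or `NA` when a residual variance is zero.
#' @export
partial_correlation <- function(y, x, controls = NULL) {
  y <- as.numeric(y); x <- as.numeric(x)
  n <- length(y)
  if (length(x) != n) bp_stop("'y' and 'x' lengths differ")
  if (anyNA(y) || anyNA(x)) bp_stop("missing values in series")
  if (is.null(controls) || (is.matrix(controls) && ncol(controls) == 0L)) {
    if (sd(y) == 0 || sd(x) == 0) return(NA_real_)
    return(cor(y, x))
  }
  Z <- as.matrix(controls)
  if (nrow(Z) != n) bp_stop("controls length differs from series")
  if (anyNA(Z)) bp_stop("missing values in controls")
  if (n < ncol(Z) + 3L) bp_stop("series too short for the number of controls")
  X <- cbind(1, Z)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) bp_stop("collinear controls")
  ry <- qr.resid(qrX, y)
  rx <- qr.resid(qrX, x)
  if (sd(ry) < 1e-12 * max(sd(y), 1) || sd(rx) < 1e-12 * max(sd(x), 1)) {
    return(NA_real_)
  }
  cor(ry, rx)
}

#' Sign-support statistic
#'
#' Fraction of a posterior sample sharing the sign of its mean; exact zeros
#' match neither sign and a zero mean gives 0.5 by convention. Values near 1
#' indicate strong evidence for an effect of that sign; values near 0.5,
#' none.
#'
#' @param samples numeric posterior sample (NAs dropped).
#' @return `P` in `[0, 1]`.
#' @export
sign_support <- function(samples) {
  samples <- samples[!is.na(samples)]
  if (!length(samples)) bp_stop("empty sample")
  m <- mean(samples)
  if (m == 0) return(0.5)
  mean(sign(samples) == sign(m))
}

# --- per-draw series extracted from posterior draws ------------------------

# Named year-indexed series as [draw x year] matrices. Year labels are the
# calendar positions used for alignment in the correlation analyses.
derived_series <- function(draws) {
  m <- draws_matrix(draws)
  T <- draws$n_years
  tv <- draws$time_varying
  grab <- function(fmt, years) {
    out <- m[, sprintf(fmt, years), drop = FALSE]
    colnames(out) <- years
    out
  }
  rep_col <- function(name, years) {
    out <- m[, rep(name, length(years)), drop = FALSE]
    colnames(out) <- years
    out
  }
  NF <- grab("N_F[%d]", 1:T); NE <- grab("N_E[%d]", 1:T)
  B <- NF + NE
  Ptot <- grab("N_P2[%d]", 1:T) + grab("N_P3[%d]", 1:T) +
    grab("N_P4[%d]", 1:T) + grab("N_P5[%d]", 1:T) + grab("N_P6[%d]", 1:T)
  P36 <- grab("N_P3[%d]", 1:T) + grab("N_P4[%d]", 1:T) +
    grab("N_P5[%d]", 1:T) + grab("N_P6[%d]", 1:T)
  Sk <- grab("N_S[%d]", 1:T)
  rec <- grab("recruits[%d]", 2:T)
  pulse <- grab("pulse[%d]", 2:T)
  fb <- grab("former_b[%d]", 2:T)
  fs <- grab("former_s[%d]", 2:T)
  I <- grab("I[%d]", 2:T)
  pif <- if (tv) grab("pi_f[%d]", 1:T) else rep_col("pi_f", 1:T)
  pie <- if (tv) grab("pi_e[%d]", 1:T) else rep_col("pi_e", 1:T)
  pp <- if (tv) grab("p_p[%d]", 2:T) else rep_col("p_p", 2:T)
  pr <- m[, "p_r"]

  lambda <- B[, -1L, drop = FALSE] / B[, -T, drop = FALSE]
  colnames(lambda) <- 2:T

  list(
    B = B,
    lambda = lambda,
    phi2 = if (tv) grab("phi2[%d]", 1:(T - 1)) else rep_col("phi2", 1:(T - 1)),
    psi_b = if (tv) grab("psi_b[%d]", 1:(T - 1)) else rep_col("psi_b", 1:(T - 1)),
    psi_s = if (tv) grab("psi_s[%d]", 1:(T - 1)) else rep_col("psi_s", 1:(T - 1)),
    int_recruit = {
      z <- integrative_recruitment(rec, P36[, -1L, drop = FALSE])
      colnames(z) <- 2:T
      z
    },
    imm_rate = {
      z <- I / B[, -1L, drop = FALSE]
      colnames(z) <- 2:T
      z
    },
    present_nb = {
      z <- Ptot[, -1L, drop = FALSE] * pp + Sk[, -1L, drop = FALSE] * pr
      colnames(z) <- 2:T
      z
    },
    pop_success = {
      z <- 2 * (NF * pif + NE * pie) / B
      colnames(z) <- 1:T
      z
    },
    composition = list(former_breeder = fb / B[, -1L, drop = FALSE],
                       former_skipper = fs / B[, -1L, drop = FALSE],
                       local_first_time = rec / B[, -1L, drop = FALSE],
                       immigrant = pulse / B[, -1L, drop = FALSE])
  )
}

# Pick year columns (labels) from a [draw x year] matrix.
year_cols <- function(mat, years) {
  mat[, as.character(years), drop = FALSE]
}

#' Posterior partial correlation between derived series
#'
#' Computes, per posterior draw, the partial correlation between a response
#' series and a (lagged) predictor controlling for further series, then
#' summarises the posterior of the coefficient by its mean, central 95%
#' credible interval and sign-support `P`. Draws in which the coefficient is
#' undefined (zero residual variance, missing values) are dropped and
#' counted.
#'
#' @param response [draw x year] matrix with year labels.
#' @param predictor [draw x year] matrix.
#' @param controls list of [draw x year] matrices (possibly empty).
#' @param response_years years of the response entering the window.
#' @param feature_years years of predictor/controls (same length; typically
#'   `response_years - lag`).
#' @param label optional metadata string.
#' @return list of class `partial_correlation_result`.
#' @export
posterior_partial_correlation <- function(response, predictor, controls = list(),
                                          response_years, feature_years,
                                          label = "") {
  if (length(response_years) != length(feature_years)) {
    bp_stop("response and feature windows differ in length")
  }
  if (length(response_years) < length(controls) + 3L) {
    bp_stop("window too short for the number of controls")
  }
  ry <- year_cols(response, response_years)
  rx <- year_cols(predictor, feature_years)
  rz <- lapply(controls, year_cols, years = feature_years)
  nd <- nrow(ry)
  r <- rep(NA_real_, nd)
  for (i in seq_len(nd)) {
    Z <- if (length(rz)) do.call(cbind, lapply(rz, function(z) z[i, ])) else NULL
    yi <- ry[i, ]; xi <- rx[i, ]
    if (anyNA(yi) || anyNA(xi) || (!is.null(Z) && anyNA(Z))) next
    r[i] <- tryCatch(partial_correlation(yi, xi, Z), error = function(e) NA_real_)
  }
  ok <- !is.na(r)
  if (!any(ok)) bp_stop("partial correlation undefined in every draw")
  rs <- r[ok]
  structure(list(
    mean = mean(rs),
    ci = unname(quantile(rs, c(0.025, 0.975))),
    P = sign_support(rs),
    samples = rs,
    dropped = sum(!ok) / nd,
    label = label
  ), class = "partial_correlation_result")
}

#' @export
print.partial_correlation_result <- function(x, ...) {
  cat(sprintf("%s%.2f [%.2f, %.2f] (P = %.2f)%s\n",
              if (nzchar(x$label)) paste0(x$label, ": ") else "",
              x$mean, x$ci[1], x$ci[2], x$P,
              if (x$dropped > 0) sprintf(" [%.0f%% draws dropped]",
                                         100 * x$dropped) else ""))
  invisible(x)
}

#' Headline association tables
#'
#' Builds the two posterior partial-correlation tables of the analysis:
#' \describe{
#'   \item{growth}{associations of the breeding population growth rate
#'     `lambda[t]` with survival, breeding rates of former breeders and
#'     skippers, the integrative recruitment rate and the immigration rate
#'     (each controlling for the other four), quantifying the contribution of
#'     breeding propensity to population dynamics;}
#'   \item{propensity}{the 4 x 3 matrix of status-specific breeding
#'     propensities at `t` (former breeders, former skippers, pre-breeders,
#'     immigrants) against population breeding success, number of breeders
#'     and present non-breeders at `t - 1`, each cell controlling for the
#'     other two population features.}
#' }
#' The window starts at the third study year so that no quantity from the
#' poorly informed first year enters the correlations. Rates governing the
#' interval `(t-1, t]` are paired with `lambda[t]`.
#'
#' @param draws a `posterior_draws` from a time-varying fit.
#' @return list of class `analysis_tables` with data.frames `growth` (5 rows)
#'   and `propensity` (4 x 3 cells), each row holding mean, CrI bounds and
#'   sign-support `P`.
#' @export
analysis_tables <- function(draws) {
  if (!draws$time_varying) {
    bp_stop("association tables need a time-varying fit")
  }
  T <- draws$n_years
  if (T < 8) bp_stop("study horizon too short for the correlation analyses")
  ds <- derived_series(draws)
  t_resp <- 3:T

  # growth-rate table: response lambda[t], rates of interval (t-1, t]
  rate_series <- list(
    survival = list(s = ds$phi2, years = t_resp - 1L),
    psi_b = list(s = ds$psi_b, years = t_resp - 1L),
    psi_s = list(s = ds$psi_s, years = t_resp - 1L),
    int_recruit = list(s = ds$int_recruit, years = t_resp),
    imm_rate = list(s = ds$imm_rate, years = t_resp)
  )
  growth <- do.call(rbind, lapply(names(rate_series), function(nm) {
    x <- rate_series[[nm]]
    others <- rate_series[setdiff(names(rate_series), nm)]
    # align all features on the response window via their own year indices
    ctrl <- lapply(others, function(o) {
      z <- year_cols(o$s, o$years)
      colnames(z) <- t_resp
      z
    })
    px <- year_cols(x$s, x$years)
    colnames(px) <- t_resp
    res <- posterior_partial_correlation(ds$lambda, px, ctrl,
                                         response_years = t_resp,
                                         feature_years = t_resp,
                                         label = nm)
    data.frame(rate = nm, mean = res$mean, lo = res$ci[1], hi = res$ci[2],
               P = res$P, dropped = res$dropped)
  }))

  # propensity table: response at t, features at t-1
  responses <- list(
    former_breeder = list(s = ds$psi_b, years = t_resp - 1L),
    former_skipper = list(s = ds$psi_s, years = t_resp - 1L),
    pre_breeder = list(s = ds$int_recruit, years = t_resp),
    immigrant = list(s = ds$imm_rate, years = t_resp)
  )
  features <- list(
    pop_success = ds$pop_success,
    n_breeders = ds$B,
    present_nonbreeders = ds$present_nb
  )
  cells <- list()
  for (rn in names(responses)) {
    rsp <- responses[[rn]]
    yresp <- year_cols(rsp$s, rsp$years)
    colnames(yresp) <- t_resp
    for (fn in names(features)) {
      ctrl_names <- setdiff(names(features), fn)
      res <- posterior_partial_correlation(
        yresp, features[[fn]],
        controls = features[ctrl_names],
        response_years = t_resp,
        feature_years = t_resp - 1L,
        label = sprintf("%s ~ %s", rn, fn))
      cells[[length(cells) + 1L]] <- data.frame(
        propensity = rn, feature = fn, mean = res$mean,
        lo = res$ci[1], hi = res$ci[2], P = res$P, dropped = res$dropped)
    }
  }
  propensity <- do.call(rbind, cells)
  rownames(growth) <- rownames(propensity) <- NULL
  structure(list(growth = growth, propensity = propensity),
            class = "analysis_tables")
}

#' @export
print.analysis_tables <- function(x, ...) {
  fmt <- function(d) {
    d$cell <- sprintf("%5.2f [%5.2f, %5.2f] (P = %.2f)", d$mean, d$lo, d$hi, d$P)
    d
  }
  cat("Partial correlations with breeding population growth rate:\n")
  g <- fmt(x$growth)
  for (i in seq_len(nrow(g))) cat(sprintf("  %-12s %s\n", g$rate[i], g$cell[i]))
  cat("\nBreeding propensity (t) vs population features (t-1):\n")
  p <- fmt(x$propensity)
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-15s ~ %-20s %s\n", p$propensity[i], p$feature[i], p$cell[i]))
  }
  invisible(x)
}
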