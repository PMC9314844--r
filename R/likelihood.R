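# The three likelihood components of the integrated model and their sum.

#' State-space count likelihood
#'
#' Log-likelihood of observed breeder counts under the log-normal observation
#' model: `log C[t] ~ Normal(log B[t], sigma_obs)`, including the `1/C[t]`
#' change-of-variable term so the density is for `C`, not `log C`.
#'
#' @param counts observed counts (vector, or data.frame with a `count` column).
#' @param B latent breeder totals (same length, > 0).
#' @param sigma_obs log-scale SD (> 0).
#' @return The log-likelihood (scalar).
#' @export
loglik_counts <- function(counts, B, sigma_obs) {
  if (is.data.frame(counts)) counts <- counts$count
  counts <- as.numeric(counts); B <- as.numeric(B)
  if (length(counts) != length(B)) bp_stop("'counts' and 'B' lengths differ")
  if (any(counts <= 0) || any(B <= 0)) bp_stop("counts and B must be positive")
  if (!is.numeric(sigma_obs) || sigma_obs <= 0) bp_stop("'sigma_obs' must be > 0")
  sum(dnorm(log(counts), log(B), sigma_obs, log = TRUE) - log(counts))
}

# Expand rate/observation objects to full-length arrays for the C++ forward.
cr_param_list <- function(rates, obs) {
  T <- rates$n_years
  list(phi0 = rates$phi0, phi2 = rates$phi2,
       rho3 = rates$rho3, rho4 = rates$rho4,
       rho5 = rates$rho5, rho6 = rates$rho6,
       psib = rates$psi_b, psis = rates$psi_s,
       pY = obs$p_y, pP = obs$p_p, pR = obs$p_r)
}

#' Capture-recapture forward log-likelihood
#'
#' Log-probability of each observation history given ringing, with the latent
#' state sequence (pre-breeder classes, first-time breeder, experienced
#' breeder, skipper, dead) marginalized by the hidden-Markov forward
#' recursion. Emission probabilities place zero mass on status
#' misassignment. Structurally impossible histories yield `-Inf` rather than
#' an error.
#'
#' @param histories a [capture_histories] object.
#' @param rates a [demographic_rates].
#' @param obs an [observation_model].
#' @param per_history return the per-history vector instead of the total.
#' @return Total log-likelihood, or the per-history vector.
#' @export
forward_loglik <- function(histories, rates, obs, per_history = FALSE) {
  if (!inherits(histories, "capture_histories")) {
    bp_stop("'histories' must be a capture_histories object")
  }
  if (rates$n_years != histories$n_years || obs$n_years != histories$n_years) {
    bp_stop("study horizons of histories, rates and observation model differ")
  }
  if (nrow(histories$obs) == 0L) {
    return(if (per_history) numeric(0) else 0)
  }
  p <- cr_param_list(rates, obs)
  ll <- bp_forward(histories$obs, histories$ring_year,
                   p$phi0, p$phi2, p$rho3, p$rho4, p$rho5, p$rho6,
                   p$psib, p$psis, p$pY, p$pP, p$pR, TRUE)
  if (per_history) ll else sum(ll)
}

#' Reproduction likelihood
#'
#' Poisson log-likelihood of annual fledgling totals per pair category, with
#' per-nest rates `2 pi_f` (both mates first-time breeders), `2 pi_e` (both
#' experienced) and, for mixed/unknown pairs, the population rate: the mean of
#' the two weighted by the latent proportions of first-time and experienced
#' breeders.
#'
#' @param table data.frame with columns `year`, `category` (`FF`, `EE`,
#'   `MIX`), `n_nests`, `n_fledglings`.
#' @param pi_f,pi_e per-capita breeding success (scalar or per-year).
#' @param N_F,N_E latent numbers of first-time and experienced breeders per
#'   year (needed in years with MIX nests).
#' @return The log-likelihood (scalar); `-Inf` if fledglings occur at zero
#'   rate.
#' @export
#' @examples
#' tab <- data.frame(year = 1, category = "MIX", n_nests = 100,
#'                   n_fledglings = 64)
#' # weighted population rate: 2*(20*0.16 + 80*0.36)/100 = 0.64 per nest
#' loglik_reproduction(tab, 0.16, 0.36, N_F = 20, N_E = 80)
loglik_reproduction <- function(table, pi_f, pi_e, N_F, N_E) {
  if (nrow(table) == 0L) return(0)
  check_nonneg(table$n_nests, "n_nests")
  check_nonneg(table$n_fledglings, "n_fledglings")
  T <- max(table$year)
  pi_f <- recycle_to(pi_f, T, "pi_f")
  pi_e <- recycle_to(pi_e, T, "pi_e")
  N_F <- recycle_to(N_F, T, "N_F")
  N_E <- recycle_to(N_E, T, "N_E")
  ll <- 0
  for (i in seq_len(nrow(table))) {
    n <- table$n_nests[i]
    if (n == 0L) next
    y <- table$year[i]
    rate <- switch(as.character(table$category[i]),
      FF = 2 * pi_f[y],
      EE = 2 * pi_e[y],
      MIX = {
        B <- N_F[y] + N_E[y]
        if (B <= 0) bp_stop("MIX nests present but no latent breeders")
        2 * (N_F[y] * pi_f[y] + N_E[y] * pi_e[y]) / B
      },
      bp_stop(sprintf("unknown category '%s'", table$category[i]))
    )
    ll <- ll + dpois(table$n_fledglings[i], n * rate, log = TRUE)
  }
  ll
}

#' State-process log-probability of a latent trajectory
#'
#' Joint log-probability of the demographic transitions of a simulated or
#' sampled trajectory under the binomial/Poisson projection model: Poisson
#' yearling production and nested binomial survival, recruitment and breeding
#' decisions. The immigrant pulse is deterministic given `I` and carries no
#' probability mass.
#'
#' @param traj a `trajectory` (or any list with `states` and `branches`).
#' @param rates a [demographic_rates].
#' @return The log-probability (scalar).
#' @export
state_logprob <- function(traj, rates) {
  st <- traj$states
  T <- ncol(st)
  lp <- 0
  for (t in seq_len(T - 1L)) {
    r <- rates_at(rates, t)
    b <- traj$branches[[t]]
    meanY <- (st[7L, t] * r$pi_f + st[8L, t] * r$pi_e) * r$phi0
    lp <- lp + dpois(b[["ynew"]], meanY, log = TRUE) +
      dbinom(b[["sy"]], st[1L, t], r$phi0, log = TRUE) +
      dbinom(b[["sp2"]], st[2L, t], r$phi2, log = TRUE) +
      dbinom(b[["sp3"]], st[3L, t], r$phi2, log = TRUE) +
      dbinom(b[["sp4"]], st[4L, t], r$phi2, log = TRUE) +
      dbinom(b[["sp5"]], st[5L, t], r$phi2, log = TRUE) +
      dbinom(b[["sp6"]], st[6L, t], r$phi2, log = TRUE) +
      dbinom(b[["rec2"]], b[["sp2"]], r$rho[1], log = TRUE) +
      dbinom(b[["rec3"]], b[["sp3"]], r$rho[2], log = TRUE) +
      dbinom(b[["rec4"]], b[["sp4"]], r$rho[3], log = TRUE) +
      dbinom(b[["rec5"]], b[["sp5"]], r$rho[4], log = TRUE) +
      dbinom(b[["sf"]], st[7L, t], r$phi2, log = TRUE) +
      dbinom(b[["fb"]], b[["sf"]], r$psi_b, log = TRUE) +
      dbinom(b[["se"]], st[8L, t], r$phi2, log = TRUE) +
      dbinom(b[["eb"]], b[["se"]], r$psi_b, log = TRUE) +
      dbinom(b[["ss"]], st[9L, t], r$phi2, log = TRUE) +
      dbinom(b[["sb"]], b[["ss"]], r$psi_s, log = TRUE)
  }
  lp
}

#' Joint log-likelihood of the integrated model
#'
#' The sum of the three data-stream components plus the state-process
#' log-probability of the latent trajectory: counts, capture histories and
#' reproduction are conditionally independent given the shared demographic
#' process.
#'
#' @param data list with `counts` (data.frame), `histories`
#'   ([capture_histories] or `NULL`) and `reproduction` (data.frame); a
#'   `study` object works as is.
#' @param rates a [demographic_rates].
#' @param obs an [observation_model].
#' @param traj latent trajectory (states + branches), e.g. the truth record of
#'   a synthetic study.
#' @return The joint log-likelihood, with the four components in attribute
#'   `"components"`.
#' @export
joint_loglik <- function(data, rates, obs, traj) {
  B <- breeders(traj$states)
  T <- ncol(traj$states)
  comp <- c(
    counts = if (!is.null(data$counts) && nrow(data$counts) > 0) {
      loglik_counts(data$counts, B, obs$sigma_obs)
    } else 0,
    capture = if (!is.null(data$histories)) {
      forward_loglik(data$histories, rates, obs)
    } else 0,
    reproduction = if (!is.null(data$reproduction) && nrow(data$reproduction) > 0) {
      loglik_reproduction(data$reproduction, rates$pi_f, rates$pi_e,
                          traj$states[7L, ], traj$states[8L, ])
    } else 0,
    state = state_logprob(traj, rates)
  )
  structure(sum(comp), components = comp)
}
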