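# Synthetic-data generator: emulates the four input streams of the analysis
# (breeder counts, capture histories, reproduction tables, patch-level
# success) from a known latent truth, for testing and calibration.

#' Configuration of a synthetic study
#'
#' Defaults reproduce the study conditions of a stationary kittiwake-like
#' population: mean demographic rates at the values reported for the study
#' population, a constant immigrant pulse that balances the local growth
#' deficit (local-only dominant eigenvalue ~0.91, immigrants ~13% of
#' breeders), about 1700 breeders, and 28 study years. Annual variation is
#' optional: probabilities vary on the logit scale, productivity and
#' immigration on the log scale.
#'
#' @param n_years study horizon (>= 3).
#' @param rates named list of mean demographic rates (see
#'   [demographic_rates]); entries override the defaults.
#' @param rate_sd logit-scale SD of annual variation shared by all probability
#'   rates (0 = constant rates); `pi_f`/`pi_e` use the same SD on log scale.
#' @param imm_mean mean annual number of immigrants.
#' @param imm_log_sd log-scale SD of annual immigration variation.
#' @param dd_psi_b density-dependence coefficient: logit-linear effect of the
#'   scaled breeder total `(B[t] - B[1]) / (0.1 B[1])` on next-interval
#'   `psi_b` (0 = none; negative values emulate competition).
#' @param initial_state length-9 class vector for year 1 (default: the
#'   stationary state under the default rates and pulse).
#' @param sigma_obs log-scale SD of the count observation error.
#' @param p_y,p_p,p_r resighting probabilities (yearlings, older pre-breeders,
#'   recruited individuals); `p_y`/`p_p` may be scalars or length
#'   `n_years - 1`.
#' @param n_marked number of fledglings ringed per year (0 = no histories).
#' @param ringed_fraction probability that a breeder is a ringed, known-history
#'   bird, used to classify nests into the three reproduction categories.
#' @param assortment probability that mates share the same experience class
#'   (0 = random mating by experience). The defaults (0.57, 0.74) are
#'   calibrated so that the long-run shares of the three nest categories
#'   match the study system's observed totals (about 5.4% first-time pairs,
#'   24.3% experienced pairs, 70.2% mixed/unknown).
#' @param n_patches number of habitat patches for the heterogeneity stream.
#' @param failure_link strength in [0, 1] of the link between year quality and
#'   the fraction of near-total-failure patches (0 = homogeneous patches).
#' @param independent_streams draw the count and reproduction streams from
#'   their own independent population realizations (same rates and
#'   immigration series) instead of the one that produced the capture
#'   histories. The default, `FALSE`, mimics a real study where all streams
#'   observe one population; `TRUE` makes the likelihood's between-stream
#'   independence assumption hold exactly, the appropriate design for
#'   calibration/coverage studies of the estimator.
#' @param seed RNG seed; recorded in the output metadata.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_years = 28L,
                             rates = list(),
                             rate_sd = 0,
                             imm_mean = 230,
                             imm_log_sd = 0,
                             dd_psi_b = 0,
                             initial_state = NULL,
                             sigma_obs = 0.05,
                             p_y = 0.05, p_p = 0.81, p_r = 0.998,
                             n_marked = 80L,
                             ringed_fraction = 0.57,
                             assortment = 0.74,
                             n_patches = 30L,
                             failure_link = 0.8,
                             independent_streams = FALSE,
                             seed = 1L) {
  base <- list(phi0 = 0.65, phi2 = 0.81, rho3 = 0.13, rho4 = 0.41,
               rho5 = 0.53, rho6 = 0.67, psi_b = 0.90, psi_s = 0.69,
               pi_f = 0.16, pi_e = 0.36)
  if (length(rates)) {
    bad <- setdiff(names(rates), names(base))
    if (length(bad)) bp_stop(sprintf("unknown rate name(s): %s", paste(bad, collapse = ", ")))
    base[names(rates)] <- rates
  }
  if (is.null(initial_state)) {
    initial_state <- c(Y = 359, P2 = 233, P3 = 164, P4 = 79, P5 = 30, P6 = 8,
                       F = 366, E = 1371, S = 188)
  }
  if (n_years < 3) bp_stop("'n_years' must be >= 3")
  cfg <- structure(list(
    n_years = as.integer(n_years), rates = base, rate_sd = rate_sd,
    imm_mean = imm_mean, imm_log_sd = imm_log_sd, dd_psi_b = dd_psi_b,
    initial_state = initial_state, sigma_obs = sigma_obs,
    p_y = p_y, p_p = p_p, p_r = p_r,
    n_marked = as.integer(n_marked), ringed_fraction = ringed_fraction,
    assortment = assortment, n_patches = as.integer(n_patches),
    failure_link = failure_link,
    independent_streams = isTRUE(independent_streams),
    seed = as.integer(seed)
  ), class = "synthetic_config")
  check_prob(unlist(base[1:8]), "probability rates")
  check_prob(c(cfg$p_y, cfg$p_p, cfg$p_r, ringed_fraction, assortment,
               failure_link), "observation/config probabilities")
  check_nonneg(c(base$pi_f, base$pi_e, sigma_obs, imm_log_sd, rate_sd), "scales")
  cfg
}

# Draw year-varying rates around the configured means (logit scale for
# probabilities, log scale for productivity).
draw_annual_rates <- function(cfg) {
  T <- cfg$n_years
  ni <- T - 1L
  jitter_logit <- function(m, n) plogis(qlogis(m) + rnorm(n, 0, cfg$rate_sd))
  jitter_log <- function(m, n) exp(log(m) + rnorm(n, 0, cfg$rate_sd))
  r <- cfg$rates
  if (cfg$rate_sd > 0) {
    demographic_rates(
      phi0 = jitter_logit(r$phi0, ni), phi2 = jitter_logit(r$phi2, ni),
      rho3 = jitter_logit(r$rho3, ni), rho4 = jitter_logit(r$rho4, ni),
      rho5 = jitter_logit(r$rho5, ni), rho6 = jitter_logit(r$rho6, ni),
      psi_b = jitter_logit(r$psi_b, ni), psi_s = jitter_logit(r$psi_s, ni),
      pi_f = jitter_log(r$pi_f, T), pi_e = jitter_log(r$pi_e, T),
      n_years = T)
  } else {
    demographic_rates(r$phi0, r$phi2, r$rho3, r$rho4, r$rho5, r$rho6,
                      r$psi_b, r$psi_s, r$pi_f, r$pi_e, n_years = T)
  }
}

#' Generate a complete synthetic study
#'
#' Simulates the latent population at the individual level and derives all
#' four observable streams: log-normally noised breeder counts, capture
#' histories of ringed chicks, the year x pair-category reproduction table and
#' the patch-level success table. The full latent truth (states, rates,
#' immigration, individual paths) is returned for recovery tests. Re-running
#' with the same configuration and seed is bit-identical.
#'
#' Density dependence of `psi_b` (if configured) is applied sequentially: the
#' breeding probability over interval `t -> t+1` is shifted on the logit scale
#' by `dd_psi_b * (B[t] - B[1]) / (0.1 B[1])` using the realized breeder total.
#'
#' @param config a [synthetic_config].
#' @return An object of class `study`: list with `counts`, `histories`,
#'   `reproduction`, `patches`, and `truth` (trajectory, rates, observation
#'   model, immigration series, config echo).
#' @export
generate_study <- function(config) {
  cfg <- config
  if (!inherits(cfg, "synthetic_config")) bp_stop("'config' must be a synthetic_config")
  set.seed(cfg$seed)
  T <- cfg$n_years

  rates <- draw_annual_rates(cfg)
  I_series <- if (cfg$imm_log_sd > 0) {
    exp(log(cfg$imm_mean) + rnorm(T - 1L, 0, cfg$imm_log_sd))
  } else rep(cfg$imm_mean, T - 1L)

  traj <- simulate_trajectory(rates, I_series, cfg$initial_state,
                              dd_psi_b = cfg$dd_psi_b)
  rates <- traj$rates  # realized rates (psi_b density-adjusted if configured)

  obs <- observation_model(cfg$p_y, cfg$p_p, cfg$p_r, cfg$sigma_obs, T)
  histories <- observe_histories(traj, obs, n_marked = cfg$n_marked)
  # under independent streams, counts and reproduction observe their own
  # population realizations, so the joint likelihood's independence
  # assumption holds exactly
  traj_counts <- if (cfg$independent_streams) {
    simulate_trajectory(rates, I_series, cfg$initial_state,
                        dd_psi_b = cfg$dd_psi_b)
  } else traj
  traj_repro <- if (cfg$independent_streams) {
    simulate_trajectory(rates, I_series, cfg$initial_state,
                        dd_psi_b = cfg$dd_psi_b)
  } else traj
  counts <- observe_counts(breeders(traj_counts$states), cfg$sigma_obs)
  reproduction <- observe_reproduction(traj_repro$states, rates,
                                       ringed_fraction = cfg$ringed_fraction,
                                       assortment = cfg$assortment)
  quality <- reproduction_success(reproduction)
  patches <- generate_patch_table(T, cfg$n_patches, quality, cfg$failure_link)

  structure(list(
    counts = counts,
    histories = histories,
    reproduction = reproduction,
    patches = patches,
    truth = list(trajectory = traj, rates = rates, observation = obs,
                 I_series = I_series, config = cfg)
  ), class = "study")
}

#' Observe breeder counts with log-normal error
#'
#' `C[t] = exp(Normal(log B[t], sigma_obs))`. Counts are breeder equivalents
#' (two per nest). With `sigma_obs = 0` the counts equal the latent totals.
#'
#' @param B latent breeder totals (all > 0 when `sigma_obs > 0`).
#' @param sigma_obs log-scale SD (>= 0).
#' @return data.frame with columns `year`, `count`.
#' @export
observe_counts <- function(B, sigma_obs) {
  B <- as.numeric(B)
  check_nonneg(sigma_obs, "sigma_obs")
  if (sigma_obs > 0 && any(B <= 0)) {
    bp_stop("latent breeder total is 0: log-normal observation undefined")
  }
  counts <- if (sigma_obs > 0) exp(rnorm(length(B), log(B), sigma_obs)) else B
  data.frame(year = seq_along(B), count = counts)
}

#' Observe capture histories of ringed chicks
#'
#' Rings up to `n_marked` fledglings per year (all fledglings if fewer were
#' produced) and generates their resighting records: each alive
#' individual-year is detected with its class's resighting probability and the
#' reported status is always the true one; dead individuals are never
#' detected.
#'
#' @param traj a `trajectory` from [simulate_trajectory] (inside
#'   [generate_study] the ringed individuals are its simulated chicks).
#' @param obs an [observation_model].
#' @param n_marked chicks ringed per year.
#' @return A [capture_histories] object (empty if `n_marked = 0`).
#' @export
observe_histories <- function(traj, obs, n_marked) {
  T <- ncol(traj$states)
  if (n_marked <= 0L) {
    return(capture_histories(matrix(integer(0), 0L, T), integer(0)))
  }
  ringed <- integer(0)
  ring_year <- integer(0)
  for (t in seq_len(T - 1L)) {
    pool <- traj$chick_ids[[t]]
    if (!length(pool)) next
    take <- if (length(pool) > n_marked) sort(sample(pool, n_marked)) else pool
    ringed <- c(ringed, take)
    ring_year <- c(ring_year, rep(t, length(take)))
  }
  n <- length(ringed)
  om <- matrix(-1L, n, T)
  for (k in seq_len(n)) {
    r <- ring_year[k]
    for (y in (r + 1L):T) {
      cl <- traj$class_mat[ringed[k], y]
      if (cl == 0L) { om[k, y] <- 0L; next }
      p <- if (cl == 1L) obs$p_y[y - 1L] else if (cl <= 6L) obs$p_p[y - 1L] else obs$p_r
      seen <- runif(1L) < p
      om[k, y] <- if (!seen) 0L else if (cl <= 6L) CODE_PREBREEDER else
        if (cl <= 8L) CODE_BREEDER else CODE_SKIPPER
    }
  }
  capture_histories(om, ring_year, id = ringed)
}

#' Observe the reproduction table
#'
#' Assigns the year's nests (`floor(B/2)`) to the three pair categories --
#' both-ringed first-time pairs (`FF`), both-ringed experienced pairs (`EE`)
#' and mixed/unknown pairs (`MIX`) -- using independent ringed-status draws
#' with an optional experience-assortment probability, then draws fledgling
#' totals as Poisson with per-nest rates `2 pi_f`, `2 pi_e` and the
#' experience-weighted population rate.
#'
#' @param states a `population_state` matrix (9 x n_years).
#' @param rates a [demographic_rates] (uses `pi_f[t]`, `pi_e[t]`).
#' @param ringed_fraction probability a breeder is ringed.
#' @param assortment probability that a pair shares the experience class.
#' @return data.frame with columns `year`, `category` (FF/EE/MIX), `n_nests`,
#'   `n_fledglings`.
#' @export
observe_reproduction <- function(states, rates, ringed_fraction, assortment = 0) {
  T <- ncol(states)
  out <- vector("list", T)
  for (t in seq_len(T)) {
    NF <- states[7L, t]; NE <- states[8L, t]
    B <- NF + NE
    nests <- B %/% 2L
    qf <- if (B > 0) NF / B else 0
    # pair experience composition: with prob `assortment` mates match
    pFF <- assortment * qf + (1 - assortment) * qf^2
    pEE <- assortment * (1 - qf) + (1 - assortment) * (1 - qf)^2
    r2 <- ringed_fraction^2  # both mates ringed
    p_cat <- c(FF = r2 * pFF, EE = r2 * pEE)
    p_cat <- c(p_cat, MIX = 1 - sum(p_cat))
    n_cat <- if (nests > 0) drop(rmultinom(1L, nests, p_cat)) else c(FF = 0L, EE = 0L, MIX = 0L)
    rate_mix <- if (B > 0) 2 * (NF * rates$pi_f[t] + NE * rates$pi_e[t]) / B else 0
    fl <- c(rpois(1L, n_cat[1L] * 2 * rates$pi_f[t]),
            rpois(1L, n_cat[2L] * 2 * rates$pi_e[t]),
            rpois(1L, n_cat[3L] * rate_mix))
    out[[t]] <- data.frame(year = t, category = c("FF", "EE", "MIX"),
                           n_nests = as.integer(n_cat),
                           n_fledglings = as.integer(fl))
  }
  do.call(rbind, out)
}

# Year series of realized population breeding success (fledglings per nest).
reproduction_success <- function(repro) {
  agg <- stats::aggregate(cbind(n_nests, n_fledglings) ~ year, data = repro, FUN = sum)
  ifelse(agg$n_nests > 0, agg$n_fledglings / agg$n_nests, NA_real_)
}

#' Generate a patch-level breeding-success table
#'
#' Emulates spatially heterogeneous habitat quality: each year a fraction of
#' patches fails almost completely, and that fraction shrinks as year quality
#' rises, so that the dispersion of patch success (weighted Gini) is
#' negatively coupled to the population mean. With `failure_link = 0` all
#' patches share the year's rate and the Gini stays near zero.
#'
#' @param n_years number of years.
#' @param n_patches number of patches (>= 2).
#' @param quality year series of mean fledglings per nest (recycled).
#' @param failure_link strength in [0, 1] of the quality-failure coupling.
#' @param mean_nests average number of nests per patch-year.
#' @return data.frame with columns `year`, `patch`, `n_nests`, `n_fledglings`.
#' @export
generate_patch_table <- function(n_years, n_patches, quality, failure_link,
                                 mean_nests = 30) {
  if (n_patches < 2) bp_stop("'n_patches' must be >= 2")
  quality <- recycle_to(quality, n_years, "quality")
  q_ref <- max(quality, 1e-8)
  eps <- 0.02  # residual success rate in failed patches
  out <- vector("list", n_years)
  for (t in seq_len(n_years)) {
    q <- max(quality[t], 0)
    # failure fraction: 0 at maximal quality, up to ~0.85 * link in bad years
    pfail <- failure_link * 0.85 * max(0, 1 - q / q_ref)
    failed <- runif(n_patches) < pfail
    # normal-patch rate chosen so the yearly mean matches the quality series
    rate_norm <- if (mean(failed) < 1) {
      max(q - mean(failed) * eps, 0) / max(1 - mean(failed), 1e-8)
    } else eps
    rate <- ifelse(failed, eps, rate_norm)
    nests <- pmax(1L, rpois(n_patches, mean_nests))
    fl <- rpois(n_patches, nests * rate)
    out[[t]] <- data.frame(year = t, patch = seq_len(n_patches),
                           n_nests = nests, n_fledglings = fl)
  }
  do.call(rbind, out)
}

#' @export
print.study <- function(x, ...) {
  T <- nrow(x$counts)
  cat(sprintf("Synthetic study: %d years\n", T))
  cat(sprintf("  counts: %d..%d breeders\n",
              round(min(x$counts$count)), round(max(x$counts$count))))
  cat(sprintf("  histories: %d ringed individuals\n", length(x$histories$id)))
  cat(sprintf("  reproduction: %d nests in total\n", sum(x$reproduction$n_nests)))
  cat(sprintf("  patches: %d patch-years\n", nrow(x$patches)))
  invisible(x)
}
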