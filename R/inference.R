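# Bayesian estimation: priors, initialization, the adaptive
# Metropolis-within-Gibbs driver, convergence diagnostics and posterior
# predictive checks.

#' Prior specification
#'
#' Vague priors with reasonable bounds: Uniform(0, 1) for all probability
#' parameters, Uniform over a bounded positive range for the per-capita
#' productivity rates and the count observation SD, Uniform(-5, 1000) for the
#' annual numbers of immigrants (the negative tail makes "no immigration"
#' testable), and discrete uniform ranges for the initial class sizes
#' (derived from the first count when available).
#'
#' @param B1 rough breeder total in year 1 (e.g. the first count), used to
#'   scale the initial-size ranges; ignored when `init_lo`/`init_hi` given.
#' @param pi_max upper bound of the productivity priors (per-capita rate).
#' @param sigma_max upper bound of the count-error SD prior.
#' @param imm_bounds immigrant-number prior bounds.
#' @param init_lo,init_hi optional length-9 integer bounds for the initial
#'   class sizes.
#' @param init_structure optional length-9 vector of expected initial class
#'   sizes as fractions of `B1` (e.g. the stable structure implied by the
#'   population's long-run rates, appropriate for a near-stationary
#'   population); the ranges become `init_spread * init_structure * B1`.
#'   Without it, generic wide ranges are used; those leave the first-year
#'   class sizes so free that their posterior transient can contaminate
#'   shared rates in reduced (constant-rate) fits.
#' @param init_spread multiplicative band around `init_structure`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(B1 = 2000, pi_max = 1.5, sigma_max = 0.25,
                       imm_bounds = c(-5, 1000),
                       init_lo = NULL, init_hi = NULL,
                       init_structure = NULL, init_spread = c(0.6, 1.6)) {
  if (imm_bounds[1] >= 0) bp_stop("immigrant prior must include negative values")
  if (!is.null(init_structure) && is.null(init_lo) && is.null(init_hi)) {
    if (length(init_structure) != 9L) bp_stop("'init_structure' must have 9 classes")
    init_lo <- as.integer(floor(init_spread[1] * init_structure * B1))
    init_hi <- as.integer(ceiling(init_spread[2] * init_structure * B1))
  }
  if (is.null(init_lo)) init_lo <- rep(0L, 9L)
  if (is.null(init_hi)) {
    mult <- c(Y = 0.6, P2 = 0.45, P3 = 0.35, P4 = 0.25, P5 = 0.15,
              P6 = 0.08, F = 0.8, E = 1.5, S = 0.4)
    init_hi <- as.integer(ceiling(mult * B1))
  }
  if (length(init_lo) != 9L || length(init_hi) != 9L ||
      any(init_hi < init_lo)) {
    bp_stop("invalid initial-size ranges")
  }
  structure(list(
    prob_bounds = c(0, 1),
    p_r_bounds = c(0, 1),
    pi_bounds = c(0, pi_max),
    sigma_bounds = c(1e-3, sigma_max),
    imm_bounds = as.numeric(imm_bounds),
    init_lo = as.integer(init_lo),
    init_hi = as.integer(init_hi)
  ), class = "prior_spec")
}

#' MCMC configuration
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burnin adaptation/burn-in iterations (< `n_iter`).
#' @param thin post-burn-in thinning interval.
#' @param seed RNG seed; chain c uses `seed + 1000 c`.
#' @param time_varying fit year-dependent demographic/detection rates (the
#'   full model) or a single shared value per rate (reduced model).
#' @param adapt tune proposal scales during burn-in (frozen afterwards).
#' @param latent_sweeps latent-state update sweeps per iteration; the latent
#'   branch counts are far cheaper to update than the parameters (which carry
#'   the capture-recapture likelihood), so extra sweeps buy state-space
#'   mixing almost for free.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2L, n_iter = 3000L, n_burnin = 1000L,
                        thin = 2L, seed = 1L, time_varying = TRUE,
                        adapt = TRUE, latent_sweeps = 3L) {
  if (n_burnin >= n_iter) bp_stop("'n_burnin' must be < 'n_iter'")
  if (n_chains < 1L) bp_stop("need at least one chain")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), time_varying = time_varying,
                 adapt = adapt, latent_sweeps = as.integer(latent_sweeps)),
            class = "mcmc_config")
}

# Crude moment estimates used only as MCMC starting values. Resighting of
# recruited birds is near-certain in this system, so year-to-year observed
# transitions of breeders/skippers approximate survival and breeding rates
# directly; overall fledglings-per-nest approximates 2*pi.
moment_inits <- function(prep) {
  # prior midpoints as fallbacks: data-free runs must start neutrally
  out <- list(phi2 = 0.5, psi_b = 0.5, psi_s = 0.5, pi_f = 0.3, pi_e = 0.3)
  tot_n <- sum(prep$repro_n)
  if (tot_n > 0) {
    pooled <- min(max(sum(prep$repro_f) / tot_n / 2, 0.05), 0.7)
    out$pi_f <- out$pi_e <- pooled
    # category-specific rates where the pure categories carry enough nests
    if (sum(prep$repro_n[, 1]) >= 50) {
      out$pi_f <- min(max(sum(prep$repro_f[, 1]) / sum(prep$repro_n[, 1]) / 2,
                          0.02), 0.7)
    }
    if (sum(prep$repro_n[, 2]) >= 50) {
      out$pi_e <- min(max(sum(prep$repro_f[, 2]) / sum(prep$repro_n[, 2]) / 2,
                          0.02), 0.7)
    }
  }
  if (nrow(prep$hobs) > 0) {
    obs <- prep$hobs
    w <- prep$hweight
    T <- ncol(obs)
    n_surv <- n_rec <- 0
    n_bb <- n_b <- n_sb <- n_s <- 0
    for (t in seq_len(T - 1L)) {
      rec_now <- obs[, t] >= 2L
      seen_next <- obs[, t + 1L] > 0L
      n_rec <- n_rec + sum(w[rec_now])
      n_surv <- n_surv + sum(w[rec_now & seen_next])
      b_now <- obs[, t] == 2L
      s_now <- obs[, t] == 3L
      n_b <- n_b + sum(w[b_now & seen_next])
      n_bb <- n_bb + sum(w[b_now & obs[, t + 1L] == 2L])
      n_s <- n_s + sum(w[s_now & seen_next])
      n_sb <- n_sb + sum(w[s_now & obs[, t + 1L] == 2L])
    }
    clamp <- function(x, lo = 0.05, hi = 0.98) min(max(x, lo), hi)
    if (n_rec >= 20) out$phi2 <- clamp(n_surv / n_rec)
    if (n_b >= 20) out$psi_b <- clamp(n_bb / n_b)
    if (n_s >= 20) out$psi_s <- clamp(n_sb / n_s)
  }
  out
}

# Normalize a study/bundle into the arrays the kernel consumes.
prepare_data <- function(data, n_years = NULL) {
  counts <- data$counts
  if (!is.null(counts) && nrow(counts) > 0) {
    T <- max(counts$year)
    cvec <- rep(NA_real_, T)
    cvec[counts$year] <- counts$count
    if (anyNA(cvec)) bp_stop("count years must be contiguous from year 1")
  } else {
    if (is.null(n_years)) bp_stop("'n_years' required when no counts are given")
    T <- as.integer(n_years)
    cvec <- numeric(0)
  }
  hist <- data$histories
  if (is.null(hist) || nrow(hist$obs) == 0L) {
    hobs <- matrix(integer(0), 0L, T)
    hring <- integer(0)
    hw <- numeric(0)
  } else {
    if (hist$n_years != T) bp_stop("history horizon differs from counts")
    pooled <- pool_histories(hist)
    hobs <- pooled$obs
    hring <- pooled$ring_year
    hw <- pooled$weight
  }
  rn <- matrix(0L, T, 3L)
  rfl <- matrix(0L, T, 3L)
  repro <- data$reproduction
  if (!is.null(repro) && nrow(repro) > 0) {
    ci <- match(repro$category, c("FF", "EE", "MIX"))
    if (anyNA(ci)) bp_stop("reproduction categories must be FF/EE/MIX")
    if (any(repro$year < 1 | repro$year > T)) bp_stop("reproduction year outside study window")
    for (i in seq_len(nrow(repro))) {
      rn[repro$year[i], ci[i]] <- rn[repro$year[i], ci[i]] + repro$n_nests[i]
      rfl[repro$year[i], ci[i]] <- rfl[repro$year[i], ci[i]] + repro$n_fledglings[i]
    }
    if (any(rfl[rn == 0L] > 0L)) bp_stop("fledglings recorded for zero nests")
  }
  list(T = T, counts = cvec, repro_n = rn, repro_f = rfl,
       hobs = hobs, hring = hring, hweight = hw)
}

#' Initial parameter and latent-state values
#'
#' Builds a deterministic-given-seed starting point with a finite joint
#' log-likelihood. The well-identified rates start at crude moment estimates
#' from the data (e.g. breeding and survival rates of recruited birds from
#' year-to-year resighting transitions, productivity from the reproduction
#' table), jittered; rates without a cheap direct estimate start at jittered
#' prior midpoints. Latent class sizes are constructed forward from rounded
#' transition expectations, with the immigrant pulse chosen each year so that
#' the latent breeder total tracks the observed count (or the prior mid-range
#' without counts). Starting near self-consistent values keeps the latent
#' states from being dragged away from the counts while the rates burn in.
#'
#' @param prep prepared data (internal form, from a study via [run_mcmc]).
#' @param prior a [prior_spec].
#' @param config an [mcmc_config].
#' @return Named list of initial values (kernel layout).
#' @keywords internal
initialize_state <- function(prep, prior, config) {
  T <- prep$T
  tv <- config$time_varying
  nI <- if (tv) T - 1L else 1L
  nY <- if (tv) T else 1L
  jit <- function(n, m = 0.5, a = 0.08) {
    pmin(pmax(m + runif(n, -a, a), 0.02), 0.98)
  }
  # moment estimates centre the starts; generous jitter overdisperses the
  # chains so that pooled draws do not understate the posterior spread
  mom <- moment_inits(prep)
  init <- list(
    phi0 = jit(nI), phi2 = jit(nI, mom$phi2, 0.05),
    rho3 = jit(nI, 0.2), rho4 = jit(nI, 0.4),
    rho5 = jit(nI, 0.5), rho6 = jit(nI, 0.6),
    psi_b = jit(nI, mom$psi_b, 0.05), psi_s = jit(nI, mom$psi_s, 0.15),
    pi_f = pmax(0.02, mom$pi_f + runif(nY, -0.05, 0.05)),
    pi_e = pmax(0.02, mom$pi_e + runif(nY, -0.05, 0.05)),
    p_y = jit(nI, 0.3), p_p = jit(nI, 0.6),
    p_r = 0.95, sigma_obs = 0.08
  )
  target_B <- if (length(prep$counts)) {
    pmax(round(prep$counts), 2)
  } else {
    rep(round(mean(prior$init_lo[7:8] + prior$init_hi[7:8]) / 2), T)
  }
  frac <- c(Y = 0.21, P2 = 0.13, P3 = 0.09, P4 = 0.05, P5 = 0.02,
            P6 = 0.005, F = 0.2, E = 0.8, S = 0.11)
  N1 <- as.integer(round(frac * target_B[1]))
  N1 <- pmin(pmax(N1, prior$init_lo), prior$init_hi)

  rate_at <- function(v, j) if (tv) v[j] else v[1]
  br <- matrix(0L, 17L, T - 1L)
  rownames(br) <- c("ynew", "sy", "sp2", "sp3", "sp4", "sp5", "sp6",
                    "rec2", "rec3", "rec4", "rec5",
                    "sf", "fb", "se", "eb", "ss", "sb")
  I <- numeric(T - 1L)
  N <- matrix(0L, 9L, T)
  N[, 1L] <- N1
  for (j in seq_len(T - 1L)) {
    piy <- if (tv) init$pi_f[j] else init$pi_f[1]
    pey <- if (tv) init$pi_e[j] else init$pi_e[1]
    f0 <- rate_at(init$phi0, j); f2 <- rate_at(init$phi2, j)
    rr <- c(rate_at(init$rho3, j), rate_at(init$rho4, j),
            rate_at(init$rho5, j), rate_at(init$rho6, j))
    pb <- rate_at(init$psi_b, j); ps <- rate_at(init$psi_s, j)
    st <- N[, j]
    b <- integer(17L)
    b[1] <- round((st[7] * piy + st[8] * pey) * f0)
    b[2] <- round(st[1] * f0)
    b[3:7] <- round(st[2:6] * f2)
    b[8:11] <- round(b[3:6] * rr)
    b[12] <- round(st[7] * f2); b[13] <- round(b[12] * pb)
    b[14] <- round(st[8] * f2); b[15] <- round(b[14] * pb)
    b[16] <- round(st[9] * f2); b[17] <- round(b[16] * ps)
    br[, j] <- b
    Floc <- sum(b[8:11]) + b[7]
    E_next <- b[13] + b[15] + b[17]
    pulse <- max(0, round(target_B[j + 1L] - E_next - Floc))
    pulse <- min(pulse, floor(prior$imm_bounds[2]))
    I[j] <- pulse
    N[1L, j + 1L] <- b[1]
    N[2L, j + 1L] <- b[2]
    N[3L:6L, j + 1L] <- b[3:6] - b[8:11]
    N[7L, j + 1L] <- Floc + pulse
    N[8L, j + 1L] <- E_next
    N[9L, j + 1L] <- (b[12] - b[13]) + (b[14] - b[15]) + (b[16] - b[17])
  }
  c(init, list(I = I, N1 = N1, branches = br))
}

#' Fit the integrated population model by MCMC
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler: single-site reflected
#' random-walk updates for all demographic and observation parameters (the
#' capture-recapture likelihood is evaluated by the marginalized forward
#' algorithm), Metropolis updates for the annual immigrant numbers and the
#' initial class sizes, and a single-site sweep over the latent branch counts
#' of the demographic process. Proposal scales adapt toward a target
#' acceptance rate during burn-in and are frozen afterwards.
#'
#' @param data a `study` from [generate_study], a bundle from [read_bundle],
#'   or a list with `counts`, `histories`, `reproduction` entries (each may be
#'   `NULL`/empty for a data-free, prior-only run).
#' @param prior a [prior_spec]; default scales the initial-size ranges to the
#'   first count.
#' @param config an [mcmc_config].
#' @param n_years study horizon, required only when no counts are supplied.
#' @return An object of class `posterior_draws`.
#' @export
run_mcmc <- function(data, prior = NULL, config = mcmc_config(),
                     n_years = NULL) {
  prep <- prepare_data(data, n_years)
  if (is.null(prior)) {
    B1 <- if (length(prep$counts)) prep$counts[1] else 2000
    prior <- prior_spec(B1 = B1)
  }
  chains <- vector("list", config$n_chains)
  accepts <- vector("list", config$n_chains)
  layout <- NULL
  for (ch in seq_len(config$n_chains)) {
    fit <- NULL
    for (attempt in 1:5) {
      set.seed(config$seed + 1000L * ch + 100000L * (attempt - 1L))
      init <- initialize_state(prep, prior, config)
      fit <- bp_mcmc_kernel(
        prep$T, prep$counts, prep$repro_n, prep$repro_f,
        prep$hobs, prep$hring, prep$hweight,
        config$time_varying, unclass(prior), init,
        config$n_iter, config$n_burnin, config$thin,
        0.44, config$adapt, config$latent_sweeps %||% 3L)
      if (isTRUE(fit$ok)) break
    }
    if (!isTRUE(fit$ok)) {
      bp_stop("could not find a finite starting point after 5 attempts",
              class = "bp_init_error")
    }
    layout <- fit$layout
    m <- fit$draws
    colnames(m) <- draw_colnames(layout)
    chains[[ch]] <- m
    accepts[[ch]] <- fit$accept
  }
  structure(list(chains = chains, accept = accepts,
                 n_years = prep$T, time_varying = config$time_varying,
                 layout = layout, prior = prior, config = config),
            class = "posterior_draws")
}

# Column names matching the kernel's record layout.
draw_colnames <- function(layout) {
  T <- layout$T; nI <- layout$nI; nY <- layout$nY; nP <- layout$nP
  idx <- function(base, n, from = 1L) {
    if (n == 1L) base else sprintf("%s[%d]", base, seq.int(from, from + n - 1L))
  }
  brn <- c("ynew", "sy", "sp2", "sp3", "sp4", "sp5", "sp6",
           "rec2", "rec3", "rec4", "rec5", "sf", "fb", "se", "eb", "ss", "sb")
  c(
    unlist(lapply(c("phi0", "phi2", "rho3", "rho4", "rho5", "rho6",
                    "psi_b", "psi_s"), idx, n = nI)),
    idx("pi_f", nY), idx("pi_e", nY),
    idx("p_y", nP, from = 2L), idx("p_p", nP, from = 2L),
    "p_r", "sigma_obs",
    sprintf("I[%d]", 2:T),
    unlist(lapply(CLASSES, function(cl) sprintf("N_%s[%d]", cl, 1:T))),
    sprintf("recruits[%d]", 2:T),
    sprintf("former_b[%d]", 2:T),
    sprintf("former_s[%d]", 2:T),
    sprintf("pulse[%d]", 2:T),
    unlist(lapply(1:(T - 1L), function(j) sprintf("br_%s[%d]", brn, j))),
    "loglik"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  kept <- nrow(x$chains[[1]])
  cat(sprintf("Posterior draws: %d chain(s) x %d kept iterations (%s model, %d years)\n",
              length(x$chains), kept,
              if (x$time_varying) "time-varying" else "constant-rate",
              x$n_years))
  invisible(x)
}

# Stack all chains into one draws x variables matrix.
draws_matrix <- function(draws, pattern = NULL) {
  m <- do.call(rbind, draws$chains)
  if (!is.null(pattern)) m <- m[, grep(pattern, colnames(m)), drop = FALSE]
  m
}

#' Posterior summary table
#'
#' @param object a `posterior_draws`.
#' @param pattern optional regular expression selecting variables.
#' @param ... unused.
#' @return data.frame with posterior mean, SD and central 95% interval.
#' @export
summary.posterior_draws <- function(object, pattern = NULL, ...) {
  m <- draws_matrix(object, pattern)
  data.frame(
    parameter = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2L, sd),
    q2.5 = apply(m, 2L, quantile, 0.025),
    q97.5 = apply(m, 2L, quantile, 0.975),
    row.names = NULL
  )
}

# --- convergence diagnostics ----------------------------------------------

# Potential scale reduction: ratio of total to mean within-chain variance,
# with the total decomposed exactly into within + between-mean parts (ML
# normalization, equal-length chains). Identical chains give exactly 1;
# disjoint constant chains diverge.
psrf_one <- function(chains_mat_list) {
  vml <- function(x) mean((x - mean(x))^2)
  W <- mean(vapply(chains_mat_list, vml, 0))
  B <- vml(vapply(chains_mat_list, mean, 0))
  if (W + B == 0) return(NA_real_)  # constant in every chain
  if (W == 0) return(Inf)
  sqrt((W + B) / W)
}

# Effective sample size via Geyer's initial positive sequence, summed over
# chains.
ess_one <- function(x) {
  n <- length(x)
  if (n < 8 || var(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 2L, 400L), plot = FALSE,
                   demean = TRUE)$acf[-1L]
  npair <- floor(length(ac) / 2)
  tau <- 1
  for (k in seq_len(npair)) {
    g <- ac[2 * k - 1] + ac[2 * k]
    if (g <= 0) break
    tau <- tau + 2 * g
  }
  min(n / tau, n)
}

#' Convergence diagnostics
#'
#' Per-parameter potential scale reduction factor (requires >= 2 chains) and
#' effective sample size.
#'
#' @param draws a `posterior_draws`.
#' @param pattern regular expression selecting variables (default: demographic
#'   and observation parameters plus immigrant numbers).
#' @return data.frame with columns `parameter`, `psrf`, `ess`.
#' @export
convergence_report <- function(draws, pattern = "^(phi|rho|psi|pi_|p_|sigma|I\\[)") {
  if (length(draws$chains) < 2L) {
    bp_stop("convergence diagnostics need at least 2 chains")
  }
  cols <- grep(pattern, colnames(draws$chains[[1]]), value = TRUE)
  out <- data.frame(
    parameter = cols,
    psrf = vapply(cols, function(cl) {
      psrf_one(lapply(draws$chains, function(m) m[, cl]))
    }, 0),
    ess = vapply(cols, function(cl) {
      sum(vapply(draws$chains, function(m) {
        e <- ess_one(m[, cl]); if (is.na(e)) 0 else e
      }, 0))
    }, 0),
    row.names = NULL
  )
  out$ess[out$ess == 0] <- NA_real_
  out
}

# --- posterior predictive checks ------------------------------------------

#' Posterior predictive checks
#'
#' For the count and reproduction streams, simulates one replicate dataset
#' per (sub-sampled) posterior draw and compares the discrepancy (sum of
#' squared Pearson residuals) of the replicate with that of the observed
#' data. The Bayesian p-value is the fraction of draws in which the replicate
#' discrepancy exceeds the observed one; values near 0 or 1 flag misfit.
#'
#' @param draws a `posterior_draws`.
#' @param data the fitted study/bundle (needs `counts`, `reproduction`).
#' @param max_draws cap on the number of draws used.
#' @return list of class `ppc_result` with elements `p_counts`, `p_repro` and
#'   the discrepancy samples.
#' @export
posterior_predictive_check <- function(draws, data, max_draws = 400L) {
  m <- draws_matrix(draws)
  if (nrow(m) == 0L) bp_stop("no posterior draws")
  T <- draws$n_years
  take <- if (nrow(m) > max_draws) {
    round(seq(1L, nrow(m), length.out = max_draws))
  } else seq_len(nrow(m))
  m <- m[take, , drop = FALSE]
  nd <- nrow(m)

  C <- rep(NA_real_, T)
  if (!is.null(data$counts) && nrow(data$counts) > 0) {
    C[data$counts$year] <- data$counts$count
  }
  have_counts <- !anyNA(C)
  NF <- m[, sprintf("N_F[%d]", 1:T), drop = FALSE]
  NE <- m[, sprintf("N_E[%d]", 1:T), drop = FALSE]
  B <- NF + NE
  tv <- draws$time_varying
  pif <- if (tv) m[, sprintf("pi_f[%d]", 1:T), drop = FALSE] else
    m[, rep("pi_f", T), drop = FALSE]
  pie <- if (tv) m[, sprintf("pi_e[%d]", 1:T), drop = FALSE] else
    m[, rep("pi_e", T), drop = FALSE]

  D_obs_c <- D_rep_c <- rep(NA_real_, nd)
  if (have_counts) {
    sig <- m[, "sigma_obs"]
    for (i in seq_len(nd)) {
      z_obs <- (log(C) - log(B[i, ])) / sig[i]
      z_rep <- rnorm(T)
      D_obs_c[i] <- sum(z_obs^2)
      D_rep_c[i] <- sum(z_rep^2)
    }
  }

  repro <- data$reproduction
  D_obs_r <- D_rep_r <- rep(NA_real_, nd)
  if (!is.null(repro) && nrow(repro) > 0) {
    keep <- repro$n_nests > 0
    rr <- repro[keep, , drop = FALSE]
    for (i in seq_len(nd)) {
      rate <- ifelse(rr$category == "FF", 2 * pif[i, rr$year],
              ifelse(rr$category == "EE", 2 * pie[i, rr$year],
                     2 * (NF[i, rr$year] * pif[i, rr$year] +
                          NE[i, rr$year] * pie[i, rr$year]) /
                       pmax(B[i, rr$year], 1)))
      mu <- rr$n_nests * rate
      ok <- mu > 0
      f_rep <- rpois(nrow(rr), mu)
      D_obs_r[i] <- sum((rr$n_fledglings[ok] - mu[ok])^2 / mu[ok])
      D_rep_r[i] <- sum((f_rep[ok] - mu[ok])^2 / mu[ok])
    }
  }

  structure(list(
    p_counts = if (have_counts) mean(D_rep_c > D_obs_c) else NA_real_,
    p_repro = if (!all(is.na(D_obs_r))) mean(D_rep_r > D_obs_r) else NA_real_,
    discrepancy = list(counts = cbind(observed = D_obs_c, replicated = D_rep_c),
                       reproduction = cbind(observed = D_obs_r,
                                            replicated = D_rep_r))
  ), class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat("Posterior predictive checks (Bayesian p-values)\n")
  cat(sprintf("  counts:       %s\n", format(round(x$p_counts, 3))))
  cat(sprintf("  reproduction: %s\n", format(round(x$p_repro, 3))))
  invisible(x)
}
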