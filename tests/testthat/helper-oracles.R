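# Shared fixtures and independent oracles used across test files.

# Demographic rates at the study population's long-run means.
study_rates <- function(n_years = 28L) {
  demographic_rates(phi0 = 0.65, phi2 = 0.81, rho3 = 0.13, rho4 = 0.41,
                    rho5 = 0.53, rho6 = 0.67, psi_b = 0.90, psi_s = 0.69,
                    pi_f = 0.16, pi_e = 0.36, n_years = n_years)
}

stationary_state <- function() {
  c(Y = 359, P2 = 233, P3 = 164, P4 = 79, P5 = 30, P6 = 8,
    F = 366, E = 1371, S = 188)
}

# Small-population configuration for fast fits.
tiny_config <- function(seed, n_years = 10L, ...) {
  args <- list(n_years = n_years, seed = seed, n_marked = 15L,
               initial_state = round(stationary_state() / 9), imm_mean = 26,
               n_patches = 10L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

random_rates <- function(n_years) {
  demographic_rates(runif(n_years - 1), runif(n_years - 1),
                    runif(n_years - 1), runif(n_years - 1),
                    runif(n_years - 1), runif(n_years - 1),
                    runif(n_years - 1), runif(n_years - 1),
                    runif(n_years, 0, 0.6), runif(n_years, 0, 0.6),
                    n_years = n_years)
}

random_obs <- function(n_years) {
  observation_model(runif(n_years - 1), runif(n_years - 1), runif(1),
                    sigma_obs = 0.1, n_years = n_years)
}

# Brute-force path-enumeration oracle for the capture-recapture likelihood:
# sums the probability of the observation sequence over every latent state
# path (P, F, E, S, dead), entirely independent of the forward recursion.
enum_forward_ll <- function(codes, ring, rates, obs) {
  T <- rates$n_years
  yrs <- (ring + 1):T
  L <- length(yrs)
  paths <- as.matrix(expand.grid(rep(list(1:5), L)))
  tot <- 0
  for (p in seq_len(nrow(paths))) {
    st <- paths[p, ]
    pr <- 1
    prev <- 1  # chick: pre-breeder of age 0
    for (k in seq_len(L)) {
      y <- yrs[k]; j <- y - 1; a <- y - ring
      s <- if (a <= 2) rates$phi0[j] else rates$phi2[j]
      f2 <- rates$phi2[j]; pb <- rates$psi_b[j]; ps <- rates$psi_s[j]
      rec <- if (a == 3) rates$rho3[j] else if (a == 4) rates$rho4[j] else
        if (a == 5) rates$rho5[j] else if (a == 6) rates$rho6[j] else
          if (a >= 7) 1 else 0
      cur <- st[k]
      tp <- if (prev == 1) c(s * (1 - rec), s * rec, 0, 0, 1 - s)[cur] else
        if (prev %in% c(2, 3)) c(0, 0, f2 * pb, f2 * (1 - pb), 1 - f2)[cur] else
          if (prev == 4) c(0, 0, f2 * ps, f2 * (1 - ps), 1 - f2)[cur] else
            c(0, 0, 0, 0, 1)[cur]
      pr <- pr * tp
      if (pr == 0) break
      o <- codes[k]
      pdet <- if (cur == 1) (if (a == 1) obs$p_y[y - 1] else obs$p_p[y - 1]) else obs$p_r
      em <- if (cur == 5) (if (o == 0) 1 else 0) else
        if (o == 0) 1 - pdet else
          if (o == 1 && cur == 1) pdet else
            if (o == 2 && cur %in% c(2, 3)) pdet else
              if (o == 3 && cur == 4) pdet else 0
      pr <- pr * em
      if (pr == 0) break
      prev <- cur
    }
    tot <- tot + pr
  }
  log(tot)
}

# Single history as a capture_histories object (optionally unvalidated).
one_history <- function(codes, ring, n_years, validate = TRUE) {
  om <- matrix(-1L, 1, n_years)
  om[1, (ring + 1):n_years] <- as.integer(codes)
  capture_histories(om, ring, validate = validate)
}

# All observation-code sequences of a given length.
all_code_seqs <- function(L) {
  as.matrix(expand.grid(rep(list(0:3), L)))
}
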